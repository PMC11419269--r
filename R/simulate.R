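#' Simulate a sensorgram family over a concentration series
#'
#' Generates one 1:1 Langmuir sensorgram per analyte concentration at a
#' given dissociation constant. Only `KD` is printed in affinity tables,
#' so any (kon, koff) factorization is accepted; the default fixes
#' `koff = 0.01/s` and derives `kon = koff/KD`. Noise and drift are seeded
#' and fully reproducible; the generator parameters are embedded in every
#' trace's metadata.
#'
#' @param KD Dissociation constant, M.
#' @param concentrations Analyte concentrations, M (non-empty).
#' @param koff Dissociation rate, 1/s (default 0.01).
#' @param kon Association rate; overrides `koff/KD` factorization if given.
#' @param Rmax Maximal response, RU.
#' @param noise_sd Gaussian noise sd, RU.
#' @param drift_slope Linear drift, RU/s.
#' @param seed Integer seed (required when `noise_sd > 0`); trace i uses
#'   `seed + i` so the family is jointly reproducible.
#' @param t_baseline,t_assoc,t_dissoc,dt Phase timing, s.
#' @return List of `sensorgram`s, one per concentration.
#' @export
make_sensorgram_family <- function(KD, concentrations, koff = 0.01,
                                   kon = NULL, Rmax = 1, noise_sd = 0,
                                   drift_slope = 0, seed = NULL,
                                   t_baseline = 60, t_assoc = 600,
                                   t_dissoc = 600, dt = 1) {
  if (KD <= 0) stop("'KD' must be positive")
  if (!length(concentrations)) stop("empty concentration series")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise is simulated")
  if (is.null(kon)) kon <- koff / KD
  params <- kinetic_params(kon = kon, koff = koff, Rmax = Rmax)
  lapply(seq_along(concentrations), function(i)
    simulate_binding(params, concentrations[i], t_baseline = t_baseline,
                     t_assoc = t_assoc, t_dissoc = t_dissoc, dt = dt,
                     noise_sd = noise_sd, drift_slope = drift_slope,
                     seed = if (is.null(seed)) NULL else seed + i,
                     sensor_id = sprintf("S%02d", i)))
}

#' Simulate a biphasic (two-component) sensorgram family
#'
#' Pointwise weighted sum of two 1:1 components, emulating the biphasic
#' traces produced by oligomeric analytes for which a single-exponential
#' 1:1 fit is not appropriate.
#'
#' @param params_fast,params_slow `kinetic_params` of the two components.
#' @param weight Weight of the fast component, in (0, 1).
#' @param concentrations Analyte concentrations, M.
#' @param noise_sd,seed,t_baseline,t_assoc,t_dissoc,dt As in
#'   [make_sensorgram_family()].
#' @return List of `sensorgram`s. Identical components are warned about
#'   (the mixture degenerates to a 1:1 trace).
#' @export
make_biphasic_family <- function(params_fast, params_slow, weight,
                                 concentrations, noise_sd = 0, seed = NULL,
                                 t_baseline = 60, t_assoc = 600,
                                 t_dissoc = 600, dt = 1) {
  stopifnot(inherits(params_fast, "kinetic_params"),
            inherits(params_slow, "kinetic_params"))
  if (weight <= 0 || weight >= 1) stop("'weight' must be in (0, 1)")
  if (!length(concentrations)) stop("empty concentration series")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise is simulated")
  if (isTRUE(all.equal(unclass(params_fast), unclass(params_slow))))
    warning("identical components: mixture reduces to a 1:1 trace")
  lapply(seq_along(concentrations), function(i) {
    conc <- concentrations[i]
    f <- simulate_binding(params_fast, conc, t_baseline, t_assoc, t_dissoc,
                          dt)
    s <- simulate_binding(params_slow, conc, t_baseline, t_assoc, t_dissoc,
                          dt)
    out <- f
    out$signal <- weight * f$signal + (1 - weight) * s$signal
    if (noise_sd > 0) {
      set.seed(seed + i)
      out$signal <- out$signal + stats::rnorm(nrow(out), 0, noise_sd)
    }
    attr(out, "sensor_id") <- sprintf("B%02d", i)
    meta <- attr(out, "meta")
    meta$params <- NULL
    meta$components <- list(fast = params_fast, slow = params_slow,
                            weight = weight)
    meta$noise_sd <- noise_sd
    meta$seed <- if (is.null(seed)) NULL else seed + i
    attr(out, "meta") <- meta
    out
  })
}

# residues whose hydropathy can be opposed by >= min_gap on the scale
feasible_motif_residues <- function(scale, min_gap) {
  names(scale)[vapply(names(scale), function(r) {
    h <- scale[[r]]
    any(sign(scale) != sign(h) & abs(scale - h) >= min_gap)
  }, logical(1))]
}

#' Generate a sequence pair with a planted complementary window
#'
#' Builds a random motif and a random target sequence, then overwrites one
#' window of the target with residues chosen, position by position, to
#' oppose the motif's hydrophobicity sign with at least `min_gap` index
#' difference. The planted window therefore has 100 percent match and
#' complementarity >= `min_gap / 9` by construction, giving the screen a
#' labelled benchmark with known ground truth.
#'
#' @param motif_length,target_length Lengths in residues.
#' @param insert_position 1-based start of the planted window in the
#'   target.
#' @param seed Integer seed (mandatory).
#' @param scale Hydropathy scale.
#' @param min_gap Minimum per-pair absolute index difference in the
#'   planted window (default 5, so C >= 5/9 > 0.5). Constraints that no
#'   residue can satisfy are rejected.
#' @return List with `motif`, `target` (residue strings) and `truth`
#'   (planted start/end, orientation, seed, min_gap).
#' @export
make_complementary_pair <- function(motif_length, target_length,
                                    insert_position, seed,
                                    scale = kd_hydropathy(), min_gap = 5) {
  scale <- validate_scale(scale)
  if (motif_length < 2L) stop("'motif_length' must be >= 2")
  if (insert_position < 1L ||
      insert_position + motif_length - 1L > target_length)
    stop("planted window does not fit in the target")
  if (min_gap > 9) stop("'min_gap' exceeds the scale span; impossible")
  pool <- feasible_motif_residues(scale, min_gap)
  if (!length(pool))
    stop("no residue admits an opposite-sign partner at this 'min_gap'")
  set.seed(seed)
  motif <- sample(pool, motif_length, replace = TRUE)
  target <- sample(names(scale), target_length, replace = TRUE)
  complement <- vapply(motif, function(r) {
    h <- scale[[r]]
    ok <- names(scale)[sign(scale) != sign(h) & abs(scale - h) >= min_gap]
    if (length(ok) == 1L) ok else sample(ok, 1L)
  }, character(1))
  w <- insert_position:(insert_position + motif_length - 1L)
  target[w] <- complement
  list(motif = paste(motif, collapse = ""),
       target = paste(target, collapse = ""),
       truth = list(start = insert_position,
                    end = insert_position + motif_length - 1L,
                    orientation = "forward", seed = seed,
                    min_gap = min_gap))
}
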