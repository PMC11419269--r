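#' Describe a sequential competition-binding assay
#'
#' A sequential BLI competition experiment: the receptor-loaded sensor is
#' dipped into the first ligand (or buffer for the control arm), moved to
#' buffer for dissociation, then moved into the second ligand. The first
#' ligand is absent from the second-association well, so bound competitor
#' can only dissociate during the second association.
#'
#' @param first_ligand,second_ligand Ligand labels.
#' @param conc_first First-ligand concentration, M (0 = no-competitor
#'   control arm).
#' @param conc_second Second-ligand concentration, M (> 0).
#' @param t_baseline,t_assoc1,t_dissoc,t_assoc2 Phase durations, s.
#' @param dt Sampling interval, s.
#' @return `competition_assay` object.
#' @export
competition_assay <- function(first_ligand, conc_first, second_ligand,
                              conc_second, t_baseline = 60, t_assoc1 = 600,
                              t_dissoc = 300, t_assoc2 = 600, dt = 1) {
  if (conc_first < 0 || conc_second <= 0)
    stop("'conc_first' must be >= 0 and 'conc_second' > 0")
  if (any(c(t_assoc1, t_dissoc, t_assoc2) <= 0))
    stop("phase durations must be positive")
  structure(list(first_ligand = first_ligand, conc_first = conc_first,
                 second_ligand = second_ligand, conc_second = conc_second,
                 t_baseline = t_baseline, t_assoc1 = t_assoc1,
                 t_dissoc = t_dissoc, t_assoc2 = t_assoc2, dt = dt),
            class = "competition_assay")
}

# integrate one phase of the two-species binding model
integrate_phase <- function(state, t0, t1, dt, cA, cB, pA, pB, Rmax,
                            shared_site) {
  times <- seq(t0, t1, by = dt)
  deriv <- function(t, y, parms) {
    RA <- y[1L]; RB <- y[2L]
    if (shared_site) {
      free <- Rmax - RA - RB
      list(c(pA$kon * cA * free - pA$koff * RA,
             pB$kon * cB * free - pB$koff * RB))
    } else {
      list(c(pA$kon * cA * (pA$Rmax - RA) - pA$koff * RA,
             pB$kon * cB * (pB$Rmax - RB) - pB$koff * RB))
    }
  }
  sol <- deSolve::ode(y = state, times = times, func = deriv, parms = NULL,
                      rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0) stop("ODE integration failed")
  sol
}

#' Simulate a sequential competition-binding sensorgram
#'
#' Integrates the two-species binding kinetics through the four phases of
#' a sequential competition assay. Under the shared-site model both
#' ligands compete for one pool of sites:
#' `dRA/dt = konA * cA * (Rmax - RA - RB) - koffA * RA` (and symmetrically
#' for B), so total occupancy never exceeds `Rmax`. Under the
#' independent-sites model each ligand binds its own sites and the signals
#' add.
#'
#' @param params_first,params_second `kinetic_params` for the first and
#'   second ligand.
#' @param assay `competition_assay`.
#' @param shared_site Logical (default TRUE).
#' @param Rmax Total site capacity for the shared-site model; defaults to
#'   `params_first$Rmax`.
#' @param noise_sd,seed Optional additive Gaussian noise.
#' @return `sensorgram` with phases `baseline`/`assoc1`/`dissoc1`/`assoc2`
#'   and meta columns `RA`, `RB` (per-species occupancy) in the metadata.
#' @export
simulate_competition <- function(params_first, params_second, assay,
                                 shared_site = TRUE,
                                 Rmax = params_first$Rmax,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params_first, "kinetic_params"),
            inherits(params_second, "kinetic_params"),
            inherits(assay, "competition_assay"))
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise is simulated")
  a <- assay
  t1 <- a$t_baseline; t2 <- t1 + a$t_assoc1; t3 <- t2 + a$t_dissoc
  t4 <- t3 + a$t_assoc2
  segs <- list(
    baseline = c(0, t1, 0, 0),
    assoc1   = c(t1, t2, a$conc_first, 0),
    dissoc1  = c(t2, t3, 0, 0),
    assoc2   = c(t3, t4, 0, a$conc_second))
  state <- c(RA = 0, RB = 0)
  time <- numeric(); RA <- numeric(); RB <- numeric(); phase <- character()
  for (nm in names(segs)) {
    s <- segs[[nm]]
    sol <- integrate_phase(state, s[1L], s[2L], a$dt, s[3L], s[4L],
                           params_first, params_second, Rmax, shared_site)
    # a boundary sample opens the new phase (state is continuous there)
    n <- nrow(sol)
    keep <- if (nm == "assoc2") seq_len(n) else seq_len(n - 1L)
    time <- c(time, sol[keep, "time"])
    RA <- c(RA, sol[keep, "RA"]); RB <- c(RB, sol[keep, "RB"])
    phase <- c(phase, rep(nm, length(keep)))
    state <- c(RA = unname(sol[n, "RA"]), RB = unname(sol[n, "RB"]))
  }
  signal <- RA + RB
  if (noise_sd > 0) {
    set.seed(seed)
    signal <- signal + stats::rnorm(length(signal), 0, noise_sd)
  }
  sg <- new_sensorgram(time, signal, phase, a$conc_second,
                       sensor_id = paste0(a$first_ligand, "->",
                                          a$second_ligand),
                       meta = list(assay = a, shared_site = shared_site,
                                   Rmax = Rmax, RA = RA, RB = RB,
                                   noise_sd = noise_sd, seed = seed))
  sg
}

#' Second-association step height of a competition trace
#'
#' The binding magnitude of the second ligand: signal at the end of the
#' second association minus signal at its start. Measuring a step height
#' rather than an absolute level insulates the metric against incomplete
#' dissociation of the first ligand.
#'
#' @param sg `sensorgram` with an `assoc2` phase.
#' @return Response units.
#' @export
extract_assoc2_magnitude <- function(sg) {
  i <- which(sg$phase == "assoc2")
  if (!length(i)) stop("sensorgram has no 'assoc2' phase")
  sg$signal[i[length(i)]] - sg$signal[i[1L]]
}

#' Percent decrease of the second-association signal
#'
#' `100 * (1 - mag_with / mag_without)`, the standard competition metric:
#' 100 percent is a complete block, 0 percent no competition. Values above
#' 100 (the competitor arm's step height went negative) are clipped to
#' 100; negative values (enhancement) are passed through with a warning.
#'
#' @param mag_with Second-association magnitude with competitor pre-bound.
#' @param mag_without Magnitude of the no-competitor control arm (> 0).
#' @return Percentage.
#' @examples
#' percent_decrease(0.886, 1)  # 11.4
#' @export
percent_decrease <- function(mag_with, mag_without) {
  if (!is.numeric(mag_without) || mag_without <= 0)
    stop("'mag_without' must be a positive number")
  pd <- 100 * (1 - mag_with / mag_without)
  if (pd < 0) warning("second association enhanced in competitor arm")
  min(pd, 100)
}

#' Classify a competition result
#'
#' @param pd Percent decrease.
#' @param full_block Threshold for `"full-block"` (default 90).
#' @param none Threshold below which the result is `"none"` (default 10).
#' @return `"full-block"`, `"partial"` or `"none"`.
#' @export
classify_competition <- function(pd, full_block = 90, none = 10) {
  if (pd >= full_block) "full-block" else if (pd < none) "none" else "partial"
}

#' Titration block curve for a competition series
#'
#' Simulates a sequential competition assay over a series of first-ligand
#' concentrations (against the shared no-competitor control) and tabulates
#' the percent decrease of the second-association magnitude.
#'
#' @param conc_first Strictly increasing first-ligand concentrations, M;
#'   may include 0 (it is the control arm regardless).
#' @param params_first,params_second `kinetic_params`.
#' @param assay Template `competition_assay`; its `conc_first` is replaced
#'   by each titration point.
#' @param shared_site,Rmax Passed to [simulate_competition()].
#' @param block_level Percent decrease counted as a complete block
#'   (default 95).
#' @return data.frame `conc_first`, `percent_decrease`, `classification`,
#'   with attribute `lowest_complete_block` (lowest concentration reaching
#'   `block_level`, or `NA`).
#' @export
titration_block_curve <- function(conc_first, params_first, params_second,
                                  assay, shared_site = TRUE,
                                  Rmax = params_first$Rmax,
                                  block_level = 95) {
  if (!length(conc_first)) stop("empty titration series")
  if (is.unsorted(conc_first, strictly = TRUE))
    stop("'conc_first' must be strictly increasing")
  arm <- function(cf) {
    a <- assay; a$conc_first <- cf
    simulate_competition(params_first, params_second, a,
                         shared_site = shared_site, Rmax = Rmax)
  }
  mag0 <- extract_assoc2_magnitude(arm(0))
  pd <- vapply(conc_first, function(cf)
    percent_decrease(extract_assoc2_magnitude(arm(cf)), mag0), numeric(1))
  out <- data.frame(conc_first = conc_first, percent_decrease = pd)
  out$classification <- vapply(pd, classify_competition, character(1))
  hit <- which(pd >= block_level)
  attr(out, "lowest_complete_block") <-
    if (length(hit)) conc_first[min(hit)] else NA_real_
  out
}
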