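#' Kinetic parameters of a 1:1 interaction
#'
#' @param kon Association rate constant, 1/(M*s).
#' @param koff Dissociation rate constant, 1/s.
#' @param Rmax Maximal response, response units (nm shift).
#' @return `kinetic_params` object; `KD = koff/kon` is derived.
#' @examples
#' kinetic_params(kon = 1e5, koff = 1e-2)$KD  # 100 nM
#' @export
kinetic_params <- function(kon, koff, Rmax = 1) {
  if (any(c(kon, koff, Rmax) <= 0)) stop("kon, koff and Rmax must be > 0")
  structure(list(kon = kon, koff = koff, Rmax = Rmax, KD = koff / kon),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> kon = %.3g /M/s, koff = %.3g /s, KD = %.3g M, Rmax = %.3g RU\n",
    x$kon, x$koff, x$KD, x$Rmax))
  invisible(x)
}

new_sensorgram <- function(time, signal, phase, analyte_conc,
                           sensor_id = "S1", meta = list()) {
  sg <- data.frame(time = time, signal = signal, phase = phase,
                   stringsAsFactors = FALSE)
  attr(sg, "analyte_conc") <- analyte_conc
  attr(sg, "sensor_id") <- sensor_id
  attr(sg, "meta") <- meta
  class(sg) <- c("sensorgram", "data.frame")
  sg
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> %s at %.4g M: %d points, phases %s\n",
              attr(x, "sensor_id"), attr(x, "analyte_conc"), nrow(x),
              paste(unique(x$phase), collapse = "/")))
  invisible(x)
}

# closed-form 1:1 Langmuir response over baseline/association/dissociation
one_to_one_response <- function(t, params, conc, t_assoc_start,
                                t_dissoc_start) {
  kobs <- params$kon * conc + params$koff
  Req <- params$Rmax * conc / (conc + params$KD)
  r <- numeric(length(t))
  a <- t >= t_assoc_start & t < t_dissoc_start
  d <- t >= t_dissoc_start
  r[a] <- Req * (1 - exp(-kobs * (t[a] - t_assoc_start)))
  R_end <- Req * (1 - exp(-kobs * (t_dissoc_start - t_assoc_start)))
  r[d] <- R_end * exp(-params$koff * (t[d] - t_dissoc_start))
  r
}

#' Simulate a 1:1 Langmuir sensorgram
#'
#' Association follows `R(t) = Req * (1 - exp(-kobs * t))` with
#' `kobs = kon * conc + koff` and `Req = Rmax * conc / (conc + KD)`;
#' dissociation decays single-exponentially with `koff` from the response
#' reached at the end of association. Optional additive Gaussian noise and
#' linear baseline drift emulate instrument imperfections.
#'
#' @param params `kinetic_params`.
#' @param conc Analyte concentration, M (0 gives a flat zero trace).
#' @param t_baseline,t_assoc,t_dissoc Phase durations, s.
#' @param dt Sampling interval, s.
#' @param noise_sd Gaussian noise standard deviation, response units.
#' @param drift_slope Linear drift, response units per second.
#' @param seed Integer seed; mandatory whenever `noise_sd > 0`.
#' @param sensor_id Sensor label.
#' @return `sensorgram` (data.frame `time`, `signal`, `phase` plus
#'   metadata attributes).
#' @export
simulate_binding <- function(params, conc, t_baseline = 60, t_assoc = 600,
                             t_dissoc = 600, dt = 1, noise_sd = 0,
                             drift_slope = 0, seed = NULL,
                             sensor_id = "S1") {
  stopifnot(inherits(params, "kinetic_params"))
  if (conc < 0) stop("analyte concentration must be non-negative")
  if (t_assoc <= 0 || t_dissoc <= 0) stop("phase durations must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (noise_sd > 0 && is.null(seed))
    stop("a seed is required when noise is simulated")
  t <- seq(0, t_baseline + t_assoc + t_dissoc, by = dt)
  ta <- t_baseline; td <- t_baseline + t_assoc
  signal <- one_to_one_response(t, params, conc, ta, td)
  phase <- ifelse(t < ta, "baseline",
                  ifelse(t < td, "association", "dissociation"))
  if (drift_slope != 0) signal <- signal + drift_slope * t
  if (noise_sd > 0) {
    set.seed(seed)
    signal <- signal + stats::rnorm(length(t), 0, noise_sd)
  }
  new_sensorgram(t, signal, phase, conc, sensor_id,
                 meta = list(params = params, noise_sd = noise_sd,
                             drift_slope = drift_slope, seed = seed,
                             t_assoc_start = ta, t_dissoc_start = td))
}

#' Double-reference subtraction
#'
#' Standard BLI referencing: the corrected trace is the sample minus the
#' loaded-sensor-in-buffer trace (drift/dissociation of the immobilized
#' protein) minus the unloaded-sensor-in-analyte trace (nonspecific analyte
#' signal), pointwise on a common time grid. With `align = TRUE` each
#' trace's mean baseline is subtracted first.
#'
#' @param sample,loaded_in_buffer,reference_in_analyte `sensorgram`s on the
#'   same time grid.
#' @param align Subtract per-trace mean baseline first (default TRUE).
#' @param tol Maximum tolerated time-grid discrepancy, s.
#' @return Corrected `sensorgram`.
#' @export
double_reference <- function(sample, loaded_in_buffer, reference_in_analyte,
                             align = TRUE, tol = 1e-6) {
  traces <- list(sample, loaded_in_buffer, reference_in_analyte)
  n <- vapply(traces, nrow, integer(1))
  if (length(unique(n)) != 1L ||
      max(abs(loaded_in_buffer$time - sample$time)) > tol ||
      max(abs(reference_in_analyte$time - sample$time)) > tol)
    stop("sensorgrams are not on a common time grid")
  sig <- lapply(traces, function(x) {
    if (align && any(x$phase == "baseline"))
      x$signal - mean(x$signal[x$phase == "baseline"])
    else x$signal
  })
  out <- sample
  out$signal <- sig[[1L]] - sig[[2L]] - sig[[3L]]
  meta <- attr(out, "meta"); meta$double_referenced <- TRUE
  attr(out, "meta") <- meta
  out
}

#' Extract the equilibrium response from an association phase
#'
#' Mean signal over the final fraction of the association phase. The trace
#' is flagged as not equilibrated when the signal is still rising across
#' the window (linear slope over the window projected over the association
#' phase exceeds 2 percent of the extracted value).
#'
#' @param sg `sensorgram` with an association phase.
#' @param window_fraction Fraction of the association phase averaged
#'   (default 0.1).
#' @return Numeric Req with attribute `equilibrated` (logical); a warning
#'   is raised for non-equilibrated traces.
#' @export
extract_req <- function(sg, window_fraction = 0.1) {
  a <- which(sg$phase %in% c("association", "assoc1"))
  if (!length(a)) stop("no association phase in sensorgram")
  nw <- max(3L, ceiling(length(a) * window_fraction))
  if (nw > length(a)) stop("association window shorter than 3 samples")
  w <- a[(length(a) - nw + 1L):length(a)]
  req <- mean(sg$signal[w])
  dur <- sg$time[a[length(a)]] - sg$time[a[1L]]
  slope <- stats::coef(stats::lm(sg$signal[w] ~ sg$time[w]))[[2L]]
  equil <- abs(req) < .Machine$double.eps ||
    abs(slope * dur) <= 0.02 * abs(req)
  if (!equil)
    warning("association phase not equilibrated; Req underestimates the plateau")
  structure(req, equilibrated = equil)
}

fit_result <- function(params, se, residual_rms, converged, model,
                       biphasic_flag = FALSE, details = NULL) {
  structure(list(params = params, se = se, residual_rms = residual_rms,
                 converged = converged, model = model,
                 biphasic_flag = biphasic_flag, details = details),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> model = %s, converged = %s\n", x$model,
              x$converged))
  if (!is.null(x$params$KD))
    cat(sprintf("  KD = %.4g M%s\n", x$params$KD,
                if (!is.null(x$se[["KD"]]) && is.finite(x$se[["KD"]]))
                  sprintf(" (se %.2g)", x$se[["KD"]]) else ""))
  cat(sprintf("  residual RMS = %.3g RU; biphasic = %s\n",
              x$residual_rms, x$biphasic_flag))
  invisible(x)
}

#' Steady-state fit of equilibrium responses
#'
#' Nonlinear least-squares fit of the one-site binding isotherm
#' `Req(c) = Rmax * c / (c + KD)` to equilibrium responses over an analyte
#' concentration series.
#'
#' @param concentrations Analyte concentrations, M (>= 4 points).
#' @param req Equilibrium responses, response units.
#' @return `fit_result` with `params$KD`, `params$Rmax`, standard errors,
#'   and residual RMS. A series without curvature (all points far below
#'   the half-saturation point) is reported as non-convergent.
#' @export
fit_steady_state <- function(concentrations, req) {
  if (length(concentrations) != length(req))
    stop("'concentrations' and 'req' must have equal length")
  if (length(concentrations) < 4L)
    stop("steady-state fit needs at least 4 concentration points")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  Rmax0 <- max(req) * 1.2
  KD0 <- concentrations[which.min(abs(req - max(req) / 2))]
  df <- data.frame(c = concentrations, r = req)
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ Rmax * c / (c + KD), data = df,
                      start = list(Rmax = Rmax0, KD = KD0),
                      lower = c(0, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(fit_result(list(KD = NA_real_, Rmax = NA_real_), NULL,
                      NA_real_, converged = FALSE, model = "steady-state",
                      details = conditionMessage(fit)))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Rmax = NA_real_, KD = NA_real_))
  if (co[["KD"]] > 10 * max(concentrations))
    return(fit_result(list(KD = co[["KD"]], Rmax = co[["Rmax"]]),
                      list(KD = se[["KD"]], Rmax = se[["Rmax"]]),
                      sqrt(mean(stats::residuals(fit)^2)),
                      converged = FALSE, model = "steady-state",
                      details = "no curvature: series entirely in the linear regime"))
  fit_result(list(KD = co[["KD"]], Rmax = co[["Rmax"]]),
             list(KD = se[["KD"]], Rmax = se[["Rmax"]]),
             sqrt(mean(stats::residuals(fit)^2)),
             converged = TRUE, model = "steady-state", details = fit)
}

# model responses for a list of sensorgrams given log-parameters
kinetic_model_residuals <- function(logpar, sensorgrams, observed,
                                    ncomp = 1L) {
  pred <- kinetic_model_predict(logpar, sensorgrams, ncomp)
  observed - pred
}

kinetic_model_predict <- function(logpar, sensorgrams, ncomp = 1L) {
  p <- exp(logpar)
  unlist(lapply(sensorgrams, function(sg) {
    keep <- sg$phase %in% c("association", "dissociation")
    t <- sg$time[keep]
    ta <- min(sg$time[sg$phase == "association"])
    td <- min(sg$time[sg$phase == "dissociation"])
    conc <- attr(sg, "analyte_conc")
    r <- 0
    for (k in seq_len(ncomp)) {
      pk <- kinetic_params(p[3 * k - 2], p[3 * k - 1], p[3 * k])
      r <- r + one_to_one_response(t, pk, conc, ta, td)
    }
    r
  }))
}

#' Global 1:1 kinetic fit across a concentration series
#'
#' Fits shared `kon`, `koff` and `Rmax` to the association and dissociation
#' phases of a family of sensorgrams by global nonlinear least squares
#' (Levenberg-Marquardt on log-parameters, enforcing positivity).
#' `KD = koff/kon` is derived. A two-component model (sum of two 1:1
#' interactions) is also fitted; when it improves the residual RMS by more
#' than `biphasic_factor`, the data are flagged as biphasic and the 1:1
#' parameters should be treated as inappropriate.
#'
#' @param sensorgrams List of `sensorgram`s (>= 3 distinct concentrations).
#' @param biphasic_factor RMS improvement ratio that flags biphasic
#'   binding (default 2).
#' @param check_biphasic Set `FALSE` to skip the two-component comparison.
#' @return `fit_result`; `details$two_component` holds the alternative fit.
#' @export
fit_kinetics <- function(sensorgrams, biphasic_factor = 2,
                         check_biphasic = TRUE) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  concs <- vapply(sensorgrams, attr, numeric(1), "analyte_conc")
  if (length(unique(concs[concs > 0])) < 3L)
    stop("kinetic fit needs at least 3 distinct analyte concentrations")
  observed <- unlist(lapply(sensorgrams, function(sg)
    sg$signal[sg$phase %in% c("association", "dissociation")]))
  # starts: Rmax from the top response, koff from the top trace's tail,
  # KD from the concentration closest to half-maximal response
  top <- sensorgrams[[which.max(concs)]]
  Rmax0 <- max(observed) * 1.2
  reqs <- vapply(sensorgrams, function(sg)
    suppressWarnings(as.numeric(extract_req(sg))), numeric(1))
  KD0 <- concs[which.min(abs(reqs - max(reqs) / 2))]
  dd <- top[top$phase == "dissociation", ]
  pos <- dd$signal > max(dd$signal) * 0.05
  koff0 <- if (sum(pos) > 3) {
    sl <- stats::coef(stats::lm(log(dd$signal[pos]) ~ dd$time[pos]))[[2L]]
    max(1e-5, -sl)
  } else 0.01
  start <- log(c(kon = koff0 / KD0, koff = koff0, Rmax = Rmax0))
  ctl <- minpack.lm::nls.lm.control(maxiter = 200)
  f1 <- minpack.lm::nls.lm(par = start, fn = kinetic_model_residuals,
                           sensorgrams = sensorgrams, observed = observed,
                           ncomp = 1L, control = ctl)
  p1 <- unname(exp(f1$par))
  rms1 <- sqrt(mean(f1$fvec^2))
  converged <- f1$info %in% 1:4
  # delta-method standard errors on the natural scale
  se <- tryCatch({
    v <- tryCatch(stats::vcov(f1), error = function(e) NULL)
    if (is.null(v)) list(kon = NA_real_, koff = NA_real_, KD = NA_real_)
    else {
      s <- sqrt(diag(v))
      vKD <- v[2, 2] + v[1, 1] - 2 * v[1, 2]
      list(kon = p1[1] * s[1], koff = p1[2] * s[2],
           KD = (p1[2] / p1[1]) * sqrt(max(vKD, 0)))
    }
  }, error = function(e) list(kon = NA_real_, koff = NA_real_,
                              KD = NA_real_))
  biphasic <- FALSE; f2 <- NULL
  # a numerically perfect 1:1 fit needs no model comparison
  if (check_biphasic && rms1 > 1e-6 * max(abs(observed))) {
    start2 <- log(c(p1[1], p1[2] * 5, p1[3] / 2,
                    p1[1], p1[2] / 5, p1[3] / 2))
    f2 <- tryCatch(
      minpack.lm::nls.lm(par = start2, fn = kinetic_model_residuals,
                         sensorgrams = sensorgrams, observed = observed,
                         ncomp = 2L, control = ctl),
      error = function(e) NULL)
    if (!is.null(f2)) {
      rms2 <- sqrt(mean(f2$fvec^2))
      biphasic <- is.finite(rms2) && rms2 > 0 && rms1 / rms2 > biphasic_factor
    }
  }
  fit_result(kinetic_params(p1[1], p1[2], p1[3]), se, rms1,
             converged = converged, model = "one-to-one",
             biphasic_flag = biphasic,
             details = list(nls = f1, two_component = f2))
}

#' Fold change of a variant dissociation constant versus wild type
#'
#' Reports the K_D ratio as a factor >= 1 together with its direction:
#' `"affinity-increase"` when the variant K_D is below wild type (tighter
#' binding), otherwise `"affinity-decrease"`. Sentinel (non-numeric,
#' no-binding) inputs yield a typed not-computable result instead of NaN.
#'
#' @param kd_variant Variant K_D (same units as `kd_wt`), or `NA` for a
#'   sentinel entry.
#' @param kd_wt Wild-type K_D (> 0).
#' @return List with `factor`, `direction`, `computable`.
#' @examples
#' fold_change(25, 281)    # 11.24-fold, affinity-increase
#' fold_change(79.8, 16.5) # 4.84-fold, affinity-decrease
#' @export
fold_change <- function(kd_variant, kd_wt) {
  if (!is.numeric(kd_wt) || is.na(kd_wt) || kd_wt <= 0)
    stop("'kd_wt' must be a positive number")
  if (!is.numeric(kd_variant) || is.na(kd_variant))
    return(list(factor = NA_real_, direction = "not-computable",
                computable = FALSE))
  if (kd_variant <= 0) stop("'kd_variant' must be positive")
  ratio <- kd_variant / kd_wt
  list(factor = max(ratio, 1 / ratio),
       direction = if (kd_variant < kd_wt) "affinity-increase"
                   else "affinity-decrease",
       computable = TRUE)
}
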