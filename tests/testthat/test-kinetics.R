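test_that("1:1 simulation matches the Langmuir closed form", {
  p <- kinetic_params(kon = 1e5, koff = 1e-2, Rmax = 1)
  expect_equal(p$KD, 1e-7)
  sg <- simulate_binding(p, conc = 100e-9, t_baseline = 0, t_assoc = 50,
                         t_dissoc = 50, dt = 1)
  # kobs = 0.02/s; at t = 50 s: 0.5 * (1 - exp(-1))
  expect_equal(sg$signal[sg$time == 50][1], 0.5 * (1 - exp(-1)),
               tolerance = 1e-10)
  # half-saturation identity at conc = KD
  long <- simulate_binding(p, conc = p$KD, t_assoc = 5000, t_dissoc = 10)
  expect_equal(max(long$signal), 0.5, tolerance = 1e-4)
  # zero concentration gives an identically zero trace
  z <- simulate_binding(p, conc = 0)
  expect_true(all(z$signal == 0))
  expect_error(simulate_binding(p, conc = -1e-9), "non-negative")
})

test_that("association rises monotonically to Req, dissociation decays", {
  p <- kinetic_params(2e5, 5e-3, Rmax = 1.4)
  for (conc in c(10e-9, 100e-9, 1e-6)) {
    sg <- simulate_binding(p, conc)
    a <- sg$signal[sg$phase == "association"]
    d <- sg$signal[sg$phase == "dissociation"]
    expect_true(all(diff(a) >= 0))
    expect_lte(max(a), p$Rmax * conc / (conc + p$KD) + 1e-12)
    expect_true(all(diff(d) <= 0))
  }
})

test_that("double referencing removes drift and nonspecific signal", {
  p <- kinetic_params(1e5, 1e-2)
  clean <- simulate_binding(p, 200e-9)
  zero <- simulate_binding(p, 0)
  # both references zero: unchanged
  same <- double_reference(clean, zero, zero)
  expect_equal(same$signal, clean$signal)
  # sample identical to the loaded-in-buffer reference: zero trace
  gone <- double_reference(clean, clean, zero)
  expect_true(all(gone$signal == 0))
  # drift in the loaded reference and an offset in the pin reference
  drifted <- simulate_binding(p, 200e-9, drift_slope = 2e-4)
  drift_ref <- simulate_binding(p, 0, drift_slope = 2e-4)
  offset_ref <- zero; offset_ref$signal <- offset_ref$signal + 0.05
  rec <- double_reference(drifted, drift_ref, offset_ref)
  expect_equal(rec$signal, clean$signal, tolerance = 1e-9)
  # mismatched grids are rejected
  short <- simulate_binding(p, 200e-9, t_assoc = 100)
  expect_error(double_reference(clean, short, zero), "time grid")
})

test_that("Req extraction recovers the plateau and flags short phases", {
  p <- kinetic_params(1e5, 1e-2, Rmax = 0.8)
  sg <- simulate_binding(p, 500e-9, t_assoc = 2000)
  req <- extract_req(sg)
  expect_true(attr(req, "equilibrated"))
  expect_equal(as.numeric(req), 0.8 * 500e-9 / (500e-9 + p$KD),
               tolerance = 5e-3)
  flat <- sg; flat$signal <- rep(0.42, nrow(sg))
  expect_equal(as.numeric(extract_req(flat)), 0.42)
  # k_obs * t_assoc < 1: still far from equilibrium
  slow <- simulate_binding(kinetic_params(1e3, 1e-4), 100e-9, t_assoc = 100)
  expect_warning(r2 <- extract_req(slow), "not equilibrated")
  expect_false(attr(r2, "equilibrated"))
  expect_error(extract_req(simulate_binding(p, 0, t_assoc = 10, dt = 10)),
               "3 samples")
})

test_that("steady-state fit recovers the generating dissociation constant", {
  req <- 1.0 * um_series / (um_series + 281e-9)
  fit <- fit_steady_state(um_series, req)
  expect_true(fit$converged)
  expect_equal(fit$params$KD, 281e-9, tolerance = 1e-3)
  expect_error(fit_steady_state(c(1e-9, 1e-6), c(0.1, 0.9)), "at least 4")
  # all points deep in the linear regime: reported, not silent
  lin <- fit_steady_state(nm_series, 1e5 * nm_series)
  expect_false(lin$converged)
})

test_that("steady-state fit tolerates measurement noise across seeds", {
  kds <- vapply(1:60, function(s) {
    set.seed(s)
    req <- um_series / (um_series + 281e-9)
    req <- req + stats::rnorm(length(req), 0, 0.01)
    fit_steady_state(um_series, req)$params$KD
  }, numeric(1))
  expect_lt(abs(stats::median(kds) / 281e-9 - 1), 0.05)
})

test_that("global kinetic fit recovers kon, koff, KD from noiseless traces", {
  grid <- expand.grid(KD = c(1e-9, 1e-7, 1e-5), kon = c(1e4, 1e6))
  for (i in seq_len(nrow(grid))) {
    KD <- grid$KD[i]; kon <- grid$kon[i]
    fam <- make_sensorgram_family(KD, nm_series, kon = kon,
                                  koff = kon * KD)
    fit <- fit_kinetics(fam, check_biphasic = FALSE)
    expect_true(fit$converged)
    expect_equal(fit$params$KD, KD, tolerance = 1e-3)
    expect_equal(fit$params$kon, kon, tolerance = 1e-3)
    expect_equal(fit$params$koff, kon * KD, tolerance = 1e-3)
  }
  expect_error(fit_kinetics(make_sensorgram_family(1e-7, 5e-7)),
               "3 distinct")
})

test_that("steady-state and kinetic paths agree on equilibrated traces", {
  fam <- make_sensorgram_family(650e-9, nm_series, t_assoc = 3000)
  req <- vapply(fam, function(s) as.numeric(extract_req(s)), numeric(1))
  ss <- fit_steady_state(nm_series, req)
  kin <- fit_kinetics(fam, check_biphasic = FALSE)
  expect_equal(ss$params$KD, kin$params$KD, tolerance = 0.02)
})

test_that("observed rates regress linearly on concentration", {
  p <- kinetic_params(2e5, 8e-3, Rmax = 1)
  concs <- c(25, 50, 100, 200, 400) * 1e-9
  kobs <- vapply(concs, function(conc) {
    sg <- simulate_binding(p, conc)
    a <- sg$phase == "association"
    t <- sg$time[a] - min(sg$time[a]); y <- sg$signal[a]
    req <- p$Rmax * conc / (conc + p$KD)
    # single-exponential rate from the log-linearized approach curve
    keep <- y / req < 0.99 & t > 0
    -stats::coef(stats::lm(log(1 - y[keep] / req) ~ t[keep]))[[2]]
  }, numeric(1))
  lin <- stats::lm(kobs ~ concs)
  expect_equal(unname(stats::coef(lin)[2]), p$kon, tolerance = 1e-2)
  expect_equal(unname(stats::coef(lin)[1]), p$koff, tolerance = 1e-2)
})

test_that("two-component traces raise the biphasic flag, 1:1 traces do not", {
  fast <- kinetic_params(1e5, 5e-2, 0.5)
  slow <- kinetic_params(1e5, 5e-3, 0.5)
  bi <- make_biphasic_family(fast, slow, 0.5, nm_series)
  fit <- fit_kinetics(bi)
  expect_true(fit$biphasic_flag)
  mono <- make_sensorgram_family(650e-9, nm_series, noise_sd = 0.005,
                                 seed = 99)
  expect_false(fit_kinetics(mono)$biphasic_flag)
})

test_that("fold change reproduces the printed table arithmetic", {
  fc <- fold_change(25, 281)
  expect_equal(fc$factor, 281 / 25)
  expect_equal(fc$direction, "affinity-increase")
  fc2 <- fold_change(79.8, 16.5)
  expect_equal(round(fc2$factor, 1), 4.8)
  expect_equal(fc2$direction, "affinity-decrease")
  expect_equal(fold_change(1, 1)$factor, 1)
  expect_error(fold_change(5, 0), "positive")
  expect_false(fold_change(NA_real_, 16.5)$computable)
})
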