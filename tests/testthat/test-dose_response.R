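test_that("dose grid is log-spaced, increasing and validated", {
  g <- dose_grid()
  expect_length(g, 121)
  expect_equal(g[1], 1e-13)
  expect_equal(g[121], 1e-3)
  expect_true(all(diff(log10(g)) > 0))
  expect_equal(diff(log10(g)), rep(diff(log10(g))[1], 120), tolerance = 1e-9)
  expect_error(dose_grid(min = 0), "min")
  expect_error(dose_grid(min = 1e-3, max = 1e-13), "min")
})

test_that("dose sweeps report all metrics, and no antigen means no signal", {
  p <- reference_params()
  g <- dose_grid(n = 31)
  rc <- sweep_dose(p, g, "bound_ratio")
  expect_s3_class(rc, "response_curve")
  expect_equal(nrow(rc), 31)
  expect_equal(rc$signal, rc$bound_ratio)

  rc0 <- sweep_dose(model_params(rtot = 0), g, "total_bound")
  expect_true(all(rc0$signal == 0))
})

test_that("bound-antibody ratio shows the biphasic bivalent shape", {
  p <- reference_params()
  g <- dose_grid(n = 61)
  biv <- sweep_dose(p, g, "bound_ratio", "bivalent")
  mono <- sweep_dose(p, g, "bound_ratio", "monovalent")

  # bivalent curve plateaus near 0.5 at low-intermediate dose then rises to ~1
  at <- function(curve, dose) curve$signal[which.min(abs(curve$Ainit - dose))]
  expect_equal(at(biv, 1e-9), 0.5, tolerance = 0.1)
  expect_equal(at(biv, 3e-10), 0.5, tolerance = 0.1)
  expect_gt(at(biv, 1e-4), 0.95)

  # the monovalent antibody saturates at a lower dose than the bivalent one
  expect_gt(at(mono, 1e-8), 0.95)
  expect_lt(at(biv, 1e-8), 0.6)
})

test_that("EC50 is the first half-max crossing, interpolated in log dose", {
  # ideal hyperbolic curve: EC50 equals the effective KD
  g <- dose_grid(1e-12, 1e-6, 121)
  KDeff <- 3.3e-9
  curve <- data.frame(Ainit = g, signal = g / (g + KDeff))
  e <- ec50(curve)
  expect_equal(e$ec50, KDeff, tolerance = 0.01)

  # invariant under positive rescaling of the signal
  curve2 <- transform(curve, signal = 7.3 * signal)
  expect_equal(ec50(curve2)$ec50, e$ec50)

  # biphasic curve: first crossing wins
  sig <- c(0, 0.4, 0.55, 0.55, 0.55, 0.7, 1)
  bip <- data.frame(Ainit = 10^seq(-12, -6), signal = sig)
  eb <- ec50(bip)
  expect_lt(eb$ec50, 1e-10)  # crossing 0.5 happens between the 2nd and 3rd dose
  expect_equal(eb$crossing_index, 2)

  expect_error(ec50(data.frame(Ainit = g, signal = 0 * g)), "undefined")
})

test_that("monovalent EC50 under antibody excess approaches koff/(2 kon)", {
  p <- model_params(kon = 1e5, koff = 1e-4, D = 1e-14, rtot = 100)
  e <- ec50(sweep_dose(p, dose_grid(n = 241), "total_bound", "monovalent"))
  expect_equal(e$ec50, 5e-10, tolerance = 0.02)
})

test_that("EC50 is stable under dose-grid refinement", {
  p <- reference_params()
  e1 <- ec50(sweep_dose(p, dose_grid(n = 121), "total_bound"))
  e2 <- ec50(sweep_dose(p, dose_grid(n = 241), "total_bound"))
  expect_lt(abs(e2$ec50 - e1$ec50) / e1$ec50, 0.02)
})

test_that("avidity shift vanishes for identical models and grows with diffusion", {
  # both valencies identical when the cross-linking arm is disabled
  p0 <- model_params(kon = 1e5, koff = 1e-4, D = 0, rtot = 1e4)
  d0 <- delta_ec50(p0, dose_grid(n = 61), "total_bound")
  expect_equal(d0$delta_ec50, 0)

  # occupancy avidity shift nondecreasing in D at fixed rtot, KD
  g <- dose_grid(n = 61)
  shifts <- vapply(c(1e-15, 1e-14, 1e-13), function(D) {
    p <- model_params(kon = 1e5, koff = 1e-4, D = D, rtot = 1e4)
    delta_ec50(p, g, "occupancy")$delta_ec50
  }, numeric(1))
  expect_true(all(diff(shifts) >= 0))
  expect_gt(shifts[1], 0)
})

test_that("avidity heatmap reduces to delta_ec50 and ranks regimes as expected", {
  g <- dose_grid(n = 61)
  h <- avidity_heatmap(1e4, 1e-9, D = 1e-14, signal_kind = "total_bound",
                       grid = g)
  expect_equal(nrow(h), 1)
  d <- delta_ec50(model_params(kon = 1e5, koff = 1e-4, D = 1e-14, rtot = 1e4),
                  g, "total_bound")
  expect_equal(h$delta_ec50, d$delta_ec50)

  # many antigens + weak binder beats few antigens (strong or weak binder)
  h3 <- avidity_heatmap(c(1e3, 1e6), c(1e-10, 1e-6), D = 1e-14,
                        signal_kind = "total_bound", grid = g)
  val <- function(rt, kd) h3$delta_ec50[h3$rtot == rt & h3$KD == kd]
  expect_gt(val(1e6, 1e-6), val(1e3, 1e-10))
  expect_gt(val(1e3, 1e-10), val(1e3, 1e-6))
})

test_that("metric heatmap exposes the antibody:antigen saturation boundary", {
  tab <- metric_heatmap(rtot_grid = 1e5,
                        Ainit_grid = 10^seq(-11, -8, length.out = 31),
                        params = reference_params(),
                        signal_kind = "occupancy")
  expect_true(all(diff(tab$value) >= -1e-9))
  expect_gt(max(tab$value), 0.99)
})
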