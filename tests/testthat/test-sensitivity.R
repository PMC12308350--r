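test_that("the Saltelli design has the documented block structure", {
  rng <- param_ranges()
  d <- saltelli_design(rng, N = 64, seed = 5)
  n <- nrow(rng)
  expect_equal(nrow(d$X), 64 * (2 * n + 2))  # A, B, AB_i, BA_i
  d1 <- saltelli_design(rng, N = 64, seed = 5, second_order = FALSE)
  expect_equal(nrow(d1$X), 64 * (n + 2))
  expect_error(saltelli_design(rng, N = 100), "power of two")

  # all samples within bounds
  for (j in seq_len(n))
    expect_true(all(d$X[, j] >= rng$lower[j] & d$X[, j] <= rng$upper[j]))

  # bit-for-bit reproducibility under a fixed seed
  expect_identical(d$X, saltelli_design(rng, N = 64, seed = 5)$X)

  # AB_i blocks differ from A only in column i
  A <- d$X[d$block == "A", ]
  for (nm in rng$name) {
    ABi <- d$X[d$block == paste0("AB_", nm), ]
    expect_identical(A[, setdiff(rng$name, nm)], ABi[, setdiff(rng$name, nm)])
    expect_false(identical(A[, nm], ABi[, nm]))
  }
})

test_that("a single-factor model concentrates all variance on its factor", {
  rng <- data.frame(name = c("x1", "x2", "x3"), lower = 0, upper = 1,
                    scale = "linear")
  d <- saltelli_design(rng, N = 1024, seed = 6, second_order = FALSE)
  y <- d$X[, "x1"]
  s <- sobol_indices(d, y, n_boot = 50)
  i <- s$indices
  expect_equal(i$S1[i$parameter == "x1"], 1, tolerance = 0.05)
  expect_equal(i$ST[i$parameter == "x1"], 1, tolerance = 0.05)
  expect_lt(max(abs(i$ST[i$parameter != "x1"])), 0.02)
})

test_that("an additive model recovers the closed-form variance split", {
  rng <- data.frame(name = c("z1", "z2", "dummy"), lower = 0, upper = 1,
                    scale = "linear")
  d <- saltelli_design(rng, N = 1024, seed = 7, second_order = FALSE)
  a <- 3; b <- 1
  y <- a * d$X[, "z1"] + b * d$X[, "z2"]
  s <- sobol_indices(d, y, n_boot = 100)
  i <- s$indices
  expect_equal(i$S1[i$parameter == "z1"], a^2 / (a^2 + b^2), tolerance = 0.05)
  expect_equal(i$S1[i$parameter == "z2"], b^2 / (a^2 + b^2), tolerance = 0.05)
  # additive: total equals first order, and the inert dummy is at the floor
  expect_equal(i$ST, i$S1, tolerance = 0.05)
  expect_lt(i$ST[i$parameter == "dummy"], 0.05)
})

test_that("a nonlinear benchmark matches its analytic Sobol decomposition", {
  # three-factor oscillatory benchmark with known indices:
  # S = (0.3139, 0.4424, 0); ST = (0.5576, 0.4424, 0.2437)
  rng <- data.frame(name = c("x1", "x2", "x3"), lower = -pi, upper = pi,
                    scale = "linear")
  d <- saltelli_design(rng, N = 2048, seed = 2, second_order = TRUE)
  X <- d$X
  y <- sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
  s <- sobol_indices(d, y, second_order = TRUE, n_boot = 0)
  i <- s$indices
  expect_equal(i$S1, c(0.3139, 0.4424, 0), tolerance = 0.05)
  expect_equal(i$ST, c(0.5576, 0.4424, 0.2437), tolerance = 0.05)
  # the only non-zero interaction is x1:x3
  s13 <- s$second_order$Sij[s$second_order$i == "x1" &
                              s$second_order$j == "x3"]
  expect_equal(s13, 0.2437, tolerance = 0.08)
  others <- s$second_order$Sij[!(s$second_order$i == "x1" &
                                   s$second_order$j == "x3")]
  expect_lt(max(abs(others)), 0.08)
})

test_that("model outputs ignore the dummy parameter and flag zero variance", {
  d <- saltelli_design(param_ranges(), N = 64, seed = 8,
                       second_order = FALSE)
  Y <- evaluate_outputs(d, 1e-9)
  yA <- Y$occupancy[d$block == "A"]
  yDum <- Y$occupancy[d$block == "AB_dummy"]
  expect_identical(yA, yDum)  # only the dummy column differs between blocks

  # constant design rows give degenerate (flagged) indices
  dconst <- d
  dconst$X[, c("kon", "koff", "rtot", "D")] <-
    matrix(rep(c(1e5, 1e-4, 1e4, 1e-14), each = nrow(d$X)), ncol = 4)
  Yc <- evaluate_outputs(dconst, 1e-9)
  sc <- sobol_indices(dconst, Yc$occupancy, n_boot = 0)
  expect_true(sc$degenerate)
  expect_true(all(is.na(sc$indices$S1)))
})

test_that("Sobol identities hold for the binding model outputs", {
  d <- saltelli_design(param_ranges(), N = 256, seed = 9,
                       second_order = FALSE)
  for (a in c(1e-10, 1e-7)) {
    Y <- evaluate_outputs(d, a)
    for (out in names(Y)) {
      s <- sobol_indices(d, Y[[out]], n_boot = 60)
      i <- s$indices
      expect_true(all(i$S1 <= i$ST + 3 * i$ST_se + 3 * i$S1_se))
      expect_lte(sum(i$S1), 1 + 3 * sqrt(sum(i$S1_se^2)))
      expect_lt(i$ST[i$parameter == "dummy"], 0.05)
    }
  }
})

test_that("the dose-resolved experiment reproduces the regime structure", {
  tab <- sensitivity_experiment(doses = c(1e-10, 1e-6), N = 256, seed = 10,
                                n_boot = 0)
  expect_setequal(names(tab), c("output", "Ainit", "parameter", "S1", "ST",
                                "S1_se", "ST_se", "N", "seed"))
  st <- function(out, dose, par)
    tab$ST[tab$output == out & tab$Ainit == dose & tab$parameter == par]
  # low dose: antigen density dominates occupancy
  others <- vapply(c("kon", "koff", "D", "dummy"),
                   function(p) st("occupancy", 1e-10, p), numeric(1))
  expect_gt(st("occupancy", 1e-10, "rtot"), max(others))
  # high dose: the bound ratio is much less sensitive to koff than occupancy
  expect_lt(st("bound_ratio", 1e-6, "koff"),
            0.5 * st("occupancy", 1e-6, "koff"))
  # total bound antibody tracks antigen number at all but the lowest doses
  others_tb <- vapply(c("kon", "koff", "D", "dummy"),
                      function(p) st("total_bound", 1e-6, p), numeric(1))
  expect_gt(st("total_bound", 1e-6, "rtot"), max(others_tb))
})
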