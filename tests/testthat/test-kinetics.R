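# independently coded term-by-term right-hand side used as an oracle
rhs_oracle <- function(r, A0, A1, A2, k1, k2, koff) {
  assoc1 <- 2 * k1 * r * A0
  dissoc1 <- koff * A1
  assoc2 <- k2 * r * A1
  dissoc2 <- 2 * koff * A2
  c(dr = -assoc1 + dissoc1 - assoc2 + dissoc2,
    dA0 = -assoc1 + dissoc1,
    dA1 = assoc1 - dissoc1 - assoc2 + dissoc2,
    dA2 = assoc2 - dissoc2)
}

test_that("full right-hand side matches a term-by-term oracle and conserves totals", {
  sets <- random_params(25, seed = 21)
  set.seed(22)
  for (p in sets) {
    # random valid state
    A2 <- runif(1, 0, p$rtot / 2 * 0.5)
    A1 <- runif(1, 0, min(p$rtot - 2 * A2, p$Atot))
    A0 <- max(p$Atot - A1 - A2, 0)
    r <- max(p$rtot - A1 - 2 * A2, 0)
    st <- list(r = r, A0 = A0, A1 = A1, A2 = A2)
    d <- rhs_full(st, p)
    expect_equal(d, rhs_oracle(r, A0, A1, A2, p$k1, p$k2, p$koff))
    # conservation of antibodies and antigens
    scale <- max(abs(d), 1e-300)
    expect_lt(abs(d["dA0"] + d["dA1"] + d["dA2"]) / scale, 1e-12)
    expect_lt(abs(d["dr"] + d["dA1"] + 2 * d["dA2"]) / scale, 1e-12)
  }
})

test_that("from the unbound state only monovalent binding starts", {
  p <- reference_params()
  d <- rhs_full(list(r = p$rtot, A0 = p$Atot, A1 = 0, A2 = 0), p)
  expect_equal(unname(d["dA1"]), 2 * p$k1 * p$rtot * p$Atot)
  expect_equal(unname(d["dA2"]), 0)
  expect_error(rhs_full(list(r = -1, A0 = 1, A1 = 0, A2 = 0), p),
               "nonnegative")
})

test_that("reduced system equals the full system under the conservation substitution", {
  sets <- random_params(10, seed = 31)
  set.seed(32)
  for (p in sets) {
    for (k in 1:10) {
      A2 <- runif(1, 0, min(p$rtot / 4, p$Atot / 2))
      A1 <- runif(1, 0, min(p$rtot - 2 * A2, p$Atot - A2))
      d_red <- rhs_reduced(A1, A2, p)
      d_full <- rhs_full(list(r = p$rtot - A1 - 2 * A2,
                              A0 = p$Atot - A1 - A2, A1 = A1, A2 = A2), p)
      expect_equal(unname(d_red["dA1"]), unname(d_full["dA1"]))
      expect_equal(unname(d_red["dA2"]), unname(d_full["dA2"]))
    }
  }
  p <- reference_params()
  expect_equal(unname(rhs_reduced(0, 0, p)),
               c(2 * p$k1 * p$rtot * p$Atot, 0))
  # with no cross-linking the bivalent pool only decays
  p0 <- model_params(kon = 1e5, koff = 1e-4, D = 0, rtot = 1e4, Ainit = 1e-9)
  expect_equal(unname(rhs_reduced(100, 50, p0)["dA2"]), -2 * p0$koff * 50)
  expect_error(rhs_reduced(p$rtot, p$rtot, p), "conservation")
})

test_that("trajectories conserve totals and stay nonnegative", {
  p <- reference_params(Ainit = 1e-9)
  # integrate the full 4-state system through rhs_full itself
  f <- function(t, y, parms)
    list(unname(rhs_full(list(r = y[1], A0 = y[2], A1 = y[3], A2 = y[4]),
                         parms)))
  times <- c(0, 10^seq(0, 6, length.out = 25))
  out <- deSolve::lsoda(c(r = p$rtot, A0 = p$Atot, A1 = 0, A2 = 0),
                        times, f, p, rtol = 1e-11, atol = 1e-8)
  ab <- out[, "A0"] + out[, "A1"] + out[, "A2"]
  ag <- out[, "r"] + out[, "A1"] + 2 * out[, "A2"]
  expect_lt(max(abs(ab - p$Atot)) / p$Atot, 1e-9)
  expect_lt(max(abs(ag - p$rtot)) / p$rtot, 1e-9)
  expect_true(all(out[, -1] > -1e-6))

  # monovalent limit: k2 = 0 keeps A2 identically zero
  p0 <- model_params(kon = 1e5, koff = 1e-4, D = 0, rtot = 1e4, Ainit = 1e-9)
  traj <- simulate_binding(p0, times)
  expect_true(all(abs(traj$A2) <= 1e-10 * p0$rtot))
})

test_that("steady-state integration handles degenerate inputs and agrees with the cubic", {
  p0 <- model_params(Ainit = 0)
  st <- integrate_to_steady_state(p0)
  expect_equal(c(st$r, st$A0, st$A1, st$A2), c(p0$rtot, 0, 0, 0))
  pr <- model_params(rtot = 0, Ainit = 1e-9)
  st <- integrate_to_steady_state(pr)
  expect_equal(c(st$r, st$A0, st$A1, st$A2), c(0, pr$Atot, 0, 0))

  p <- reference_params(Ainit = 1e-10)
  st <- integrate_to_steady_state(p)
  eq <- solve_bivalent_equilibrium(p)
  expect_lt(rel_diff(st$A1, eq$A1), 1e-6)
  expect_lt(rel_diff(st$A2, eq$A2), 1e-6)
})

test_that("equilibrium binding is nondecreasing in antibody dose", {
  doses <- 10^seq(-12, -6, length.out = 7)
  bound <- vapply(doses, function(a) {
    st <- integrate_to_steady_state(reference_params(Ainit = a))
    st$A1 + st$A2
  }, numeric(1))
  expect_true(all(diff(bound) >= -1e-6 * max(bound)))
})

test_that("trajectory CSV round-trips", {
  p <- reference_params(Ainit = 1e-9)
  traj <- simulate_binding(p, c(0, 10, 100))
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read.csv(f)
  expect_equal(names(back), c("t", "r", "A0", "A1", "A2"))
  expect_equal(back$A1, traj$A1, tolerance = 1e-12)
  unlink(f)
})
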