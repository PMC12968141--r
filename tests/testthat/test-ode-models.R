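test_that("logistic rate matches hand-computed values and rejects bad input", {
  p <- list(r = 0.5, K = 100)
  expect_identical(logistic_rhs(0, p), 0)
  expect_identical(logistic_rhs(100, p), 0)
  expect_equal(logistic_rhs(50, p), 12.5)
  expect_equal(logistic_rhs(c(0, 50, 100), p), c(0, 12.5, 0))
  expect_error(logistic_rhs(NaN, p), "non-finite")
  expect_error(logistic_rhs(1, list(r = 0.5, K = -1)), "positive")
})

test_that("closed-form logistic solution hits its landmarks", {
  p <- logistic_true
  expect_equal(logistic_analytic(0, p), 1.0)
  # half-capacity crossing: (K/P0 - 1) e^{-rt} = 1 at t = log(99)/r
  t_half <- log(99) / 0.5
  expect_equal(logistic_analytic(t_half, p), 50.0)
  expect_equal(logistic_analytic(100, p), 100.0, tolerance = 1e-12)
  expect_error(logistic_analytic(1, list(r = 0.5, K = 100, P0 = 0)),
               "positive")
  expect_error(logistic_analytic(-1, p), "t >= 0")
})

test_that("analytic logistic solution satisfies the ODE identically", {
  tt <- seq(0, 100, length.out = 400)
  P <- logistic_analytic(tt, logistic_true)
  resid <- logistic_analytic_deriv(tt) - logistic_rhs(P, logistic_true)
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("binding kinetics rates are conservative and match hand arithmetic", {
  p <- list(k_on = 1 / 60, k_off = 0.5 / 60)
  r0 <- gene_rhs(c(17, 25, 0), p)
  expect_equal(r0, c(-425 / 60, -425 / 60, 425 / 60))
  # without free promoter or factor, only unbinding acts
  expect_equal(gene_rhs(c(0, 0, 4), p),
               c(p$k_off * 4, p$k_off * 4, -p$k_off * 4))
  # rates at the quadratic-root equilibrium vanish
  eq <- gene_equilibrium()
  expect_lt(max(abs(gene_rhs(unname(eq), p))), 1e-4)
  expect_error(gene_rhs(c(1, 2), p), "3 states")
  expect_error(gene_rhs(c(1, 2, 3), list(k_on = -1, k_off = 0)), "nonnegative")

  # conservation pattern holds exactly for random states and rates
  set.seed(11)
  for (i in 1:20) {
    st <- runif(3, 0, 30)
    pr <- list(k_on = runif(1, 0, 0.2), k_off = runif(1, 0, 0.2))
    rr <- gene_rhs(st, pr)
    expect_identical(rr[1] + rr[3], 0)
    expect_identical(rr[2] + rr[3], 0)
  }
})

test_that("numerical integration reproduces the closed form", {
  sys <- logistic_system()
  tt <- seq(0, 100, length.out = 300)
  traj <- integrate_ode(sys, list(r = 0.5, K = 100), ic = 1, t_grid = tt)
  expect_identical(traj$states[1, ], c(P = 1))
  expect_lt(max(abs(traj$states[, 1] - logistic_analytic(tt, logistic_true))),
            1e-6)

  # randomized parameters across the biologically plausible box
  set.seed(7)
  for (i in 1:4) {
    r <- runif(1, 0.1, 2); K <- runif(1, 10, 500); P0 <- runif(1, 0.5, 20)
    tt2 <- seq(0, 50, length.out = 120)
    tr2 <- integrate_ode(sys, list(r = r, K = K), ic = P0, t_grid = tt2)
    expect_lt(max(abs(tr2$states[, 1] -
                        logistic_analytic(tt2, list(r = r, K = K, P0 = P0)))),
              1e-6)
  }
})

test_that("integrated binding trajectories conserve totals and reach the equilibrium", {
  sys <- gene_binding_system()
  p <- list(k_on = 1 / 60, k_off = 0.5 / 60)
  tt <- seq(0, 100, length.out = 300)
  traj <- integrate_ode(sys, p, ic = c(17, 25, 0), t_grid = tt)
  expect_lt(max(abs(traj$states[, "prom"] + traj$states[, "promtf"] - 17)), 1e-6)
  expect_lt(max(abs(traj$states[, "tf"] + traj$states[, "promtf"] - 25)), 1e-6)

  long <- integrate_ode(sys, p, ic = c(17, 25, 0),
                        t_grid = seq(0, 2000, length.out = 200))
  final <- long$states[nrow(long$states), ]
  expect_equal(unname(final), unname(gene_equilibrium()), tolerance = 1e-3)
})

test_that("integration validates its inputs", {
  sys <- logistic_system()
  expect_error(integrate_ode(sys, list(r = 1, K = 10), ic = c(1, 2),
                             t_grid = 0:10), "dimension")
  expect_error(integrate_ode(sys, list(r = 1, K = 10), ic = 1,
                             t_grid = c(0, 0, 1)), "strictly increasing")
})

test_that("trajectories round-trip through CSV", {
  sys <- gene_binding_system()
  traj <- integrate_ode(sys, list(k_on = 1 / 60, k_off = 0.5 / 60),
                        ic = c(17, 25, 0), t_grid = seq(0, 10, length.out = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$times, traj$times)
  expect_equal(back$states, traj$states, tolerance = 1e-12)
  expect_identical(colnames(back$states), c("prom", "tf", "promtf"))
})
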