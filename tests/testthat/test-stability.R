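test_that("infection-free point with full positive guidance is stable for all delays", {
  sr <- stability_report(paper_epi(), c(1, 0.5), "infection_free")
  expect_equal(sr$verdict, "stable_all_tau")
  expect_identical(sr$r_value, 0)
  expect_true(all(Re(sr$tau0_eigenvalues) < 0))
  # -m x1 is among the delay-free eigenvalues
  expect_true(any(abs(sr$tau0_eigenvalues - (-0.5)) < 1e-12))
  expect_length(sr$omega_roots, 0)
})

test_that("-m x1 is an exact root of the characteristic function at E0", {
  set.seed(333)
  for (i in 1:20) {
    p <- rand_epi(); g <- c(runif(1, 0.05, 1), runif(1))
    e0 <- infection_free_equilibrium(p, g)
    J <- panicseir:::.seir3_jacobian(e0, g, p)
    lam <- -p$m * g[1]
    pq <- panicseir:::.char_PQ(as.complex(lam), J$J0, J$Jt)
    expect_lt(Mod(pq$P + exp(-lam * p$tau) * pq$Q), 1e-10)
  }
})

test_that("subthreshold draws with strong recovery are stable for all delays", {
  # gamma > beta a / (m x1) implies the exact delay-free condition at E0
  set.seed(444)
  n <- 0
  while (n < 20) {
    p <- rand_epi(); g <- c(runif(1, 0.05, 1), runif(1))
    if (basic_reproduction_number(p, g) >= 1 ||
        p$gamma <= p$beta * p$a / (p$m * g[1])) next
    n <- n + 1
    sr <- stability_report(p, g, "infection_free")
    expect_equal(sr$verdict, "stable_all_tau")
    expect_length(sr$omega_roots, 0)  # no positive omega^2 root
  }
})

test_that("stability verdict matches perturbation decay by integration", {
  p <- paper_epi()
  sr <- stability_report(p, c(1, 0.5), "infection_free")
  expect_equal(sr$verdict, "stable_all_tau")
  tr <- integrate_coupled(c(1, 0.5), c(2.5, 0.5, 0.5), paper_pm(),
                          paper_rates(), p, t_end = 60, dt = 0.01,
                          evolve_game = FALSE)
  n <- nrow(tr)
  expect_lt(abs(tr$S[n] - 2), 1e-4)
  expect_lt(tr$E[n] + tr$I[n], 1e-4)
})

test_that("endemic report: Routh-Hurwitz coefficients and verdict", {
  p <- paper_epi()
  g <- c(0.1, 0.05)
  sr <- stability_report(p, g, "endemic")
  expect_equal(sr$verdict, "stable_all_tau")
  expect_true(all(sr$coefficients[c("a1", "a2", "a3")] > 0))
  expect_true(all(Re(sr$tau0_eigenvalues) < 0))
  expect_error(stability_report(p, g, "endemic", point = c(1, 1, 1)),
               "not an equilibrium")
  expect_error(stability_report(p, c(0.5, 0.5), "endemic"), "no endemic")
})

test_that("L1 descends under the global-stability condition", {
  p <- paper_epi()      # gamma = 0.5 > beta a / m = 0.4 at x1 = 1
  g <- c(1, 0.5)
  tr <- integrate_coupled(g, c(2, 8, 10), paper_pm(), paper_rates(), p,
                          t_end = 50, dt = 0.01, evolve_game = FALSE)
  ld <- lyapunov_descent(tr, p, g, "L1")
  expect_true(all(ld$dLdt <= 1e-8, na.rm = TRUE))
  expect_lt(ld$L[nrow(ld)], ld$L[1])
})

test_that("Lyapunov candidates vanish and rest at their equilibria", {
  p <- paper_epi(); g <- c(1, 0.5)
  e0 <- infection_free_equilibrium(p, g)
  tr0 <- integrate_coupled(g, e0, paper_pm(), paper_rates(), p,
                           t_end = 10, dt = 0.01, evolve_game = FALSE)
  ld0 <- lyapunov_descent(tr0, p, g, "L1")
  expect_true(all(abs(ld0$L) < 1e-10))
  expect_true(all(abs(ld0$dLdt) < 1e-10, na.rm = TRUE))

  g2 <- c(0.1, 0.05)
  pe <- positive_equilibrium(p, g2)
  tr2 <- integrate_coupled(g2, pe, paper_pm(), paper_rates(), p,
                           t_end = 10, dt = 0.01, evolve_game = FALSE)
  ld2 <- lyapunov_descent(tr2, p, g2, "L2", equilibrium = pe)
  expect_true(all(abs(ld2$L) < 1e-12))
})

test_that("L2 decays to zero along a converging endemic trajectory", {
  # the squared-sum candidate is not pointwise monotone along the delayed
  # flow (transient rises occur); the robust property is overall decay to
  # the equilibrium value zero
  p <- paper_epi(); g <- c(0.1, 0.05)
  pe <- positive_equilibrium(p, g)
  tr <- integrate_coupled(g, pe * 1.3, paper_pm(), paper_rates(), p,
                          t_end = 200, dt = 0.05, evolve_game = FALSE)
  ld <- lyapunov_descent(tr, p, g, "L2", equilibrium = pe)
  expect_gt(ld$L[1], 1)
  expect_lt(ld$L[nrow(ld)], 1e-12)
  expect_lt(min(ld$dLdt, na.rm = TRUE), 0)
})
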