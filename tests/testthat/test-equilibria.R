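test_that("the four strategy corners are always fixed points", {
  set.seed(707)
  for (i in 1:10) {
    pm <- rand_pm(); gr <- rand_rates()
    eq <- suppressMessages(find_equilibria(pm, gr))
    corners <- eq[eq$name %in% paste0("E", 1:4), ]
    expect_equal(nrow(corners), 4L)
    expect_setequal(paste(corners$x1, corners$y1),
                    c("0 0", "0 1", "1 0", "1 1"))
    for (k in seq_len(nrow(eq)))
      expect_lt(max(abs(replicator_rhs(c(eq$x1[k], eq$y1[k]), pm, gr))),
                1e-12)
  }
})

test_that("benchmark payoffs admit no interior point (degenerate denominators)", {
  eq <- suppressMessages(find_equilibria(paper_pm(), paper_rates(0.5, 0.5)))
  expect_false("E5" %in% eq$name)
  expect_match(attr(eq, "e5_note"), "denominator")
})

test_that("interior fixed point agrees with a root-finding oracle", {
  set.seed(808)
  found <- 0
  while (found < 10) {
    pm <- rand_pm(); gr <- rand_rates()
    eq <- suppressMessages(find_equilibria(pm, gr))
    e5 <- eq[eq$name == "E5", ]
    if (nrow(e5) == 0) next
    found <- found + 1
    # each bracket is linear in one coordinate; root-find independently
    x_star <- uniroot(function(x1) panicseir:::.bracket_y(pm, gr, x1),
                      c(-10, 10), extendInt = "yes", tol = 1e-14)$root
    y_star <- uniroot(function(y1) panicseir:::.bracket_x(pm, gr, y1),
                      c(-10, 10), extendInt = "yes", tol = 1e-14)$root
    expect_equal(e5$x1, x_star, tolerance = 1e-9)
    expect_equal(e5$y1, y_star, tolerance = 1e-9)
    expect_lt(max(abs(replicator_rhs(c(e5$x1, e5$y1), pm, gr))), 1e-12)
  }
})

test_that("game Jacobian matches printed partials and finite differences", {
  pm <- paper_pm(); gr <- paper_rates()
  J <- game_jacobian(c(0, 0), pm, gr)
  expect_equal(unname(J), diag(c(4, 2)))
  # corner off-diagonals vanish for any parameters
  set.seed(909)
  for (i in 1:10) {
    pm2 <- rand_pm(); gr2 <- rand_rates()
    for (pt in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
      Jc <- game_jacobian(pt, pm2, gr2)
      expect_identical(unname(Jc[1, 2]), 0)
      expect_identical(unname(Jc[2, 1]), 0)
    }
    # central finite differences at a random interior state
    st <- runif(2, 0.05, 0.95)
    h <- 1e-6
    num <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- h
      num[, j] <- (replicator_rhs(st + e, pm2, gr2) -
                     replicator_rhs(st - e, pm2, gr2)) / (2 * h)
    }
    expect_equal(unname(game_jacobian(st, pm2, gr2)), num, tolerance = 1e-6)
  }
})

test_that("det/trace labels match the benchmark stability pattern", {
  pm <- paper_pm(); gr <- paper_rates()
  expect_equal(classify_equilibrium(c(1, 1), pm, gr)$label, "ESS")
  expect_equal(classify_equilibrium(c(0, 0), pm, gr)$label, "unstable")
  e2 <- classify_equilibrium(c(0, 1), pm, gr)
  e3 <- classify_equilibrium(c(1, 0), pm, gr)
  expect_equal(e2$label, "saddle")
  expect_equal(e3$label, "saddle")
  expect_lt(e2$det, 0)  # saddle regardless of trace
  expect_error(classify_equilibrium(c(0.6, 0.5), pm, gr), "not a fixed point")
})

test_that("det/trace labels agree with the eigenvalue oracle on random draws", {
  set.seed(1010)
  for (i in 1:50) {
    pm <- rand_pm(); gr <- rand_rates()
    eq <- suppressMessages(find_equilibria(pm, gr))
    for (k in seq_len(nrow(eq))) {
      rep <- classify_equilibrium(c(eq$x1[k], eq$y1[k]), pm, gr)
      lab <- eigen_label(rep$jac)
      if (rep$label == "degenerate" || lab == "degenerate") next
      expect_equal(rep$label, lab)
    }
  }
})

test_that("scenario classification reproduces the tabulated cases", {
  pm <- paper_pm()
  # fully degenerate brackets: four subcases decided by two signs
  for (p21 in c(0.5, 1, 1.5)) for (q21 in c(0.5, 1, 1.5)) {
    cls <- classify_scenario(pm, paper_rates(p21, q21))
    expect_equal(cls$case, "I.4")
    expect_equal(unname(cls$ess), matrix(c(1, 1), 1, 2))
  }
  # both discriminants negative: all-negative regime, ESS at the origin
  cls <- classify_scenario(pm, paper_rates(p21 = 2, q21 = 4))
  expect_equal(cls$case, "I.1")
  expect_equal(unname(cls$ess), matrix(c(0, 0), 1, 2))
  expect_equal(cls$equilibria$label[cls$equilibria$name == "E1"], "ESS")
})

test_that("scenario classification covers the one-sided degenerate table", {
  # deg1 = 0 (b4 - c21 = b6), deg2 != 0: the eight-sign table applies
  pm <- payoff_matrix(b1 = 14, b2 = 10, b3 = 7, b4 = 5, b5 = 3, b6 = 1,
                      c1 = 5, c11 = 5, c21 = 4)
  cls <- classify_scenario(pm, game_rates(p21 = 0.5, q21 = 0.5))
  expect_equal(cls$case, "II.8")
  expect_equal(unname(cls$ess), matrix(c(1, 1), 1, 2))
  pm2 <- payoff_matrix(b1 = 13, b2 = 10, b3 = 7, b4 = 5, b5 = 3, b6 = 1,
                       c1 = 5, c11 = 5, c21 = 4)
  cls2 <- classify_scenario(pm2, game_rates(p21 = 2.5, q21 = 4))
  expect_equal(cls2$case, "II.1")
  expect_equal(unname(cls2$ess), matrix(c(0, 0), 1, 2))
  # cross-check the tabulated ESS against the numeric labels
  for (cl in list(cls, cls2)) {
    ess_num <- cl$equilibria[cl$equilibria$label == "ESS", c("x1", "y1")]
    expect_equal(unname(as.matrix(ess_num)), unname(cl$ess))
  }
})

test_that("a deciding condition at zero triggers the degenerate fallback", {
  # q21 = 3 freezes the public bracket identically at zero
  cls <- classify_scenario(paper_pm(), paper_rates(p21 = 1, q21 = 3))
  expect_true(cls$degenerate)
  expect_equal(cls$case, "numeric")
  expect_true(all(cls$equilibria$label == "degenerate"))
})
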