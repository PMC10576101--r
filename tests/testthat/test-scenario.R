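test_that("the benchmark preset carries the documented constants", {
  sc <- load_scenario("paper_default")
  expect_equal(unclass(sc$payoffs)[c("b1", "b2", "b3", "b4", "b5", "b6",
                                     "c1", "c11", "c21")],
               list(b1 = 15, b2 = 10, b3 = 7, b4 = 5, b5 = 3, b6 = 1,
                    c1 = 5, c11 = 5, c21 = 4))
  expect_equal(unclass(sc$rates),
               list(lambda1 = 1, rho1 = 1, p21 = 1, q21 = 1))
  expect_equal(unclass(sc$epi)[c("a", "beta", "alpha", "gamma", "m")],
               list(a = 1, beta = 0.2, alpha = 1, gamma = 0.5, m = 0.5))
  expect_equal(unname(sc$init_game), c(0.6, 0.5))
  expect_equal(unname(sc$init_epi), c(2, 8, 10, 0))
})

test_that("config files override the preset and reject bad keys", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# dependence overrides", "[rates]", "p21 = 1.5",
               "q21 = 0.5"), cfg)
  sc <- load_scenario(cfg)
  expect_equal(sc$rates$p21, 1.5)
  expect_equal(sc$rates$q21, 0.5)
  expect_equal(sc$payoffs$b1, 15)  # untouched keys inherit the preset

  writeLines(c("p21 = 1.5", "bogus = 3", "also_bad = 1"), cfg)
  expect_error(load_scenario(cfg), "bogus, also_bad")
  writeLines("b2 = 20", cfg)
  expect_error(load_scenario(cfg), "b1 > b2")
  expect_error(load_scenario("no_such_preset"), "unknown preset")
  expect_error(load_scenario("paper_default", overrides = c(zz = 1)),
               "unknown scenario keys")
})

test_that("bundled example config loads the slow-official scenario", {
  cfg <- system.file("extdata", "slow_official_scenario.cfg",
                     package = "panicseir")
  expect_true(nzchar(cfg))
  sc <- load_scenario(cfg)
  expect_equal(sc$rates$p21, 1.5)
  expect_equal(sc$rates$q21, 0.5)
})

test_that("reproduction-number surfaces are monotone with the right signs", {
  p <- paper_epi()
  g1 <- seq(0.1, 1, length.out = 10)
  g2 <- seq(0.05, 0.5, length.out = 10)
  sg <- r_sensitivity(p, vary = c("m", "gamma"), grid1 = g1, grid2 = g1)
  expect_equal(unname(sg$monotonicity), c("decreasing", "decreasing"))
  sg2 <- r_sensitivity(p, vary = c("beta", "m"), grid1 = g2, grid2 = g1)
  expect_equal(unname(sg2$monotonicity), c("increasing", "decreasing"))
  # single cell reduces to the scalar value
  sg1 <- r_sensitivity(p, game = c(0.5, 0.5), vary = c("m", "gamma"),
                       grid1 = 0.5, grid2 = 0.5)
  expect_equal(as.numeric(sg1$R),
               basic_reproduction_number(p, c(0.5, 0.5)))
  expect_error(r_sensitivity(p, game = c(0, 0.5), vary = c("m", "gamma"),
                             grid1 = g1, grid2 = g1), "singular")
  expect_error(r_sensitivity(p, vary = c("m", "tau"), grid1 = g1,
                             grid2 = g1), "vary must name")
})

test_that("reports are deterministic and atomically written", {
  sc <- load_scenario("paper_default",
                      overrides = c(p21 = 0.5, q21 = 0.5, t_end_game = 20,
                                    t_end_coupled = 40))
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  r1 <- run_report(sc, out_dir = d1)
  r2 <- run_report(sc, out_dir = d2)
  for (f in c("game_trajectory.csv", "coupled_trajectory.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_equal(r1$classification$case, "I.4")
  expect_equal(r1$R_game_steady, 0, tolerance = 1e-6)
  # tampered scenario: error raised before any file is written
  bad <- sc; bad$payoffs$b2 <- 20
  d3 <- file.path(tempfile(), "c")
  expect_error(run_report(bad, out_dir = d3), "b1 > b2")
  expect_false(dir.exists(d3))
})

test_that("benchmark report flags infection-free convergence", {
  sc <- load_scenario("paper_default", overrides = c(p21 = 0.5, q21 = 0.5))
  r <- run_report(sc)
  expect_true(r$infection_free)
  expect_lt(r$I_end, 1e-3)
  expect_equal(unname(r$classification$ess), matrix(c(1, 1), 1, 2))
  js <- report_to_json(r)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$classification$case, "I.4")
})
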