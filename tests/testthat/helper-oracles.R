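# Shared fixtures and independent oracles, built in code.

# Benchmark payoffs/rates/epidemic parameters (the bundled preset values).
paper_pm <- function() payoff_matrix()
paper_rates <- function(p21 = 1, q21 = 1) game_rates(p21 = p21, q21 = q21)
paper_epi <- function(tau = 1) epi_params(tau = tau)

# Rejection-sample a payoff matrix satisfying the ordering assumptions.
rand_pm <- function() {
  repeat {
    v <- sort(runif(4, 0.5, 12), decreasing = TRUE)
    pm <- try(payoff_matrix(b1 = runif(1, 5, 20), b2 = runif(1, 0.5, 4.9),
                            b3 = v[1], b4 = v[2], b5 = v[3], b6 = v[4],
                            c1 = runif(1, 0.5, 6), c11 = runif(1, 0.5, 6),
                            c21 = runif(1, 0.5, 6)),
              silent = TRUE)
    if (!inherits(pm, "try-error")) return(pm)
  }
}

rand_rates <- function(pmax = 2) {
  game_rates(lambda1 = runif(1, 0.5, 2), rho1 = runif(1, 0.5, 2),
             p21 = runif(1, 0, pmax), q21 = runif(1, 0, pmax))
}

rand_epi <- function(taumax = 3) {
  epi_params(a = runif(1, 0.5, 2), beta = runif(1, 0.05, 0.5),
             alpha = runif(1, 0.2, 2), gamma = runif(1, 0.1, 1),
             m = runif(1, 0.1, 1), tau = runif(1, 0, taumax))
}

# Eigenvalue-sign stability oracle for a 2x2 Jacobian.
eigen_label <- function(J, tol = 1e-9) {
  ev <- Re(eigen(J, only.values = TRUE)$values)
  if (max(abs(ev)) < tol) return("degenerate")
  if (all(ev < -tol)) return("ESS")
  if (all(ev > tol)) return("unstable")
  if (ev[1] * ev[2] < 0) return("saddle")
  "degenerate"
}

# Closed-form logistic solution of x' = r x (1 - x), x(0) = x0.
logistic_exact <- function(t, x0, r) 1 / (1 + (1 / x0 - 1) * exp(-r * t))

# Analytic method-of-steps solution of y'(t) = -y(t - 1), y = 1 on [-1, 0]:
# a polynomial of degree k + 1 on each segment [k, k + 1], built by exact
# piecewise integration of the previous segment.
dde_linear_oracle <- function(times) {
  kmax <- max(0, ceiling(max(times)))
  segs <- vector("list", kmax + 1)
  coef_prev <- 1     # history polynomial, constant 1
  endval <- 1
  for (k in 0:kmax) {
    intg <- -coef_prev / seq_along(coef_prev)   # integral of -P_{k-1}
    coef_k <- c(endval, intg)
    segs[[k + 1]] <- coef_k
    endval <- sum(coef_k)                        # value at segment end
    coef_prev <- coef_k
  }
  vapply(times, function(t) {
    if (t <= 0) return(1)
    k <- min(floor(t - 1e-12), kmax)
    u <- t - k
    cf <- segs[[k + 1]]
    sum(cf * u^(seq_along(cf) - 1))
  }, numeric(1))
}
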