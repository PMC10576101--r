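# Characteristic function of the linearized delayed model at an equilibrium:
# det(lambda I - J0 - z Jt) with z = exp(-lambda tau).  Linear in z, so it
# splits as P(lambda) + z Q(lambda).  Evaluated by explicit 3x3 cofactor
# expansion, vectorized over lambda (complex).
.char_PQ <- function(lambda, J0, Jt) {
  det3 <- function(lam, J) {
    m11 <- lam - J[1, 1]; m12 <- -J[1, 2]; m13 <- -J[1, 3]
    m21 <- -J[2, 1]; m22 <- lam - J[2, 2]; m23 <- -J[2, 3]
    m31 <- -J[3, 1]; m32 <- -J[3, 2]; m33 <- lam - J[3, 3]
    m11 * (m22 * m33 - m23 * m32) - m12 * (m21 * m33 - m23 * m31) +
      m13 * (m21 * m32 - m22 * m31)
  }
  P <- det3(lambda, J0)
  PQ <- det3(lambda, J0 + Jt)
  list(P = P, Q = PQ - P)
}

#' Numeric stability verification for an equilibrium of the delayed model
#'
#' Assembles the evidence used to decide local asymptotic stability for all
#' delays at either the infection-free or the endemic equilibrium of the
#' decoupled three-compartment model:
#' \enumerate{
#'   \item the eigenvalues of the delay-free (`tau = 0`) Jacobian at the
#'     equilibrium;
#'   \item the printed closed-form coefficient conditions: the quadratic
#'     coefficients `A`, `B` of the reduced characteristic factor at the
#'     infection-free point, or the cubic Routh-Hurwitz coefficients
#'     `a0..a3` at the endemic point (reported as printed; the numeric
#'     characteristic construction is authoritative);
#'   \item a scan for pure-imaginary characteristic roots: with the
#'     characteristic function split as `P(lambda) + Q(lambda) e^(-lambda
#'     tau)`, a root `i omega` exists for some delay iff
#'     `F(omega) = |P(i omega)|^2 - |Q(i omega)|^2` has a positive zero; the
#'     scan covers `omega` in `(0, omega_max]` on a fine grid with bisection
#'     refinement at sign changes.
#' }
#' The verdict is `stable_all_tau` when all delay-free eigenvalues have
#' negative real part and no pure-imaginary root exists, `unstable` when a
#' delay-free eigenvalue has positive real part, and `inconclusive`
#' otherwise (a delay-induced Hopf crossing is possible).
#'
#' @inheritParams seir_rhs
#' @param regime `"infection_free"` or `"endemic"`.
#' @param point Optional equilibrium to verify; computed from `regime` when
#'   missing. A point that is not an equilibrium raises an error.
#' @param omega_max Upper end of the imaginary-root scan; defaults to ten
#'   times the largest model rate.
#' @param n_grid Number of scan grid points.
#'
#' @return An object of class `"spectral_report"`: list with `regime`,
#'   `r_value`, `equilibrium`, `tau0_eigenvalues`, `coefficients`,
#'   `imaginary_root_scan` (data frame of `omega`, `F`), `omega_roots` and
#'   `verdict`.
#' @export
stability_report <- function(p, game, regime = c("infection_free", "endemic"),
                             point = NULL, omega_max = NULL, n_grid = 1e4) {
  regime <- match.arg(regime)
  g <- .check_game_state(game)
  x1 <- g[["x1"]]; y1 <- g[["y1"]]; x2 <- 1 - x1; y2 <- 1 - y1
  R <- if (x1 > 0) basic_reproduction_number(p, g) else NA_real_

  if (is.null(point)) {
    point <- if (regime == "infection_free") infection_free_equilibrium(p, g)
    else {
      pe <- suppressMessages(positive_equilibrium(p, g))
      if (is.null(pe))
        stop(sprintf("no endemic equilibrium exists (R = %.6g)", R),
             call. = FALSE)
      pe
    }
  }
  res <- max(abs(seir3_rhs(point, point[[3]], g, p)))
  if (res > 1e-8)
    stop(sprintf("supplied point is not an equilibrium (residual %.3g)", res),
         call. = FALSE)

  J <- .seir3_jacobian(point, g, p)
  eig <- eigen(J$J0 + J$Jt, only.values = TRUE)$values

  b <- p$m * x2 + y1; cc <- p$gamma + y2
  coefficients <- if (regime == "infection_free") {
    # printed quadratic-factor coefficients (B undefined at x1 = 0)
    c(A = b + cc,
      B = if (x1 > 0) b * cc - y2 * p$beta * p$a * x2 / x1 else NA_real_)
  } else {
    Istar <- point[[3]]; Sstar <- point[[1]]
    aa <- p$beta * Istar / (1 + p$alpha * Istar)
    d <- p$beta * Sstar / (1 + p$alpha * Istar)^2
    c(a0 = 1,
      a1 = b + cc + aa + p$m * x1,
      a2 = b * cc - p$m * x2 * y2 + (aa + p$m * x1) * (b + cc) -
        p$m * x2 * d,
      a3 = (aa + p$m * x1) * (b * cc - p$m * x2 * y2) +
        aa * d * p$m * x2 - (aa + p$m * x1) * d * p$m * x2)
  }

  if (is.null(omega_max))
    omega_max <- 10 * max(p$m, p$gamma, p$beta, p$a, p$alpha, 1,
                          abs(Re(eig)), abs(Im(eig)))
  omega <- seq(omega_max / n_grid, omega_max, length.out = n_grid)
  pq <- .char_PQ(1i * omega, J$J0, J$Jt)
  Fo <- Mod(pq$P)^2 - Mod(pq$Q)^2
  Ffun <- function(w) {
    v <- .char_PQ(1i * w, J$J0, J$Jt)
    Mod(v$P)^2 - Mod(v$Q)^2
  }
  roots <- numeric(0)
  flips <- which(Fo[-1] * Fo[-length(Fo)] < 0)
  for (i in flips) {
    r <- stats::uniroot(Ffun, c(omega[i], omega[i + 1]), tol = 1e-12)$root
    roots <- c(roots, r)
  }
  roots <- roots[roots > 1e-8]

  max_re <- max(Re(eig))
  verdict <- if (max_re > 1e-9) "unstable"
  else if (max_re < -1e-9 && length(roots) == 0) "stable_all_tau"
  else "inconclusive"

  structure(list(regime = regime, r_value = R, equilibrium = point,
                 tau0_eigenvalues = eig, coefficients = coefficients,
                 imaginary_root_scan = data.frame(omega = omega, F = Fo),
                 omega_roots = roots, verdict = verdict,
                 game = g, jacobian = J),
            class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat(sprintf("Spectral report (%s equilibrium)\n", x$regime))
  cat(sprintf("  R = %.6g; equilibrium (S, E, I) = (%.6g, %.6g, %.6g)\n",
              x$r_value, x$equilibrium[[1]], x$equilibrium[[2]],
              x$equilibrium[[3]]))
  cat("  tau = 0 eigenvalues:",
      paste(sprintf("%.4g%+.4gi", Re(x$tau0_eigenvalues),
                    Im(x$tau0_eigenvalues)), collapse = ", "), "\n")
  cat("  pure-imaginary roots found:",
      if (length(x$omega_roots)) paste(signif(x$omega_roots, 6),
                                       collapse = ", ") else "none", "\n")
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Lyapunov-descent evaluation along a trajectory
#'
#' Evaluates one of the two Lyapunov candidates along a stored trajectory
#' and returns finite-difference samples of its time derivative. `L1`
#' targets the infection-free equilibrium `S0 = a/(m x1)`:
#' \deqn{L_1 = S - S^0 - S^0 \ln(S/S^0) + E + I +
#'   \int_{t-\tau}^{t} \beta S^0 I(s)/(1+\alpha I(s))\, ds}
#' and is nonincreasing when `R < 1` and `gamma > beta a / (m x1)`. `L2`
#' targets the endemic equilibrium:
#' \deqn{L_2 = [(S - S^*) + (E - E^*) + (I - I^*)]^2.}
#' The integral term of `L1` is evaluated by the trapezoid rule on the
#' trajectory grid, so `L1` samples start at `t = tau`. Derivatives are
#' central differences; a tolerance of about `1e-8` absorbs the
#' finite-difference noise in descent checks.
#'
#' @param traj A trajectory from [integrate_coupled()] (or any data frame
#'   with columns `time`, `S`, `E`, `I` on a uniform grid with attribute
#'   `dt`; attribute `tau` is used for the `L1` integral).
#' @param p An [epi_params()].
#' @param game Numeric `(x1, y1)` used in the equilibrium the candidate
#'   targets (the descent statements hold for a fixed game state).
#' @param which `"L1"` or `"L2"`.
#' @param equilibrium For `L2`, the endemic point `(S*, E*, I*)`; computed
#'   via [positive_equilibrium()] when missing.
#'
#' @return A data frame with columns `time`, `L`, `dLdt` (`dLdt` is `NA` at
#'   the two ends).
#' @export
lyapunov_descent <- function(traj, p, game, which = c("L1", "L2"),
                             equilibrium = NULL) {
  which <- match.arg(which)
  g <- .check_game_state(game)
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- diff(traj$time[1:2])
  if (which == "L1") {
    S0 <- p$a / (p$m * g[["x1"]])
    tau <- attr(traj, "tau")
    if (is.null(tau)) tau <- p$tau
    K <- if (tau > 0) as.integer(round(tau / dt)) else 0L
    gI <- p$beta * S0 * traj$I / (1 + p$alpha * traj$I)
    cumG <- c(0, cumsum((gI[-1] + gI[-length(gI)]) / 2 * dt))
    idx <- seq.int(K + 1L, nrow(traj))
    G <- cumG[idx] - cumG[idx - K]
    L <- traj$S[idx] - S0 - S0 * log(traj$S[idx] / S0) +
      traj$E[idx] + traj$I[idx] + G
    tt <- traj$time[idx]
  } else {
    if (is.null(equilibrium))
      equilibrium <- positive_equilibrium(p, g)
    if (is.null(equilibrium))
      stop("no endemic equilibrium available for L2", call. = FALSE)
    L <- ((traj$S - equilibrium[[1]]) + (traj$E - equilibrium[[2]]) +
            (traj$I - equilibrium[[3]]))^2
    tt <- traj$time
  }
  n <- length(L)
  dLdt <- rep(NA_real_, n)
  if (n >= 3) dLdt[2:(n - 1)] <- (L[3:n] - L[1:(n - 2)]) / (2 * dt)
  data.frame(time = tt, L = L, dLdt = dLdt)
}
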