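#' Holling type II saturated incidence
#'
#' New-infection flux `beta * S * I_lag / (1 + alpha * I_lag)`: mass action
#' at low infective counts, saturating as infectives grow. The infective
#' count is read at the lagged time in the delayed model.
#'
#' @param S Susceptible count (>= 0).
#' @param I_lag Infective count at the lagged time (>= 0).
#' @param beta Transmission coefficient.
#' @param alpha Saturation constant (per individual).
#'
#' @return New-infection flux (individuals per unit time).
#' @examples
#' holling_incidence(2, 10, 0.2, 1) # 4/11
#' @export
holling_incidence <- function(S, I_lag, beta, alpha) {
  if (any(S < 0) || any(I_lag < 0))
    stop("S and I_lag must be nonnegative", call. = FALSE)
  beta * S * I_lag / (1 + alpha * I_lag)
}

#' Right-hand sides of the delayed SEIR panic model
#'
#' `seir_rhs()` is the full four-compartment model:
#' \deqn{S' = a - \beta S I_\tau/(1+\alpha I_\tau) - m x_1 S}
#' \deqn{E' = \beta S I_\tau/(1+\alpha I_\tau) - m x_2 E - y_1 E + y_2 I}
#' \deqn{I' = m x_2 E - \gamma I - y_2 I}
#' \deqn{R' = \gamma I + m x_1 S + y_1 E}
#' where `I_tau = I(t - tau)` and the opinion-game probabilities
#' `(x1, y1)` set the transition rates. The four derivatives sum to the
#' inflow `a` identically. `seir3_rhs()` is the decoupled three-compartment
#' form (the recovered equation feeds back into nothing).
#'
#' @param state Numeric `(S, E, I, R)` for `seir_rhs`, `(S, E, I)` for
#'   `seir3_rhs`.
#' @param I_lag Infective count at time `t - tau` (>= 0).
#' @param game Numeric `(x1, y1)` opinion-field strategy probabilities.
#' @param p An [epi_params()].
#'
#' @return Named numeric vector of time derivatives.
#' @examples
#' p <- epi_params(a = 1, beta = 0.2, alpha = 1, gamma = 0.5, m = 0.5)
#' seir3_rhs(c(2, 8, 10), 10, c(0.6, 0.5), p)
#' @export
seir_rhs <- function(state, I_lag, game, p) {
  st <- .check_epi_state(state, n = 4L)
  g <- .check_game_state(game)
  d3 <- seir3_rhs(st[1:3], I_lag, g, p)
  dR <- p$gamma * st[["I"]] + p$m * g[["x1"]] * st[["S"]] +
    g[["y1"]] * st[["E"]]
  c(d3, dR = dR)
}

#' @rdname seir_rhs
#' @export
seir3_rhs <- function(state, I_lag, game, p) {
  st <- .check_epi_state(state, n = 3L)
  g <- .check_game_state(game)
  if (!is.numeric(I_lag) || length(I_lag) != 1L || !is.finite(I_lag) ||
      I_lag < 0)
    stop("I_lag must be a single nonnegative number", call. = FALSE)
  x1 <- g[["x1"]]; y1 <- g[["y1"]]; x2 <- 1 - x1; y2 <- 1 - y1
  S <- st[["S"]]; E <- st[["E"]]; I <- st[["I"]]
  phiS <- holling_incidence(S, I_lag, p$beta, p$alpha)
  c(dS = p$a - phiS - p$m * x1 * S,
    dE = phiS - p$m * x2 * E - y1 * E + y2 * I,
    dI = p$m * x2 * E - p$gamma * I - y2 * I)
}

#' Basic reproduction number of the panic-contagion model
#'
#' The threshold quantity
#' `R = beta * a * x2 / (x1 * (m*x2 + y1) * (gamma + y2))`. Panic dies out
#' when `R < 1` (the infection-free equilibrium is stable) and persists when
#' `R > 1`. The expression is singular at `x1 = 0`; that is reported as an
#' explicit error rather than `NaN`/`Inf`.
#'
#' @inheritParams seir_rhs
#' @return A dimensionless scalar.
#' @examples
#' basic_reproduction_number(epi_params(), c(0.5, 0.5)) # 0.2666...
#' @export
basic_reproduction_number <- function(p, game) {
  g <- .check_game_state(game)
  x1 <- g[["x1"]]; y1 <- g[["y1"]]; x2 <- 1 - x1; y2 <- 1 - y1
  if (x1 <= 0)
    stop("basic reproduction number undefined at x1 = 0", call. = FALSE)
  den <- x1 * (p$m * x2 + y1) * (p$gamma + y2)
  if (den == 0)
    stop("basic reproduction number undefined: vanishing denominator",
         call. = FALSE)
  p$beta * p$a * x2 / den
}

#' Infection-free equilibrium of the decoupled model
#'
#' `E0 = (a / (m x1), 0, 0)`: with no exposed or infective individuals,
#' susceptibles balance inflow `a` against removal at rate `m x1`. It is a
#' fixed point of the three-compartment model for every admissible game
#' state with `x1 > 0`.
#'
#' @inheritParams seir_rhs
#' @return Named numeric `c(S, E, I)`.
#' @export
infection_free_equilibrium <- function(p, game) {
  g <- .check_game_state(game)
  if (g[["x1"]] <= 0)
    stop("infection-free equilibrium undefined at x1 = 0", call. = FALSE)
  c(S = p$a / (p$m * g[["x1"]]), E = 0, I = 0)
}

# Jacobian of seir3_rhs at a state, split into instantaneous (J0) and
# delayed (Jt, derivative w.r.t. I(t - tau)) parts; evaluated with I_lag = I.
.seir3_jacobian <- function(state, game, p) {
  g <- .check_game_state(game)
  x1 <- g[["x1"]]; y1 <- g[["y1"]]; x2 <- 1 - x1; y2 <- 1 - y1
  S <- state[[1]]; I <- state[[3]]
  a1 <- p$beta * I / (1 + p$alpha * I)          # d(phi S)/dS
  d <- p$beta * S / (1 + p$alpha * I)^2         # d(phi S)/dI_lag
  J0 <- matrix(c(-a1 - p$m * x1, 0, 0,
                 a1, -(p$m * x2 + y1), y2,
                 0, p$m * x2, -(p$gamma + y2)),
               3, 3, byrow = TRUE)
  Jt <- matrix(0, 3, 3)
  Jt[1, 3] <- -d
  Jt[2, 3] <- d
  list(J0 = J0, Jt = Jt)
}

#' Endemic (positive) equilibrium of the decoupled model
#'
#' When the basic reproduction number exceeds one, the three-compartment
#' model admits a unique steady state with all components positive. At
#' steady state the infective equation gives `E* = (gamma + y2) I* / (m x2)`
#' exactly; eliminating `S` and `E` reduces the remaining balance to a
#' single linear equation in `I*`, whose solution seeds a Newton polish on
#' the full three-dimensional residual (converged residual below `1e-10`).
#'
#' @inheritParams seir_rhs
#' @return Named numeric `c(S, E, I)` with attributes `R` (the reproduction
#'   number) and `residual`, or `NULL` (with a message reporting `R`) when
#'   `R <= 1` or no positive root exists.
#' @export
positive_equilibrium <- function(p, game) {
  g <- .check_game_state(game)
  R <- basic_reproduction_number(p, g)
  if (R <= 1) {
    message(sprintf("no endemic equilibrium: R = %.6g <= 1", R))
    return(NULL)
  }
  x1 <- g[["x1"]]; y1 <- g[["y1"]]; x2 <- 1 - x1; y2 <- 1 - y1
  b <- p$m * x2 + y1; cc <- p$gamma + y2
  if (x2 <= 0) {
    message("no endemic equilibrium: x2 = 0 (no exposed-to-infective flow)")
    return(NULL)
  }
  # steady state: incidence = k * I with k = (b c - m x2 y2) / (m x2),
  # S = (a - k I) / (m x1); beta S / (1 + alpha I) = k is linear in I.
  k <- (b * cc - p$m * x2 * y2) / (p$m * x2)
  I0 <- (p$beta * p$a - k * p$m * x1) / (k * (p$beta + p$alpha * p$m * x1))
  if (!is.finite(I0) || I0 <= 0) {
    message(sprintf("no positive root found (R = %.6g)", R))
    return(NULL)
  }
  st <- c((p$a - k * I0) / (p$m * x1), cc * I0 / (p$m * x2), I0)
  # Newton polish on the full residual with the tau = 0 Jacobian
  for (it in 1:50) {
    f <- seir3_rhs(pmax(st, 0), max(st[3], 0), g, p)
    if (max(abs(f)) < 1e-13) break
    J <- .seir3_jacobian(st, g, p)
    st <- st - solve(J$J0 + J$Jt, f)
  }
  res <- max(abs(seir3_rhs(st, st[3], g, p)))
  if (any(st <= 0) || res > 1e-10) {
    message(sprintf("no positive root found (R = %.6g)", R))
    return(NULL)
  }
  out <- c(S = st[[1]], E = st[[2]], I = st[[3]])
  attr(out, "R") <- R
  attr(out, "residual") <- res
  out
}
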