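#' Expected payoffs of the official opinion field
#'
#' Under public positive-response probability `y1`, positive guidance earns
#' `u1 = y1 (b1 - c1 - c11 + c21) + y2 (b2 - c1 + c21)` and negative guidance
#' earns `u2 = y1 (b1 - c1 - c11) + y2 (b2 - c1)`; the field average is
#' `ubar = x1 u1 + x2 u2` with `x2 = 1 - x1`, `y2 = 1 - y1`.
#'
#' @param pm A [payoff_matrix()].
#' @param state Numeric `(x1, y1)`: probabilities of positive guidance and
#'   positive response.
#'
#' @return Named numeric `c(u1, u2, ubar)` (utility units).
#' @examples
#' official_payoffs(payoff_matrix(), c(0.6, 1)) # u1 = 9, u2 = 5
#' @export
official_payoffs <- function(pm, state) {
  s <- .check_game_state(state)
  x1 <- s[["x1"]]; y1 <- s[["y1"]]; y2 <- 1 - y1
  u1 <- y1 * (pm$b1 - pm$c1 - pm$c11 + pm$c21) + y2 * (pm$b2 - pm$c1 + pm$c21)
  u2 <- y1 * (pm$b1 - pm$c1 - pm$c11) + y2 * (pm$b2 - pm$c1)
  c(u1 = u1, u2 = u2, ubar = x1 * u1 + (1 - x1) * u2)
}

#' Expected payoffs of the public opinion field
#'
#' Under official positive-guidance probability `x1`, a positive response
#' earns `u1 = x1 (b3 - c21) + x2 b5` and a negative response earns
#' `u2 = x1 (b4 - c21) + x2 b6`; the field average is `ubar = y1 u1 + y2 u2`.
#'
#' @inheritParams official_payoffs
#' @return Named numeric `c(u1, u2, ubar)` (utility units).
#' @examples
#' public_payoffs(payoff_matrix(), c(1, 0.5)) # u1 = 3, u2 = 1
#' @export
public_payoffs <- function(pm, state) {
  s <- .check_game_state(state)
  x1 <- s[["x1"]]; y1 <- s[["y1"]]; x2 <- 1 - x1
  u1 <- x1 * (pm$b3 - pm$c21) + x2 * pm$b5
  u2 <- x1 * (pm$b4 - pm$c21) + x2 * pm$b6
  c(u1 = u1, u2 = u2, ubar = y1 * u1 + (1 - y1) * u2)
}

# The selection "brackets" of the modified replicator: dx1/dt = lambda1 x1 x2 * bx,
# dy1/dt = rho1 y1 y2 * by.  bx is linear in y1, by linear in x1.
.bracket_x <- function(pm, rates, y1) {
  (pm$b2 - pm$c1 + pm$c21) - rates$p21 * (pm$b2 - pm$c1) +
    (1 - rates$p21) * (pm$b1 - pm$c11 - pm$b2) * y1
}

.bracket_y <- function(pm, rates, x1) {
  pm$b5 - rates$q21 * pm$b6 +
    (pm$b3 - pm$c21 - pm$b5 - rates$q21 * (pm$b4 - pm$c21) +
       rates$q21 * pm$b6) * x1
}

#' Modified replicator right-hand side for the two opinion fields
#'
#' The classical replicator is modified by the within-group dependence
#' coefficients: the growth of the positive-strategy share follows
#' `dx1/dt = lambda1 x1 (1 - x1) (u1A - p21 u2A)` for the official field and
#' `dy1/dt = rho1 y1 (1 - y1) (u1B - q21 u2B)` for the public field, where
#' `uiA`, `uiB` are the strategy payoffs of [official_payoffs()] and
#' [public_payoffs()]. With `p21 = q21 = 1` this is the classical two-field
#' replicator. Both components vanish at the four strategy corners.
#'
#' @inheritParams official_payoffs
#' @param rates A [game_rates()].
#'
#' @return Named numeric `c(dx1, dy1)` (probability per unit time).
#' @examples
#' replicator_rhs(c(0.6, 0.5), payoff_matrix(), game_rates()) # (0.96, 0.5)
#' @export
replicator_rhs <- function(state, pm, rates) {
  s <- .check_game_state(state)
  x1 <- s[["x1"]]; y1 <- s[["y1"]]
  c(dx1 = rates$lambda1 * x1 * (1 - x1) * .bracket_x(pm, rates, y1),
    dy1 = rates$rho1 * y1 * (1 - y1) * .bracket_y(pm, rates, x1))
}

#' General n-strategy replicator with strategy-dependence coefficients
#'
#' For one game group whose strategy counts grow as
#' `n_i' = kappa_i n_i u_i`, the share dynamics are
#' `z_i' = z_i kappa_i [u_i - ubar + sum_a (1 - kappa_a / kappa_i) z_a u_a]`
#' with `z_i = n_i / sum(n)` and `ubar = sum(z u)`. When all `kappa_i` are
#' equal this collapses to the classical replicator `z_i' = z_i kappa (u_i -
#' ubar)`. The returned derivatives sum to zero (shares conserve mass).
#'
#' @param counts Nonnegative strategy counts `n_i` (not all zero).
#' @param payoffs Strategy payoffs `u_i` (utility units).
#' @param kappa Strictly positive influence coefficients `kappa_i`.
#'
#' @return Numeric vector of share derivatives `dz_i/dt`.
#' @export
general_replicator_rhs <- function(counts, payoffs, kappa) {
  if (length(counts) == 0L) stop("empty population", call. = FALSE)
  if (length(payoffs) != length(counts) || length(kappa) != length(counts))
    stop("counts, payoffs and kappa must have equal length", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and nonnegative", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero counts", call. = FALSE)
  if (any(!is.finite(kappa)) || any(kappa <= 0))
    stop("kappa must be finite and > 0", call. = FALSE)
  z <- counts / sum(counts)
  ubar <- sum(z * payoffs)
  dep <- vapply(seq_along(z),
                function(i) sum((1 - kappa / kappa[i]) * z * payoffs),
                numeric(1))
  z * kappa * (payoffs - ubar + dep)
}
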