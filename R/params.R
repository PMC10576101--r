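#' Game payoff constants for the two opinion fields
#'
#' Bundles the nine constants of the official-field / public-field payoff
#' matrix. `b1`, `b2` are the official field's benefits when the public
#' attitude is positive resp. negative (regardless of its own strategy);
#' `b3`..`b6` are the public field's benefits for the four strategy pairs
#' (positive guidance & positive response, positive & negative, negative &
#' positive, negative & negative); `c1` is the official field's fixed cost,
#' `c11` its additional cost when the public responds positively, and `c21`
#' the public field's additional cost under positive official guidance. All
#' values are dimensionless utilities and must satisfy `b1 > b2` and
#' `b3 > b4 > b5 > b6`, with every constant strictly positive.
#'
#' The defaults are the bundled emergency-response benchmark
#' parameterization (see [load_scenario()]).
#'
#' @param b1,b2 Official-field benefits (positive / negative public attitude).
#' @param b3,b4,b5,b6 Public-field benefits per strategy pair.
#' @param c1 Official-field fixed cost.
#' @param c11 Official-field additional cost.
#' @param c21 Public-field additional cost.
#'
#' @return An object of class `"payoff_matrix"` (a validated named list).
#' @examples
#' pm <- payoff_matrix()
#' official_payoffs(pm, c(0.6, 0.5))
#' @export
payoff_matrix <- function(b1 = 15, b2 = 10, b3 = 7, b4 = 5, b5 = 3, b6 = 1,
                          c1 = 5, c11 = 5, c21 = 4) {
  pm <- list(b1 = b1, b2 = b2, b3 = b3, b4 = b4, b5 = b5, b6 = b6,
             c1 = c1, c11 = c11, c21 = c21)
  bad <- character(0)
  for (nm in names(pm)) {
    v <- pm[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad <- c(bad, sprintf("%s must be a single positive number", nm))
  }
  if (length(bad) == 0L) {
    if (!(b1 > b2)) bad <- c(bad, "b1 > b2 is required")
    if (!(b3 > b4 && b4 > b5 && b5 > b6))
      bad <- c(bad, "b3 > b4 > b5 > b6 is required")
  }
  if (length(bad)) stop("invalid payoff matrix: ", paste(bad, collapse = "; "),
                        call. = FALSE)
  structure(pm, class = "payoff_matrix")
}

#' Strategy influence and dependence coefficients
#'
#' `lambda1` and `rho1` are the influence coefficients (per unit time) of the
#' positive strategy in the official resp. public field. `p21 = lambda2/lambda1`
#' and `q21 = rho2/rho1` are the dimensionless within-group dependence
#' coefficients; the secondary coefficients `lambda2`, `rho2` are never stored
#' independently. With `p21 = q21 = 1` the modified replicator reduces to the
#' classical one.
#'
#' @param lambda1 Official-field influence coefficient (> 0).
#' @param rho1 Public-field influence coefficient (> 0).
#' @param p21 Official-field dependence coefficient (>= 0).
#' @param q21 Public-field dependence coefficient (>= 0).
#'
#' @return An object of class `"game_rates"`.
#' @export
game_rates <- function(lambda1 = 1, rho1 = 1, p21 = 1, q21 = 1) {
  stopifnot(is.numeric(lambda1), length(lambda1) == 1L, is.finite(lambda1),
            is.numeric(rho1), length(rho1) == 1L, is.finite(rho1),
            is.numeric(p21), length(p21) == 1L, is.finite(p21),
            is.numeric(q21), length(q21) == 1L, is.finite(q21))
  if (lambda1 <= 0 || rho1 <= 0) stop("lambda1 and rho1 must be > 0", call. = FALSE)
  if (p21 < 0 || q21 < 0) stop("p21 and q21 must be >= 0", call. = FALSE)
  structure(list(lambda1 = lambda1, rho1 = rho1, p21 = p21, q21 = q21),
            class = "game_rates")
}

#' Epidemiological parameters of the panic-contagion model
#'
#' @param a Population inflow (individuals per unit time, > 0).
#' @param beta Transmission coefficient (> 0).
#' @param alpha Incidence saturation constant (per individual, > 0).
#' @param gamma Recovery rate (per unit time, > 0).
#' @param m Authority of the official opinion field (per unit time, > 0);
#'   susceptibles recover at rate `m*x1` and exposed become infective at
#'   rate `m*x2`.
#' @param tau Delay (time units, >= 0) between exposure of susceptibles and
#'   the incidence they generate.
#'
#' @return An object of class `"epi_params"`.
#' @export
epi_params <- function(a = 1, beta = 0.2, alpha = 1, gamma = 0.5, m = 0.5,
                       tau = 0) {
  p <- list(a = a, beta = beta, alpha = alpha, gamma = gamma, m = m, tau = tau)
  bad <- character(0)
  for (nm in c("a", "beta", "alpha", "gamma", "m")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad <- c(bad, sprintf("%s must be a single positive number", nm))
  }
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    bad <- c(bad, "tau must be a single number >= 0")
  if (length(bad)) stop("invalid epidemic parameters: ",
                        paste(bad, collapse = "; "), call. = FALSE)
  structure(p, class = "epi_params")
}

# Validate a (x1, y1) strategy-probability pair; returns named numeric.
.check_game_state <- function(state, tol = 1e-9) {
  if (!is.numeric(state) || length(state) != 2L || any(!is.finite(state)))
    stop("game state must be a finite numeric vector (x1, y1)", call. = FALSE)
  if (any(state < -tol) || any(state > 1 + tol))
    stop("game state probabilities must lie in [0, 1]", call. = FALSE)
  c(x1 = unname(state[1]), y1 = unname(state[2]))
}

.check_epi_state <- function(state, n = 3L) {
  if (!is.numeric(state) || !(length(state) %in% c(3L, 4L)) ||
      any(!is.finite(state)))
    stop("epidemic state must be finite numeric (S, E, I[, R])", call. = FALSE)
  if (any(state < 0))
    stop("compartment sizes must be nonnegative", call. = FALSE)
  out <- unname(state)
  if (n == 4L && length(out) == 3L) out <- c(out, 0)
  names(out) <- c("S", "E", "I", "R")[seq_len(max(n, length(out)))]
  out[seq_len(n)]
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Opinion-field payoff matrix (utility units)\n")
  cat(sprintf("  official: b1=%g b2=%g  costs c1=%g c11=%g\n",
              x$b1, x$b2, x$c1, x$c11))
  cat(sprintf("  public:   b3=%g b4=%g b5=%g b6=%g  cost c21=%g\n",
              x$b3, x$b4, x$b5, x$b6, x$c21))
  invisible(x)
}

#' @export
print.game_rates <- function(x, ...) {
  cat(sprintf(
    "Replicator rates: lambda1=%g rho1=%g  dependence p21=%g q21=%g\n",
    x$lambda1, x$rho1, x$p21, x$q21))
  invisible(x)
}

#' @export
print.epi_params <- function(x, ...) {
  cat(sprintf(
    "SEIR parameters: a=%g beta=%g alpha=%g gamma=%g m=%g tau=%g\n",
    x$a, x$beta, x$alpha, x$gamma, x$m, x$tau))
  invisible(x)
}
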