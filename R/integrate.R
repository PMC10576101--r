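# Build the trajectory container (a data frame with solver metadata).
.trajectory <- function(df, params, dt, tau, scheme) {
  structure(df, params = params, dt = dt, tau = tau, scheme = scheme,
            class = c("panic_trajectory", "data.frame"))
}

#' Integrate the opinion-game replicator system
#'
#' Fixed-step RK4 solution of the two-field modified replicator dynamics.
#' No artificial clamping is applied; trajectories started in the unit
#' square remain there up to integration tolerance (checked to `1e-9`,
#' violation aborts).
#'
#' @param initial Numeric `(x1, y1)` starting probabilities.
#' @inheritParams replicator_rhs
#' @param t_end Final time (default 50 model time units).
#' @param dt Step size (default 0.01).
#'
#' @return A `panic_trajectory` data frame with columns `time`, `x1`, `y1`.
#' @examples
#' tr <- integrate_game(c(0.6, 0.5), payoff_matrix(), game_rates(),
#'                      t_end = 10)
#' steady_state_time(tr, "x1", 1)
#' @export
integrate_game <- function(initial, pm, rates, t_end = 50, dt = 0.01) {
  g0 <- .check_game_state(initial)
  rhs <- function(t, y, ylag) replicator_rhs(y, pm, rates)
  sol <- dde_integrate(rhs, unname(g0), tau = 0, t_end = t_end, dt = dt)
  if (any(sol$state < -1e-9) || any(sol$state > 1 + 1e-9))
    stop("game trajectory left [0,1]^2 beyond tolerance; reduce dt",
         call. = FALSE)
  .trajectory(data.frame(time = sol$time, x1 = sol$state[, 1],
                         y1 = sol$state[, 2]),
              params = list(pm = pm, rates = rates),
              dt = sol$dt, tau = 0, scheme = "rk4")
}

#' Integrate the coupled game / delayed SEIR system
#'
#' Method-of-steps RK4 for the one-way coupled system: the opinion-game
#' probabilities evolve by the modified replicator dynamics (no feedback
#' from the epidemic), and at every step feed the transition rates
#' `m*x1`, `m*x2`, `y1`, `y2` of the delayed SEIR model, whose incidence
#' reads the infective count at `t - tau`. The pre-history is constant at
#' the initial state unless supplied. The step size is shrunk so `tau/dt`
#' is an integer (at least 20 steps per lag). With `tau = 0` the system is
#' an ODE and the result matches a reference adaptive integrator to about
#' `1e-6` relative.
#'
#' @param initial_game Numeric `(x1, y1)`.
#' @param initial_epi Numeric `(S, E, I)` or `(S, E, I, R)`; `R` defaults
#'   to 0.
#' @inheritParams replicator_rhs
#' @param p An [epi_params()] (its `tau` is the lag used).
#' @param t_end Final time (default 200 model time units).
#' @param dt Requested step size (default 0.01; shrunk to align with the
#'   lag).
#' @param history Optional function `(t) -> I` giving the infective count
#'   for `t < 0`; defaults to the constant initial value.
#' @param evolve_game If `FALSE`, the game state is held fixed at
#'   `initial_game` (useful for stability echoes of the epidemic subsystem).
#'
#' @return A `panic_trajectory` data frame with columns `time`, `x1`, `y1`,
#'   `S`, `E`, `I`, `R`.
#' @export
integrate_coupled <- function(initial_game, initial_epi, pm, rates, p,
                              t_end = 200, dt = 0.01, history = NULL,
                              evolve_game = TRUE) {
  g0 <- .check_game_state(initial_game)
  e0 <- .check_epi_state(initial_epi, n = 4L)
  y0 <- c(unname(g0), unname(e0))
  histI <- history
  hist_fun <- function(t) {
    y <- y0
    if (!is.null(histI)) y[5] <- histI(t)
    y
  }
  rhs <- function(t, y, ylag) {
    dg <- if (evolve_game) {
      x1 <- min(max(y[1], 0), 1); yy1 <- min(max(y[2], 0), 1)
      c(rates$lambda1 * x1 * (1 - x1) * .bracket_x(pm, rates, yy1),
        rates$rho1 * yy1 * (1 - yy1) * .bracket_y(pm, rates, x1))
    } else c(0, 0)
    x1 <- y[1]; yy1 <- y[2]; x2 <- 1 - x1; yy2 <- 1 - yy1
    S <- y[3]; E <- y[4]; I <- y[5]
    Ilag <- max(ylag[5], 0)
    phiS <- p$beta * S * Ilag / (1 + p$alpha * Ilag)
    c(dg,
      p$a - phiS - p$m * x1 * S,
      phiS - p$m * x2 * E - yy1 * E + yy2 * I,
      p$m * x2 * E - p$gamma * I - yy2 * I,
      p$gamma * I + p$m * x1 * S + yy1 * E)
  }
  sol <- dde_integrate(rhs, y0, tau = p$tau, t_end = t_end, dt = dt,
                       history = hist_fun)
  if (any(sol$state[, 3:6] < -1e-9))
    stop("negative compartment beyond tolerance; reduce dt", call. = FALSE)
  .trajectory(data.frame(time = sol$time, x1 = sol$state[, 1],
                         y1 = sol$state[, 2], S = sol$state[, 3],
                         E = sol$state[, 4], I = sol$state[, 5],
                         R = sol$state[, 6]),
              params = list(pm = pm, rates = rates, p = p),
              dt = sol$dt, tau = p$tau, scheme = "rk4-method-of-steps")
}

#' Earliest time a trajectory component settles into a band
#'
#' Returns the earliest grid time after which the component stays within
#' `eps` of `target` for the remainder of the trajectory (hold-to-end
#' semantics: a component that leaves the band after entering it is timed
#' from its final entry).
#'
#' @param traj A `panic_trajectory` (or data frame with a `time` column).
#' @param component Column name to monitor.
#' @param target Target value.
#' @param eps Half-width of the settling band (default 0.01, absolute).
#'
#' @return The settling time, `0` if the trajectory starts and stays inside
#'   the band, or `NA` if it never settles.
#' @export
steady_state_time <- function(traj, component, target, eps = 0.01) {
  stopifnot(eps > 0)
  if (!component %in% names(traj))
    stop(sprintf("unknown component '%s'", component), call. = FALSE)
  v <- traj[[component]]
  ok <- abs(v - target) <= eps
  n <- length(ok)
  if (!ok[n]) return(NA_real_)
  bad <- which(!ok)
  idx <- if (length(bad)) max(bad) + 1L else 1L
  traj$time[idx]
}

#' Delay sweep of the coupled model
#'
#' Re-runs the coupled integration for several lags with everything else
#' held identical, and summarizes each run by the susceptible peak (value
#' and time) and the settling time of the exposed compartment.
#'
#' @param scenario A `panic_scenario` (see [load_scenario()]).
#' @param taus Nonnegative lags to sweep (default `c(1, 2, 3)`).
#' @param eps Settling band half-width for the exposed compartment.
#'
#' @return An object of class `"delay_sweep"`: list with `summary` (data
#'   frame of `tau`, `S_peak`, `S_peak_time`, `S_trough`, `E_settle_time`)
#'   and `trajectories` (one `panic_trajectory` per lag).
#' @export
delay_sweep <- function(scenario, taus = c(1, 2, 3), eps = 0.01) {
  stopifnot(is.numeric(taus), all(taus >= 0))
  trajs <- lapply(taus, function(tau) {
    p <- scenario$epi
    p$tau <- tau
    integrate_coupled(scenario$init_game, scenario$init_epi,
                      scenario$payoffs, scenario$rates, p,
                      t_end = scenario$t_end_coupled, dt = scenario$dt)
  })
  summ <- do.call(rbind, lapply(seq_along(taus), function(i) {
    tr <- trajs[[i]]
    ip <- which.max(tr$S)
    data.frame(tau = taus[i], S_peak = tr$S[ip], S_peak_time = tr$time[ip],
               S_trough = min(tr$S),
               E_settle_time = steady_state_time(tr, "E", 0, eps = eps))
  }))
  structure(list(summary = summ, trajectories = trajs, taus = taus),
            class = "delay_sweep")
}

#' @export
print.delay_sweep <- function(x, ...) {
  cat("Delay sweep of the coupled panic model\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
print.panic_trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory: %d samples on [0, %g], dt = %g, tau = %g (%s)\n",
    nrow(x), x$time[nrow(x)], attr(x, "dt"), attr(x, "tau"),
    attr(x, "scheme")))
  utils::str(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Plot a simulated trajectory
#'
#' Game-only trajectories show the two strategy probabilities; coupled
#' trajectories add a second panel with the SEIR compartments.
#'
#' @param x A `panic_trajectory`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.panic_trajectory <- function(x, ...) {
  coupled <- "S" %in% names(x)
  if (coupled) {
    old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
  }
  graphics::matplot(x$time, cbind(x$x1, x$y1), type = "l", lty = 1,
                    col = c("blue", "darkorange"), xlab = "time",
                    ylab = "strategy probability", ...)
  graphics::legend("bottomright", c("official x1", "public y1"),
                   col = c("blue", "darkorange"), lty = 1, bty = "n")
  if (coupled) {
    graphics::matplot(x$time, cbind(x$S, x$E, x$I), type = "l", lty = 1,
                      col = c("forestgreen", "purple", "red"),
                      xlab = "time", ylab = "individuals", ...)
    graphics::legend("topright", c("S", "E", "I"),
                     col = c("forestgreen", "purple", "red"), lty = 1,
                     bty = "n")
  }
  invisible(x)
}

#' Write a trajectory to CSV with metadata header
#'
#' Writes `#`-prefixed metadata lines (scheme, dt, tau, flattened
#' parameters) followed by a standard header row and the samples. Output is
#' deterministic: identical trajectories produce byte-identical files.
#'
#' @param traj A `panic_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  params <- attr(traj, "params")
  flat <- unlist(params)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# scheme: %s", attr(traj, "scheme")), con)
  writeLines(sprintf("# dt: %.17g", attr(traj, "dt")), con)
  writeLines(sprintf("# tau: %.17g", attr(traj, "tau")), con)
  if (length(flat))
    writeLines(sprintf("# param %s: %.17g", names(flat), flat), con)
  utils::write.table(format(as.data.frame(traj), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
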