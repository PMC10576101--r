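#' The coupled panic-spread model as a single object
#'
#' Wraps a scenario into a model object holding the cached game analysis:
#' scenario case classification, labelled fixed points, and the basic
#' reproduction number at the initial strategy probabilities. The model is
#' a deterministic dynamical system; [simulate()][simulate.panic_model()]
#' integrates it forward.
#'
#' @param scenario A `panic_scenario` (see [load_scenario()]); defaults to
#'   the bundled benchmark parameterization.
#'
#' @return An object of class `"panic_model"`.
#' @examples
#' m <- panic_model()
#' summary(m)
#' tr <- simulate(m, t_end = 20)
#' @export
panic_model <- function(scenario = load_scenario("paper_default")) {
  if (!inherits(scenario, "panic_scenario"))
    stop("scenario must be a panic_scenario", call. = FALSE)
  cls <- classify_scenario(scenario$payoffs, scenario$rates)
  R0 <- tryCatch(basic_reproduction_number(scenario$epi, scenario$init_game),
                 error = function(e) NA_real_)
  structure(list(scenario = scenario, classification = cls, R_initial = R0),
            class = "panic_model")
}

#' @export
print.panic_model <- function(x, ...) {
  cat("Delayed SEIR evolutionary-game panic model\n")
  cat(sprintf("  scenario '%s'; game case %s; R at start = %.4g\n",
              x$scenario$name, x$classification$case, x$R_initial))
  invisible(x)
}

#' @export
summary.panic_model <- function(object, ...) {
  structure(list(model = object), class = "summary.panic_model")
}

#' @export
print.summary.panic_model <- function(x, ...) {
  m <- x$model
  print(m$scenario)
  print(m$classification)
  cat(sprintf("  basic reproduction number at initial strategies: %.6g\n",
              m$R_initial))
  invisible(x)
}

#' @export
coef.panic_model <- function(object, ...) {
  sc <- object$scenario
  c(unlist(sc$payoffs), unlist(sc$rates), unlist(sc$epi),
    x1 = unname(sc$init_game[["x1"]]), y1 = unname(sc$init_game[["y1"]]),
    S = unname(sc$init_epi[["S"]]), E = unname(sc$init_epi[["E"]]),
    I = unname(sc$init_epi[["I"]]), R = unname(sc$init_epi[["R"]]))
}

#' Simulate the coupled panic model forward
#'
#' The model is deterministic; `seed` and `nsim` are accepted for
#' compatibility with the [stats::simulate()] generic (repeated simulations
#' are identical).
#'
#' @param object A `panic_model`.
#' @param nsim Number of (identical) trajectories to return.
#' @param seed Ignored (accepted for generic compatibility).
#' @param t_end,dt,tau Optional overrides of the scenario solver settings
#'   and lag.
#' @param ... Unused.
#'
#' @return A `panic_trajectory` (or a list of them when `nsim > 1`).
#' @export
simulate.panic_model <- function(object, nsim = 1, seed = NULL,
                                 t_end = NULL, dt = NULL, tau = NULL, ...) {
  sc <- object$scenario
  p <- sc$epi
  if (!is.null(tau)) p$tau <- tau
  run <- function() integrate_coupled(
    sc$init_game, sc$init_epi, sc$payoffs, sc$rates, p,
    t_end = if (is.null(t_end)) sc$t_end_coupled else t_end,
    dt = if (is.null(dt)) sc$dt else dt)
  if (nsim == 1) run() else replicate(nsim, run(), simplify = FALSE)
}

#' @export
plot.panic_model <- function(x, t_end = NULL, ...) {
  plot(simulate(x, t_end = t_end), ...)
}
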