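# Recognized flat-config keys and where they land in the scenario.
.scenario_keys <- c("b1", "b2", "b3", "b4", "b5", "b6", "c1", "c11", "c21",
                    "lambda1", "rho1", "p21", "q21",
                    "a", "beta", "alpha", "gamma", "m", "tau",
                    "x1", "y1", "S", "E", "I", "R",
                    "dt", "t_end_game", "t_end_coupled")

.paper_default_values <- c(
  b1 = 15, b2 = 10, b3 = 7, b4 = 5, b5 = 3, b6 = 1, c1 = 5, c11 = 5, c21 = 4,
  lambda1 = 1, rho1 = 1, p21 = 1, q21 = 1,
  a = 1, beta = 0.2, alpha = 1, gamma = 0.5, m = 0.5, tau = 1,
  x1 = 0.6, y1 = 0.5, S = 2, E = 8, I = 10, R = 0,
  dt = 0.01, t_end_game = 50, t_end_coupled = 200)

.build_scenario <- function(v, name) {
  sc <- list(
    name = name,
    payoffs = payoff_matrix(b1 = v[["b1"]], b2 = v[["b2"]], b3 = v[["b3"]],
                            b4 = v[["b4"]], b5 = v[["b5"]], b6 = v[["b6"]],
                            c1 = v[["c1"]], c11 = v[["c11"]],
                            c21 = v[["c21"]]),
    rates = game_rates(lambda1 = v[["lambda1"]], rho1 = v[["rho1"]],
                       p21 = v[["p21"]], q21 = v[["q21"]]),
    epi = epi_params(a = v[["a"]], beta = v[["beta"]], alpha = v[["alpha"]],
                     gamma = v[["gamma"]], m = v[["m"]], tau = v[["tau"]]),
    init_game = .check_game_state(c(v[["x1"]], v[["y1"]])),
    init_epi = .check_epi_state(c(v[["S"]], v[["E"]], v[["I"]], v[["R"]]),
                                n = 4L),
    dt = v[["dt"]],
    t_end_game = v[["t_end_game"]],
    t_end_coupled = v[["t_end_coupled"]])
  if (sc$dt <= 0 || sc$t_end_game <= 0 || sc$t_end_coupled <= 0)
    stop("dt and horizon settings must be positive", call. = FALSE)
  structure(sc, class = "panic_scenario")
}

#' Load a simulation scenario from a preset or a config file
#'
#' A scenario bundles the payoff matrix, replicator rates, epidemic
#' parameters, initial conditions and solver settings. The preset
#' `"paper_default"` carries the benchmark emergency parameterization:
#' payoffs `b1=15, b2=10, b3=7, b4=5, b5=3, b6=1`, costs
#' `c1=5, c11=5, c21=4`, rates `lambda1=rho1=1` with `p21=q21=1`, epidemic
#' parameters `a=1, beta=0.2, alpha=1, gamma=0.5, m=0.5` with lag `tau=1`,
#' and initial conditions `(x1, y1) = (0.6, 0.5)`, `(S, E, I) = (2, 8, 10)`.
#'
#' Config files are flat `key = value` text: `#` comments and `[section]`
#' headers are ignored, keys are globally unique. Unknown keys are rejected
#' with all offending keys listed. Missing keys inherit the preset values,
#' so a file needs only the overrides.
#'
#' @param source The preset name `"paper_default"` or a config file path.
#' @param overrides Optional named numeric overrides applied after parsing
#'   (e.g. `c(p21 = 1.5, q21 = 0.5)`).
#' @param verbose If `TRUE`, echo every resolved parameter as a message.
#'
#' @return An object of class `"panic_scenario"`.
#' @examples
#' sc <- load_scenario("paper_default", overrides = c(p21 = 0.5, q21 = 0.5))
#' sc$rates
#' @export
load_scenario <- function(source = "paper_default", overrides = NULL,
                          verbose = FALSE) {
  v <- .paper_default_values
  name <- source
  if (!identical(source, "paper_default")) {
    if (!file.exists(source))
      stop(sprintf("unknown preset or missing config file: '%s'", source),
           call. = FALSE)
    lines <- readLines(source, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    if (any(lengths(kv) != 2L))
      stop("config lines must be 'key = value'", call. = FALSE)
    keys <- trimws(vapply(kv, `[`, "", 1L))
    vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
    unknown <- setdiff(keys, .scenario_keys)
    if (length(unknown))
      stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(is.na(vals)))
      stop("non-numeric values for keys: ",
           paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
    v[keys] <- vals
    name <- basename(source)
  }
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), .scenario_keys)
    if (length(unknown))
      stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    v[names(overrides)] <- overrides
  }
  if (verbose)
    for (k in names(v)) message(sprintf("scenario %s: %s = %g", name, k,
                                        v[[k]]))
  .build_scenario(v, name)
}

#' @export
print.panic_scenario <- function(x, ...) {
  cat(sprintf("Panic-spread scenario '%s'\n", x$name))
  print(x$payoffs)
  print(x$rates)
  print(x$epi)
  cat(sprintf("  initial game (x1, y1) = (%g, %g); epi (S, E, I, R) = (%g, %g, %g, %g)\n",
              x$init_game[["x1"]], x$init_game[["y1"]], x$init_epi[["S"]],
              x$init_epi[["E"]], x$init_epi[["I"]], x$init_epi[["R"]]))
  cat(sprintf("  solver: dt = %g, horizons %g (game) / %g (coupled)\n",
              x$dt, x$t_end_game, x$t_end_coupled))
  invisible(x)
}

#' Sensitivity surface of the basic reproduction number
#'
#' Evaluates `R` elementwise over a grid of two varied epidemic parameters
#' (any two of `m`, `gamma`, `beta`), at fixed strategy probabilities.
#' A monotonicity summary (the sign pattern of the discrete partial
#' differences along each axis) is attached.
#'
#' @param p An [epi_params()] providing the fixed parameter values.
#' @param game Numeric `(x1, y1)`; defaults to `(0.5, 0.5)`. `x1 = 0` is
#'   rejected (the reproduction number is singular there).
#' @param vary Character vector of the two varied parameter names.
#' @param grid1,grid2 Positive value grids for the two varied parameters.
#'
#' @return An object of class `"sensitivity_grid"`: list with `vary`,
#'   `grid1`, `grid2`, `R` (matrix, rows follow `grid1`), `fixed` (record
#'   of every fixed parameter incl. the strategy probabilities) and
#'   `monotonicity` (named `"increasing"`/`"decreasing"`/`"mixed"`).
#' @examples
#' sg <- r_sensitivity(epi_params(), vary = c("m", "gamma"),
#'                     grid1 = seq(0.1, 1, 0.1), grid2 = seq(0.1, 1, 0.1))
#' sg$monotonicity
#' @export
r_sensitivity <- function(p, game = c(0.5, 0.5), vary = c("m", "gamma"),
                          grid1, grid2) {
  g <- .check_game_state(game)
  if (g[["x1"]] <= 0)
    stop("x1 = 0 makes the reproduction number singular", call. = FALSE)
  allowed <- c("m", "gamma", "beta")
  if (length(vary) != 2L || !all(vary %in% allowed) || vary[1] == vary[2])
    stop("vary must name two distinct parameters among m, gamma, beta",
         call. = FALSE)
  stopifnot(all(grid1 > 0), all(grid2 > 0))
  Rmat <- matrix(NA_real_, length(grid1), length(grid2))
  for (i in seq_along(grid1)) {
    for (j in seq_along(grid2)) {
      pp <- p
      pp[[vary[1]]] <- grid1[i]
      pp[[vary[2]]] <- grid2[j]
      Rmat[i, j] <- basic_reproduction_number(pp, g)
    }
  }
  mono <- function(dmat) {
    if (all(dmat > 0)) "increasing"
    else if (all(dmat < 0)) "decreasing"
    else "mixed"
  }
  monotonicity <- c(mono(apply(Rmat, 2, diff)),
                    mono(t(apply(Rmat, 1, diff))))
  names(monotonicity) <- vary
  fixed <- c(unlist(p[setdiff(c("a", "beta", "alpha", "gamma", "m"), vary)]),
             x1 = g[["x1"]], y1 = g[["y1"]])
  structure(list(vary = vary, grid1 = grid1, grid2 = grid2, R = Rmat,
                 fixed = fixed, monotonicity = monotonicity),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("R sensitivity surface over %s (%d x %d grid)\n",
              paste(x$vary, collapse = " x "), length(x$grid1),
              length(x$grid2)))
  cat("  monotonicity:",
      paste(sprintf("%s: %s", names(x$monotonicity), x$monotonicity),
            collapse = ", "), "\n")
  cat("  fixed:", paste(sprintf("%s = %g", names(x$fixed), x$fixed),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Write a sensitivity grid as CSV
#'
#' Row and column headers are the parameter values; metadata (fixed
#' parameters, strategy probabilities) goes into `#`-prefixed lines.
#'
#' @param grid A `"sensitivity_grid"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(grid, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# vary: %s (rows) x %s (cols)", grid$vary[1],
                     grid$vary[2]), con)
  writeLines(sprintf("# fixed %s: %.17g", names(grid$fixed), grid$fixed), con)
  m <- cbind(grid$grid1, grid$R)
  colnames(m) <- c(grid$vary[1], format(grid$grid2, digits = 15,
                                        trim = TRUE))
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Full scenario report
#'
#' Runs the complete analysis pipeline for a scenario: game-case
#' classification, labelled fixed points, the reproduction number at the
#' initial and at the game steady-state strategy probabilities, the game
#' and coupled trajectories with settling times, and the epidemic
#' endpoints. Optionally writes the trajectories as CSV. The report is
#' deterministic given the scenario, and nothing is written unless the
#' whole computation succeeds.
#'
#' @param scenario A `panic_scenario`.
#' @param out_dir Optional directory for trajectory CSVs (created if
#'   missing); when `NULL` no files are written.
#'
#' @return An object of class `"panic_report"`.
#' @export
run_report <- function(scenario, out_dir = NULL) {
  if (!inherits(scenario, "panic_scenario"))
    stop("scenario must be a panic_scenario", call. = FALSE)
  # re-validate (guards against tampered objects); errors out before any IO
  sc <- .build_scenario(c(unlist(scenario$payoffs),
                          unlist(scenario$rates),
                          unlist(scenario$epi),
                          x1 = unname(scenario$init_game[["x1"]]),
                          y1 = unname(scenario$init_game[["y1"]]),
                          S = unname(scenario$init_epi[["S"]]),
                          E = unname(scenario$init_epi[["E"]]),
                          I = unname(scenario$init_epi[["I"]]),
                          R = unname(scenario$init_epi[["R"]]),
                          dt = scenario$dt,
                          t_end_game = scenario$t_end_game,
                          t_end_coupled = scenario$t_end_coupled),
                        scenario$name)

  cls <- classify_scenario(sc$payoffs, sc$rates)
  game_tr <- integrate_game(sc$init_game, sc$payoffs, sc$rates,
                            t_end = sc$t_end_game, dt = sc$dt)
  coup_tr <- integrate_coupled(sc$init_game, sc$init_epi, sc$payoffs,
                               sc$rates, sc$epi, t_end = sc$t_end_coupled,
                               dt = sc$dt)
  n <- nrow(coup_tr)
  g_end <- c(game_tr$x1[nrow(game_tr)], game_tr$y1[nrow(game_tr)])
  safeR <- function(g) tryCatch(basic_reproduction_number(sc$epi, g),
                                error = function(e) NA_real_)
  times <- c(x1 = steady_state_time(game_tr, "x1", round(g_end[1])),
             y1 = steady_state_time(game_tr, "y1", round(g_end[2])),
             S = steady_state_time(coup_tr, "S", coup_tr$S[n]),
             E = steady_state_time(coup_tr, "E", 0),
             I = steady_state_time(coup_tr, "I", 0))
  rep <- list(
    scenario = sc$name,
    classification = cls,
    equilibria = cls$equilibria,
    R_initial = safeR(sc$init_game),
    R_game_steady = safeR(g_end),
    steady_state_times = times,
    E_end = coup_tr$E[n],
    I_end = coup_tr$I[n],
    infection_free = is.finite(coup_tr$I[n]) && coup_tr$I[n] < 1e-3 &&
      coup_tr$E[n] < 1e-3,
    csv_paths = NULL)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(game = file.path(out_dir, "game_trajectory.csv"),
               coupled = file.path(out_dir, "coupled_trajectory.csv"))
    write_trajectory_csv(game_tr, paths[["game"]])
    write_trajectory_csv(coup_tr, paths[["coupled"]])
    rep$csv_paths <- paths
  }
  rep$game_trajectory <- game_tr
  rep$coupled_trajectory <- coup_tr
  structure(rep, class = "panic_report")
}

#' @export
print.panic_report <- function(x, ...) {
  cat(sprintf("Panic-spread report for scenario '%s'\n", x$scenario))
  cat(sprintf("  game case %s; ESS %s\n", x$classification$case,
              if (!is.null(x$classification$ess) &&
                  nrow(x$classification$ess) > 0)
                paste(sprintf("(%g, %g)", x$classification$ess[, 1],
                              x$classification$ess[, 2]), collapse = ", ")
              else "none"))
  cat(sprintf("  R at initial strategies: %.6g; at game steady state: %.6g\n",
              x$R_initial, x$R_game_steady))
  st <- x$steady_state_times
  cat("  settling times:",
      paste(sprintf("%s = %s", names(st),
                    ifelse(is.na(st), "never", signif(st, 4))),
            collapse = ", "), "\n")
  cat(sprintf("  endpoint E = %.4g, I = %.4g (%s)\n", x$E_end, x$I_end,
              if (x$infection_free) "infection-free" else "panic persists"))
  if (!is.null(x$csv_paths))
    cat("  CSVs:", paste(x$csv_paths, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a report (or classification) to JSON
#'
#' @param x A `panic_report`, `scenario_class` or `spectral_report`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_to_json <- function(x, path = NULL) {
  strip <- function(v) {
    if (inherits(v, "panic_trajectory")) return(NULL)
    if (is.complex(v)) return(list(re = Re(v), im = Im(v)))
    if (is.list(v) && !is.data.frame(v)) {
      out <- lapply(unclass(v), strip)
      return(out[!vapply(out, is.null, logical(1))])
    }
    v
  }
  js <- jsonlite::toJSON(strip(x), auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
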