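#' Fixed points of the modified replicator system
#'
#' The four strategy corners `(0,0)`, `(0,1)`, `(1,0)`, `(1,1)` are always
#' fixed points. An interior fixed point `E5` exists when both selection
#' brackets can vanish inside the unit square; its closed form is
#' `x1* = (b5 - q21 b6) / (b5 - b3 + c21 + q21 (b4 - c21) - q21 b6)` and
#' `y1* = (b2 - c1 + c21 - p21 (b2 - c1)) / ((1 - p21)(b2 + c11 - b1))`.
#' `E5` is reported only when both denominators are nonzero and both
#' coordinates are strictly interior; otherwise it is omitted and the reason
#' is attached as attribute `"e5_note"` (and emitted as a message).
#'
#' @inheritParams replicator_rhs
#' @param tol Absolute tolerance for the denominator / interiority checks.
#'
#' @return A data frame with columns `name`, `x1`, `y1`; one row per fixed
#'   point. Every returned point has replicator norm below `1e-12`.
#' @export
find_equilibria <- function(pm, rates, tol = 1e-9) {
  pts <- data.frame(name = c("E1", "E2", "E3", "E4"),
                    x1 = c(0, 0, 1, 1), y1 = c(0, 1, 0, 1),
                    stringsAsFactors = FALSE)
  den_x <- pm$b5 - pm$b3 + pm$c21 + rates$q21 * (pm$b4 - pm$c21) -
    rates$q21 * pm$b6
  den_y <- (1 - rates$p21) * (pm$b2 + pm$c11 - pm$b1)
  note <- NULL
  if (abs(den_x) <= tol || abs(den_y) <= tol) {
    note <- "interior point E5 absent: a bracket denominator vanishes"
  } else {
    x5 <- (pm$b5 - rates$q21 * pm$b6) / den_x
    y5 <- ((pm$b2 - pm$c1 + pm$c21) - rates$p21 * (pm$b2 - pm$c1)) / den_y
    if (x5 > tol && x5 < 1 - tol && y5 > tol && y5 < 1 - tol) {
      pts <- rbind(pts, data.frame(name = "E5", x1 = x5, y1 = y5,
                                   stringsAsFactors = FALSE))
    } else {
      note <- sprintf(
        "interior point E5 absent: closed form (%.6g, %.6g) not strictly interior",
        x5, y5)
    }
  }
  if (!is.null(note)) {
    message(note)
    attr(pts, "e5_note") <- note
  }
  pts
}

#' Jacobian of the modified replicator system
#'
#' Hand-coded partial derivatives of [replicator_rhs()] with respect to
#' `(x1, y1)`. The off-diagonal entries carry the vertex factors
#' `x1 (1 - x1)` and `y1 (1 - y1)` and therefore vanish at every corner.
#'
#' @inheritParams replicator_rhs
#' @return A 2x2 numeric matrix.
#' @export
game_jacobian <- function(state, pm, rates) {
  s <- .check_game_state(state)
  x1 <- s[["x1"]]; y1 <- s[["y1"]]
  j11 <- rates$lambda1 * (1 - 2 * x1) * .bracket_x(pm, rates, y1)
  j12 <- rates$lambda1 * x1 * (1 - x1) *
    (1 - rates$p21) * (pm$b1 - pm$c11 - pm$b2)
  j21 <- rates$rho1 * y1 * (1 - y1) *
    (pm$b3 - pm$c21 - pm$b5 - rates$q21 * (pm$b4 - pm$c21) +
       rates$q21 * pm$b6)
  j22 <- rates$rho1 * (1 - 2 * y1) * .bracket_y(pm, rates, x1)
  matrix(c(j11, j21, j12, j22), 2, 2,
         dimnames = list(c("dx1", "dy1"), c("x1", "y1")))
}

#' Stability label of a replicator fixed point
#'
#' Classifies a fixed point by the determinant/trace sign rule of the 2x2
#' Jacobian: `ESS` (evolutionarily stable) if `det > tol` and `trace < -tol`;
#' `unstable` if `det > tol` and `trace > tol`; `saddle` if `det < -tol`;
#' `degenerate` otherwise (the deciding quantity is within tolerance of
#' zero).
#'
#' @param point Numeric `(x1, y1)`; must be a fixed point of
#'   [replicator_rhs()] (checked, error otherwise).
#' @inheritParams replicator_rhs
#' @param tol Sign tolerance; quantities within `tol` of zero are treated as
#'   degenerate.
#'
#' @return An object of class `"equilibrium_report"`: a list with `point`,
#'   `jac`, `det`, `trace`, `label` and `interior`.
#' @export
classify_equilibrium <- function(point, pm, rates, tol = 1e-9) {
  s <- .check_game_state(point)
  rhs <- replicator_rhs(s, pm, rates)
  if (max(abs(rhs)) > 1e-8)
    stop(sprintf("point (%.6g, %.6g) is not a fixed point (|rhs| = %.3g)",
                 s[["x1"]], s[["y1"]], max(abs(rhs))), call. = FALSE)
  J <- game_jacobian(s, pm, rates)
  d <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  tr <- J[1, 1] + J[2, 2]
  label <- if (d > tol && tr < -tol) "ESS"
  else if (d > tol && tr > tol) "unstable"
  else if (d < -tol) "saddle"
  else "degenerate"
  structure(list(point = s, jac = J, det = d, trace = tr, label = label,
                 interior = all(s > tol & s < 1 - tol)),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("Fixed point (%.6g, %.6g): %s  [det = %.6g, trace = %.6g]\n",
              x$point[["x1"]], x$point[["y1"]], x$label, x$det, x$trace))
  invisible(x)
}

#' Case classification of the whole game scenario
#'
#' Evaluates the sign conditions that partition the payoff/dependence
#' parameter space into the printed stability cases. The deciding quantities
#' are the selection brackets at the strategy vertices:
#' `s1 = (b1-c1-c11+c21) - p21 (b1-c1-c11)` (official bracket at `y1 = 1`),
#' `s2 = (b2-c1+c21) - p21 (b2-c1)` (official bracket at `y1 = 0`),
#' `s3 = (b3-c21) - q21 (b4-c21)` (public bracket at `x1 = 1`),
#' `s4 = b5 - q21 b6` (public bracket at `x1 = 0`), together with the two
#' degeneracy conditions `deg1 = b5 - b3 + c21 + q21 (b4-c21) - q21 b6` and
#' `deg2 = (1 - p21)(b2 + c11 - b1)`.
#'
#' When both degeneracy conditions vanish ("case I") the brackets are
#' constant and the four subcases are decided by the signs of `s1` and `s3`.
#' When only `deg1` vanishes ("case II") the eight tabulated sign
#' combinations of `(s1, s2, s3)` each single out one ESS corner. Any
#' parameter set outside these regions, or with a deciding quantity inside
#' the tolerance band, falls back to per-equilibrium numeric classification
#' via [classify_equilibrium()].
#'
#' @inheritParams replicator_rhs
#' @param tol Sign tolerance for the case decisions.
#'
#' @return An object of class `"scenario_class"`: list with `case` (e.g.
#'   `"I.4"`, `"II.3"`, or `"numeric"`), `ess` (matrix of ESS points, possibly
#'   zero rows), `conditions` (named numeric `s1..s4, deg1, deg2`),
#'   `degenerate` flag and `equilibria` (labelled fixed-point table).
#' @export
classify_scenario <- function(pm, rates, tol = 1e-9) {
  s1 <- (pm$b1 - pm$c1 - pm$c11 + pm$c21) -
    rates$p21 * (pm$b1 - pm$c1 - pm$c11)
  s2 <- (pm$b2 - pm$c1 + pm$c21) - rates$p21 * (pm$b2 - pm$c1)
  s3 <- (pm$b3 - pm$c21) - rates$q21 * (pm$b4 - pm$c21)
  s4 <- pm$b5 - rates$q21 * pm$b6
  deg1 <- pm$b5 - pm$b3 + pm$c21 + rates$q21 * (pm$b4 - pm$c21) -
    rates$q21 * pm$b6
  deg2 <- (1 - rates$p21) * (pm$b2 + pm$c11 - pm$b1)
  conds <- c(s1 = s1, s2 = s2, s3 = s3, s4 = s4, deg1 = deg1, deg2 = deg2)

  sgn <- function(v) if (v > tol) 1L else if (v < -tol) -1L else 0L
  case <- NULL; ess <- NULL; degenerate <- FALSE

  if (abs(deg1) <= tol && abs(deg2) <= tol) {
    # brackets constant in the opposite field's probability; s1 == s2, s3 == s4
    if (sgn(s1) == 0L || sgn(s3) == 0L) {
      degenerate <- TRUE
    } else {
      sub <- if (s1 < 0 && s3 < 0) list("I.1", c(0, 0))
      else if (s1 < 0 && s3 > 0) list("I.2", c(0, 1))
      else if (s1 > 0 && s3 < 0) list("I.3", c(1, 0))
      else list("I.4", c(1, 1))
      case <- sub[[1]]; ess <- matrix(sub[[2]], 1, 2)
    }
  } else if (abs(deg1) <= tol) {
    if (any(vapply(c(s1, s2, s3), sgn, integer(1)) == 0L)) {
      degenerate <- TRUE
    } else {
      key <- paste(sgn(s1), sgn(s2), sgn(s3))
      tab <- list("-1 -1 -1" = list("II.1", c(0, 0)),
                  "1 -1 -1"  = list("II.2", c(0, 0)),
                  "-1 1 -1"  = list("II.3", c(1, 0)),
                  "1 -1 1"   = list("II.4", c(1, 1)),
                  "-1 -1 1"  = list("II.5", c(0, 1)),
                  "-1 1 1"   = list("II.6", c(0, 1)),
                  "1 1 -1"   = list("II.7", c(1, 0)),
                  "1 1 1"    = list("II.8", c(1, 1)))
      sub <- tab[[key]]
      case <- sub[[1]]; ess <- matrix(sub[[2]], 1, 2)
    }
  }

  eq <- suppressMessages(find_equilibria(pm, rates, tol = tol))
  eq$label <- vapply(seq_len(nrow(eq)), function(i)
    classify_equilibrium(c(eq$x1[i], eq$y1[i]), pm, rates, tol = tol)$label,
    character(1))

  if (is.null(case)) {
    # parameter region outside the tabulated cases (or on a sign boundary):
    # fall back to the numeric per-equilibrium labels
    case <- "numeric"
    keep <- eq$label == "ESS"
    ess <- as.matrix(eq[keep, c("x1", "y1"), drop = FALSE])
  }
  if (!is.null(ess)) colnames(ess) <- c("x1", "y1")
  structure(list(case = case, ess = ess, conditions = conds,
                 degenerate = degenerate, equilibria = eq),
            class = "scenario_class")
}

#' @export
print.scenario_class <- function(x, ...) {
  cat("Evolutionary-game scenario classification\n")
  cat("  case:", x$case, if (x$degenerate) "(degenerate boundary; numeric fallback)" else "", "\n")
  if (!is.null(x$ess) && nrow(x$ess) > 0) {
    cat("  ESS:",
        paste(sprintf("(%g, %g)", x$ess[, 1], x$ess[, 2]), collapse = ", "),
        "\n")
  } else {
    cat("  ESS: none\n")
  }
  cat("  fixed points:\n")
  for (i in seq_len(nrow(x$equilibria)))
    cat(sprintf("    %s (%g, %g): %s\n", x$equilibria$name[i],
                x$equilibria$x1[i], x$equilibria$y1[i], x$equilibria$label[i]))
  invisible(x)
}
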