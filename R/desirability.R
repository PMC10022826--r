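# Derringer-Suich desirability functions and multi-response optimization.
#
# Each response is transformed to a [0, 1] desirability by a linear ramp
# between scaling bounds L and U; the overall desirability is the weighted
# geometric mean D = (prod d_i^w_i)^(1/sum w_i).  The composition search
# combines an exhaustive fine grid over the two free simplex dimensions
# with Nelder-Mead refinement.

#' Define a desirability goal for one response
#'
#' @param response Response name (must match a fitted model's name when
#'   used in [optimize_composition()]).
#' @param goal One of `minimize`, `maximize`, `in_range`, `target`.
#' @param low,high Scaling bounds in response units (`low < high`);
#'   conventionally the observed response range.
#' @param weight Importance weight, 1-5.
#' @param target Target value (required for `goal = "target"`).
#' @return A `desirability_goal`.
#' @export
desirability_goal <- function(response,
                              goal = c("minimize", "maximize", "in_range",
                                       "target"),
                              low, high, weight = 1, target = NULL) {
  goal <- match.arg(goal)
  assert_scalar_num(low, "low"); assert_scalar_num(high, "high")
  if (low >= high) stop("need low < high", call. = FALSE)
  if (weight < 1) stop("weight must be >= 1", call. = FALSE)
  if (goal == "target") {
    assert_scalar_num(target, "target")
    if (target <= low || target >= high) {
      stop("target must lie strictly inside (low, high)", call. = FALSE)
    }
  }
  structure(list(response = response, goal = goal, low = low, high = high,
                 weight = weight, target = target),
            class = "desirability_goal")
}

#' Default optimization goals for a floating-minitablet formulation
#'
#' Minimize floating lag time (s, bounds 18-60, weight 5), maximize total
#' floating time (h, 15.5-22, weight 4), minimize 1-h release (%,
#' 13.23-28.33, weight 3), keep 12-h release in range (71.58-87.7, weight
#' 3), maximize 24-h release (96.01-100.15, weight 3).
#'
#' @return List of [desirability_goal()] objects.
#' @export
default_goals <- function() {
  list(
    desirability_goal("lag_time", "minimize", 18, 60, weight = 5),
    desirability_goal("float_time", "maximize", 15.5, 22, weight = 4),
    desirability_goal("release_1h", "minimize", 13.23, 28.33, weight = 3),
    desirability_goal("release_12h", "in_range", 71.58, 87.7, weight = 3),
    desirability_goal("release_24h", "maximize", 96.01, 100.15, weight = 3)
  )
}

#' Desirability of a response value under a goal
#'
#' Linear (s = t = 1) Derringer-Suich ramps: for `minimize`, d = 1 below
#' `low`, 0 above `high`; `maximize` is mirrored; `in_range` is the 0/1
#' indicator of \[low, high\]; `target` ramps up to 1 at the target and
#' back down.
#'
#' @param goal A [desirability_goal()].
#' @param y Response value(s).
#' @return Desirability value(s) in \[0, 1\].
#' @export
desirability_value <- function(goal, y) {
  stopifnot(inherits(goal, "desirability_goal"))
  L <- goal$low; U <- goal$high
  switch(goal$goal,
    minimize = clamp((U - y) / (U - L), 0, 1),
    maximize = clamp((y - L) / (U - L), 0, 1),
    in_range = as.numeric(y >= L & y <= U),
    target = {
      Tg <- goal$target
      ifelse(y <= Tg, clamp((y - L) / (Tg - L), 0, 1),
             clamp((U - y) / (U - Tg), 0, 1))
    }
  )
}

#' Weighted geometric-mean overall desirability
#'
#' `D = (prod d_i^w_i)^(1 / sum w_i)`.
#'
#' @param d Individual desirabilities in \[0, 1\].
#' @param weights Importance weights (recycled scalar allowed).
#' @return Overall desirability D in \[0, 1\].
#' @export
overall_desirability <- function(d, weights = 1) {
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]",
                               call. = FALSE)
  weights <- rep_len(weights, length(d))
  if (any(d == 0)) return(0)
  exp(sum(weights * log(d)) / sum(weights))
}

# Composite D at one composition given fitted models and goals.
# in_range goals with d = 1 are dropped from the weight sum when
# exclude_in_range (Design-Expert-like behavior); a violated in_range
# still forces D = 0.
composite_desirability <- function(x, models, goals, exclude_in_range = TRUE) {
  d <- numeric(length(goals)); w <- numeric(length(goals))
  keep <- rep(TRUE, length(goals))
  preds <- numeric(length(goals))
  for (i in seq_along(goals)) {
    g <- goals[[i]]
    yhat <- predict(models[[g$response]], x)
    preds[i] <- yhat
    d[i] <- desirability_value(g, yhat)
    w[i] <- g$weight
    if (exclude_in_range && g$goal == "in_range" && d[i] == 1) keep[i] <- FALSE
  }
  D <- if (!any(keep)) 1 else overall_desirability(d[keep], w[keep])
  list(D = D, d = d, predictions = stats::setNames(preds,
        vapply(goals, `[[`, character(1), "response")))
}

#' Find the composition maximizing overall desirability
#'
#' Exhaustive grid search over the two free simplex dimensions at
#' `grid_step` resolution, followed by Nelder-Mead refinement from the
#' best grid point (with infeasible proposals rejected).  Deterministic
#' given `seed`.
#'
#' @param models Named list of fitted `scheffe_model`s, one per goal
#'   response.
#' @param goals List of [desirability_goal()] objects.
#' @param constraints A [mixture_constraints()]; defaults to the first
#'   model's constraints.
#' @param grid_step Grid resolution in component %, default 0.5.
#' @param seed Integer seed (used only for refinement restarts).
#' @param exclude_in_range Drop satisfied in-range goals from the weight
#'   sum (Design-Expert convention); set `FALSE` for strict inclusion.
#' @return List: `composition`, `coded`, `D`, `predictions`,
#'   `desirabilities`.
#' @export
optimize_composition <- function(models, goals, constraints = NULL,
                                 grid_step = 0.5, seed = 1,
                                 exclude_in_range = TRUE) {
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "response")
  }
  for (g in goals) {
    if (!g$response %in% names(models)) {
      stop("no fitted model for goal response: ", g$response, call. = FALSE)
    }
  }
  constraints <- constraints %||% models[[1]]$constraints
  L <- constraints$lower; U <- constraints$upper; Tt <- constraints$total
  x2 <- seq(L[2], U[2], by = grid_step)
  x3 <- seq(L[3], U[3], by = grid_step)
  grid <- expand.grid(X2 = x2, X3 = x3)
  grid$X1 <- Tt - grid$X2 - grid$X3
  grid <- grid[grid$X1 >= L[1] - 1e-9 & grid$X1 <= U[1] + 1e-9,
               c("X1", "X2", "X3")]
  if (!nrow(grid)) stop("mixture region is empty", call. = FALSE)
  Dg <- vapply(seq_len(nrow(grid)), function(i) {
    composite_desirability(as.numeric(grid[i, ]), models, goals,
                           exclude_in_range)$D
  }, numeric(1))
  best_i <- which.max(Dg)
  best_x <- as.numeric(grid[best_i, ])
  best_D <- Dg[best_i]
  if (max(Dg) == 0) {
    warning("desirability is zero over the whole grid: no feasible optimum",
            call. = FALSE)
  }
  # local refinement on the free (X2, X3) coordinates
  obj <- function(z) {
    x <- c(Tt - z[1] - z[2], z[1], z[2])
    if (!is_feasible(x, constraints, tol = 1e-9)) return(1e6)
    -composite_desirability(x, models, goals, exclude_in_range)$D
  }
  opt <- with_seed(seed, stats::optim(best_x[2:3], obj,
                                      method = "Nelder-Mead",
                                      control = list(reltol = 1e-12,
                                                     maxit = 2000)))
  if (-opt$value > best_D) {
    best_x <- c(Tt - sum(opt$par), opt$par)
    best_D <- -opt$value
  }
  res <- composite_desirability(best_x, models, goals, exclude_in_range)
  list(composition = stats::setNames(best_x, constraints$names),
       coded = drop(code_composition(best_x, constraints)),
       D = res$D,
       predictions = res$predictions,
       desirabilities = res$d)
}
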