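# Dissolution release-kinetics fitting, mechanism classification, and
# swelling/erosion metrics.
#
# Five classical models of cumulative percent released F(t):
#   zero order        F = k0 t
#   first order       F = 100 (1 - exp(-k1 t))
#   Higuchi           F = kH sqrt(t)
#   Korsmeyer-Peppas  F = kKP t^n
#   Hixson-Crowell    F = 100 (1 - (1 - kHC t)^3), clamped at 100%

.kinetic_models <- c("zero_order", "first_order", "higuchi",
                     "korsmeyer_peppas", "hixson_crowell")

#' Evaluate a release-kinetics model
#'
#' @param model One of `zero_order`, `first_order`, `higuchi`,
#'   `korsmeyer_peppas`, `hixson_crowell`.
#' @param params Named list/vector of parameters: `k` for all models plus
#'   `n` for Korsmeyer-Peppas.
#' @param time Time points (h).
#' @return Cumulative percent released.
#' @export
release_curve <- function(model, params, time) {
  model <- match.arg(model, .kinetic_models)
  k <- params[["k"]]
  switch(model,
    zero_order = k * time,
    first_order = 100 * (1 - exp(-k * time)),
    higuchi = k * sqrt(time),
    korsmeyer_peppas = k * time^params[["n"]],
    hixson_crowell = 100 * (1 - pmax(1 - k * time, 0)^3)
  )
}

#' Construct a dissolution profile
#'
#' @param time Sampling times (h), strictly increasing, first >= 0.
#' @param released Cumulative percent released (non-negative, up to ~105%
#'   allowing assay noise).  A warning (not an error) is issued for
#'   non-monotone values.
#' @param formulation Optional label.
#' @return A `dissolution_profile` data frame.
#' @export
dissolution_profile <- function(time, released, formulation = "F") {
  stopifnot(length(time) == length(released))
  if (any(diff(time) <= 0)) stop("times must be strictly increasing",
                                 call. = FALSE)
  if (time[1] < 0) stop("times must be >= 0", call. = FALSE)
  if (any(released < 0)) stop("released fractions must be non-negative",
                              call. = FALSE)
  if (any(diff(released) < 0)) {
    warning("non-monotone release profile", call. = FALSE)
  }
  out <- data.frame(formulation = formulation, time_h = time,
                    released_pct = released, stringsAsFactors = FALSE)
  class(out) <- c("dissolution_profile", class(out))
  out
}

# SSE of a model with given parameters against (t, F) data.
.kin_sse <- function(model, params, t, f) {
  sum((f - release_curve(model, params, t))^2)
}

# One-parameter profile fit: coarse log-grid around a linearization start,
# then golden-section refinement via stats::optimize.
.fit_one_param <- function(model, t, f, k_start) {
  k_start <- max(k_start, 1e-8)
  grid <- k_start * 10^seq(-1.5, 1.5, length.out = 61)
  sse <- vapply(grid, function(k) .kin_sse(model, list(k = k), t, f),
                numeric(1))
  i <- which.min(sse)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(k) .kin_sse(model, list(k = k), t, f),
                         interval = c(lo, hi), tol = 1e-12)
  list(k = opt$minimum)
}

#' Fit one release-kinetics model to a dissolution profile
#'
#' Nonlinear least squares with closed-form linearization starts
#' (regression through the origin for zero-order/Higuchi, log-linear for
#' first-order and Hixson-Crowell, log-log for Korsmeyer-Peppas) followed
#' by refinement; reports `R2 = 1 - SSE/SST`.
#'
#' @param profile A [dissolution_profile()] or data frame with columns
#'   `time_h`, `released_pct`.
#' @param model Model name (see [release_curve()]).
#' @param f60 If `TRUE`, restrict the Korsmeyer-Peppas fit to points with
#'   F <= 60% (the power-law validity convention).
#' @return A `kinetic_fit`: `model`, `parameters`, `R2`, `adj_R2`,
#'   `fitted`.
#' @export
fit_kinetics <- function(profile, model, f60 = FALSE) {
  model <- match.arg(model, .kinetic_models)
  t <- profile$time_h; f <- profile$released_pct
  keep <- t > 0
  if (model == "korsmeyer_peppas" && f60) keep <- keep & f <= 60
  t <- t[keep]; f <- f[keep]
  if (length(t) < 3) stop("need at least 3 points with t > 0", call. = FALSE)
  params <- switch(model,
    zero_order = list(k = sum(f * t) / sum(t^2)),
    higuchi = list(k = sum(f * sqrt(t)) / sum(t)),
    first_order = {
      ok <- f < 100
      k0 <- if (any(ok)) sum(-log(1 - f[ok] / 100) * t[ok]) / sum(t[ok]^2)
            else 1 / max(t)
      .fit_one_param(model, t, f, k0)
    },
    hixson_crowell = {
      z <- 1 - pmax(1 - f / 100, 0)^(1 / 3)
      k0 <- sum(z * t) / sum(t^2)
      .fit_one_param(model, t, f, k0)
    },
    korsmeyer_peppas = {
      ok <- f > 0
      if (sum(ok) < 3) stop("too few positive release points", call. = FALSE)
      ll <- stats::lm(log(f[ok]) ~ log(t[ok]))
      start <- list(k = exp(stats::coef(ll)[[1]]), n = stats::coef(ll)[[2]])
      fit <- tryCatch(
        suppressWarnings(
          stats::nls(f ~ k * t^n, data = data.frame(t = t, f = f),
                     start = start,
                     control = stats::nls.control(maxiter = 200,
                                                  warnOnly = TRUE))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        as.list(stats::coef(fit))
      } else {
        op <- stats::optim(unlist(start), function(p) {
          if (p[1] <= 0 || p[2] <= 0) return(1e12)
          .kin_sse(model, list(k = p[1], n = p[2]), t, f)
        }, control = list(reltol = 1e-14, maxit = 5000))
        list(k = op$par[[1]], n = op$par[[2]])
      }
    })
  fitted <- release_curve(model, params, t)
  sse <- sum((f - fitted)^2)
  sst <- sum((f - mean(f))^2)
  n_obs <- length(f); p <- if (model == "korsmeyer_peppas") 2L else 1L
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  adj <- if (sst > 0 && n_obs > p + 1) {
    1 - (1 - r2) * (n_obs - 1) / (n_obs - p - 1)
  } else NA_real_
  structure(list(model = model, parameters = params, R2 = r2, adj_R2 = adj,
                 time = t, observed = f, fitted = fitted, n_points = n_obs),
            class = "kinetic_fit")
}

#' Fit all five release-kinetics models
#'
#' @inheritParams fit_kinetics
#' @return Data frame with one row per model (`model`, `k`, `n`, `R2`,
#'   `adj_R2`, `best`); the best model (highest R2) is flagged and stored
#'   in `attr(, "best")`.
#' @export
fit_all <- function(profile, f60 = FALSE) {
  fits <- lapply(.kinetic_models, function(m) fit_kinetics(profile, m, f60))
  tab <- data.frame(
    model = .kinetic_models,
    k = vapply(fits, function(f) f$parameters$k, numeric(1)),
    n = vapply(fits, function(f) f$parameters$n %||% NA_real_, numeric(1)),
    R2 = vapply(fits, `[[`, numeric(1), "R2"),
    adj_R2 = vapply(fits, `[[`, numeric(1), "adj_R2"),
    stringsAsFactors = FALSE
  )
  tab$best <- tab$R2 == max(tab$R2)
  attr(tab, "best") <- tab$model[which.max(tab$R2)]
  attr(tab, "fits") <- stats::setNames(fits, .kinetic_models)
  tab
}

#' Classify the drug-release mechanism from the power-law exponent
#'
#' Thresholds on the Korsmeyer-Peppas exponent n.  The default
#' (`mode = "paper"`) uses 0.65/0.89 cut points, matching reports that
#' label n around 0.5-0.62 as Fickian for swellable matrices;
#' `mode = "standard"` uses the classical 0.45/0.89 cylinder thresholds.
#'
#' @param n Release exponent (> 0).
#' @param mode `"paper"` or `"standard"`.
#' @return One of `"Fickian diffusion"`,
#'   `"anomalous (non-Fickian) transport"`, `"case-II"`.
#' @export
classify_mechanism <- function(n, mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("release exponent n must be positive and finite", call. = FALSE)
  }
  lo <- if (mode == "paper") 0.65 else 0.45
  ifelse(n < lo, "Fickian diffusion",
         ifelse(n < 0.89, "anomalous (non-Fickian) transport", "case-II"))
}

#' Percent swelling of a hydrophilic matrix
#'
#' `(W_swollen - W_initial) / W_initial * 100`.
#'
#' @param initial Initial dry weight (mg).
#' @param swollen Weight after swelling (mg).
#' @return Percent swelling.
#' @export
swelling_percent <- function(initial, swollen) {
  if (any(initial <= 0) || any(swollen <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  (swollen - initial) / initial * 100
}

#' Percent erosion of a matrix
#'
#' `(W_initial - W_remnant_dry) / W_initial * 100`.
#'
#' @param initial Initial dry weight (mg).
#' @param remnant Remnant dry weight after the test (mg), <= initial.
#' @return Percent erosion.
#' @export
erosion_percent <- function(initial, remnant) {
  if (any(initial <= 0) || any(remnant < 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  if (any(remnant > initial)) {
    stop("remnant weight cannot exceed the initial weight", call. = FALSE)
  }
  (initial - remnant) / initial * 100
}

#' Read long-format dissolution profiles from CSV
#'
#' Expects columns `formulation`, `time_h`, `released_pct`.
#'
#' @param path CSV path.
#' @return Named list of [dissolution_profile()] objects.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("formulation", "time_h", "released_pct")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("profile CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$formulation), function(d) {
    d <- d[order(d$time_h), ]
    dissolution_profile(d$time_h, d$released_pct, d$formulation[1])
  })
  out
}
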