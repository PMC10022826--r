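# Heckel compaction analysis.
#
# The Heckel linearization ln(1/(1 - rho_r)) = K P + A relates the
# relative density rho_r of a compact to the applied pressure P (MPa); the
# reciprocal of the slope, Py = 1/K, is the mean yield pressure, a measure
# of plastic deformability.  Real compression profiles show a curved
# low-pressure particle-rearrangement region that must be excluded from
# the linear fit.

#' Apparent density of a cylindrical tablet
#'
#' `rho_a = weight / (pi r^2 h)` with weight in mg and dimensions in mm,
#' which yields g/mL directly.
#'
#' @param weight_mg Tablet weight (mg).
#' @param radius_mm Tablet radius (mm).
#' @param thickness_mm Tablet thickness (mm).
#' @return Apparent density (g/mL).
#' @export
apparent_density <- function(weight_mg, radius_mm, thickness_mm) {
  if (any(weight_mg <= 0) || any(radius_mm <= 0) || any(thickness_mm <= 0)) {
    stop("tablet weight and dimensions must be positive", call. = FALSE)
  }
  weight_mg / (pi * radius_mm^2 * thickness_mm)
}

#' Relative density of a compact
#'
#' `rho_r = rho_a / rho_t` in (0, 1].
#'
#' @inheritParams apparent_density
#' @param true_density True (particle) density of the blend (g/mL).
#' @return Relative density.
#' @export
relative_density <- function(weight_mg, radius_mm, thickness_mm,
                             true_density) {
  if (any(true_density <= 0)) stop("true density must be positive",
                                   call. = FALSE)
  ra <- apparent_density(weight_mg, radius_mm, thickness_mm)
  rr <- ra / true_density
  if (any(rr > 1 + 1e-9)) {
    stop("apparent density exceeds true density: inconsistent measurement",
         call. = FALSE)
  }
  pmin(rr, 1)
}

#' Heckel transform of relative density
#'
#' `y = ln(1 / (1 - rho_r))`.
#'
#' @param rho_r Relative density in \[0, 1).
#' @return Transformed densification.
#' @export
heckel_transform <- function(rho_r) {
  if (any(rho_r < 0) || any(rho_r >= 1)) {
    stop("relative density must lie in [0, 1)", call. = FALSE)
  }
  log(1 / (1 - rho_r))
}

#' Fit the Heckel equation and estimate the mean yield pressure
#'
#' Ordinary least squares of `ln(1/(1-rho_r))` on pressure over a linear
#' region.  With `region = "auto"`, the contiguous window of at least
#' `min_points` points spanning at least `min_span` of the pressure range
#' that maximizes R-squared is selected, which excludes the low-pressure
#' particle-rearrangement phase; pass `region = c(lo, hi)` (MPa) to fit a
#' fixed window.
#'
#' @param pressure Applied pressures (MPa).
#' @param rho_r Relative densities (same length), or pass tablet
#'   measurements via `points` instead.
#' @param points Optional data frame with columns `pressure_MPa`,
#'   `weight_mg`, `radius_mm`, `thickness_mm`, `true_density` from which
#'   `pressure` and `rho_r` are derived.
#' @param region `"auto"` or numeric `c(lo, hi)` pressure window.
#' @param min_points Minimum points in an auto window (default 5).
#' @param min_span Minimum auto-window span as a fraction of the pressure
#'   range (default 0.4).
#' @return A `heckel_fit`: slope `K` (1/MPa), intercept `A`, `Py = 1/K`
#'   (MPa), `R2`, and the fitted pressure `range`.
#' @export
fit_heckel <- function(pressure = NULL, rho_r = NULL, points = NULL,
                       region = "auto", min_points = 5, min_span = 0.4) {
  if (!is.null(points)) {
    pressure <- points$pressure_MPa
    rho_r <- relative_density(points$weight_mg, points$radius_mm,
                              points$thickness_mm, points$true_density)
  }
  ord <- order(pressure)
  pressure <- pressure[ord]; rho_r <- rho_r[ord]
  y <- heckel_transform(rho_r)
  n <- length(pressure)
  fit_window <- function(idx) {
    px <- pressure[idx]; py <- y[idx]
    sxx <- sum((px - mean(px))^2)
    K <- sum((px - mean(px)) * (py - mean(py))) / sxx
    A <- mean(py) - K * mean(px)
    sst <- sum((py - mean(py))^2)
    sse <- sum((py - A - K * px)^2)
    list(K = K, A = A, R2 = if (sst > 0) 1 - sse / sst else NA_real_,
         idx = idx)
  }
  if (identical(region, "auto")) {
    if (n < min_points) {
      stop("need at least ", min_points, " points for automatic ",
           "region detection; supply a manual region", call. = FALSE)
    }
    span_all <- diff(range(pressure))
    best <- NULL
    for (i in seq_len(n - min_points + 1L)) {
      for (j in seq(i + min_points - 1L, n)) {
        if (pressure[j] - pressure[i] < min_span * span_all) next
        w <- fit_window(i:j)
        if (is.null(best) || w$R2 > best$R2) best <- w
      }
    }
    if (is.null(best)) {
      stop("no contiguous window meets the span criterion; supply a ",
           "manual fitting region", call. = FALSE)
    }
  } else {
    idx <- which(pressure >= region[1] & pressure <= region[2])
    if (length(idx) < 4) {
      stop("fewer than 4 points in the requested pressure region",
           call. = FALSE)
    }
    best <- fit_window(idx)
  }
  if (best$K <= 0) {
    stop("non-positive Heckel slope: data are not densifying with pressure",
         call. = FALSE)
  }
  structure(list(K = best$K, A = best$A, Py = 1 / best$K, R2 = best$R2,
                 range = range(pressure[best$idx]),
                 n_points = length(best$idx)),
            class = "heckel_fit")
}

#' @export
print.heckel_fit <- function(x, ...) {
  cat(sprintf(
    "Heckel fit: K = %.5f 1/MPa, A = %.4f, Py = %.1f MPa (R2 = %.4f)\n",
    x$K, x$A, x$Py, x$R2))
  cat(sprintf("fitted over %d points in [%.1f, %.1f] MPa\n",
              x$n_points, x$range[1], x$range[2]))
  invisible(x)
}
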