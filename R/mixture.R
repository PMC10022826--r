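# Constrained three-component mixture designs and Scheffe response models.
#
# The experimental region is the polytope {L_i <= X_i <= U_i, sum X_i = T}
# embedded in the plane of constant total T (percent of net formulation;
# the remainder of the formulation is fixed, e.g. drug + lubricant).
# Designs are searched under I-optimality (minimum average prediction
# variance over the region); response surfaces are Scheffe polynomials
# (no intercept) in coded components.

#' Mixture constraints for a three-component design
#'
#' Defaults correspond to a gastroretentive matrix blend: HPMC (X1)
#' 34-45%, ethylcellulose (X2) 0-10%, sodium bicarbonate (X3) 5-15%,
#' with 40% drug + 1% lubricant fixed, so the variable total is T = 59%.
#'
#' @param lower,upper Numeric length-3 bounds (% of net formulation).
#' @param total Variable total T (%); `sum(lower) <= total <= sum(upper)`.
#' @param fixed Named numeric vector of fixed components (%); must satisfy
#'   `sum(fixed) + total == 100`.
#' @param names Component names.
#' @return A `mixture_constraints` object.
#' @export
mixture_constraints <- function(lower = c(34, 0, 5), upper = c(45, 10, 15),
                                total = 59,
                                fixed = c(drug = 40, lubricant = 1),
                                names = c("X1", "X2", "X3")) {
  stopifnot(length(lower) == 3, length(upper) == 3, length(names) == 3)
  if (any(upper < lower)) stop("upper bounds must be >= lower bounds",
                               call. = FALSE)
  if (sum(lower) > total + 1e-9 || sum(upper) < total - 1e-9) {
    stop("infeasible constraints: need sum(lower) <= total <= sum(upper)",
         call. = FALSE)
  }
  if (abs(sum(fixed) + total - 100) > 1e-9) {
    stop("fixed components plus the variable total must equal 100%",
         call. = FALSE)
  }
  out <- list(names = names, lower = as.numeric(lower),
              upper = as.numeric(upper), total = total, fixed = fixed)
  class(out) <- "mixture_constraints"
  out
}

is_feasible <- function(x, constraints, tol = 1e-7) {
  all(x >= constraints$lower - tol) && all(x <= constraints$upper + tol) &&
    abs(sum(x) - constraints$total) <= max(tol, 1e-7 * constraints$total)
}

#' Code a composition into pseudo-components or real proportions
#'
#' L-pseudo coding maps `X_i` to `(X_i - L_i) / (T - sum(L))`, so coded
#' values are in \[0, 1\] and sum to one; `"proportion"` coding uses
#' `X_i / T`.
#'
#' @param x Numeric length-3 composition (%), or a matrix/data frame with
#'   one composition per row.
#' @param constraints A [mixture_constraints()].
#' @param coding `"pseudo"` (default) or `"proportion"`.
#' @param tol Feasibility tolerance on the component sum (% units); design
#'   tables rounded to one decimal carry up to ~0.2.
#' @return Coded matrix with the same number of rows as `x`.
#' @export
code_composition <- function(x, constraints, coding = c("pseudo", "proportion"),
                             tol = 0.2) {
  coding <- match.arg(coding)
  m <- if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else
    as.matrix(x[, constraints$names, drop = FALSE])
  if (ncol(m) != 3) stop("compositions must have 3 components", call. = FALSE)
  bad <- abs(rowSums(m) - constraints$total) > tol
  if (any(bad)) {
    stop("composition row(s) ", paste(which(bad), collapse = ", "),
         " do not sum to the variable total ", constraints$total,
         call. = FALSE)
  }
  oob <- apply(m, 1, function(r) any(r < constraints$lower - tol) ||
                 any(r > constraints$upper + tol))
  if (any(oob)) {
    stop("composition row(s) ", paste(which(oob), collapse = ", "),
         " fall outside the component bounds", call. = FALSE)
  }
  # renormalize away table-rounding slack so coded rows sum to 1 exactly
  m <- m * (constraints$total / rowSums(m))
  coded <- if (coding == "pseudo") {
    sweep(m, 2, constraints$lower) / (constraints$total - sum(constraints$lower))
  } else {
    m / constraints$total
  }
  colnames(coded) <- constraints$names
  coded
}

# Extreme vertices of the constrained region: intersections of pairs of
# active bounds on the plane sum(x) = T, filtered for feasibility.
region_vertices <- function(constraints, tol = 1e-9) {
  L <- constraints$lower; U <- constraints$upper; T <- constraints$total
  pts <- list()
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    for (bi in c(L[i], U[i])) for (bj in c(L[j], U[j])) {
      x <- numeric(3)
      x[i] <- bi; x[j] <- bj
      k <- setdiff(1:3, c(i, j))
      x[k] <- T - bi - bj
      if (is_feasible(x, constraints, tol = 1e-7)) pts[[length(pts) + 1L]] <- x
    }
  }
  if (!length(pts)) stop("mixture region is empty", call. = FALSE)
  m <- unique(round(do.call(rbind, pts), 9))
  # order around the centroid so consecutive rows share an edge
  if (nrow(m) > 2) {
    ctr <- colMeans(m)
    # project onto the 2-d plane using components 2 and 3 as coordinates
    ang <- atan2(m[, 3] - ctr[3], m[, 2] - ctr[2])
    m <- m[order(ang), , drop = FALSE]
  }
  colnames(m) <- constraints$names
  m
}

#' Candidate points for a constrained mixture design
#'
#' Returns the extreme vertices of the constrained simplex region, edge
#' midpoints, the overall centroid, and axial check points (midway between
#' the centroid and each vertex).
#'
#' @param constraints A [mixture_constraints()].
#' @return Data frame of candidate compositions (%) with a `type` column.
#' @export
generate_candidates <- function(constraints) {
  v <- region_vertices(constraints)
  n <- nrow(v)
  ctr <- matrix(colMeans(v), 1, dimnames = list(NULL, constraints$names))
  pts <- list(data.frame(v, type = "vertex", check.names = FALSE))
  if (n > 1) {
    edges <- (v + v[c(2:n, 1), , drop = FALSE]) / 2
    if (n == 2) edges <- edges[1, , drop = FALSE]
    pts <- c(pts, list(data.frame(edges, type = "edge_midpoint",
                                  check.names = FALSE)))
    axial <- (v + ctr[rep(1, n), ]) / 2
    pts <- c(pts, list(data.frame(ctr, type = "centroid", check.names = FALSE),
                       data.frame(axial, type = "axial", check.names = FALSE)))
  }
  out <- do.call(rbind, pts)
  out <- out[!duplicated(round(out[, constraints$names], 9)), ]
  rownames(out) <- NULL
  stopifnot(all(apply(out[, constraints$names], 1, is_feasible, constraints)))
  out
}

# Scheffe model term matrix for coded components (columns X1..X3).
scheffe_terms <- function(order) {
  base <- c("X1", "X2", "X3")
  quad <- c("X1:X2", "X1:X3", "X2:X3")
  switch(order,
    linear = base,
    quadratic = c(base, quad),
    special_cubic = c(base, quad, "X1:X2:X3"),
    full_cubic = c(base, quad, "X1:X2:X3",
                   "X1:X2:(X1-X2)", "X1:X3:(X1-X3)", "X2:X3:(X2-X3)"),
    stop("unknown model order: ", order, call. = FALSE)
  )
}

scheffe_matrix <- function(coded, order) {
  x1 <- coded[, 1]; x2 <- coded[, 2]; x3 <- coded[, 3]
  cols <- list(X1 = x1, X2 = x2, X3 = x3)
  if (order %in% c("quadratic", "special_cubic", "full_cubic")) {
    cols <- c(cols, list(`X1:X2` = x1 * x2, `X1:X3` = x1 * x3,
                         `X2:X3` = x2 * x3))
  }
  if (order %in% c("special_cubic", "full_cubic")) {
    cols <- c(cols, list(`X1:X2:X3` = x1 * x2 * x3))
  }
  if (order == "full_cubic") {
    cols <- c(cols, list(`X1:X2:(X1-X2)` = x1 * x2 * (x1 - x2),
                         `X1:X3:(X1-X3)` = x1 * x3 * (x1 - x3),
                         `X2:X3:(X2-X3)` = x2 * x3 * (x2 - x3)))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- scheffe_terms(order)
  m
}

# Uniform sample of feasible compositions (rejection sampling in the
# (X2, X3) box, X1 = T - X2 - X3).
sample_region <- function(constraints, n) {
  L <- constraints$lower; U <- constraints$upper; T <- constraints$total
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 64L)
    x2 <- stats::runif(m, L[2], U[2])
    x3 <- stats::runif(m, L[3], U[3])
    x1 <- T - x2 - x3
    keep <- x1 >= L[1] & x1 <= U[1]
    out <- rbind(out, cbind(x1, x2, x3)[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- constraints$names
  out
}

i_criterion <- function(design_idx, Fc, Fmc) {
  M <- crossprod(Fc[design_idx, , drop = FALSE])
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  # mean over MC points of f(x)' M^{-1} f(x)
  z <- backsolve(ch, forwardsolve(t(ch), t(Fmc)))
  mean(colSums(z^2))
}

#' I-optimal mixture design by point exchange
#'
#' Selects `n_runs` support points from a candidate set minimizing the
#' I-criterion (average scaled prediction variance over the region,
#' approximated by Monte-Carlo integration), then duplicates the
#' `n_replicates` support points with the highest prediction variance.
#' The exchange is first-improvement in candidate-index order and is
#' deterministic given `seed`.
#'
#' @param candidates Candidate compositions (data frame from
#'   [generate_candidates()] or any feasible set).
#' @param constraints A [mixture_constraints()].
#' @param order Scheffe model order (`linear`, `quadratic`,
#'   `special_cubic`, `full_cubic`).
#' @param n_runs Number of distinct support points (>= number of terms).
#' @param n_replicates Number of support points to duplicate.
#' @param seed Integer seed fixing the Monte-Carlo sample and the exchange
#'   start.
#' @param n_mc Monte-Carlo integration points (>= 2000 recommended).
#' @param coding Component coding for the model matrix.
#' @return Data frame of design runs: `run`, components (%), coded
#'   components, `replicate_of`.
#' @export
i_optimal_design <- function(candidates, constraints, order = "linear",
                             n_runs, n_replicates = 0, seed = 1,
                             n_mc = 2000, coding = "pseudo") {
  cand <- as.matrix(candidates[, constraints$names, drop = FALSE])
  p <- length(scheffe_terms(order))
  if (n_runs < p) {
    stop(sprintf("underdetermined design: n_runs (%d) < number of model terms (%d)",
                 n_runs, p), call. = FALSE)
  }
  if (n_runs > nrow(cand)) {
    stop("n_runs exceeds the number of candidate points", call. = FALSE)
  }
  Fc <- scheffe_matrix(code_composition(cand, constraints, coding), order)
  res <- with_seed(seed, {
    mc <- sample_region(constraints, n_mc)
    Fmc <- scheffe_matrix(code_composition(mc, constraints, coding), order)
    idx <- sample.int(nrow(cand), n_runs)
    best <- i_criterion(idx, Fc, Fmc)
    # fall back to a nonsingular start if the random one is singular
    tries <- 0L
    while (!is.finite(best) && tries < 50L) {
      idx <- sample.int(nrow(cand), n_runs)
      best <- i_criterion(idx, Fc, Fmc)
      tries <- tries + 1L
    }
    repeat {
      improved <- FALSE
      for (pos in seq_len(n_runs)) {
        for (ci in seq_len(nrow(cand))) {
          if (ci %in% idx) next
          trial <- idx; trial[pos] <- ci
          crit <- i_criterion(trial, Fc, Fmc)
          if (crit < best - 1e-12) {
            idx <- trial; best <- crit; improved <- TRUE
            break
          }
        }
      }
      if (!improved) break
    }
    list(idx = idx, crit = best, Fmc = Fmc)
  })
  idx <- sort(res$idx)
  M <- crossprod(Fc[idx, , drop = FALSE])
  lev <- rowSums((Fc[idx, , drop = FALSE] %*% solve(M)) * Fc[idx, , drop = FALSE])
  rep_of <- integer(0)
  if (n_replicates > 0) {
    ord <- order(lev, decreasing = TRUE)
    rep_of <- ord[seq_len(min(n_replicates, n_runs))]
  }
  rows <- c(seq_along(idx), rep_of)
  comp <- cand[idx[rows], , drop = FALSE]
  coded <- code_composition(comp, constraints, coding)
  colnames(coded) <- paste0(constraints$names, "_coded")
  out <- data.frame(run = paste0("F", seq_along(rows)), comp, coded,
                    replicate_of = c(rep(NA_integer_, length(idx)), rep_of),
                    check.names = FALSE)
  attr(out, "i_criterion") <- res$crit
  attr(out, "order") <- order
  attr(out, "seed") <- seed
  rownames(out) <- NULL
  out
}

#' Fit a Scheffe polynomial response model
#'
#' Least-squares fit without intercept on coded components.  With
#' `order = "auto"`, all estimable orders are fitted and the one with the
#' highest adjusted R-squared is returned.
#'
#' @param design Data frame containing the component columns (%) named as
#'   in `constraints`.
#' @param response Numeric response vector, one value per design row.
#' @param constraints A [mixture_constraints()].
#' @param order Model order or `"auto"`.
#' @param coding `"pseudo"` or `"proportion"`.
#' @param response_name Label stored in the model.
#' @return A `scheffe_model`: coefficients, fit statistics, residuals.
#' @export
fit_scheffe <- function(design, response, constraints,
                        order = c("linear", "quadratic", "special_cubic",
                                  "full_cubic", "auto"),
                        coding = c("pseudo", "proportion"),
                        response_name = deparse(substitute(response))) {
  order <- match.arg(order)
  coding <- match.arg(coding)
  y <- as.numeric(response)
  if (any(!is.finite(y))) stop("responses must be finite", call. = FALSE)
  coded <- code_composition(design, constraints, coding)
  if (nrow(coded) != length(y)) {
    stop("design and response lengths differ", call. = FALSE)
  }
  fit_one <- function(ord) {
    X <- scheffe_matrix(coded, ord)
    if (nrow(X) < ncol(X)) return(NULL)
    qr_X <- qr(X)
    if (qr_X$rank < ncol(X)) {
      aliased <- colnames(X)[-qr_X$pivot[seq_len(qr_X$rank)]]
      stop("rank-deficient Scheffe term matrix; aliased term(s): ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qr_X, y)
    fitted <- drop(X %*% beta)
    resid <- y - fitted
    sse <- sum(resid^2)
    sst <- sum((y - mean(y))^2)
    n <- length(y); p <- ncol(X)
    r2 <- if (sst > 0) 1 - sse / sst else NA_real_
    # Scheffe models absorb the intercept (sum of coded x = 1), so the
    # mean-corrected total SS is the conventional reference; the model df
    # for the F test is p - 1 for the same reason.
    adj <- if (sst > 0 && n > p) 1 - (sse / (n - p)) / (sst / (n - 1)) else NA_real_
    fstat <- p_val <- NA_real_
    if (n > p && sst > sse && p > 1) {
      fstat <- ((sst - sse) / (p - 1)) / (sse / (n - p))
      p_val <- stats::pf(fstat, p - 1, n - p, lower.tail = FALSE)
    }
    structure(list(response = response_name, order = ord, coding = coding,
                   constraints = constraints, terms = colnames(X),
                   coefficients = beta, fitted = fitted, residuals = resid,
                   R2 = r2, adj_R2 = adj, F_stat = fstat, p_value = p_val,
                   sigma2 = if (n > p) sse / (n - p) else NA_real_,
                   constant_response = sst == 0),
              class = "scheffe_model")
  }
  if (order != "auto") {
    m <- fit_one(order)
    if (is.null(m)) stop("too few runs for a ", order, " model", call. = FALSE)
    if (isTRUE(m$constant_response)) {
      warning("constant response: R-squared undefined", call. = FALSE)
    }
    return(m)
  }
  fits <- list()
  for (ord in c("linear", "quadratic", "special_cubic", "full_cubic")) {
    m <- tryCatch(fit_one(ord), error = function(e) NULL)
    if (!is.null(m)) fits[[ord]] <- m
  }
  if (!length(fits)) stop("no estimable model order", call. = FALSE)
  adj <- vapply(fits, function(m) m$adj_R2 %||% NA_real_, numeric(1))
  if (all(is.na(adj))) return(fits[[length(fits)]])
  fits[[which.max(adj)]]
}

#' @export
print.scheffe_model <- function(x, ...) {
  cat(sprintf("Scheffe %s model for '%s' (%s coding)\n",
              x$order, x$response, x$coding))
  print(round(x$coefficients, 4))
  cat(sprintf("R2 = %.4f  adj R2 = %.4f  F = %.3f (p = %.3g)\n",
              x$R2, x$adj_R2, x$F_stat, x$p_value))
  invisible(x)
}

#' Predict from a Scheffe model at new compositions
#'
#' @param object A `scheffe_model`.
#' @param newdata Composition (length-3 vector in %) or matrix/data frame
#'   of compositions.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.scheffe_model <- function(object, newdata, ...) {
  coded <- code_composition(newdata, object$constraints, object$coding)
  drop(scheffe_matrix(coded, object$order) %*% object$coefficients)
}
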