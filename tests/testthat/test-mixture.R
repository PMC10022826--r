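# Mixture designs and Scheffe response models.

test_that("pseudo-component coding matches hand arithmetic", {
  expect_equal(drop(code_composition(c(36.6, 10, 12.4), default_cons)),
               c(X1 = 0.13, X2 = 0.50, X3 = 0.37))
  expect_equal(drop(code_composition(c(34, 10, 15), default_cons)),
               c(X1 = 0, X2 = 0.5, X3 = 0.5))
  expect_equal(drop(code_composition(c(45, 0, 14), default_cons)),
               c(X1 = 0.55, X2 = 0, X3 = 0.45))
  coded <- code_composition(table3, default_cons)
  expect_equal(unname(rowSums(coded)), rep(1, 16), tolerance = 1e-9)
  expect_true(all(coded >= -1e-9 & coded <= 1 + 1e-9))
  # proportion coding sums to 1 as well
  prop <- code_composition(table3, default_cons, coding = "proportion")
  expect_equal(unname(rowSums(prop)), rep(1, 16), tolerance = 1e-9)
  expect_error(code_composition(c(30, 10, 19), default_cons), "bounds")
  expect_error(code_composition(c(30, 10, 20), default_cons), "sum")
})

test_that("candidate sets respect the constraint geometry", {
  cand <- generate_candidates(default_cons)
  comp <- as.matrix(cand[, default_cons$names])
  expect_true(all(comp[, 1] >= 34 - 1e-9 & comp[, 1] <= 45 + 1e-9))
  expect_true(all(comp[, 2] >= -1e-9 & comp[, 2] <= 10 + 1e-9))
  expect_true(all(comp[, 3] >= 5 - 1e-9 & comp[, 3] <= 15 + 1e-9))
  expect_equal(unname(rowSums(comp)), rep(59, nrow(comp)))
  # unconstrained simplex: the three pure-component vertices appear
  simplex <- mixture_constraints(lower = c(0, 0, 0), upper = c(59, 59, 59),
                                 total = 59)
  cs <- generate_candidates(simplex)
  verts <- as.matrix(cs[cs$type == "vertex", simplex$names])
  for (i in 1:3) {
    pure <- rep(0, 3); pure[i] <- 59
    expect_true(any(apply(verts, 1, function(v) all(abs(v - pure) < 1e-6))))
  }
  # degenerate region collapses to a point
  degen <- mixture_constraints(lower = c(34, 10, 15), upper = c(45, 10, 15),
                               total = 59)
  cd <- generate_candidates(degen)
  expect_equal(nrow(unique(round(cd[, degen$names], 6))), 1)
  expect_error(mixture_constraints(lower = c(40, 10, 15),
                                   upper = c(45, 12, 16), total = 59),
               "infeasible")
})

test_that("I-optimal search finds the simplex vertices for a linear model", {
  simplex <- mixture_constraints(lower = c(0, 0, 0), upper = c(59, 59, 59),
                                 total = 59)
  cand <- generate_candidates(simplex)
  d <- i_optimal_design(cand, simplex, order = "linear", n_runs = 3,
                        seed = 3)
  # brute-force oracle: enumerate all candidate triples and minimize the
  # I-criterion on the same Monte-Carlo sample
  comp <- as.matrix(cand[, simplex$names])
  Fc <- formuqbd:::scheffe_matrix(code_composition(comp, simplex), "linear")
  mc <- formuqbd:::with_seed(3, formuqbd:::sample_region(simplex, 2000))
  Fmc <- formuqbd:::scheffe_matrix(code_composition(mc, simplex), "linear")
  combos <- utils::combn(nrow(comp), 3)
  crits <- apply(combos, 2, function(ix) formuqbd:::i_criterion(ix, Fc, Fmc))
  best <- comp[combos[, which.min(crits)], ]
  got <- as.matrix(d[, simplex$names])
  expect_equal(got[order(got[, 1], got[, 2]), ],
               best[order(best[, 1], best[, 2]), ], ignore_attr = TRUE)
  # for the unconstrained simplex those are the three pure vertices
  expect_equal(sort(apply(got, 1, max)), rep(59, 3))
})

test_that("designs are deterministic, replicated, and well-conditioned", {
  cand <- generate_candidates(default_cons)
  d1 <- i_optimal_design(cand, default_cons, order = "linear", n_runs = 11,
                         n_replicates = 5, seed = 7)
  d2 <- i_optimal_design(cand, default_cons, order = "linear", n_runs = 11,
                         n_replicates = 5, seed = 7)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 16)
  expect_equal(sum(!is.na(d1$replicate_of)), 5)
  # replicated rows duplicate existing support points
  reps <- d1[!is.na(d1$replicate_of), ]
  for (i in seq_len(nrow(reps))) {
    expect_equal(unlist(reps[i, default_cons$names]),
                 unlist(d1[reps$replicate_of[i], default_cons$names]))
  }
  X <- formuqbd:::scheffe_matrix(
    code_composition(d1[, default_cons$names], default_cons), "linear")
  expect_lt(kappa(crossprod(X)), 1e8)
  expect_error(i_optimal_design(cand, default_cons, order = "full_cubic",
                                n_runs = 5, seed = 1),
               "underdetermined")
})

test_that("optimized designs beat random feasible designs on the I-criterion", {
  cand <- generate_candidates(default_cons)
  comp <- as.matrix(cand[, default_cons$names])
  Fc <- formuqbd:::scheffe_matrix(code_composition(comp, default_cons),
                                  "quadratic")
  for (seed in c(2, 9)) {
    d <- i_optimal_design(cand, default_cons, order = "quadratic",
                          n_runs = 8, seed = seed)
    mc <- formuqbd:::with_seed(seed,
                               formuqbd:::sample_region(default_cons, 2000))
    Fmc <- formuqbd:::scheffe_matrix(code_composition(mc, default_cons),
                                     "quadratic")
    opt_idx <- match(
      apply(round(d[, default_cons$names], 9), 1, paste, collapse = "/"),
      apply(round(comp, 9), 1, paste, collapse = "/"))
    opt_crit <- formuqbd:::i_criterion(opt_idx, Fc, Fmc)
    rand_crits <- formuqbd:::with_seed(seed + 100, replicate(100, {
      formuqbd:::i_criterion(sample.int(nrow(comp), 8), Fc, Fmc)
    }))
    expect_lte(opt_crit, min(rand_crits) + 1e-9)
  }
})

test_that("noiseless Scheffe surfaces are recovered exactly at every order", {
  cand <- generate_candidates(default_cons)
  X <- cand[, default_cons$names]
  truth <- list(
    linear = c(10, 20, -5),
    quadratic = c(10, 20, -5, 3, -2, 4),
    special_cubic = c(10, 20, -5, 3, -2, 4, 8),
    full_cubic = c(10, 20, -5, 3, -2, 4, 8, 1, -1, 2)
  )
  for (ord in names(truth)) {
    y <- gen_mixture_responses(X, truth[[ord]], default_cons, order = ord,
                               noise_sd = 0, seed = 1)
    m <- fit_scheffe(X, y, default_cons, order = ord)
    expect_equal(unname(m$coefficients), truth[[ord]], tolerance = 1e-8,
                 info = ord)
    expect_equal(m$fitted, y, tolerance = 1e-9)
    # fit -> predict reproduces fitted values at the design points
    expect_equal(unname(predict(m, X)), y, tolerance = 1e-9)
  }
})

test_that("refit lag-time model reproduces the reported sign pattern", {
  m <- fit_lag_model()
  expect_equal(m$order, "linear")
  expect_gt(m$coefficients[["X1"]], 0)
  expect_gt(m$coefficients[["X2"]], 0)
  expect_lt(m$coefficients[["X3"]], 0)
  # the effervescent agent (X3) shortens, the insoluble polymer (X2)
  # lengthens the lag: same ordering as the printed equation
  expect_gt(m$coefficients[["X2"]], m$coefficients[["X1"]])
})

test_that("Scheffe predictions honor the simplex identities", {
  simplex <- mixture_constraints(lower = c(0, 0, 0), upper = c(59, 59, 59),
                                 total = 59)
  verts <- diag(3) * 59
  colnames(verts) <- simplex$names
  y <- c(4, 9, 1)
  m <- fit_scheffe(as.data.frame(verts), y, simplex, order = "linear")
  # vertex prediction = vertex coefficient; centroid = mean of coefficients
  expect_equal(unname(predict(m, verts)), y, tolerance = 1e-9)
  expect_equal(unname(predict(m, rep(59 / 3, 3))), mean(y),
               tolerance = 1e-9)
  # constant responses give all-equal linear coefficients, flagged R2
  cand <- generate_candidates(default_cons)
  expect_warning(
    mc <- fit_scheffe(cand[, default_cons$names], rep(7, nrow(cand)),
                      default_cons, order = "linear"),
    "constant")
  expect_equal(unname(mc$coefficients), rep(7, 3), tolerance = 1e-9)
  expect_true(is.na(mc$R2))
})

test_that("rank deficiency is reported with the aliased terms", {
  # three distinct points cannot support a quadratic (6-term) model:
  # the fit stops either as underdetermined or as aliased
  pts <- data.frame(X1 = c(45, 34, 40), X2 = c(0, 10, 5),
                    X3 = c(14, 15, 14))
  expect_error(fit_scheffe(pts, c(1, 2, 3), default_cons,
                           order = "quadratic"),
               "too few|aliased")
  # duplicated support with n >= p triggers the aliasing branch
  pts6 <- pts[c(1, 1, 2, 2, 3, 3), ]
  expect_error(fit_scheffe(pts6, 1:6, default_cons, order = "quadratic"),
               "aliased")
})

test_that("order='auto' selects by adjusted R-squared", {
  cand <- generate_candidates(default_cons)
  X <- cand[, default_cons$names]
  y <- gen_mixture_responses(X, c(10, 20, -5, 3, -2, 4), default_cons,
                             order = "quadratic", noise_sd = 0, seed = 2)
  m <- fit_scheffe(X, y, default_cons, order = "auto")
  # a noiseless quadratic surface: anything below quadratic cannot fit it,
  # so the selected model must contain the quadratic terms
  expect_true(m$order %in% c("quadratic", "special_cubic", "full_cubic"))
  expect_equal(unname(m$coefficients[1:6]), c(10, 20, -5, 3, -2, 4),
               tolerance = 1e-6)
})
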