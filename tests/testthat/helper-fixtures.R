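# Shared objects for the test suite: default constraints, fixture tables,
# and refit response models.

default_cons <- mixture_constraints()

table3 <- load_fixture("table3")
table6 <- load_fixture("table6")
table7 <- load_fixture("table7")

fit_lag_model <- function() {
  fit_scheffe(table3, table6$lag_time_s, default_cons, order = "linear",
              response_name = "lag_time")
}

fit_float_model <- function() {
  fit_scheffe(table3, table6$float_time_h, default_cons,
              order = "quadratic", response_name = "float_time")
}

# Synthetic release-response surfaces on the ranges reported for 1/12/24 h
# release (linear in pseudo components), used where per-formulation release
# values are not published.
release_surface_models <- function(noise_sd = 1, seed = 11) {
  true <- list(release_1h = c(16, 14, 28), release_12h = c(80, 72, 88),
               release_24h = c(97, 96, 100.1))
  models <- lapply(names(true), function(nm) {
    y <- gen_mixture_responses(table3, true[[nm]], default_cons,
                               order = "linear", noise_sd = noise_sd,
                               seed = seed + match(nm, names(true)))
    fit_scheffe(table3, y, default_cons, order = "linear",
                response_name = nm)
  })
  names(models) <- names(true)
  models
}

# Exhaustive grid evaluation of composite desirability (independent oracle
# for the optimizer).
grid_max_desirability <- function(models, goals, cons, step = 0.5) {
  x2 <- seq(cons$lower[2], cons$upper[2], by = step)
  x3 <- seq(cons$lower[3], cons$upper[3], by = step)
  best <- -Inf
  for (a in x2) for (b in x3) {
    x1 <- cons$total - a - b
    if (x1 < cons$lower[1] - 1e-9 || x1 > cons$upper[1] + 1e-9) next
    D <- formuqbd:::composite_desirability(c(x1, a, b), models, goals)$D
    if (D > best) best <- D
  }
  best
}
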