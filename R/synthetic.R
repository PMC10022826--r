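# Seeded synthetic-data generators.
#
# Each generator is a deterministic function of its arguments and a seed,
# producing inputs with the statistical structure the corresponding
# analysis stage assumes: internally consistent powder records, Scheffe
# surfaces with additive Gaussian noise, the five release-kinetics curves,
# Heckel-linear compression profiles (with an optional low-pressure
# rearrangement phase), and two-compartment oral plasma curves with
# proportional noise.

# Archetype parameter means (native units).  direct_compressible is
# calibrated so the scored IGC clears the >= 5 direct-compression
# criterion; cohesive_poor_flow reproduces a deficient cohesion index and
# angle of repose; fine_hygroscopic is deficient in fines and moisture
# uptake.
.powder_archetypes <- list(
  direct_compressible = list(Da = 0.55, Dc = 0.68, Icd = 150, alpha = 28,
                             t = 4, HR = 2, H = 1.5, Pf = 8, Itheta = 0.012),
  cohesive_poor_flow  = list(Da = 0.50, Dc = 0.66, Icd = 28.4, alpha = 39.9,
                             t = 12, HR = 3, H = 4, Pf = 15, Itheta = 0.010),
  fine_hygroscopic    = list(Da = 0.42, Dc = 0.55, Icd = 110, alpha = 33,
                             t = 7, HR = 8, H = 12, Pf = 45, Itheta = 0.006)
)

#' Generate a synthetic powder record
#'
#' Samples the directly measured parameters around an archetype mean with
#' 3% proportional Gaussian noise, clamps to physical ranges, and
#' recomputes the derived indices (Ie, Ic, IH) from the sampled densities
#' so the record is internally consistent.
#'
#' @param archetype One of `direct_compressible`, `cohesive_poor_flow`,
#'   `fine_hygroscopic`.
#' @param seed Integer seed.
#' @param noise_cv Proportional noise coefficient of variation (default
#'   0.03).
#' @return A [powder_record()].
#' @export
gen_powder_record <- function(archetype = c("direct_compressible",
                                            "cohesive_poor_flow",
                                            "fine_hygroscopic"),
                              seed = 1, noise_cv = 0.03) {
  archetype <- match.arg(archetype)
  mu <- .powder_archetypes[[archetype]]
  with_seed(seed, {
    s <- lapply(mu, function(m) m * (1 + stats::rnorm(1, sd = noise_cv)))
    s$Da <- clamp(s$Da, 0.05, 1)
    s$Dc <- clamp(max(s$Dc, s$Da * 1.01), 0.05, 1.2)
    s$Icd <- clamp(s$Icd, 0, 200)
    s$alpha <- clamp(s$alpha, 0, 90)
    s$t <- max(s$t, 0)
    s$HR <- clamp(s$HR, 0, 100)
    s$H <- clamp(s$H, 0, 100)
    s$Pf <- clamp(s$Pf, 0, 100)
    s$Itheta <- clamp(s$Itheta, 0, 2e-2)
    powder_record(material_name = paste0(archetype, "_", seed),
                  Da = s$Da, Dc = s$Dc, Icd = s$Icd, alpha = s$alpha,
                  t = s$t, HR = s$HR, H = s$H, Pf = s$Pf,
                  Itheta = s$Itheta)
  })
}

#' Generate mixture responses from a known Scheffe surface
#'
#' `y = f(x; beta) + N(0, sd)`, evaluated in the requested coding;
#' replicated runs receive independent noise.
#'
#' @param design Data frame of compositions (%) with the component
#'   columns named as in `constraints`.
#' @param coefficients Named coefficient vector matching the term names of
#'   the chosen `order` (see `formuqbd:::scheffe_terms`).
#' @param constraints A [mixture_constraints()].
#' @param order Scheffe model order.
#' @param noise_sd Additive Gaussian noise standard deviation (response
#'   units).
#' @param seed Integer seed.
#' @param coding Component coding.
#' @return Numeric response vector, one value per design row.
#' @export
gen_mixture_responses <- function(design, coefficients, constraints,
                                  order = "linear", noise_sd = 0, seed = 1,
                                  coding = "pseudo") {
  coded <- code_composition(design, constraints, coding)
  X <- scheffe_matrix(coded, order)
  if (length(coefficients) != ncol(X)) {
    stop("coefficient length does not match the ", order,
         " model term count (", ncol(X), ")", call. = FALSE)
  }
  mu <- drop(X %*% coefficients)
  with_seed(seed, mu + stats::rnorm(length(mu), sd = noise_sd))
}

#' Generate a synthetic dissolution profile
#'
#' Evaluates one of the five release models on a time grid, adds Gaussian
#' noise, and clips to \[0, 105\]% (assay-noise ceiling).
#'
#' @param model Kinetic model name (see [release_curve()]).
#' @param params Model parameters (`k`, plus `n` for Korsmeyer-Peppas).
#' @param time Sampling times (h).
#' @param noise_sd Additive noise sd (percent-released units).
#' @param seed Integer seed.
#' @param formulation Profile label.
#' @return A [dissolution_profile()].
#' @export
gen_dissolution <- function(model, params, time = c(0.5, 1, 2, 4, 6, 8, 10,
                                                    12, 16, 20, 24),
                            noise_sd = 0, seed = 1, formulation = "synth") {
  f <- release_curve(model, params, time)
  f <- with_seed(seed, f + stats::rnorm(length(f), sd = noise_sd))
  f <- clamp(f, 0, 105)
  suppressWarnings(dissolution_profile(time, f, formulation))
}

#' Generate synthetic Heckel compression data
#'
#' Back-computes relative densities from `y = K P + A` (plus optional
#' noise), optionally bending the low-pressure region downwards to
#' emulate particle rearrangement (`y - b exp(-P / p0)`), and converts
#' them to tablet weights at fixed dimensions consistent with the
#' apparent-density relation.
#'
#' @param K Heckel slope (1/MPa), e.g. `1/157`.
#' @param A Heckel intercept.
#' @param pressure Pressure grid (MPa).
#' @param noise_sd Additive Gaussian noise on the Heckel ordinate.
#' @param rearrangement If `TRUE`, add a low-pressure rearrangement phase
#'   (deviation `b = 0.35`, decay `p0 = 8` MPa, negligible above ~25 MPa).
#' @param seed Integer seed.
#' @param true_density True density (g/mL).
#' @param radius_mm,thickness_mm Tablet dimensions (mm).
#' @return Data frame with `pressure_MPa`, `weight_mg`, `radius_mm`,
#'   `thickness_mm`, `true_density`, `rho_r`.
#' @export
gen_heckel <- function(K = 1 / 157, A = 0.8,
                       pressure = seq(15, 148, by = 7), noise_sd = 0,
                       rearrangement = FALSE, seed = 1, true_density = 1.62,
                       radius_mm = 1.5, thickness_mm = 2.15) {
  stopifnot(K > 0, A > 0)
  y <- K * pressure + A
  if (rearrangement) y <- y - 0.35 * exp(-pressure / 8)
  y <- with_seed(seed, y + stats::rnorm(length(y), sd = noise_sd))
  rho <- 1 - exp(-y)
  if (any(rho > 1 - 1e-9)) {
    warning("generated relative density indistinguishable from 1; truncated",
            call. = FALSE)
    rho <- pmin(rho, 1 - 1e-9)
  }
  weight <- rho * true_density * pi * radius_mm^2 * thickness_mm
  data.frame(pressure_MPa = pressure, weight_mg = weight,
             radius_mm = radius_mm, thickness_mm = thickness_mm,
             true_density = true_density, rho_r = rho)
}

#' Generate a synthetic oral plasma profile
#'
#' Two-compartment first-order-absorption closed form with optional
#' proportional Gaussian noise, clipped at zero.
#'
#' @param config A [pbpk_config()] (disposition parameters).
#' @param ka Absorption rate constant (1/h).
#' @param f_bio Bioavailable fraction.
#' @param dose Dose (mg).
#' @param time Sampling grid (h).
#' @param noise_cv Proportional noise coefficient of variation.
#' @param seed Integer seed.
#' @return A `plasma_profile` data frame.
#' @export
gen_plasma <- function(config = pbpk_config(), ka = 2.185, f_bio = 0.918,
                       dose = 60, time = seq(0, 24, by = 0.05),
                       noise_cv = 0, seed = 1) {
  conc <- two_compartment_oral(time, dose, f_bio, ka, config)
  conc <- with_seed(seed,
                    conc * (1 + stats::rnorm(length(conc), sd = noise_cv)))
  out <- data.frame(time_h = time, conc_ug_per_mL = pmax(conc, 0))
  class(out) <- c("plasma_profile", class(out))
  out
}
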