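# Packaged fixtures, configuration helpers, and the end-to-end pipeline.

.fixture_files <- c(
  table3 = "table3_compositions.csv",
  table4 = "table4_pbpk.csv",
  table6 = "table6_evaluation.csv",
  table7 = "table7_kinetics.csv",
  ir_pk  = "ir_pk.csv",
  er_pk  = "er_pk.csv"
)

#' Load a packaged data fixture
#'
#' Fixtures are the published evaluation tables of a loxoprofen sodium
#' floating-minitablet study, shipped as plain CSV: `table3` (16 blend
#' compositions), `table4` (PBPK input parameters), `table6`
#' (physicochemical / buoyancy evaluation), `table7` (release-kinetics
#' constants), `ir_pk` (immediate-release non-compartmental metrics),
#' `er_pk` (simulated extended-release metrics).
#'
#' @param name Fixture name.
#' @return Data frame.
#' @export
load_fixture <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.fixture_files)) {
    stop("unknown fixture: ", paste(as.character(name), collapse = ", "),
         "; available: ", paste(names(.fixture_files), collapse = ", "),
         call. = FALSE)
  }
  path <- system.file("extdata", .fixture_files[[name]],
                      package = "formuqbd", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a PBPK configuration from the `table4` fixture
#'
#' @param dose Dose (mg).
#' @param ... Overrides passed to [pbpk_config()] (e.g. the refined
#'   `k21 = 0.02116`).
#' @return A [pbpk_config()].
#' @export
pbpk_config_from_fixture <- function(dose = 120, ...) {
  t4 <- load_fixture("table4")
  v <- stats::setNames(t4$value, t4$parameter)
  args <- list(logP = v[["logP"]], pKa = v[["pKa"]], mw = v[["mw_g_mol"]],
               solubility = v[["solubility_mg_mL"]],
               diffusion_coeff = v[["diffusion_cm2_s"]],
               particle_density = v[["particle_density_g_mL"]],
               peff = v[["peff_cm_s"]], fup = v[["fup_pct"]],
               rbp = v[["rbp"]], vc = v[["vc_L_kg"]],
               k12 = v[["k12_per_h"]], k21 = v[["k21_per_h"]],
               cl = v[["cl_L_h_kg"]], dose = dose)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pbpk_config, args)
}

#' Run the full formulation-development pipeline on packaged fixtures
#'
#' Executes powder scoring, design generation, response-model fitting,
#' desirability optimization, dissolution kinetics, Heckel analysis, and
#' the PBPK comparison in order, on packaged fixtures plus seeded
#' synthetic stand-ins where raw data are not published.  The report is a
#' deterministic function of `seed`.
#'
#' @param seed Integer seed controlling all randomness.
#' @param out_dir Optional directory; when given, the report is written to
#'   `report.json` there.
#' @param er_duration PBPK simulation horizon (h).
#' @return Nested report list (also serializable to JSON).
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL, er_duration = 30) {
  report <- list(seed = seed)

  # 1. SeDeM scoring of a cohesive drug-like powder (synthetic stand-in)
  rec <- gen_powder_record("cohesive_poor_flow", seed = seed)
  prof <- build_profile(rec)
  report$sedem <- list(
    material = rec$material_name,
    radii = as.list(round(prof$radii, 4)),
    IP = prof$IP, IPP = prof$IPP, IGC = prof$IGC,
    correction_pct_cohesion = correction_percentage(
      re = 10, rp = unname(prof$radii[["Icd"]]), target = 5)
  )

  # 2. Mixture design and response models from the printed tables
  cons <- mixture_constraints()
  cand <- generate_candidates(cons)
  design <- i_optimal_design(cand, cons, order = "linear", n_runs = 11,
                             n_replicates = 5, seed = seed)
  t3 <- load_fixture("table3")
  t6 <- load_fixture("table6")
  lag_model <- fit_scheffe(t3, t6$lag_time_s, cons, order = "linear",
                           response_name = "lag_time")
  float_model <- fit_scheffe(t3, t6$float_time_h, cons, order = "quadratic",
                             response_name = "float_time")
  report$design <- list(
    n_runs = nrow(design),
    i_criterion = attr(design, "i_criterion"),
    lag_model = list(coef = as.list(round(lag_model$coefficients, 4)),
                     R2 = lag_model$R2),
    float_model = list(coef = as.list(round(float_model$coefficients, 4)),
                       R2 = float_model$R2)
  )

  # 3. Desirability optimization on the refit lag/float models
  goals <- list(
    desirability_goal("lag_time", "minimize", 18, 60, weight = 5),
    desirability_goal("float_time", "maximize", 15.5, 22, weight = 4)
  )
  opt <- optimize_composition(list(lag_time = lag_model,
                                   float_time = float_model),
                              goals, cons, seed = seed)
  report$optimization <- list(composition = as.list(round(opt$composition, 3)),
                              D = opt$D,
                              predictions = as.list(opt$predictions))

  # 4. Dissolution kinetics of the optimized formulation (first-order
  #    profile regenerated from the printed rate constant)
  t7 <- load_fixture("table7")
  k1 <- t7$first_k1[t7$formulation == "F2"]
  profile <- gen_dissolution("first_order", list(k = k1), noise_sd = 0,
                             seed = seed, formulation = "F2_synth")
  fits <- fit_all(profile)
  kp_n <- fits$n[fits$model == "korsmeyer_peppas"]
  report$dissolution <- list(
    best_model = attr(fits, "best"),
    first_order_k = fits$k[fits$model == "first_order"],
    kp_n = kp_n,
    mechanism = classify_mechanism(kp_n)
  )

  # 5. Heckel analysis (synthetic two-phase compression curve anchored to
  #    the reported yield pressure)
  press <- gen_heckel(K = 1 / 157, A = 0.8,
                      pressure = seq(5, 148, by = 6.5),
                      rearrangement = TRUE, noise_sd = 0.002, seed = seed)
  hk <- fit_heckel(points = press)
  report$heckel <- list(K = hk$K, A = hk$A, Py = hk$Py, R2 = hk$R2,
                        fit_range_MPa = hk$range)

  # 6. PBPK simulation of the extended-release form and comparison
  #    metrics from the fixture AUCs
  cfg <- pbpk_config_from_fixture(dose = 120)
  sim <- simulate_plasma(release_function("first_order", list(k = k1)),
                         cfg, gi_params(), duration = er_duration,
                         step = 0.05)
  met <- pk_metrics(sim)
  ir <- load_fixture("ir_pk"); er <- load_fixture("er_pk")
  irv <- stats::setNames(ir$value, ir$metric)
  erv <- stats::setNames(er$value, er$metric)
  obs_inf <- 2 * irv[["AUC0_inf_ug_mL_h"]]
  obs_t <- 2 * irv[["AUC0_t_ug_mL_h"]]
  report$pbpk <- list(
    simulated = list(Cmax = met$Cmax, Tmax = met$Tmax,
                     AUC0_t = met$AUC0_t, AUC0_inf = met$AUC0_inf,
                     mass_balance_error = attr(sim, "mass_balance_error")),
    comparison = list(
      relative_BA_pct = relative_bioavailability(
        obs_inf, erv[["dose_mg"]],
        erv[["AUC0_inf_ug_mL_h"]], erv[["dose_mg"]]),
      FE_inf = fold_error(obs_inf, erv[["AUC0_inf_ug_mL_h"]],
                          reported_orientation = TRUE),
      FE_t = fold_error(obs_t, erv[["AUC0_t_ug_mL_h"]],
                        reported_orientation = TRUE),
      PE_inf_pct = percent_prediction_error(obs_inf,
                                            erv[["AUC0_inf_ug_mL_h"]]),
      PE_t_pct = percent_prediction_error(obs_t, erv[["AUC0_t_ug_mL_h"]])
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
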