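# SeDeM expert-system powder scoring.
#
# The SeDeM diagram converts 12 measured powder parameters into 0-10
# "radius" scores grouped into five incidences (dimensions, compressibility,
# flowability/powder flow, lubricity/stability, lubricity/dosage).  A mean
# radius (IPP) rescaled by a polygon-area reliability factor gives the good
# compression index (IGC); materials with IGC >= 5 are considered suitable
# for direct compression.

# Parameter registry: conversion factor v -> r and its algebraic inverse.
# The bulk-density factor is taken as 10 v, like tapped density.
.sedem_registry <- list(
  Da     = list(incidence = "dimensions",
                to_r = function(v) 10 * v,        from_r = function(r) r / 10),
  Dc     = list(incidence = "dimensions",
                to_r = function(v) 10 * v,        from_r = function(r) r / 10),
  Ie     = list(incidence = "compressibility",
                to_r = function(v) 10 * v / 1.2,  from_r = function(r) 1.2 * r / 10),
  Ic     = list(incidence = "compressibility",
                to_r = function(v) v / 5,         from_r = function(r) 5 * r),
  Icd    = list(incidence = "compressibility",
                to_r = function(v) v / 20,        from_r = function(r) 20 * r),
  IH     = list(incidence = "flowability",
                to_r = function(v) (30 - 10 * v) / 2, from_r = function(r) (30 - 2 * r) / 10),
  alpha  = list(incidence = "flowability",
                to_r = function(v) 10 - v / 5,    from_r = function(r) 5 * (10 - r)),
  t      = list(incidence = "flowability",
                to_r = function(v) 10 - v / 2,    from_r = function(r) 2 * (10 - r)),
  HR     = list(incidence = "lubricity_stability",
                to_r = function(v) 10 - v,        from_r = function(r) 10 - r),
  H      = list(incidence = "lubricity_stability",
                to_r = function(v) 10 - v / 2,    from_r = function(r) 2 * (10 - r)),
  Pf     = list(incidence = "lubricity_dosage",
                to_r = function(v) 10 - v / 5,    from_r = function(r) 5 * (10 - r)),
  Itheta = list(incidence = "lubricity_dosage",
                to_r = function(v) 500 * v,       from_r = function(r) r / 500)
)

#' SeDeM parameter identifiers
#'
#' The 12 SeDeM parameters in canonical (diagram) order: bulk density `Da`,
#' tapped density `Dc`, interparticle porosity `Ie`, Carr's index `Ic`,
#' cohesion index `Icd`, Hausner ratio `IH`, angle of repose `alpha`, powder
#' flow time `t`, loss on drying `HR`, hygroscopicity `H`, fines fraction
#' `Pf` (% below 50 um), and homogeneity index `Itheta`.
#'
#' @return Character vector of length 12.
#' @export
sedem_parameters <- function() names(.sedem_registry)

#' Incidence group of each SeDeM parameter
#'
#' @return Named character vector mapping parameter id to incidence group
#'   (`dimensions`, `compressibility`, `flowability`, `lubricity_stability`,
#'   `lubricity_dosage`).
#' @export
sedem_incidences <- function() {
  vapply(.sedem_registry, `[[`, character(1), "incidence")
}

#' Convert a measured SeDeM parameter value into its radius score
#'
#' Applies the standard SeDeM conversion factor for the parameter and clamps
#' the result to the diagram range \[0, 10\] (with a warning when clamping
#' occurs).
#'
#' @param parameter_id One of [sedem_parameters()].
#' @param value Measured value in the parameter's native units
#'   (densities g/mL, `Ic`/`HR`/`H`/`Pf` in %, `Icd` in N, `alpha` in
#'   degrees, `t` in seconds, `Ie`/`IH`/`Itheta` dimensionless).
#' @return Radius score in \[0, 10\].
#' @examples
#' compute_radius("Ic", 25)      # 5
#' compute_radius("Icd", 28.4)   # 1.42
#' compute_radius("alpha", 39.9) # 2.02
#' @export
compute_radius <- function(parameter_id, value) {
  if (!is.character(parameter_id) || length(parameter_id) != 1L ||
      !parameter_id %in% names(.sedem_registry)) {
    stop("unknown SeDeM parameter id: ",
         paste(as.character(parameter_id), collapse = ", "), call. = FALSE)
  }
  assert_scalar_num(value, "value")
  r <- .sedem_registry[[parameter_id]]$to_r(value)
  if (r < 0 || r > 10) {
    warning(sprintf("radius for %s (value %g) outside [0, 10]; clamped",
                    parameter_id, value), call. = FALSE)
  }
  clamp(r, 0, 10)
}

# Algebraic inverse of the conversion factor (no clamping); used by the
# generators and the round-trip property tests.
radius_to_value <- function(parameter_id, r) {
  stopifnot(parameter_id %in% names(.sedem_registry))
  .sedem_registry[[parameter_id]]$from_r(r)
}

#' Build a powder record from the 12 measured SeDeM parameters
#'
#' `Ie`, `Ic` and `IH` are derived quantities: `Ie = (Dc - Da)/(Dc * Da)`,
#' `Ic = (Dc - Da)/Dc * 100`, `IH = Dc/Da`.  If supplied, they must agree
#' with the values recomputed from `Da` and `Dc` to within `1e-6`; if
#' omitted they are filled in.
#'
#' @param material_name Material label.
#' @param Da,Dc Bulk and tapped density (g/mL), `Dc >= Da > 0`.
#' @param Icd Cohesion index (N).
#' @param alpha Angle of repose (degrees, 0-90).
#' @param t Powder flow time (s).
#' @param HR Loss on drying (%).
#' @param H Hygroscopicity (%).
#' @param Pf Fines fraction below 50 um (%).
#' @param Itheta Homogeneity index (dimensionless, >= 0).
#' @param Ie,Ic,IH Optional stored derived values, checked for consistency.
#' @return A `powder_record` (named list).
#' @export
powder_record <- function(material_name, Da, Dc, Icd, alpha, t, HR, H, Pf,
                          Itheta, Ie = NULL, Ic = NULL, IH = NULL) {
  assert_scalar_num(Da, "Da", positive = TRUE)
  assert_scalar_num(Dc, "Dc", positive = TRUE)
  if (Dc < Da) stop("tapped density Dc cannot be below bulk density Da",
                    call. = FALSE)
  Ie_d <- (Dc - Da) / (Dc * Da)
  Ic_d <- (Dc - Da) / Dc * 100
  IH_d <- Dc / Da
  check_derived <- function(stored, derived, name) {
    if (!is.null(stored) && abs(stored - derived) > 1e-6) {
      stop(sprintf("stored %s (%g) inconsistent with value derived from Da/Dc (%g)",
                   name, stored, derived), call. = FALSE)
    }
    derived
  }
  Ie <- check_derived(Ie, Ie_d, "Ie")
  Ic <- check_derived(Ic, Ic_d, "Ic")
  IH <- check_derived(IH, IH_d, "IH")
  for (nm in c("Icd", "alpha", "t", "HR", "H", "Pf", "Itheta")) {
    assert_scalar_num(get(nm), nm)
  }
  if (alpha < 0 || alpha > 90) stop("alpha must lie in [0, 90] degrees",
                                    call. = FALSE)
  for (nm in c("HR", "H", "Pf")) {
    v <- get(nm)
    if (v < 0 || v > 100) stop(sprintf("%s must lie in [0, 100] %%", nm),
                               call. = FALSE)
  }
  if (Itheta < 0) stop("Itheta must be >= 0", call. = FALSE)
  rec <- list(material_name = as.character(material_name), Da = Da, Dc = Dc,
              Ie = Ie, Ic = Ic, Icd = Icd, IH = IH, alpha = alpha, t = t,
              HR = HR, H = H, Pf = Pf, Itheta = Itheta)
  class(rec) <- "powder_record"
  rec
}

#' Score a powder record as a SeDeM profile
#'
#' Computes the 12 radius scores, the mean radius per incidence group, the
#' parameter index `IP` (fraction of radii >= 5), the parametric profile
#' index `IPP` (mean radius), and the good compression index
#' `IGC = IPP * f`, where `f` is the polygon-to-circle area reliability
#' factor (0.952 for a 12-parameter diagram).
#'
#' @param record A [powder_record()].
#' @param f Reliability factor; default `0.952`.
#' @return A `sedem_profile` with elements `radii`, `incidence_means`,
#'   `IP`, `IPP`, `IGC`, `f`.
#' @export
build_profile <- function(record, f = 0.952) {
  stopifnot(inherits(record, "powder_record"))
  assert_scalar_num(f, "f", positive = TRUE)
  ids <- sedem_parameters()
  radii <- vapply(ids, function(id) compute_radius(id, record[[id]]),
                  numeric(1))
  inc <- sedem_incidences()
  incidence_means <- tapply(radii, inc[ids], mean)
  incidence_means <- incidence_means[unique(unname(inc))]
  prof <- list(
    material_name = record$material_name,
    radii = radii,
    incidence_means = as.list(incidence_means),
    IP  = mean(radii >= 5),
    IPP = mean(radii),
    f   = f,
    IGC = mean(radii) * f
  )
  class(prof) <- "sedem_profile"
  prof
}

#' @export
print.sedem_profile <- function(x, ...) {
  cat("SeDeM profile:", x$material_name, "\n")
  print(round(x$radii, 2))
  cat(sprintf("IP = %.3f  IPP = %.2f  IGC = %.2f (f = %.3f)\n",
              x$IP, x$IPP, x$IGC, x$f))
  cat(if (x$IGC >= 5) "suitable" else "not suitable",
      "for direct compression (IGC >= 5 criterion)\n")
  invisible(x)
}

#' Percentage of corrective excipient needed to fix a deficient parameter
#'
#' For a material whose radius `rp` on some parameter falls below the
#' acceptability threshold, the fraction of a corrective excipient with
#' radius `re` needed to bring the blend to the target radius `target` is
#' `CP = 100 - (re - target)/(re - rp) * 100`.
#'
#' @param re Radius of the corrective excipient (must exceed `rp`).
#' @param rp Radius of the deficient material.
#' @param target Target blend radius, default 5; must lie in `(rp, 10]`.
#' @return Excipient percentage in \[0, 100\].
#' @examples
#' correction_percentage(10, 1.42)  # 41.72...
#' @export
correction_percentage <- function(re, rp, target = 5) {
  assert_scalar_num(re, "re"); assert_scalar_num(rp, "rp")
  assert_scalar_num(target, "target")
  if (re <= rp) {
    stop("infeasible correction: excipient radius re must exceed rp",
         call. = FALSE)
  }
  if (target > 10 || target <= 0) {
    stop("target radius must lie in (0, 10]", call. = FALSE)
  }
  if (target <= rp) return(0)  # already at or above the target
  if (re <= target) {
    warning("excipient radius does not exceed the target: even 100% ",
            "excipient cannot reach it", call. = FALSE)
    return(100)
  }
  cp <- 100 - (re - target) / (re - rp) * 100
  clamp(cp, 0, 100)
}

#' Radar-diagram vertex coordinates for a SeDeM profile
#'
#' Vertices are placed at 30-degree spacing in the canonical parameter
#' order, starting at 12 o'clock and proceeding clockwise.
#'
#' @param profile A `sedem_profile`.
#' @return Data frame with columns `parameter`, `angle_deg`, `radius`,
#'   `x`, `y`.
#' @export
radar_polygon <- function(profile) {
  stopifnot(inherits(profile, "sedem_profile"))
  ids <- sedem_parameters()
  angle_deg <- (seq_along(ids) - 1L) * 30
  theta <- pi / 2 - angle_deg * pi / 180   # clockwise from vertical
  r <- unname(profile$radii[ids])
  data.frame(parameter = ids, angle_deg = angle_deg, radius = r,
             x = r * cos(theta), y = r * sin(theta),
             stringsAsFactors = FALSE)
}

#' Read powder records from a CSV file
#'
#' Expects one row per material with columns `material` plus the parameter
#' symbols `Da, Dc, Icd, alpha, t, HR, H, Pf, Itheta` (and optionally the
#' derived `Ie, Ic, IH`, which are then consistency-checked).
#'
#' @param path CSV path.
#' @return List of [powder_record()] objects.
#' @export
read_powders <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("material", "Da", "Dc", "Icd", "alpha", "t", "HR", "H", "Pf",
            "Itheta")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("powder CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    powder_record(row$material, Da = row$Da, Dc = row$Dc, Icd = row$Icd,
                  alpha = row$alpha, t = row$t, HR = row$HR, H = row$H,
                  Pf = row$Pf, Itheta = row$Itheta,
                  Ie = row[["Ie"]], Ic = row[["Ic"]], IH = row[["IH"]])
  })
}
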