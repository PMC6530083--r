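#' Saponification and iodine values of a FAME profile
#'
#' Empirical fuel indices computed from the weight-percent composition:
#' `SV = sum(560 * pct_i / M_i)` (mg KOH per g) and
#' `IV = sum(k * DB_i * pct_i / M_i)` (g I2 per 100 g), where `M_i` is the
#' component molecular mass and `DB_i` its double-bond count. The iodine
#' constant `k` defaults to 254, the value used across the empirical
#' biodiesel literature; 245 is selectable.
#'
#' @param profile A normalized [fame_profile()].
#' @param basis Mass basis, `"free_acid"` (default) or `"methyl_ester"`.
#' @param constant Iodine constant, 254 (default) or 245.
#' @return Numeric scalar.
#' @examples
#' saponification_value(fame_profile(c("C16:0" = 100)))  # 218.38
#' iodine_value(fame_profile(c("C18:1" = 100)))          # 89.92
#' @export
saponification_value <- function(profile, basis = c("free_acid", "methyl_ester")) {
  .assert_normalized(profile)
  basis <- match.arg(basis)
  if (nrow(profile) == 0) stop("empty profile")
  sum(560 * profile$percent / molecular_mass(profile, basis))
}

#' @rdname saponification_value
#' @export
iodine_value <- function(profile, basis = c("free_acid", "methyl_ester"),
                         constant = c(254, 245)) {
  .assert_normalized(profile)
  basis <- match.arg(basis)
  constant <- match.arg(as.character(constant[1]), c("254", "245"))
  constant <- as.numeric(constant)
  if (nrow(profile) == 0) stop("empty profile")
  sum(constant * profile$double_bonds * profile$percent /
        molecular_mass(profile, basis))
}

#' Cetane number and higher heating value from SV and IV
#'
#' Empirical correlations on the saponification and iodine values:
#' `CN = 46.3 + 5458/SV - 0.255 IV` and
#' `HHV = 49.43 - 0.041 SV - 0.015 IV` (MJ/kg).
#'
#' @param sv Saponification value, mg KOH (> 0 for CN).
#' @param iv Iodine value, g I2 / 100 g (>= 0).
#' @return Numeric scalar.
#' @examples
#' cetane_number(159.66, 107.76)       # 53.01
#' higher_heating_value(159.66, 107.76) # 41.27
#' @export
cetane_number <- function(sv, iv) {
  stopifnot(is.numeric(sv), is.numeric(iv))
  if (any(sv <= 0)) stop("saponification value must be positive")
  if (any(iv < 0)) stop("iodine value must be non-negative")
  46.3 + 5458 / sv - 0.255 * iv
}

#' @rdname cetane_number
#' @export
higher_heating_value <- function(sv, iv) {
  stopifnot(is.numeric(sv), is.numeric(iv), sv >= 0, iv >= 0)
  49.43 - 0.041 * sv - 0.015 * iv
}

#' Long-chain saturation factor and cold filter plugging point
#'
#' `LCSF = 0.1 * %C16:0 + 0.5 * %C18:0` (weight percent of the saturated
#' palmitic and stearic species) and `CFPP = 3.417 * LCSF - 16.477` (deg C).
#' CFPP is defined (-16.477) even for profiles without C16:0/C18:0.
#'
#' @inheritParams saponification_value
#' @return List with `lcsf` (percent weight) and `cfpp` (deg C).
#' @export
lcsf_cfpp <- function(profile) {
  .assert_normalized(profile)
  pc16 <- sum(profile$percent[profile$label == "C16:0"])
  pc18 <- sum(profile$percent[profile$label == "C18:0"])
  lcsf <- 0.1 * pc16 + 0.5 * pc18
  list(lcsf = lcsf, cfpp = 3.417 * lcsf - 16.477)
}

#' Kinematic viscosity and density from mixture descriptors
#'
#' Correlations on the percent-weighted mean molecular mass `M` and mean
#' double-bond count `DB` of the mixture:
#' `ln(kv) = -12.503 + 2.496 ln(M) - 0.178 DB` (kv in mm^2/s, natural
#' logarithm) and `density = 0.8463 + 4.9/M + 0.0118 DB` (g/cm^3).
#'
#' @param desc A [mixture_descriptors()] list (or a normalized
#'   `fame_profile`, from which descriptors are computed).
#' @param basis Mass basis used when `desc` is a profile.
#' @return List with `ln_kv`, `kv` (mm^2/s) and `density` (g/cm^3).
#' @export
viscosity_density <- function(desc, basis = c("free_acid", "methyl_ester")) {
  if (inherits(desc, "fame_profile"))
    desc <- mixture_descriptors(desc, match.arg(basis))
  stopifnot(is.list(desc), all(c("mean_mass", "mean_db") %in% names(desc)))
  if (!is.finite(desc$mean_mass) || desc$mean_mass <= 0)
    stop("mean molecular mass must be positive")
  ln_kv <- -12.503 + 2.496 * log(desc$mean_mass) - 0.178 * desc$mean_db
  list(ln_kv = ln_kv, kv = exp(ln_kv),
       density = 0.8463 + 4.9 / desc$mean_mass + 0.0118 * desc$mean_db)
}

#' Oxidative stability from linoleic and linolenic content
#'
#' `OS = 117.9295 / (%C18:2 + %C18:3) + 2.5905` hours. A profile with no
#' C18:2/C18:3 has no finite induction-time prediction: the result is `Inf`
#' with attribute `unbounded = TRUE` rather than an error.
#'
#' @inheritParams saponification_value
#' @return Numeric scalar (hours), possibly `Inf` with attribute `unbounded`.
#' @export
oxidative_stability <- function(profile) {
  .assert_normalized(profile)
  w <- sum(profile$percent[profile$label %in% c("C18:2", "C18:3")])
  if (w <= 0)
    return(structure(Inf, unbounded = TRUE))
  structure(117.9295 / w + 2.5905, unbounded = FALSE)
}

#' Full biodiesel property report for a FAME profile
#'
#' Evaluates the ten empirical fuel-property correlations on one normalized
#' FAME profile: saponification value (SV), iodine value (IV), cetane number
#' (CN), degree of unsaturation (DU), long-chain saturation factor (LCSF),
#' higher heating value (HHV), cold filter plugging point (CFPP), kinematic
#' viscosity (ln kv and kv) and density, plus oxidative stability (OS).
#'
#' @inheritParams saponification_value
#' @param iv_constant Iodine constant, 254 (default) or 245.
#' @return A `fuel_report` list with fields `sv`, `iv`, `cn`, `du`, `lcsf`,
#'   `hhv`, `cfpp`, `ln_kv`, `kv`, `density`, `os`, `os_unbounded`, plus the
#'   `basis` and `iv_constant` used.
#' @examples
#' p <- fame_profile(c("C16:0" = 20, "C18:0" = 5, "C18:1" = 45,
#'                     "C18:2" = 25, "C18:3" = 5))
#' fuel_report(p)
#' @export
fuel_report <- function(profile, basis = c("free_acid", "methyl_ester"),
                        iv_constant = c(254, 245)) {
  .assert_normalized(profile)
  basis <- match.arg(basis)
  sv <- saponification_value(profile, basis)
  iv <- iodine_value(profile, basis, iv_constant)
  cls <- class_fractions(profile)
  lc <- lcsf_cfpp(profile)
  vd <- viscosity_density(profile, basis)
  os <- oxidative_stability(profile)
  structure(list(
    sv = sv, iv = iv, cn = cetane_number(sv, iv), du = cls$du,
    lcsf = lc$lcsf, hhv = higher_heating_value(sv, iv), cfpp = lc$cfpp,
    ln_kv = vd$ln_kv, kv = vd$kv, density = vd$density,
    os = as.numeric(os), os_unbounded = isTRUE(attr(os, "unbounded")),
    basis = basis, iv_constant = as.numeric(match.arg(as.character(iv_constant[1]), c("254", "245")))
  ), class = "fuel_report")
}

#' @export
print.fuel_report <- function(x, ...) {
  cat("Predicted biodiesel physical properties (", x$basis,
      " mass basis, IV constant ", x$iv_constant, "):\n", sep = "")
  cat(sprintf("  SV   %8.2f mg KOH\n  IV   %8.2f gI2/100 g\n  CN   %8.2f\n",
              x$sv, x$iv, x$cn))
  cat(sprintf("  DU   %8.2f %%wt\n  LCSF %8.2f %%wt\n  HHV  %8.2f MJ/kg\n",
              x$du, x$lcsf, x$hhv))
  cat(sprintf("  CFPP %8.2f degC\n  kv   %8.2f mm2/s (ln kv %.3f)\n  D    %8.4f g/cm3\n",
              x$cfpp, x$kv, x$ln_kv, x$density))
  if (x$os_unbounded) cat("  OS   unbounded (no C18:2/C18:3)\n")
  else cat(sprintf("  OS   %8.2f h\n", x$os))
  invisible(x)
}

#' Biodiesel fuel standards
#'
#' Limit sets for the international biodiesel standards used in strain
#' screening: EN 14214 (Europe), ASTM D6751 (USA) and IS 15607 (India).
#' Indices without a stated limit are unconstrained.
#'
#' @param name One of `"EN14214"`, `"ASTM_D6751"`, `"IS15607"`.
#' @return A `fuel_standard`: list with `name` and `limits`, each limit a
#'   `c(lower, upper)` pair (NA = unbounded on that side).
#' @export
fuel_standard <- function(name = c("EN14214", "ASTM_D6751", "IS15607")) {
  name <- match.arg(name)
  limits <- switch(name,
    EN14214 = list(iv = c(NA, 120), cn = c(51, NA), kv = c(3.5, 5),
                   density = c(0.86, 0.9), os = c(6, NA)),
    ASTM_D6751 = list(cn = c(47, NA), kv = c(1.9, 6)),
    IS15607 = list(cn = c(51, NA), kv = c(3.5, 5), density = c(0.86, 0.9)))
  structure(list(name = name, limits = limits), class = "fuel_standard")
}

#' Check a fuel report against a standard
#'
#' @param report A [fuel_report()].
#' @param standard A [fuel_standard()] or a standard name.
#' @return A `compliance_result`: data frame of per-index verdicts
#'   (`"pass"`, `"fail"`, `"not_constrained"`) with attributes `standard`
#'   and `overall_pass` (TRUE iff no index fails).
#' @examples
#' p <- fame_profile(c("C16:0" = 20, "C18:1" = 60, "C18:2" = 20))
#' check_compliance(fuel_report(p), "ASTM_D6751")
#' @export
check_compliance <- function(report, standard = "EN14214") {
  stopifnot(inherits(report, "fuel_report"))
  if (is.character(standard)) standard <- fuel_standard(standard)
  stopifnot(inherits(standard, "fuel_standard"))
  indices <- c("sv", "iv", "cn", "du", "lcsf", "hhv", "cfpp", "kv", "density", "os")
  verdict <- vapply(indices, function(idx) {
    lim <- standard$limits[[idx]]
    if (is.null(lim)) return("not_constrained")
    val <- report[[idx]]
    if (idx == "os" && report$os_unbounded) val <- Inf
    ok <- (is.na(lim[1]) || val >= lim[1]) && (is.na(lim[2]) || val <= lim[2])
    if (ok) "pass" else "fail"
  }, character(1))
  out <- data.frame(index = indices, verdict = unname(verdict),
                    stringsAsFactors = FALSE)
  structure(out, class = c("compliance_result", "data.frame"),
            standard = standard$name,
            overall_pass = !any(verdict == "fail"))
}

#' @export
print.compliance_result <- function(x, ...) {
  cat("Compliance with", attr(x, "standard"), "-",
      if (attr(x, "overall_pass")) "PASS" else "FAIL", "\n")
  constrained <- x[x$verdict != "not_constrained", , drop = FALSE]
  print.data.frame(constrained, row.names = FALSE)
  invisible(x)
}
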