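#' Biomass productivity
#'
#' `BP = (final biomass - initial biomass) / cultivation time` in
#' mg/ml/h. A net biomass decline gives a negative productivity, returned
#' with a warning rather than an error.
#'
#' @param initial,final Biomass concentration, mg/ml.
#' @param hours Cultivation time, h (> 0).
#' @return Productivity in mg/ml/h.
#' @examples
#' biomass_productivity(0, 44.4, 120)  # 0.37 mg/ml/h
#' @export
biomass_productivity <- function(initial, final, hours) {
  stopifnot(is.numeric(initial), is.numeric(final), is.numeric(hours))
  if (any(hours <= 0)) stop("cultivation time must be positive")
  bp <- (final - initial) / hours
  if (any(bp < 0)) warning("negative biomass productivity (biomass decline)")
  bp
}

#' Lipid yield, content and productivity
#'
#' Gravimetric lipid metrics from a Folch-type extraction:
#' yield `L = 100 (w1 - w2) / wB` (g lipid per 100 g wet biomass, with `w1`
#' and `w2` the final and tare weights of the collection tube), content
#' `LC = 100 * lipid mass / biomass mass`, and productivity
#' `LP = BP * L / 100` (mg/ml/h).
#'
#' @param w1 Final weight of tube plus lipid, g.
#' @param w2 Tare weight of tube, g (`w1 >= w2`).
#' @param wb Wet biomass weight, g (> 0).
#' @param lipid_mass,biomass_mass Masses for the content ratio, g
#'   (`biomass_mass` > 0). Default `lipid_mass = w1 - w2`.
#' @param bp Biomass productivity, mg/ml/h (for LP; optional).
#' @return List with `yield` (%), `content` (%) if computable, and `lp`
#'   (mg/ml/h) if `bp` was given.
#' @examples
#' lipid_metrics(w1 = 10.10, w2 = 10.00, wb = 1, biomass_mass = 0.5, bp = 0.08)
#' @export
lipid_metrics <- function(w1, w2, wb, lipid_mass = w1 - w2,
                          biomass_mass = NULL, bp = NULL) {
  stopifnot(is.numeric(w1), is.numeric(w2), is.numeric(wb))
  if (any(w1 < w2)) stop("final tube weight below tare (w1 < w2)")
  if (any(wb <= 0)) stop("wet biomass weight must be positive")
  out <- list(yield = 100 * (w1 - w2) / wb)
  if (!is.null(biomass_mass)) {
    if (any(biomass_mass <= 0)) stop("biomass mass must be positive")
    out$content <- 100 * lipid_mass / biomass_mass
  }
  if (!is.null(bp)) out$lp <- bp * out$yield / 100
  out
}

#' Lipid productivity from biomass productivity and yield
#'
#' @param bp Biomass productivity, mg/ml/h.
#' @param yield Lipid yield, percent.
#' @return `bp * yield / 100`, mg/ml/h.
#' @export
lipid_productivity <- function(bp, yield) {
  stopifnot(is.numeric(bp), is.numeric(yield))
  bp * yield / 100
}
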