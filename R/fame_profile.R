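#' FAME weight-percent profiles
#'
#' A `fame_profile` stores the weight-percent composition of a lipid sample
#' over identified fatty acids, as produced by GC-FID FAME analysis. Profiles
#' are expressed as percent of *identified* fatty acids and are normalized so
#' the percentages sum to exactly 100; mole-percent input is not supported.
#'
#' @param percent Named numeric vector of weight percentages (names are
#'   fatty-acid labels such as `"C18:1"`), or an unnamed numeric vector with
#'   `acids` supplied. All values must be non-negative with at least one
#'   positive; duplicate acids are not allowed.
#' @param acids Optional labels (or a `fatty_acid` object) matching `percent`.
#' @param normalize If `TRUE` (default) rescale to sum to 100.
#' @return A `fame_profile`: data frame with columns `label`, `carbons`,
#'   `double_bonds`, `percent`, and attribute `normalized`.
#' @examples
#' fame_profile(c("C16:0" = 25, "C18:1" = 25))   # rescaled to 50/50
#' @export
fame_profile <- function(percent, acids = names(percent), normalize = TRUE) {
  if (is.data.frame(percent) && all(c("fatty_acid", "percent") %in% names(percent))) {
    acids <- percent$fatty_acid
    percent <- percent$percent
  }
  if (is.null(acids)) stop("fatty-acid labels are required (names of 'percent' or 'acids')")
  fa <- fatty_acid(acids)
  percent <- as.numeric(percent)
  if (length(percent) != nrow(fa)) stop("'percent' and 'acids' lengths differ")
  if (any(!is.finite(percent)) || any(percent < 0))
    stop("percentages must be finite and non-negative")
  if (sum(percent) <= 0) stop("profile is all zero: nothing to normalize")
  if (anyDuplicated(fa$label))
    stop("duplicate fatty acid(s): ", paste(unique(fa$label[duplicated(fa$label)]), collapse = ", "))
  out <- data.frame(fa, percent = percent, stringsAsFactors = FALSE)
  normalized <- FALSE
  if (normalize) {
    out$percent <- 100 * out$percent / sum(out$percent)
    normalized <- TRUE
  }
  structure(out, class = c("fame_profile", "data.frame"), normalized = normalized)
}

#' @rdname fame_profile
#' @param x Object to test or normalize.
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

#' @rdname fame_profile
#' @export
normalize_profile <- function(x) {
  if (inherits(x, "fame_profile"))
    return(fame_profile(x$percent, x$label, normalize = TRUE))
  fame_profile(x, normalize = TRUE)
}

.assert_normalized <- function(profile) {
  if (!inherits(profile, "fame_profile"))
    stop("expected a 'fame_profile' object")
  if (!is_normalized(profile))
    stop("profile must be normalized (see normalize_profile())")
  invisible(profile)
}

#' Saturation-class summary of a FAME profile
#'
#' Aggregates a normalized profile into saturated (SFA, zero double bonds),
#' monounsaturated (MUFA, exactly one) and polyunsaturated (PUFA, two or
#' more) weight percentages, plus the degree of unsaturation
#' DU = MUFA + 2 PUFA (percent weight).
#'
#' @param profile A normalized [fame_profile()].
#' @return A `class_summary` list with `sfa`, `mufa`, `pufa`, `du`.
#' @examples
#' p <- fame_profile(c("C16:0" = 70, "C18:1" = 10, "C18:2" = 20))
#' class_fractions(p)$du  # 10 + 2*20 = 50
#' @export
class_fractions <- function(profile) {
  .assert_normalized(profile)
  sfa <- sum(profile$percent[profile$double_bonds == 0L])
  mufa <- sum(profile$percent[profile$double_bonds == 1L])
  pufa <- sum(profile$percent[profile$double_bonds >= 2L])
  structure(list(sfa = sfa, mufa = mufa, pufa = pufa, du = mufa + 2 * pufa),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("SFA %.2f%%  MUFA %.2f%%  PUFA %.2f%%  (DU %.2f %%wt)\n",
              x$sfa, x$mufa, x$pufa, x$du))
  invisible(x)
}

#' Percent-weighted mixture descriptors
#'
#' The mean molecular mass and mean double-bond count of a FAME mixture,
#' weighted by weight percent: `mean_mass = sum(pct * M) / 100` and
#' `mean_db = sum(pct * DB) / 100`. These are the mixture-level mass and
#' unsaturation terms consumed by the kinematic-viscosity and density
#' correlations.
#'
#' @inheritParams class_fractions
#' @param basis Mass basis passed to [molecular_mass()].
#' @return A list with `mean_mass` (g/mol) and `mean_db` (dimensionless).
#' @export
mixture_descriptors <- function(profile, basis = c("free_acid", "methyl_ester")) {
  .assert_normalized(profile)
  basis <- match.arg(basis)
  if (nrow(profile) == 0) stop("empty profile")
  m <- molecular_mass(profile, basis)
  list(mean_mass = sum(profile$percent * m) / 100,
       mean_db = sum(profile$percent * profile$double_bonds) / 100)
}

#' Blend two FAME profiles
#'
#' Weight-fraction blend: `lambda` parts of `a` per `1 - lambda` parts of
#' `b`. Acids present in only one profile contribute zero from the other.
#'
#' @param a,b Normalized [fame_profile()] objects.
#' @param lambda Blend fraction of `a`, in \[0, 1\].
#' @return A normalized `fame_profile`.
#' @export
blend_profiles <- function(a, b, lambda) {
  .assert_normalized(a); .assert_normalized(b)
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  labels <- union(a$label, b$label)
  pa <- stats::setNames(rep(0, length(labels)), labels)
  pb <- pa
  pa[a$label] <- a$percent
  pb[b$label] <- b$percent
  fame_profile(lambda * pa + (1 - lambda) * pb)
}

#' @export
print.fame_profile <- function(x, digits = 2, ...) {
  cat(sprintf("FAME profile: %d identified fatty acids%s\n", nrow(x),
              if (is_normalized(x)) " (normalized, sums to 100%)" else ""))
  df <- data.frame(fatty_acid = x$label, percent = round(x$percent, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
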