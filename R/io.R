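.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  strip.white = TRUE, fileEncoding = "UTF-8")
}

#' Read and write FAME profile tables
#'
#' FAME tables are CSV/TSV files with header `fatty_acid,percent`, the
#' fatty-acid column in `"C<n>:<d>"` notation, UTF-8, `#` comment lines.
#'
#' @param path File path.
#' @param normalize Normalize the profile on read (default TRUE).
#' @return [read_fame_table()]: a [fame_profile()]. [write_fame_table()]:
#'   the path, invisibly.
#' @export
read_fame_table <- function(path, normalize = TRUE) {
  df <- .read_csv(path)
  need <- c("fatty_acid", "percent")
  if (!all(need %in% names(df)))
    stop("FAME table must have columns ", paste(need, collapse = ", "),
         "; found: ", paste(names(df), collapse = ", "))
  bad <- which(!is.finite(df$percent) | df$percent < 0)
  if (length(bad))
    stop("invalid percent at row(s) ", paste(bad, collapse = ", "))
  fame_profile(df$percent, df$fatty_acid, normalize = normalize)
}

#' @rdname read_fame_table
#' @param profile A [fame_profile()].
#' @export
write_fame_table <- function(profile, path) {
  stopifnot(inherits(profile, "fame_profile"))
  utils::write.csv(data.frame(fatty_acid = profile$label,
                              percent = profile$percent),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a colony-count table
#'
#' CSV with columns `strain,time_min,cfu_mean` (optionally `cfu_se`);
#' `time_min = 0` encodes the untreated control. A dash cell (`"-"` or
#' en-dash) means "no colony on the plate": it is mapped to a structural
#' zero and flagged in the logical `lethal` column, as distinct from absent
#' data.
#'
#' @param path File path.
#' @return Data frame with numeric `cfu_mean` and added `lethal` column.
#' @export
read_colony_table <- function(path) {
  df <- .read_csv(path)
  need <- c("strain", "time_min", "cfu_mean")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  raw <- trimws(as.character(df$cfu_mean))
  dash <- raw %in% c("-", "–", "—")
  cfu <- suppressWarnings(as.numeric(raw))
  cfu[dash] <- 0
  bad <- which(is.na(cfu))
  if (length(bad))
    stop("unparseable CFU at row(s) ", paste(bad, collapse = ", "))
  neg <- which(cfu < 0)
  if (length(neg))
    stop("negative CFU at row(s) ", paste(neg, collapse = ", "))
  df$cfu_mean <- cfu
  df$lethal <- dash
  df
}

#' Load the in-package study fixtures
#'
#' Returns the transcribed screening-study tables shipped with the package:
#' `growth_optima` (wild-strain OD/colony optima), `design_responses` (the
#' 3x3 dose/volume factorial run means, with ambiguous transcriptions
#' flagged `uncertain`), `colony_counts` (exposure-time CFU series),
#' `lipid_metrics` (lipid yield/content/productivity, with the documented
#' `lp_consistent` flag) and `fuel_indices` (reported biodiesel property
#' panel). All tables are validated on load; no network access is involved.
#'
#' @return A named list of data frames.
#' @export
load_study_fixtures <- function() {
  pkgdir <- system.file("extdata", package = "scoil")
  fx <- list(
    growth_optima = .read_csv(file.path(pkgdir, "growth_optima.csv")),
    design_responses = .read_csv(file.path(pkgdir, "design_responses.csv")),
    colony_counts = read_colony_table(file.path(pkgdir, "colony_counts.csv")),
    lipid_metrics = .read_csv(file.path(pkgdir, "lipid_metrics.csv")),
    fuel_indices = .read_csv(file.path(pkgdir, "fuel_indices.csv")))
  stopifnot(nrow(fx$design_responses) == 45,
            all(fx$design_responses$cfu >= 0),
            is.logical(fx$design_responses$uncertain),
            all(fx$colony_counts$cfu_mean >= 0),
            all(fx$fuel_indices$sv > 0))
  fx
}

#' Treatment series for a study strain
#'
#' Builds a [treatment_series()] from the packaged colony-count fixture.
#'
#' @param strain Strain id present in the fixture.
#' @return A [treatment_series()].
#' @examples
#' survival_curve(study_treatment_series("YlTun15"))
#' @export
study_treatment_series <- function(strain) {
  cc <- load_study_fixtures()$colony_counts
  d <- cc[cc$strain == strain, ]
  if (nrow(d) == 0) stop("unknown strain: ", strain)
  ctl <- d$cfu_mean[d$time_min == 0]
  trt <- d[d$time_min > 0, ]
  trt <- trt[order(trt$time_min), ]
  treatment_series(strain, ctl, trt$time_min, trt$cfu_mean)
}
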