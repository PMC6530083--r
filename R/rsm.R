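# Run ordering of the published 3x3 EMS dose/volume design (concentration mM,
# volume ul). Used when the requested levels match, so run ids line up with
# the study's experiment numbers.
.STUDY_RUN_ORDER <- data.frame(
  conc_mM = c(75, 100, 25, 25, 100, 75, 100, 25, 75),
  vol_ul  = c(100, 50, 15, 50, 100, 15, 15, 100, 50))

#' Two-factor full-factorial design
#'
#' Builds the full cross of mutagen concentration and volume levels (a 3x3
#' grid in the default screening design, 9 runs). When the levels are the
#' study's defaults (25/75/100 mM by 15/50/100 ul) the runs are ordered to
#' match the published experiment numbering; otherwise runs follow
#' cross-product order.
#'
#' @param levels_x Distinct concentration levels (mM).
#' @param levels_y Distinct volume levels (ul).
#' @param replicates Replicates per run (default 3).
#' @return A `factorial_design` data frame with columns `run`, `conc_mM`,
#'   `vol_ul`; attribute `replicates`.
#' @export
factorial_design <- function(levels_x = c(25, 75, 100),
                             levels_y = c(15, 50, 100),
                             replicates = 3) {
  if (anyDuplicated(levels_x) || anyDuplicated(levels_y))
    stop("duplicate factor levels")
  if (length(levels_x) < 2 || length(levels_y) < 2)
    stop("need at least two distinct levels per factor")
  stopifnot(replicates >= 1)
  if (setequal(levels_x, c(25, 75, 100)) && setequal(levels_y, c(15, 50, 100))) {
    runs <- .STUDY_RUN_ORDER
  } else {
    runs <- expand.grid(conc_mM = sort(levels_x), vol_ul = sort(levels_y),
                        KEEP.OUT.ATTRS = FALSE)
  }
  out <- data.frame(run = seq_len(nrow(runs)), runs)
  structure(out, class = c("factorial_design", "data.frame"),
            replicates = as.integer(replicates))
}

# column order matches the coefficient convention b0 + b1 x + b2 x^2 +
# b3 y + b4 y^2 + b5 xy used throughout
.quad_model_matrix <- function(x, y) {
  cbind(intercept = 1, x = x, x2 = x^2, y = y, y2 = y^2, xy = x * y)
}

#' Fit a quadratic response surface
#'
#' Ordinary least squares fit of the six-coefficient quadratic surface
#' `Z = b0 + b1 x + b2 x^2 + b3 y + b4 y^2 + b5 xy` in natural factor units
#' (mM, ul), via QR decomposition ([stats::lm()]). The response may be run
#' means (one value per run) or per-replicate data; for a balanced design
#' the two give identical coefficients.
#'
#' @param design A [factorial_design()].
#' @param response Either a numeric vector of run means (length
#'   `nrow(design)`, in run order) or a data frame with columns `run` and
#'   `value` (replicate rows allowed).
#' @param name Response name for printing (e.g. `"colonies"`, `"growth"`).
#' @return An `rsm` object wrapping the `lm` fit, with `coefficients` named
#'   `b0`..`b5`, `r_squared`, `residual_ss`, and methods `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `anova`.
#' @examples
#' d <- factorial_design()
#' z <- with(d, 200 + 1.2 * conc_mM - 0.02 * conc_mM^2 - 1.9 * vol_ul +
#'             0.005 * vol_ul^2 - 0.005 * conc_mM * vol_ul)
#' coef(rsm_fit(d, z))
#' @export
rsm_fit <- function(design, response, name = "response") {
  stopifnot(inherits(design, "factorial_design"))
  if (is.data.frame(response)) {
    stopifnot(all(c("run", "value") %in% names(response)))
    i <- match(response$run, design$run)
    if (anyNA(i)) stop("response refers to unknown run id(s)")
    x <- design$conc_mM[i]; y <- design$vol_ul[i]; z <- response$value
  } else {
    if (length(response) != nrow(design))
      stop("run-mean response must have one value per design run")
    x <- design$conc_mM; y <- design$vol_ul; z <- as.numeric(response)
  }
  if (length(unique(paste(x, y))) < 6)
    stop("need >= 6 distinct design points to fit 6 coefficients")
  dat <- data.frame(z = z, x = x, y = y)
  fit <- stats::lm(z ~ x + y + I(x^2) + I(y^2) + I(x * y), data = dat)
  qrf <- qr(stats::model.matrix(fit))
  if (qrf$rank < 6) {
    cols <- colnames(stats::model.matrix(fit))
    stop("rank-deficient design; collinear column(s): ",
         paste(cols[-seq_len(qrf$rank)], collapse = ", "))
  }
  b <- stats::coef(fit)[c("(Intercept)", "x", "I(x^2)", "y", "I(y^2)", "I(x * y)")]
  names(b) <- c("b0", "b1", "b2", "b3", "b4", "b5")
  res <- stats::residuals(fit)
  tss <- sum((z - mean(z))^2)
  structure(list(coefficients = b, response = name, lm = fit,
                 residual_ss = sum(res^2),
                 r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
                 design = design),
            class = "rsm")
}

#' @export
coef.rsm <- function(object, ...) object$coefficients

#' @export
residuals.rsm <- function(object, ...) stats::residuals(object$lm)

#' Evaluate a fitted (or published) response surface
#'
#' Polynomial evaluation of the quadratic surface at arbitrary factor
#' settings. Predictions are not clipped: a negative predicted colony count
#' is returned as-is with attribute `negative` flagging the offending
#' entries (quadratic surfaces extrapolate below zero).
#'
#' @param object An `rsm` fit, or a numeric vector of six coefficients
#'   `b0..b5` via [rsm_surface()].
#' @param x,y Concentration (mM) and volume (ul) settings.
#' @param ... Unused.
#' @return Numeric vector of predictions, attribute `negative`.
#' @export
predict.rsm <- function(object, x, y, ...) {
  rsm_predict_coef(object$coefficients, x, y)
}

#' @rdname predict.rsm
#' @param coefficients Numeric vector `c(b0, b1, b2, b3, b4, b5)` for
#'   `b0 + b1 x + b2 x^2 + b3 y + b4 y^2 + b5 xy`.
#' @export
rsm_predict_coef <- function(coefficients, x, y) {
  stopifnot(length(coefficients) == 6, is.finite(x), is.finite(y))
  b <- as.numeric(coefficients)
  z <- b[1] + b[2] * x + b[3] * x^2 + b[4] * y + b[5] * y^2 + b[6] * x * y
  structure(z, negative = z < 0)
}

#' @export
print.rsm <- function(x, digits = 3, ...) {
  b <- round(x$coefficients, digits)
  cat(sprintf("Quadratic response surface for '%s':\n", x$response))
  cat(sprintf("  Z = %g %+g x %+g x^2 %+g y %+g y^2 %+g xy\n",
              b[1], b[2], b[3], b[4], b[5], b[6]))
  cat(sprintf("  R^2 = %.3f, residual SS = %.3f\n", x$r_squared, x$residual_ss))
  invisible(x)
}

#' @export
summary.rsm <- function(object, ...) {
  s <- summary(object$lm)
  cat("Response:", object$response, "\n")
  print(s$coefficients)
  invisible(s)
}

#' Factorial ANOVA of a two-factor quadratic surface
#'
#' Sequential (type I) decomposition of the response sum of squares into the
#' five surface terms (x, y, x^2, y^2, xy) plus residual, with F statistics
#' against the residual mean square and upper-tail F probabilities. Requires
#' per-replicate data (residual degrees of freedom must be positive).
#'
#' @param design A [factorial_design()].
#' @param response Data frame with columns `run` and `value`, >= 2
#'   replicates per run.
#' @return An `rsm_anova` data frame with columns `effect`, `ss`, `df`,
#'   `ms`, `f`, `p`.
#' @export
factorial_anova <- function(design, response) {
  stopifnot(inherits(design, "factorial_design"), is.data.frame(response))
  stopifnot(all(c("run", "value") %in% names(response)))
  reps <- table(response$run)
  if (any(reps < 2))
    stop("factorial ANOVA needs >= 2 replicates per run (residual df would be 0)")
  fit <- rsm_fit(design, response)
  a <- stats::anova(fit$lm)
  effects <- c("x", "y", "I(x^2)", "I(y^2)", "I(x * y)", "Residuals")
  a <- a[effects, ]
  out <- data.frame(effect = c("x", "y", "x2", "y2", "xy", "residual"),
                    ss = a$`Sum Sq`, df = a$Df, ms = a$`Mean Sq`,
                    f = a$`F value`, p = a$`Pr(>F)`)
  structure(out, class = c("rsm_anova", "data.frame"),
            total_ss = sum(a$`Sum Sq`))
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat("Factorial ANOVA (sequential SS)\n")
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 6); df$ms <- signif(df$ms, 6)
  df$f <- signif(df$f, 4); df$p <- signif(df$p, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Screen strains over a factorial design
#'
#' Per-strain summary of a multi-strain screening experiment: the optimum
#' run (highest growth response, ties broken by lowest run id), the lethal
#' runs (zero colony count), and the sign of the correlation between
#' mutagen concentration and colony count.
#'
#' @param design A [factorial_design()].
#' @param responses Data frame with columns `strain`, `run`, `cfu`, `od`
#'   (run means).
#' @return A `screening_summary` list, one element per strain with
#'   `best_run`, `best_od`, `lethal_runs`, `conc_cfu_correlation`.
#' @export
screen_design <- function(design, responses) {
  stopifnot(inherits(design, "factorial_design"),
            all(c("strain", "run", "cfu", "od") %in% names(responses)))
  out <- lapply(split(responses, responses$strain), function(d) {
    d <- d[order(d$run), ]
    best <- d$run[which.max(d$od)]  # which.max takes the first (lowest run) tie
    lethal <- d$run[d$cfu == 0]
    conc <- design$conc_mM[match(d$run, design$run)]
    r <- if (stats::sd(d$cfu) > 0 && stats::sd(conc) > 0)
      stats::cor(conc, d$cfu) else NA_real_
    list(best_run = best, best_od = max(d$od), lethal_runs = lethal,
         conc_cfu_correlation = r)
  })
  structure(out, class = "screening_summary")
}

#' @export
print.screening_summary <- function(x, ...) {
  for (s in names(x)) {
    e <- x[[s]]
    cat(sprintf("%s: best growth at run %d (OD %.2f); lethal runs: %s; cor(conc, CFU) = %.2f\n",
                s, e$best_run, e$best_od,
                if (length(e$lethal_runs)) paste(e$lethal_runs, collapse = ",") else "none",
                e$conc_cfu_correlation))
  }
  invisible(x)
}

#' Compare a fitted surface with published coefficients
#'
#' Tabulates fitted versus published coefficients with absolute differences
#' and a per-coefficient tolerance of two units in the last printed decimal
#' place of the published value. Disagreements are reported in the table,
#' never silently dropped.
#'
#' @param fit An `rsm` object.
#' @param published Numeric vector of six published coefficients `b0..b5`.
#' @return Data frame with columns `term`, `fitted`, `published`, `diff`,
#'   `tolerance`, `within`.
#' @export
rsm_compare <- function(fit, published) {
  stopifnot(inherits(fit, "rsm"), length(published) == 6)
  published <- as.numeric(published)
  decimals <- vapply(published, function(v) {
    s <- sub("0+$", "", sub(".*\\.", "", format(v, scientific = FALSE)))
    if (grepl("\\.", format(v, scientific = FALSE))) nchar(s) else 0L
  }, 1L)
  tol <- 2 * 10^(-decimals)
  d <- abs(fit$coefficients - published)
  data.frame(term = names(fit$coefficients),
             fitted = unname(fit$coefficients), published = published,
             diff = unname(d), tolerance = tol, within = unname(d <= tol))
}
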