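#' Colony-count time series for one mutagen-treated strain
#'
#' Bundles the untreated-control colony count (CFU) and the counts observed
#' after increasing mutagen exposure times for one yeast strain. Counts may
#' be replicate means (real-valued). A structurally missing plate ("no
#' colony on the plate") is encoded as count 0.
#'
#' @param strain Strain identifier.
#' @param control_cfu Untreated-control CFU (> 0; replicate mean allowed).
#' @param times Exposure times in minutes, strictly increasing.
#' @param counts CFU at each exposure time (>= 0), same length as `times`.
#' @param replicate_counts Optional list of per-time replicate vectors.
#' @return A `treatment_series` object.
#' @export
treatment_series <- function(strain, control_cfu, times, counts,
                             replicate_counts = NULL) {
  stopifnot(length(control_cfu) == 1, is.numeric(control_cfu))
  if (!is.finite(control_cfu) || control_cfu <= 0)
    stop("control CFU must be positive")
  times <- as.numeric(times); counts <- as.numeric(counts)
  if (length(times) != length(counts)) stop("'times' and 'counts' lengths differ")
  if (any(diff(times) <= 0)) stop("exposure times must be strictly increasing")
  if (any(counts < 0)) stop("negative CFU")
  structure(list(strain = as.character(strain), control_cfu = control_cfu,
                 times = times, counts = counts,
                 replicate_counts = replicate_counts),
            class = "treatment_series")
}

#' Survival and mortality curve from colony counts
#'
#' Survival at exposure time t is `100 * count(t) / control_cfu` percent;
#' mortality is its complement, so the two sum to exactly 100 at every time.
#' Values are retained at full precision; reporting (printing) rounds to two
#' decimals. Counts above the control give survival > 100 and are flagged
#' rather than rejected.
#'
#' @param series A [treatment_series()].
#' @return A `survival_curve` data frame with columns `time`, `count`,
#'   `survival`, `mortality`, `exceeds_control`.
#' @examples
#' s <- treatment_series("YlTun15", 205, c(15, 30, 45, 60), c(178, 89, 66, 23))
#' survival_curve(s)   # survival 11.22% at 60 min
#' @export
survival_curve <- function(series) {
  stopifnot(inherits(series, "treatment_series"))
  surv <- 100 * series$counts / series$control_cfu
  out <- data.frame(time = series$times, count = series$counts,
                    survival = surv, mortality = 100 - surv,
                    exceeds_control = surv > 100)
  if (any(out$exceeds_control))
    warning("count(s) above control: survival > 100% at t = ",
            paste(out$time[out$exceeds_control], collapse = ", "))
  structure(out, class = c("survival_curve", "data.frame"),
            strain = series$strain)
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival/mortality for", attr(x, "strain"), "(% of untreated control)\n")
  df <- data.frame(time_min = x$time, cfu = x$count,
                   survival = round(x$survival, 2),
                   mortality = round(x$mortality, 2))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Earliest lethal exposure time
#'
#' The earliest observed exposure time at which no colonies formed
#' (CFU = 0), or `NA` if the strain survived all observed exposures.
#'
#' @param series A [treatment_series()].
#' @return Time in minutes, or `NA_real_`.
#' @examples
#' lethal_time(treatment_series("CtTun15", 213, c(15, 30, 45), c(97, 13, 0)))  # 45
#' @export
lethal_time <- function(series) {
  stopifnot(inherits(series, "treatment_series"))
  hit <- which(series$counts == 0)
  if (length(hit) == 0) NA_real_ else series$times[min(hit)]
}

#' Tukey HSD letter grouping of treatment means
#'
#' One-way ANOVA followed by all-pairs Tukey honestly-significant-difference
#' comparisons using the studentized-range distribution, summarized as
#' compact letter display: groups sharing no letter differ at level `alpha`.
#' Letters are assigned scanning groups in descending mean order, merging
#' maximal runs of mutually non-significant groups.
#'
#' Groups with zero pooled within-group variance are grouped by exact mean
#' equality.
#'
#' @param groups Named list of replicate vectors (>= 2 groups, >= 2
#'   replicates each).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return A `tukey_groups` data frame with columns `group`, `mean`, `n`,
#'   `letters`, sorted by descending mean; attribute `p_matrix` carries the
#'   pairwise adjusted p-values.
#' @examples
#' set.seed(1)
#' tukey_groups(list(a = rnorm(6, 0), b = rnorm(6, 0), c = rnorm(6, 100)))
#' @export
tukey_groups <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) stop("each group needs >= 2 replicates (singleton group found)")
  stopifnot(alpha > 0, alpha < 1)
  k <- length(groups)
  means <- vapply(groups, mean, 1)
  df_err <- sum(n) - k
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1)) / df_err

  idx <- order(means, decreasing = TRUE)
  sig <- matrix(FALSE, k, k)  # in sorted order
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- idx[i]; b <- idx[j]
    if (mse <= 0) {
      sig[i, j] <- sig[j, i] <- means[a] != means[b]
    } else {
      q <- abs(means[a] - means[b]) /
        sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
      p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
      sig[i, j] <- sig[j, i] <- p < alpha
    }
  }

  # maximal runs of consecutive (sorted) groups with no internal significance
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[i:(j + 1), i:(j + 1)])) j <- j + 1
    runs[[i]] <- i:j
  }
  keep <- !vapply(seq_along(runs), function(r)
    any(vapply(seq_along(runs), function(s)
      s != r && all(runs[[r]] %in% runs[[s]]), TRUE)), TRUE)
  runs <- runs[keep]
  letters_out <- rep("", k)
  for (r in seq_along(runs))
    letters_out[runs[[r]]] <- paste0(letters_out[runs[[r]]], letters[r])

  pmat <- matrix(NA_real_, k, k, dimnames = list(names(groups)[idx], names(groups)[idx]))
  if (mse > 0)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      a <- idx[i]; b <- idx[j]
      q <- abs(means[a] - means[b]) / sqrt(mse / 2 * (1 / n[a] + 1 / n[b]))
      pmat[i, j] <- pmat[j, i] <-
        stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
    }
  out <- data.frame(group = names(groups)[idx], mean = unname(means[idx]),
                    n = unname(n[idx]), letters = letters_out,
                    stringsAsFactors = FALSE)
  structure(out, class = c("tukey_groups", "data.frame"),
            alpha = alpha, mse = mse, df = df_err, p_matrix = pmat)
}

#' @export
print.tukey_groups <- function(x, ...) {
  cat(sprintf("Tukey HSD letter grouping (alpha = %g, df = %d)\n",
              attr(x, "alpha"), attr(x, "df")))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
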