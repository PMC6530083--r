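# All generators are pure functions of (params, seed): RNG state is saved and
# restored so reruns are bit-identical and the caller's stream is untouched.
.with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) { # numerically degenerate draw; fall back to the mean
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

#' Kill-surface parameters for colony-count simulation
#'
#' Expected colony count over the mutagen dose/volume plane is modeled as
#' `exp(a0 + a1 x + a2 x^2 + a3 y + a4 y^2 + a5 xy)` CFU with Poisson
#' replicate noise (the minimal noise model for plate counts). `n0 =
#' exp(a0)` is the expected zero-dose count.
#'
#' @param coef Numeric vector `a0..a5` of log-scale surface coefficients for
#'   `a0 + a1 x + a2 x^2 + a3 y + a4 y^2 + a5 xy` (x concentration mM,
#'   y volume ul).
#' @param k Per-minute exponential decay rate used by the survival-series
#'   generator (default 0).
#' @param n0 Expected untreated-control CFU; defaults to the zero-dose
#'   surface value `exp(a0)`.
#' @return A `kill_surface_params` list.
#' @export
kill_surface_params <- function(coef, k = 0, n0 = exp(coef[1])) {
  coef <- as.numeric(coef)
  stopifnot(length(coef) == 6, all(is.finite(coef)), k >= 0, n0 > 0)
  structure(list(coef = coef, n0 = n0, k = k),
            class = "kill_surface_params")
}

#' Strain-named simulation presets
#'
#' Default generator settings named after the study's five strains,
#' reproducing the magnitudes of the screening data: the log-quadratic
#' kill surface is the OLS fit of `log(CFU + 1)` to that strain's design
#' responses, the zero-dose expectation is the strain's untreated-control
#' plate count (205-311 CFU), and the survival decay rate `k` is set so the
#' expected 60-min survival equals the strain's observed rate.
#'
#' @param strain One of `"YlTun15"`, `"RmTun15"`, `"TaTun15"`,
#'   `"DhTun2015"`, `"CtTun15"`.
#' @return A [kill_surface_params()] object.
#' @export
kill_surface_preset <- function(strain = c("YlTun15", "RmTun15", "TaTun15",
                                           "DhTun2015", "CtTun15")) {
  strain <- match.arg(strain)
  fx <- load_study_fixtures()
  d <- fx$design_responses[fx$design_responses$strain == strain, ]
  design <- factorial_design()
  x <- design$conc_mM[match(d$run, design$run)]
  y <- design$vol_ul[match(d$run, design$run)]
  X <- .quad_model_matrix(x, y)
  a <- qr.solve(X, log(d$cfu + 1))
  ctl <- fx$colony_counts
  n0 <- ctl$cfu_mean[ctl$strain == strain & ctl$time_min == 0]
  sc <- survival_curve(study_treatment_series(strain))
  # decay rate from the latest exposure that still yielded colonies
  alive <- sc[sc$survival > 0, ]
  last <- alive[which.max(alive$time), ]
  k <- -log(last$survival / 100) / last$time
  kill_surface_params(a, k = k, n0 = n0)
}

#' Simulate replicate colony counts over a factorial design
#'
#' Draws `replicates` Poisson counts per design run with mean
#' `exp(quadratic(x, y))` from the kill surface. Deterministic for a given
#' seed. The expected counts are recorded as attribute `truth` along with
#' the population OLS coefficients (the projection of the expected counts
#' onto the quadratic model space), the estimand of a surface refit.
#'
#' @param params A [kill_surface_params()].
#' @param design A [factorial_design()].
#' @param replicates Replicates per run.
#' @param seed Integer seed.
#' @return Data frame with columns `run`, `rep`, `value`; attribute `truth`.
#' @export
simulate_design_responses <- function(params, design, replicates = 3, seed) {
  stopifnot(inherits(params, "kill_surface_params"),
            inherits(design, "factorial_design"), replicates >= 1)
  mu <- exp(.quad_model_matrix(design$conc_mM, design$vol_ul) %*% params$coef)[, 1]
  out <- .with_seed(seed, {
    data.frame(run = rep(design$run, each = replicates),
               rep = rep(seq_len(replicates), nrow(design)),
               value = stats::rpois(nrow(design) * replicates,
                                    rep(mu, each = replicates)))
  })
  X <- .quad_model_matrix(design$conc_mM, design$vol_ul)
  beta_star <- qr.solve(X, mu)
  names(beta_star) <- c("b0", "b1", "b2", "b3", "b4", "b5")
  structure(out, truth = list(expected = mu, ols_target = beta_star,
                              params = params, seed = seed))
}

#' Survival-series simulation parameters
#'
#' @param n0 Expected untreated-control CFU (> 0).
#' @param k Per-minute decay rate (>= 0).
#' @param dose_effect Multiplier on `k` for the applied dose (default 1).
#' @return A `survival_sim_params` list.
#' @export
survival_sim_params <- function(n0, k, dose_effect = 1) {
  stopifnot(n0 > 0, k >= 0, dose_effect >= 0)
  structure(list(n0 = n0, k = k, dose_effect = dose_effect),
            class = "survival_sim_params")
}

#' Simulate a mutagen-exposure survival series
#'
#' Counts decay exponentially in exposure time, `E[count(t)] = n0 *
#' exp(-k * dose_effect * t)`, with Poisson noise on each plate; the control
#' plate is drawn as Poisson(n0) but the series' recorded control is the
#' expectation `n0`, so survival estimates are unbiased. Expected counts and
#' survival percentages are recorded as attribute `truth`.
#'
#' @param params A [survival_sim_params()] (a [kill_surface_params()] is
#'   accepted: its `n0` and `k` are used).
#' @param times Exposure times (min), strictly increasing.
#' @param seed Integer seed.
#' @param strain Strain id for the series.
#' @return A [treatment_series()] with attribute `truth`.
#' @export
simulate_survival_series <- function(params, times = c(15, 30, 45, 60), seed,
                                     strain = "sim") {
  if (inherits(params, "kill_surface_params"))
    params <- survival_sim_params(params$n0, params$k)
  stopifnot(inherits(params, "survival_sim_params"), all(diff(times) > 0))
  mu <- params$n0 * exp(-params$k * params$dose_effect * times)
  counts <- .with_seed(seed, stats::rpois(length(times), mu))
  s <- treatment_series(strain, params$n0, times, counts)
  attr(s, "truth") <- list(expected_counts = mu,
                           expected_survival = 100 * mu / params$n0,
                           params = params, seed = seed)
  s
}

#' Logistic growth-curve parameters
#'
#' @param K Carrying capacity, OD600 units (> 0).
#' @param r Growth rate, 1/h (> 0).
#' @param t_m Inflection (midpoint) time, h.
#' @param sigma Gaussian observation SD, OD600 units (>= 0).
#' @return A `growth_params` list.
#' @export
growth_params <- function(K = 24, r = 0.08, t_m = 60, sigma = 0.5) {
  stopifnot(K > 0, r > 0, sigma >= 0)
  structure(list(K = K, r = r, t_m = t_m, sigma = sigma),
            class = "growth_params")
}

#' Simulate an OD600 growth curve
#'
#' Logistic mean `K / (1 + exp(-r (t - t_m)))` with additive Gaussian noise,
#' truncated at zero (optical densities are non-negative).
#'
#' @param params A [growth_params()].
#' @param times Observation times, h.
#' @param seed Integer seed.
#' @return Data frame `time`, `od600`; attribute `truth` with the noise-free
#'   curve.
#' @export
simulate_growth_curve <- function(params, times = seq(0, 144, by = 24), seed) {
  stopifnot(inherits(params, "growth_params"))
  mu <- params$K / (1 + exp(-params$r * (times - params$t_m)))
  od <- .with_seed(seed, pmax(0, stats::rnorm(length(times), mu, params$sigma)))
  structure(data.frame(time = times, od600 = od),
            truth = list(expected = mu, params = params, seed = seed))
}

#' FAME-profile simulation parameters
#'
#' Compositions are drawn hierarchically: class shares (SFA/MUFA/PUFA) from
#' a Dirichlet centred on the class targets with concentration
#' `dispersion`, then acids within each class from a Dirichlet over the
#' class members. Larger `dispersion` concentrates draws at the target
#' composition.
#'
#' @param acids Character vector of fatty-acid labels.
#' @param class_targets Named numeric `c(sfa=, mufa=, pufa=)` summing to 100.
#' @param dispersion Dirichlet concentration parameter (> 0), default 200.
#' @param within Optional named weights over `acids` (default equal within
#'   class).
#' @return A `fame_sim_params` list.
#' @export
fame_sim_params <- function(acids = c("C14:0", "C15:0", "C16:0", "C18:0",
                                      "C16:1", "C18:1", "C16:2", "C18:2",
                                      "C18:3", "C20:4", "C20:5", "C22:6"),
                            class_targets = c(sfa = 35, mufa = 30, pufa = 35),
                            dispersion = 200, within = NULL) {
  stopifnot(all(c("sfa", "mufa", "pufa") %in% names(class_targets)),
            dispersion > 0)
  if (abs(sum(class_targets) - 100) > 1e-9)
    stop("class targets must sum to 100")
  fa <- fatty_acid(acids)
  cls <- ifelse(fa$double_bonds == 0L, "sfa",
                ifelse(fa$double_bonds == 1L, "mufa", "pufa"))
  present <- unique(cls)
  missing_cls <- setdiff(names(class_targets)[class_targets > 0], present)
  if (length(missing_cls))
    stop("no acid available for class(es) with positive target: ",
         paste(missing_cls, collapse = ", "))
  if (is.null(within)) within <- stats::setNames(rep(1, nrow(fa)), fa$label)
  structure(list(acids = fa, class = cls,
                 class_targets = class_targets[c("sfa", "mufa", "pufa")],
                 dispersion = dispersion, within = within),
            class = "fame_sim_params")
}

#' Simulate a FAME composition
#'
#' @param params A [fame_sim_params()].
#' @param seed Integer seed.
#' @return A normalized [fame_profile()]; attribute `truth` records the
#'   target composition.
#' @export
simulate_fame_profile <- function(params, seed) {
  stopifnot(inherits(params, "fame_sim_params"))
  tg <- params$class_targets
  prof <- .with_seed(seed, {
    shares <- stats::setNames(numeric(3), names(tg))
    pos <- tg > 0
    shares[pos] <- .rdirichlet1(params$dispersion * tg[pos] / 100)
    pct <- stats::setNames(numeric(nrow(params$acids)), params$acids$label)
    for (cl in names(tg)[pos]) {
      members <- which(params$class == cl)
      w <- params$within[params$acids$label[members]]
      alpha <- params$dispersion * (w / sum(w)) * unname(tg[cl]) / 100
      pct[members] <- 100 * shares[cl] * .rdirichlet1(alpha)
    }
    pct
  })
  p <- fame_profile(prof)  # zero entries retained
  target <- stats::setNames(numeric(nrow(params$acids)), params$acids$label)
  for (cl in names(tg)) {
    members <- which(params$class == cl)
    w <- params$within[params$acids$label[members]]
    target[members] <- unname(tg[cl]) * w / sum(w)
  }
  attr(p, "truth") <- list(class_targets = tg, target = target, seed = seed)
  p
}

#' Generate a complete synthetic screening study
#'
#' Bundles, for five synthetic strains patterned on the study's presets:
#' factorial design colony responses, survival time series, growth curves,
#' FAME profiles and lipid measurements, each with recorded ground truth,
#' so every downstream analysis (surface fitting, survival statistics,
#' productivity metrics, fuel reports) can be exercised end to end with
#' known answers.
#'
#' @param seed Integer seed; sub-seeds are derived deterministically.
#' @return A `synthetic_study` list with elements `design`,
#'   `design_responses`, `survival`, `growth`, `profiles`, `lipid`, `truth`.
#' @export
make_study_fixture <- function(seed) {
  strains <- c("YlTun15", "RmTun15", "TaTun15", "DhTun2015", "CtTun15")
  design <- factorial_design()
  class_targets <- list(  # class structure spanning the observed range
    YlTun15 = c(sfa = 22, mufa = 43, pufa = 35),
    RmTun15 = c(sfa = 38, mufa = 17, pufa = 45),
    TaTun15 = c(sfa = 27, mufa = 46, pufa = 27),
    DhTun2015 = c(sfa = 66, mufa = 15, pufa = 19),
    CtTun15 = c(sfa = 33, mufa = 9, pufa = 58))
  lipid_yield <- c(YlTun15 = 10.3, RmTun15 = 8.2, TaTun15 = 3.7,
                   DhTun2015 = 2.3, CtTun15 = 2.5)  # g / 100 g wet biomass
  growth <- list()
  responses <- list(); survival <- list(); profiles <- list(); lipid <- list()
  truth <- list()
  for (i in seq_along(strains)) {
    s <- strains[i]
    sub <- as.integer(seed %% 100000L) * 10L + i
    ks <- kill_surface_preset(s)
    responses[[s]] <- simulate_design_responses(ks, design, replicates = 3,
                                                seed = sub)
    survival[[s]] <- simulate_survival_series(ks, seed = sub + 1L, strain = s)
    gp <- growth_params(K = c(24.1, 24.4, 27.4, 21.9, 28.2)[i],
                        r = 0.07, t_m = 55, sigma = 0.5)
    growth[[s]] <- simulate_growth_curve(gp, seed = sub + 2L)
    fp <- fame_sim_params(class_targets = class_targets[[s]])
    profiles[[s]] <- simulate_fame_profile(fp, seed = sub + 3L)
    wb <- 1.0
    dl <- .with_seed(sub + 4L,
                     max(0.01, stats::rnorm(1, lipid_yield[[s]] / 100, 0.02)))
    lipid[[s]] <- list(wb = wb, w1 = 10 + dl, w2 = 10,
                       biomass_mass = wb * 0.25)
    truth[[s]] <- list(kill_surface = ks, growth = gp,
                       class_targets = class_targets[[s]],
                       lipid_yield = 100 * dl / wb)
  }
  structure(list(design = design, design_responses = responses,
                 survival = survival, growth = growth, profiles = profiles,
                 lipid = lipid, truth = truth, seed = seed),
            class = "synthetic_study")
}
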