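test_that("generators are pure functions of (params, seed)", {
  d <- factorial_design()
  p <- kill_surface_params(c(log(250), 0.01, -2e-4, -0.01, 5e-5, -1e-5), k = 0.03)
  a <- simulate_design_responses(p, d, 3, seed = 99)
  b <- simulate_design_responses(p, d, 3, seed = 99)
  expect_identical(a$value, b$value)
  c2 <- simulate_design_responses(p, d, 3, seed = 100)
  expect_false(identical(a$value, c2$value))

  # caller's RNG stream untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(simulate_design_responses(p, d, 3, seed = 1))
  expect_identical(rnorm(1), before)

  s1 <- simulate_survival_series(survival_sim_params(205, 0.036), seed = 5)
  s2 <- simulate_survival_series(survival_sim_params(205, 0.036), seed = 5)
  expect_identical(s1$counts, s2$counts)
  f1 <- simulate_fame_profile(fame_sim_params(), seed = 5)
  f2 <- simulate_fame_profile(fame_sim_params(), seed = 5)
  expect_identical(f1$percent, f2$percent)
})

test_that("flat kill surface reproduces its Poisson zero-dose mean", {
  d <- factorial_design()
  n0 <- 250
  p <- kill_surface_params(c(log(n0), 0, 0, 0, 0, 0))
  R <- 200
  sim <- simulate_design_responses(p, d, replicates = R, seed = 61)
  expect_equal(mean(sim$value), n0, tolerance = 3 * sqrt(n0 / (R * 9)) / n0)
  # Poisson dispersion: variance on the scale of the mean
  expect_equal(stats::var(sim$value) / mean(sim$value), 1, tolerance = 0.15)
})

test_that("lethal surfaces yield all-zero runs detected by screening", {
  d <- factorial_design()
  p <- kill_surface_params(c(-20, 0, 0, 0, 0, 0))
  sim <- simulate_design_responses(p, d, 3, seed = 62)
  expect_true(all(sim$value == 0))
  means <- tapply(sim$value, sim$run, mean)[as.character(d$run)]
  scr <- screen_design(d, data.frame(strain = "s", run = d$run,
                                     cfu = as.numeric(means), od = 1))
  expect_equal(scr$s$lethal_runs, d$run)
})

test_that("survival series follow their closed-form expectation", {
  # no kill: survival ~ 100% at all times
  s0 <- simulate_survival_series(survival_sim_params(300, 0), seed = 63)
  sc0 <- suppressWarnings(survival_curve(s0))  # Poisson noise can exceed n0
  expect_true(all(abs(sc0$survival - 100) < 20))
  expect_equal(attr(s0, "truth")$expected_survival, rep(100, 4))

  # overwhelming kill: lethal from the first exposure
  sk <- simulate_survival_series(survival_sim_params(300, 5), seed = 64)
  expect_equal(lethal_time(sk), 15)

  # preset tuned to the observed 60-min survival: empirical mean over many
  # seeds within 3 Poisson standard errors of the expectation
  p <- kill_surface_preset("YlTun15")
  expect_equal(round(100 * exp(-p$k * 60), 2), 11.22)
  n <- 300
  surv60 <- vapply(seq_len(n), function(s) {
    ser <- simulate_survival_series(p, seed = 1000 + s)
    survival_curve(ser)$survival[4]
  }, 1)
  mu <- p$n0 * exp(-p$k * 60)
  se <- 100 * sqrt(mu / n) / p$n0
  expect_lt(abs(mean(surv60) - 100 * mu / p$n0), 3 * se)
})

test_that("simulated FAME compositions close to 100 and hit class targets", {
  prm <- fame_sim_params(class_targets = c(sfa = 30, mufa = 45, pufa = 25),
                         dispersion = 200)
  for (s in 1:20)
    expect_equal(sum(simulate_fame_profile(prm, seed = s)$percent), 100,
                 tolerance = 1e-9)

  draws <- vapply(1:1000, function(s) {
    cf <- class_fractions(simulate_fame_profile(prm, seed = s))
    c(cf$sfa, cf$mufa, cf$pufa)
  }, numeric(3))
  expect_equal(rowMeans(draws), c(30, 45, 25), tolerance = 1 / 25)

  # dispersion -> infinity concentrates at the target composition
  tight <- fame_sim_params(class_targets = c(sfa = 30, mufa = 45, pufa = 25),
                           dispersion = 1e7)
  cf <- class_fractions(simulate_fame_profile(tight, seed = 3))
  expect_equal(c(cf$sfa, cf$mufa, cf$pufa), c(30, 45, 25), tolerance = 0.02)

  expect_error(fame_sim_params(class_targets = c(sfa = 50, mufa = 50, pufa = 10)),
               "sum to 100")
})

test_that("generated values respect their type invariants", {
  set.seed(65)
  for (i in 1:40) {
    prm <- fame_sim_params(class_targets = {
      t3 <- .rd <- stats::runif(3, 0.05, 1); t3 <- 100 * t3 / sum(t3)
      names(t3) <- c("sfa", "mufa", "pufa"); t3
    }, dispersion = stats::runif(1, 10, 500))
    p <- simulate_fame_profile(prm, seed = i)
    expect_true(all(p$percent >= 0))
    expect_true(is_normalized(p))
    s <- simulate_survival_series(survival_sim_params(runif(1, 50, 400),
                                                      runif(1, 0, 0.1)),
                                  seed = i)
    expect_true(all(s$counts >= 0))
    g <- simulate_growth_curve(growth_params(K = runif(1, 15, 30)), seed = i)
    expect_true(all(g$od600 >= 0))
  }
})

test_that("a full synthetic study supports the whole pipeline", {
  st <- make_study_fixture(seed = 424242)
  expect_identical(names(st$design_responses),
                   c("YlTun15", "RmTun15", "TaTun15", "DhTun2015", "CtTun15"))
  # bit-identical rerun
  st2 <- make_study_fixture(seed = 424242)
  expect_identical(st$design_responses$YlTun15$value,
                   st2$design_responses$YlTun15$value)

  d <- st$design
  for (s in names(st$design_responses)) {
    sim <- st$design_responses[[s]]
    fit <- rsm_fit(d, sim, name = s)
    expect_true(all(is.finite(coef(fit))))
    # recovery: fitted coefficients within 3 SE of the OLS target
    tr <- attr(sim, "truth")$ols_target
    se <- sqrt(diag(stats::vcov(fit$lm)))[c("(Intercept)", "x", "I(x^2)",
                                            "y", "I(y^2)", "I(x * y)")]
    expect_true(mean(abs(coef(fit) - tr) <= 3 * se) >= 5 / 6)

    sc <- survival_curve(st$survival[[s]])
    expect_equal(sc$survival + sc$mortality, rep(100, nrow(sc)))

    rep_ <- fuel_report(st$profiles[[s]])
    fin <- unlist(rep_[c("sv", "iv", "cn", "du", "lcsf", "hhv", "cfpp",
                         "ln_kv", "kv", "density")])
    expect_true(all(is.finite(fin)))

    lm_ <- st$lipid[[s]]
    met <- lipid_metrics(lm_$w1, lm_$w2, lm_$wb, biomass_mass = lm_$biomass_mass)
    expect_equal(met$yield, st$truth[[s]]$lipid_yield, tolerance = 1e-9)
  }
})
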