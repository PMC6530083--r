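test_that("factorial design is the full cross with study run ordering", {
  d <- factorial_design()
  expect_equal(nrow(d), 9)
  expect_equal(nrow(unique(d[, c("conc_mM", "vol_ul")])), 9)
  # run ids line up with the published experiment numbering
  expect_equal(unlist(d[d$run == 1, c("conc_mM", "vol_ul")]),
               c(conc_mM = 75, vol_ul = 100))
  expect_equal(unlist(d[d$run == 2, c("conc_mM", "vol_ul")]),
               c(conc_mM = 100, vol_ul = 50))
  expect_equal(unlist(d[d$run == 9, c("conc_mM", "vol_ul")]),
               c(conc_mM = 75, vol_ul = 50))

  expect_equal(nrow(factorial_design(c(1, 2), c(3, 4))), 4)
  expect_error(factorial_design(c(25, 25), c(15, 50)), "duplicate")
  expect_error(factorial_design(25, c(15, 50, 100)), "two distinct levels")
})

test_that("noise-free quadratic data is interpolated to 1e-8", {
  d <- factorial_design()
  b <- c(1, 2, -0.1, 3, -0.05, 0.01)
  z <- rsm_predict_coef(b, d$conc_mM, d$vol_ul)
  fit <- rsm_fit(d, as.numeric(z))
  expect_equal(unname(coef(fit)), b, tolerance = 1e-8)
  # refit on own noise-free predictions returns the same coefficients
  z2 <- predict(fit, d$conc_mM, d$vol_ul)
  fit2 <- rsm_fit(d, as.numeric(z2))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
})

test_that("OLS matches an explicit normal-equations oracle", {
  set.seed(41)
  d <- factorial_design()
  z <- rnorm(9, 100, 30)
  fit <- rsm_fit(d, z)
  X <- cbind(1, d$conc_mM, d$conc_mM^2, d$vol_ul, d$vol_ul^2,
             d$conc_mM * d$vol_ul)
  oracle <- solve(t(X) %*% X, t(X) %*% z)[, 1]
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8)
  # residual orthogonality to every design column
  r <- residuals(fit)
  for (j in 1:6)
    expect_lt(abs(sum(r * X[, j])),
              1e-8 * sqrt(sum(X[, j]^2)) * sqrt(sum(r^2)) + 1e-10)
})

test_that("fit on replicates equals fit on run means for balanced data", {
  set.seed(42)
  d <- factorial_design()
  reps <- data.frame(run = rep(d$run, each = 3),
                     value = rnorm(27, rep(seq(20, 180, length.out = 9), each = 3), 10))
  means <- tapply(reps$value, reps$run, mean)[as.character(d$run)]
  expect_equal(coef(rsm_fit(d, reps)), coef(rsm_fit(d, as.numeric(means))),
               tolerance = 1e-12)
})

test_that("surface prediction evaluates the published-style polynomial", {
  b_yl_cell <- c(206.885, 1.181, -0.021, -1.874, 0.005, -0.005)
  # hand evaluation: 206.885 + 88.575 - 118.125 - 93.7 + 12.5 - 18.75
  expect_equal(as.numeric(rsm_predict_coef(b_yl_cell, 75, 50)), 77.385,
               tolerance = 1e-9)
  expect_equal(as.numeric(rsm_predict_coef(rep(0, 6), 13, 7)), 0)
  neg <- rsm_predict_coef(c(-5, 0, 0, 0, 0, 0), 1, 1)
  expect_true(attr(neg, "negative"))
})

test_that("refit on the transcribed run means is reported against the published equation", {
  # clean (unambiguous) column: YlTun15 colony counts
  d <- factorial_design()
  fit <- rsm_fit(d, fixture_run_means("YlTun15", "cfu"), name = "colonies")
  cmp <- rsm_compare(fit, c(206.885, 1.181, -0.021, -1.874, 0.005, -0.005))
  expect_equal(nrow(cmp), 6)
  expect_true(all(is.finite(cmp$diff)))
  # curvature terms agree within two units of the last printed decimal
  expect_true(all(cmp$within[cmp$term %in% c("b2", "b4")]))
  # disagreements elsewhere are reported, not dropped
  expect_true(all(c("fitted", "published", "diff", "within") %in% names(cmp)))
})

test_that("sequential ANOVA matches a brute-force projection oracle", {
  set.seed(43)
  d <- factorial_design()
  reps <- data.frame(run = rep(d$run, each = 3),
                     value = rnorm(27, rep(c(10, 40, 90, 60, 20, 80, 30, 70, 50),
                                           each = 3), 5))
  a <- factorial_anova(d, reps)

  # oracle: SS from explicit successive orthogonal projections
  i <- match(reps$run, d$run)
  x <- d$conc_mM[i]; y <- d$vol_ul[i]; z <- reps$value
  cols <- list(rep(1, 27), x, y, x^2, y^2, x * y)  # sequential term order
  ss_seq <- numeric(5)
  for (k in 2:6) {
    Xk1 <- do.call(cbind, cols[1:(k - 1)])
    Xk <- do.call(cbind, cols[1:k])
    rss <- function(X) sum(stats::lsfit(X, z, intercept = FALSE)$residuals^2)
    ss_seq[k - 1] <- rss(Xk1) - rss(Xk)
  }
  expect_equal(a$ss[1:5], ss_seq[c(1, 2, 3, 4, 5)], tolerance = 1e-8)
  # decomposition: effect SS + residual SS = total SS
  expect_equal(sum(a$ss), sum((z - mean(z))^2), tolerance = 1e-8)
  expect_equal(sum(a$df), 26)
  # total SS invariant under run reordering
  perm <- sample(nrow(reps))
  a2 <- factorial_anova(d, reps[perm, ])
  expect_equal(sum(a2$ss), sum(a$ss), tolerance = 1e-8)
})

test_that("ANOVA degenerate and strong-effect behavior", {
  d <- factorial_design()
  const <- data.frame(run = rep(d$run, each = 2), value = 7)
  # constant response: F-tests are vacuous (0/0), only the SS matter here
  a <- suppressWarnings(factorial_anova(d, const))
  expect_equal(a$ss[1:5], rep(0, 5), tolerance = 1e-10)

  expect_error(factorial_anova(d, data.frame(run = d$run, value = rnorm(9))),
               "replicates")

  set.seed(44)
  # strong concentration effect, 3 replicates: p far below 1e-4
  mu <- 10 * d$conc_mM
  reps <- data.frame(run = rep(d$run, each = 3),
                     value = rnorm(27, rep(mu, each = 3), 1))
  a2 <- factorial_anova(d, reps)
  expect_lt(a2$p[a2$effect == "x"], 1e-4)
})

test_that("coefficients are recovered within 3 SE under Gaussian noise", {
  set.seed(45)
  d <- factorial_design()
  b <- c(200, 1.2, -0.02, -1.9, 0.005, -0.005)
  mu <- as.numeric(rsm_predict_coef(b, d$conc_mM, d$vol_ul))
  hits <- 0L; total <- 0L
  for (r in 1:1000) {
    reps <- data.frame(run = rep(d$run, each = 3),
                       value = rnorm(27, rep(mu, each = 3), 8))
    fit <- rsm_fit(d, reps)
    se <- sqrt(diag(stats::vcov(fit$lm)))[c("(Intercept)", "x", "I(x^2)",
                                            "y", "I(y^2)", "I(x * y)")]
    hits <- hits + sum(abs(coef(fit) - b) <= 3 * se)
    total <- total + 6L
  }
  expect_gte(hits / total, 0.99)
})

test_that("design screening finds optima, lethal runs and dose correlation", {
  fx <- load_study_fixtures()
  scr <- screen_design(factorial_design(), fx$design_responses)
  expect_equal(scr$RmTun15$best_run, 9)
  expect_equal(scr$CtTun15$lethal_runs, c(1, 2, 5))
  expect_lt(scr$YlTun15$conc_cfu_correlation, 0)

  flat <- data.frame(strain = "s", run = 1:9, cfu = 10, od = 5)
  expect_equal(screen_design(factorial_design(), flat)$s$best_run, 1)
})
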