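test_that("intercept-only symmetric data fits probability one half", {
  d <- data.frame(y = c(1, 0, 1, 0))
  f <- svy_logit(y ~ 1, srs_design(d))
  expect_equal(unname(coef(f)), 0, tolerance = 1e-10)
  expect_equal(unique(round(f$fitted, 10)), 0.5)
})

test_that("equal weights reproduce the classical MLE", {
  set.seed(31)
  n <- 400
  d <- data.frame(x1 = rnorm(n),
                  x2 = factor(sample(c("a", "b", "c"), n, TRUE)))
  d$y <- rbinom(n, 1, plogis(-0.4 + 0.9 * d$x1 + 0.6 * (d$x2 == "b")))
  f <- svy_logit(y ~ x1 + x2, srs_design(d))
  g <- stats::glm(y ~ x1 + x2, data = d, family = binomial)
  expect_lt(max(abs(coef(f) - coef(g))), 1e-6)
  expect_equal(AIC(f), AIC(g), tolerance = 1e-6)
})

test_that("coefficients, sandwich SEs and AIC are weight-scale invariant", {
  set.seed(37)
  n <- 200
  d <- data.frame(x = rnorm(n), cl = rep(1:20, each = 10))
  d$y <- rbinom(n, 1, plogis(0.5 * d$x))
  w <- runif(n, 1, 5)
  f1 <- svy_logit(y ~ x, svy_design(d, "cl", weights = w))
  f2 <- svy_logit(y ~ x, svy_design(d, "cl", weights = w * 1000))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-9)
  expect_equal(AIC(f1), AIC(f2), tolerance = 1e-9)
})

test_that("sandwich covariance is symmetric PSD and CIs contain the OR", {
  set.seed(43)
  pop <- small_population()
  s <- draw_svy_sample(pop, 4, 20, seed = 2)
  s$anc4n <- as.numeric(s$anc_visits == "4+")
  des <- svy_design(s, "cluster_id", "stratum_id", "weight")
  f <- svy_logit(SBA ~ wealth_c + anc4n + urban, des)
  V <- vcov(f)
  expect_equal(V, t(V), tolerance = 1e-12)
  expect_true(all(eigen(V, only.values = TRUE)$values > -1e-12))
  tab <- or_table(f)
  num <- tab[!is.na(tab$or), ]
  expect_true(all(num$ci_low < num$or & num$or < num$ci_high))
  expect_true(all(num$or > 0))
})

test_that("a single fit recovers the generating coefficients", {
  pop <- cached("recovery_pop", generate_population(
    sim_config(clusters_per_stratum = 20, households_per_cluster = 55,
               seed = 301)))
  s <- draw_svy_sample(pop, 8, 39, seed = 302)
  des <- svy_design(s, "cluster_id", "stratum_id", "weight")
  f <- svy_logit(SBA ~ wealth_c + educ_c + anc4 + planned + urban + radio +
                   working, des)
  truth <- pop$truth$component_coefficients$SBA
  se <- sqrt(diag(vcov(f)))
  z <- (coef(f) - truth[names(coef(f))]) / se
  expect_true(all(abs(z) < 3))
})

test_that("backward stepwise drops noise, never increases AIC, is deterministic", {
  set.seed(47)
  n <- 800
  d <- data.frame(x = rnorm(n), noise = factor(sample(letters[1:3], n, TRUE)),
                  z = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.2 + 0.8 * d$x))
  des <- srs_design(d)
  full <- svy_logit(y ~ x + noise + z, des)
  sel <- step_aic(full)
  expect_true(all(diff(sel$trail$aic) < 0))
  expect_lte(sel$trail$aic[nrow(sel$trail)], full$aic)
  expect_gte(nrow(sel$trail), 2)  # at least one null term removed
  expect_true("x" %in% attr(stats::terms(sel$formula), "term.labels"))
  # whole factor block dropped at once: no "noiseb"-style term labels
  expect_false(any(grepl("noise[a-z]", sel$trail$dropped)))
  sel2 <- step_aic(full)
  expect_identical(sel$trail, sel2$trail)
  expect_identical(deparse(sel$formula), deparse(sel2$formula))
  # locked terms are never dropped
  sel3 <- step_aic(full, locked = c("noise"))
  expect_false("noise" %in% sel3$trail$dropped)
})

test_that("all-null predictors can reduce to the intercept-only model", {
  set.seed(53)
  n <- 600
  d <- data.frame(a = rnorm(n), b = factor(sample(c("u", "v"), n, TRUE)))
  d$y <- rbinom(n, 1, 0.4)
  sel <- step_aic(svy_logit(y ~ a + b, srs_design(d)))
  expect_true(all(diff(sel$trail$aic) < 0))
  expect_lte(length(attr(stats::terms(sel$formula), "term.labels")), 2)
})

test_that("Hosmer-Lemeshow groups balance weight and vanish for a saturated fit", {
  set.seed(59)
  n <- 100
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(d$x))
  f <- svy_logit(y ~ x, srs_design(d))
  hl <- hosmer_lemeshow(f, g = 10)
  expect_equal(hl$df, 8)
  expect_true(max(hl$groups$w) - min(hl$groups$w) <= 1)
  expect_equal(sum(hl$groups$w), n)
  # grouped-data model reproduced exactly: statistic ~ 0
  d2 <- data.frame(g = factor(rep(letters[1:5], each = 60)))
  d2$y <- rbinom(300, 1, c(0.1, 0.3, 0.5, 0.7, 0.9)[as.integer(d2$g)])
  f2 <- svy_logit(y ~ g, srs_design(d2))
  expect_warning(hl2 <- hosmer_lemeshow(f2, g = 10), "distinct fitted")
  expect_lt(hl2$statistic, 1e-8)
})

test_that("odds-ratio table renders reference rows as em-dashes", {
  set.seed(61)
  n <- 500
  d <- data.frame(wealth = factor(sample(c("Richest", "Middle", "Poorest"),
                                         n, TRUE),
                                  levels = c("Richest", "Middle", "Poorest")),
                  x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.5 * (d$wealth == "Poorest") + 0.4 * d$x))
  f <- svy_logit(y ~ wealth + x, srs_design(d))
  tab <- or_table(f, decimals = 2)
  ref <- tab[tab$level == "Richest", ]
  expect_identical(ref$OR, "—")
  expect_identical(ref$CI95, "—")
  expect_true(is.na(ref$or))
  expect_equal(nrow(tab[tab$variable == "wealth", ]), 3)
  expect_equal(nrow(tab[tab$variable == "x", ]), 1)
})

test_that("prediction works on new data including unseen rows", {
  set.seed(67)
  d <- data.frame(x = rnorm(100))
  d$y <- rbinom(100, 1, plogis(d$x))
  f <- svy_logit(y ~ x, srs_design(d))
  nd <- data.frame(x = c(-1, 0, 1))
  pr <- predict(f, nd, type = "response")
  expect_true(all(diff(pr) > 0))
  expect_equal(predict(f, nd, type = "link"),
               stats::qlogis(pr), tolerance = 1e-10)
})
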