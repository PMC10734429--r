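test_that("day standardization round-trips and centres correctly", {
  x <- c(121, 131, 141, 151)
  st <- standardize_day(x)
  expect_equal(mean(st$z), 0)
  expect_equal(sd(st$z), 1)
  expect_equal(st$z, -rev(st$z))  # symmetric input -> antisymmetric z
  expect_equal(unstandardize_day(st$z, st), x)
  expect_error(standardize_day(rep(130, 5)), "constant")
})

test_that("fit_lmm collapses to OLS when bird effects are absent", {
  ## antisymmetric within-bird residuals force the bird variance to its
  ## zero boundary, where GLS is exactly OLS
  set.seed(37)
  n_b <- 30
  d <- data.frame(bird_id = rep(sprintf("b%02d", 1:n_b), each = 2),
                  x = rnorm(2 * n_b))
  eps <- as.vector(rbind(e <- abs(rnorm(n_b, 0, 0.5)), -e))
  d$y <- 2 + 3 * d$x + eps
  fit <- fit_lmm(y ~ x, d, group = "bird_id", method = "ML")
  ols <- lm(y ~ x, d)
  expect_equal(fit$sigma2_u, 0)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("balanced one-way design matches closed-form ANOVA estimators", {
  set.seed(41)
  g <- 12; r <- 4
  bird <- rep(sprintf("b%02d", 1:g), each = r)
  u <- rnorm(g, 0, 1.5)
  y <- 5 + u[as.integer(factor(bird))] + rnorm(g * r, 0, 0.8)
  d <- data.frame(bird_id = bird, y = y)
  fit <- fit_lmm(y ~ 1, d, group = "bird_id", method = "REML")
  ## textbook method-of-moments = REML for balanced one-way designs
  msb <- anova(lm(y ~ bird))["bird", "Mean Sq"]
  mse <- anova(lm(y ~ bird))["Residuals", "Mean Sq"]
  expect_equal(fit$sigma2_e, mse, tolerance = 1e-5)
  expect_equal(fit$sigma2_u, (msb - mse) / r, tolerance = 1e-5)
  expect_equal(unname(fit$beta), mean(y), tolerance = 1e-8)
})

test_that("fit_lmm reproduces lme4 likelihoods, coefficients and SEs", {
  skip_if_not_installed("lme4")
  d <- simulate_lmm_data(50, seed = 43)
  f <- api ~ phenotype + sex + zday + I(zday^2) + phenotype:zday
  for (method in c("ML", "REML")) {
    mine <- fit_lmm(f, d, group = "bird_id", method = method)
    ref <- lme4::lmer(
      api ~ phenotype + sex + zday + I(zday^2) + phenotype:zday +
        (1 | bird_id), d, REML = method == "REML")
    expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-5)
    expect_equal(unname(mine$beta), unname(lme4::fixef(ref)),
                 tolerance = 1e-5)
    expect_equal(unname(mine$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
                 tolerance = 1e-4)
  }
  expect_error(fit_lmm(api ~ phenotype + I(2 * as.numeric(phenotype == "switcher")),
                       transform(d, phenotype = factor(phenotype)),
                       group = "bird_id"),
               "aliased|rank")
})

test_that("AICc carries the exact small-sample correction", {
  d <- simulate_lmm_data(30, seed = 47)
  fit <- fit_lmm(api ~ zday, d, group = "bird_id")
  k <- length(fit$beta) + 2
  expect_equal(fit$k, k)
  aic <- -2 * fit$logLik + 2 * k
  expect_equal(fit$AICc - aic, 2 * k * (k + 1) / (fit$n - k - 1),
               tolerance = 1e-12)
})

test_that("likelihood-ratio test is zero on identical models and non-negative", {
  d <- simulate_lmm_data(40, seed = 53)
  full <- fit_lmm(api ~ zday + sex, d, group = "bird_id")
  same <- fit_lmm(api ~ zday + sex, d, group = "bird_id")
  lrt0 <- likelihood_ratio_test(full, same)
  expect_equal(lrt0$X2, 0, tolerance = 1e-6)
  expect_equal(lrt0$p, 1)
  red <- fit_lmm(api ~ zday, d, group = "bird_id")
  lrt <- likelihood_ratio_test(full, red)
  expect_gte(lrt$X2, 0)
  expect_equal(lrt$df, 1)
  expect_error(likelihood_ratio_test(
    red, fit_lmm(api ~ sex, d, group = "bird_id")), "nested")
  expect_error(likelihood_ratio_test(
    fit_lmm(api ~ zday, d, group = "bird_id", method = "REML"), red),
    "ML")
})

test_that("dredge enumerates exactly the marginality-respecting subsets", {
  ## independent combinatorial oracle: count subsets of
  ## {phenotype, sex, zday, zday^2, phenotype:zday} closed under marginality
  terms <- c("phenotype", "sex", "zday", "I(zday^2)", "phenotype:zday")
  deps <- list("phenotype" = character(0), "sex" = character(0),
               "zday" = character(0), "I(zday^2)" = "zday",
               "phenotype:zday" = c("phenotype", "zday"))
  count <- 0
  for (mask in 0:(2^5 - 1)) {
    inc <- terms[bitwAnd(mask, 2^(0:4)) > 0]
    if (all(unlist(deps[inc]) %in% inc)) count <- count + 1
  }
  expect_equal(count, 16)
  d <- simulate_lmm_data(40, seed = 59)
  dd <- dredge_aicc(api ~ phenotype + sex + zday + I(zday^2) + phenotype:zday,
                    d, group = "bird_id")
  expect_equal(nrow(dd$table), count)
  ## one optional term -> exactly 2 candidates
  dd2 <- dredge_aicc(api ~ sex, d, group = "bird_id")
  expect_equal(nrow(dd2$table), 2)
  expect_true(all(dd$table$delta >= 0))
})

test_that("the nesting rule removes supersets of better-supported models", {
  ## construct data where x2 is pure noise: the model with x2 sits within
  ## 6 AICc units of the x1-only model but is its strict superset
  set.seed(62)
  n_b <- 40
  d <- data.frame(bird_id = rep(sprintf("b%02d", 1:n_b), each = 2))
  d$x1 <- rnorm(nrow(d))
  d$x2 <- rnorm(nrow(d))
  d$y <- 1 + 2 * d$x1 + rep(rnorm(n_b, 0, 0.5), each = 2) + rnorm(nrow(d), 0, 0.5)
  dd <- dredge_aicc(y ~ x1 + x2, d, group = "bird_id")
  tab <- dd$table
  row_x1 <- tab[tab$terms == "x1", ]
  row_x12 <- tab[tab$terms == "x1 + x2", ]
  ## the noise model sits inside the six-unit window but above its nested
  ## parent, so the nesting rule must drop it
  expect_true(row_x12$within_cutoff)
  expect_gt(row_x12$AICc, row_x1$AICc)
  expect_false(row_x12$retained)
  expect_true(row_x1$retained)
  expect_equal(dd$best_terms, "x1")
})

test_that("profile likelihood peaks at the optimum and recovers strong effects", {
  d <- simulate_lmm_data(80, seed = 67)
  fit <- fit_lmm(api ~ phenotype + sex + zday + I(zday^2) + phenotype:zday,
                 d, group = "bird_id")
  ## optimizer sanity: boundary fits never beat the optimum
  boundary <- fit_lmm(api ~ phenotype + sex + zday + I(zday^2) + phenotype:zday,
                      d[order(d$bird_id), ], group = "bird_id")
  expect_equal(fit$logLik, boundary$logLik, tolerance = 1e-8)
  expect_true(fit$sigma2_u > 0)
  ## true coefficients inside 3.5 SE for a strong-signal fit; baseline sex
  ## is F (alphabetical), so the intercept absorbs the female effect and
  ## the reported contrast is sexM = -0.45
  truth <- c(`(Intercept)` = 3.85, phenotypeswitcher = -0.2,
             phenotypeterrestrial = -0.4, sexM = -0.45, zday = 0.7,
             `I(zday^2)` = -0.15, `phenotypeswitcher:zday` = -0.25,
             `phenotypeterrestrial:zday` = 0.40)
  expect_true(all(abs(fit$beta[names(truth)] - truth) < 3.5 * fit$se))
})

test_that("api trajectory analysis recovers slopes and the interaction", {
  d <- simulate_lmm_data(90, seed = 71)
  d$api <- pmin(7, pmax(1, round(d$api)))  # ordinal field scale
  res <- api_trajectory_analysis(d)
  sl <- setNames(res$slopes$slope_zday, res$slopes$phenotype)
  expect_equal(unname(which.max(sl[c("marine", "switcher", "terrestrial")])), 3)
  expect_lt(res$interaction_lrt$p, 0.05)
  expect_equal(res$interaction_lrt$df, 2)
  ## predictions are on the raw day scale and cover all phenotypes
  expect_setequal(unique(as.character(res$predictions$phenotype)),
                  c("marine", "switcher", "terrestrial"))
  expect_true(all(res$predictions$day_of_year >= 121 &
                    res$predictions$day_of_year <= 151))
})
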