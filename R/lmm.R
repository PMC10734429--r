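## mixed_models: Gaussian random-intercept linear mixed models estimated by
## profiling the likelihood over the variance ratio, plus AICc model
## selection with the six-unit and nesting rules.
##
## For V = sigma2_e * (I + lambda * Z Z') with Z the bird-intercept
## indicator, V0^{-1} is block diagonal with per-group correction
## lambda / (1 + lambda * n_g), so all GLS quantities reduce to per-group
## sums and the likelihood profiles to a 1-D search over lambda.

#' Standardize day of year
#'
#' Centres and scales by the sample (n-1) standard deviation, keeping the
#' transform parameters for back-conversion to raw day of year.
#'
#' @param day numeric day-of-year values (>= 2 distinct).
#' @return list: `z`, `center`, `scale`.
#' @export
standardize_day <- function(day) {
  if (length(unique(day[!is.na(day)])) < 2)
    stop_val("constant day_of_year: cannot standardize")
  m <- mean(day, na.rm = TRUE)
  s <- stats::sd(day, na.rm = TRUE)
  list(z = (day - m) / s, center = m, scale = s)
}

#' Back-transform standardized day to raw day of year
#'
#' @param z standardized values.
#' @param st list from [standardize_day()].
#' @export
unstandardize_day <- function(z, st) z * st$scale + st$center

#' Fit a Gaussian random-intercept linear mixed model
#'
#' Maximum-likelihood (or REML) fit via a 1-D profile over
#' `lambda = sigma2_u / sigma2_e`: for fixed `lambda` the GLS solution is
#' closed-form; `lambda` is optimized by bounded scalar search. Wald
#' standard errors come from the GLS information matrix.
#'
#' @param fixed fixed-effects formula, e.g. `api ~ phenotype + sex + zday`.
#' @param data data.frame containing the variables and the grouping column.
#' @param group name of the random-intercept grouping column (bird id).
#' @param method `"ML"` (default; required for AICc selection and
#'   likelihood-ratio tests) or `"REML"`.
#' @return object of class `lmm_fit`: `beta`, `se`, `vcov_beta`,
#'   `sigma2_u`, `sigma2_e`, `lambda`, `logLik`, `AICc`, `n`, `n_groups`,
#'   `k` (fixed effects + 2 variance parameters), `term_labels`, `formula`,
#'   `method`.
#' @export
fit_lmm <- function(fixed, data, group = "bird_id",
                    method = c("ML", "REML")) {
  method <- match.arg(method)
  if (!group %in% names(data)) stop_val("grouping column '%s' not found", group)
  vars <- unique(c(all.vars(fixed), group))
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  X <- stats::model.matrix(fixed, df)
  y <- stats::model.response(stats::model.frame(fixed, df))
  g <- factor(df[[group]])
  n <- length(y); p <- ncol(X)
  if (n < p + 2) stop_val("too few observations (%d) for %d coefficients", n, p)
  qx <- qr(X)
  if (qx$rank < p)
    stop_val("rank-deficient design; aliased column(s): %s",
             paste(colnames(X)[qx$pivot[(qx$rank + 1):p]], collapse = ", "))
  if (nlevels(g) < 2) stop_val("need >= 2 groups for a random intercept")

  n_g <- as.vector(table(g))
  Sx <- rowsum(X, g)                    # G x p per-group column sums
  Sy <- as.vector(rowsum(y, g))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  prof <- function(lambda) {
    cg <- lambda / (1 + lambda * n_g)
    A <- XtX - crossprod(Sx * sqrt(cg))
    b <- Xty - crossprod(Sx, cg * Sy)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    rss <- max(yty - sum(cg * Sy^2) - 2 * sum(b * beta) +
                 as.numeric(crossprod(beta, A %*% beta)), 1e-12)
    ## with A beta = b this is yty_V - b'beta, written defensively
    logdet <- sum(log1p(lambda * n_g))
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
    } else {
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdet +
                      2 * sum(log(diag(ch))) + (n - p))
    }
    list(ll = ll, beta = as.vector(beta), s2 = s2, chol = ch, rss = rss)
  }

  obj <- function(loglam) prof(exp(loglam))$ll
  opt <- stats::optimize(obj, interval = c(-12, 10), maximum = TRUE,
                         tol = 1e-7)
  cand <- c(0, exp(opt$maximum))
  lls <- vapply(cand, function(l) prof(l)$ll, 0)
  lambda <- cand[which.max(lls)]
  fit <- prof(lambda)
  Ainv <- chol2inv(fit$chol)
  vcov_beta <- fit$s2 * Ainv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  beta <- stats::setNames(fit$beta, colnames(X))
  k <- p + 2
  ll <- fit$ll
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  structure(list(beta = beta,
                 se = stats::setNames(sqrt(diag(vcov_beta)), colnames(X)),
                 vcov_beta = vcov_beta,
                 sigma2_u = lambda * fit$s2,
                 sigma2_e = fit$s2,
                 lambda = lambda,
                 logLik = ll,
                 AICc = aicc,
                 n = n, n_groups = nlevels(g), k = k,
                 term_labels = attr(stats::terms(fixed), "term.labels"),
                 formula = fixed,
                 method = method),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept LMM (", x$method, "), n = ", x$n,
      ", groups = ", x$n_groups, "\n", sep = "")
  print(data.frame(estimate = x$beta, se = x$se))
  cat(sprintf("sigma2_bird = %.4g, sigma2_resid = %.4g, logLik = %.3f, AICc = %.3f\n",
              x$sigma2_u, x$sigma2_e, x$logLik, x$AICc))
  invisible(x)
}

#' Likelihood-ratio test of nested ML fits
#'
#' @param fit_full,fit_reduced `lmm_fit` objects fitted by ML; the reduced
#'   model's terms must be a subset of the full model's.
#' @return list: `X2`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  if (fit_full$method != "ML" || fit_reduced$method != "ML")
    stop_val("likelihood-ratio tests require ML fits")
  if (!all(fit_reduced$term_labels %in% fit_full$term_labels))
    stop_val("models are not nested")
  df <- length(fit_full$beta) - length(fit_reduced$beta)
  x2 <- max(0, 2 * (fit_full$logLik - fit_reduced$logLik))
  list(X2 = x2, df = df,
       p = if (df > 0) stats::pchisq(x2, df, lower.tail = FALSE) else 1)
}

## term dependencies for marginality: an interaction requires its main
## effects; a quadratic I(x^2) requires x
term_deps <- function(term) {
  if (grepl(":", term, fixed = TRUE)) return(strsplit(term, ":", fixed = TRUE)[[1]])
  m <- regmatches(term, regexec("^I\\((\\w+)\\^2\\)$", term))[[1]]
  if (length(m) == 2) return(m[2])
  character(0)
}

## all subsets of term labels closed under marginality
marginal_subsets <- function(term_labels) {
  n <- length(term_labels)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    inc <- term_labels[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- all(vapply(inc, function(t) all(term_deps(t) %in% inc), TRUE))
    if (ok) out[[length(out) + 1L]] <- inc
  }
  out
}

#' AICc dredge of a global random-intercept model
#'
#' Enumerates every subset of the global model's fixed terms that respects
#' marginality (quadratics require their main effect, interactions their
#' components), fits each by ML, ranks by AICc, retains models within
#' `delta_cutoff` units of the best, then applies the nesting rule:
#' a retained model whose terms are a strict superset of another retained
#' model with lower AICc is removed.
#'
#' @param global fixed-effects formula of the global model.
#' @param data data.frame.
#' @param group random-intercept grouping column.
#' @param delta_cutoff AICc retention window (default 6).
#' @return list: `table` (data.frame terms / n_terms / k / logLik / AICc /
#'   delta / within_cutoff / retained, ranked by AICc), `fits` (list of
#'   `lmm_fit` in table order), `best` (the retained model with lowest
#'   AICc).
#' @export
dredge_aicc <- function(global, data, group = "bird_id", delta_cutoff = 6) {
  response <- all.vars(global)[1]
  subsets <- marginal_subsets(attr(stats::terms(global), "term.labels"))
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    terms_i <- subsets[[i]]
    f <- stats::reformulate(if (length(terms_i)) terms_i else "1",
                            response = response)
    fit <- tryCatch(fit_lmm(f, data, group = group, method = "ML"),
                    error = function(e) NULL)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      terms = if (length(terms_i)) paste(sort(terms_i), collapse = " + ") else "1",
      n_terms = length(terms_i),
      k = if (is.null(fit)) NA_integer_ else fit$k,
      logLik = if (is.null(fit)) NA_real_ else fit$logLik,
      AICc = if (is.null(fit)) NA_real_ else fit$AICc,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$AICc)
  tab <- tab[ok, ]; fits <- fits[ok]; subsets <- subsets[ok]
  ord <- order(tab$AICc)
  tab <- tab[ord, ]; fits <- fits[ord]; subsets <- subsets[ord]
  tab$delta <- tab$AICc - tab$AICc[1]
  tab$within_cutoff <- tab$delta <= delta_cutoff
  retained <- tab$within_cutoff
  ## nesting rule: drop supersets of better-supported (lower AICc) models
  for (i in which(retained)) {
    for (j in which(retained)) {
      if (tab$AICc[j] < tab$AICc[i] &&
          all(subsets[[j]] %in% subsets[[i]]) &&
          length(subsets[[j]]) < length(subsets[[i]])) {
        retained[i] <- FALSE
        break
      }
    }
  }
  tab$retained <- retained
  rownames(tab) <- NULL
  best_idx <- which(retained)[which.min(tab$AICc[retained])]
  list(table = tab, fits = fits, best = fits[[best_idx]],
       best_terms = tab$terms[best_idx])
}

#' Body-condition (API) trajectory analysis
#'
#' Standardizes day of year, dredges the global model
#' `api ~ phenotype + sex + zday + I(zday^2) + phenotype:zday` (bird as
#' random intercept), reports the retained model set, tests the
#' phenotype-by-day interaction by likelihood ratio, derives per-phenotype
#' day slopes with standard errors from the global fit, and emits tidy
#' trajectory predictions on the raw day scale.
#'
#' @param data data.frame with `api`, `phenotype`, `sex`, `day_of_year`,
#'   `bird_id`.
#' @param delta_cutoff AICc retention window (default 6).
#' @return list: `selection` (dredge output), `global_fit`,
#'   `interaction_lrt`, `slopes` (data.frame phenotype / slope_zday / se),
#'   `predictions` (data.frame phenotype / sex / day_of_year / api_hat),
#'   `day_standardizer`.
#' @export
api_trajectory_analysis <- function(data, delta_cutoff = 6) {
  need <- c("api", "phenotype", "sex", "day_of_year", "bird_id")
  df <- data[stats::complete.cases(data[need]), need]
  df <- df[df$phenotype %in% phen3 & df$sex %in% c("F", "M"), ]
  birds_per <- vapply(split(df$bird_id, df$phenotype),
                      function(b) length(unique(b)), 0L)
  if (any(birds_per < 3))
    stop_val("phenotype(s) with < 3 birds with API: %s",
             paste(names(birds_per)[birds_per < 3], collapse = ", "))
  st <- standardize_day(df$day_of_year)
  df$zday <- st$z
  df$phenotype <- factor(df$phenotype, levels = phen3)
  df$sex <- factor(df$sex, levels = c("M", "F"))
  global <- api ~ phenotype + sex + zday + I(zday^2) + phenotype:zday
  sel <- dredge_aicc(global, df, group = "bird_id",
                     delta_cutoff = delta_cutoff)
  gfit <- fit_lmm(global, df, group = "bird_id", method = "ML")
  rfit <- fit_lmm(api ~ phenotype + sex + zday + I(zday^2), df,
                  group = "bird_id", method = "ML")
  lrt <- likelihood_ratio_test(gfit, rfit)
  ## per-phenotype slopes on the z-day scale from the global fit
  nm <- names(gfit$beta)
  slope_of <- function(g) {
    v <- numeric(length(nm))
    v[match("zday", nm)] <- 1
    int <- paste0("phenotype", g, ":zday")
    if (int %in% nm) v[match(int, nm)] <- 1
    c(sum(v * gfit$beta), sqrt(as.numeric(crossprod(v, gfit$vcov_beta %*% v))))
  }
  sl <- t(vapply(phen3, slope_of, numeric(2)))
  slopes <- data.frame(phenotype = phen3, slope_zday = sl[, 1], se = sl[, 2],
                       row.names = NULL, stringsAsFactors = FALSE)
  ## tidy predictions from the global fit on the raw day scale
  grid <- expand.grid(day_of_year = seq(min(df$day_of_year),
                                        max(df$day_of_year)),
                      phenotype = factor(phen3, levels = phen3),
                      sex = factor(c("M", "F"), levels = c("M", "F")))
  grid$zday <- (grid$day_of_year - st$center) / st$scale
  Xg <- stats::model.matrix(~ phenotype + sex + zday + I(zday^2) +
                              phenotype:zday, grid)
  grid$api_hat <- as.numeric(Xg %*% gfit$beta)
  list(selection = sel, global_fit = gfit, interaction_lrt = lrt,
       slopes = slopes,
       predictions = grid[c("phenotype", "sex", "day_of_year", "api_hat")],
       day_standardizer = st)
}

#' Simulate data from a known random-intercept model
#'
#' Test harness for parameter-recovery and calibration studies of
#' [fit_lmm()]: birds with 1-4 samples each, phenotype, sex and a May day
#' grid, and a *continuous* Gaussian response generated from the same
#' coefficient vocabulary as the study's API model.
#'
#' @param n_birds number of birds.
#' @param betas named coefficients (see [sim_config()]'s `api_betas`).
#' @param sigma_bird,sigma_resid variance components (SDs).
#' @param seed integer seed.
#' @return data.frame: `bird_id`, `phenotype`, `sex`, `day_of_year`,
#'   `zday`, `api`.
#' @export
simulate_lmm_data <- function(n_birds = 100,
                              betas = c(intercept = 3.4, sex_F = 0.45,
                                        zday = 0.7, zday2 = -0.15,
                                        phenotype_switcher = -0.2,
                                        phenotype_terrestrial = -0.4,
                                        zday_x_switcher = -0.25,
                                        zday_x_terrestrial = 0.40),
                              sigma_bird = 0.35, sigma_resid = 0.45,
                              seed = 1) {
  set.seed(seed)
  days <- 121:151
  phen <- sample(phen3, n_birds, replace = TRUE)
  sex <- sample(c("F", "M"), n_birds, replace = TRUE)
  re <- stats::rnorm(n_birds, 0, sigma_bird)
  n_s <- sample(1:4, n_birds, replace = TRUE,
                prob = c(0.35, 0.37, 0.16, 0.12))
  rows <- lapply(seq_len(n_birds), function(i) {
    d <- sort(sample(days, n_s[i]))
    z <- (d - mean(days)) / stats::sd(days)
    mu <- betas[["intercept"]] + betas[["sex_F"]] * (sex[i] == "F") +
      betas[["zday"]] * z + betas[["zday2"]] * z^2 +
      betas[["phenotype_switcher"]] * (phen[i] == "switcher") +
      betas[["phenotype_terrestrial"]] * (phen[i] == "terrestrial") +
      betas[["zday_x_switcher"]] * z * (phen[i] == "switcher") +
      betas[["zday_x_terrestrial"]] * z * (phen[i] == "terrestrial")
    data.frame(bird_id = sprintf("B%03d", i), phenotype = phen[i],
               sex = sex[i], day_of_year = d, zday = z,
               api = mu + re[i] + stats::rnorm(length(d), 0, sigma_resid),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
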