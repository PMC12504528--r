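# Helper: simulate a simple Gaussian crossed design for the slope model.
sim_crossed_gaussian <- function(n_subj, n_item, beta1, su = 0.06, si = 0.05,
                                 se = 0.45) {
  d <- expand.grid(subj = seq_len(n_subj), item = seq_len(n_item))
  d$x <- rnorm(nrow(d))
  d$y <- 0.6 + beta1 * d$x + rnorm(n_subj, 0, su)[d$subj] +
    rnorm(n_item, 0, si)[d$item] + rnorm(nrow(d), 0, se)
  d
}

test_that("slope model reduces to closed-form OLS when variances are pinned", {
  set.seed(1)
  d <- sim_crossed_gaussian(6, 5, beta1 = 0.3)
  fit <- fit_slope_lmm(d$y, d$x, d$subj, d$item, pin_variances = TRUE)
  expect_equal(unname(coef(fit)["jol"]), cov(d$y, d$x) / var(d$x),
               tolerance = 1e-10)
  expect_equal(unname(fit$variance_components[c("subject_var", "item_var")]),
               c(0, 0))
})

test_that("REML estimates match the grid-search + GLS oracle on toy data", {
  set.seed(4)
  toy <- expand.grid(s = 1:4, i = 1:4)
  toy$x <- rnorm(16)
  toy$y <- 0.3 * toy$x + rnorm(4, 0, 0.4)[toy$s] + rnorm(4, 0, 0.3)[toy$i] +
    rnorm(16, 0, 0.5)
  X <- cbind(1, toy$x)
  Zu <- model.matrix(~ 0 + factor(toy$s))
  Zi <- model.matrix(~ 0 + factor(toy$i))
  oracle <- oracle_reml_fit(toy$y, X, Zu, Zi)

  fit <- fit_slope_lmm(toy$y, toy$x, toy$s, toy$i)
  vc <- fit$variance_components
  par_fit <- log(pmax(c(vc[["subject_var"]], vc[["item_var"]],
                        vc[["residual_var"]]), 1e-12))
  crit_at_fit <- oracle_reml_crit(par_fit, toy$y, X, Zu, Zi)
  expect_lt(crit_at_fit - oracle$crit, 1e-4)
  expect_equal(unname(coef(fit)), unname(oracle$beta), tolerance = 1e-4)
})

test_that("slope model is scale-equivariant and row-order invariant", {
  set.seed(2)
  d <- sim_crossed_gaussian(10, 8, beta1 = 0.2)
  fit <- fit_slope_lmm(d$y, d$x, d$subj, d$item)
  fit_scaled <- fit_slope_lmm(3 * d$y, d$x, d$subj, d$item)
  expect_equal(unname(coef(fit_scaled)), 3 * unname(coef(fit)),
               tolerance = 1e-5)
  expect_equal(unname(fit_scaled$variance_components),
               9 * unname(fit$variance_components), tolerance = 1e-4)

  perm <- sample(nrow(d))
  fit_perm <- fit_slope_lmm(d$y[perm], d$x[perm], d$subj[perm], d$item[perm])
  expect_equal(coef(fit_perm), coef(fit), tolerance = 1e-8)
})

test_that("degenerate slope-model inputs are handled as contracted", {
  # all-equal outcome: slope 0, zero variance, flagged
  fit <- fit_slope_lmm(rep(1, 12), rnorm(12), rep(1:3, 4), rep(1:4, 3))
  expect_true(fit$degenerate)
  expect_equal(unname(coef(fit)["jol"]), 0)
  expect_equal(unname(fit$variance_components), c(0, 0, 0))
  # constant predictor is refused
  expect_error(fit_slope_lmm(rnorm(12), rep(2, 12), rep(1:3, 4), rep(1:4, 3)),
               "degenerate predictor")
  # single-level groupings drop their variance to zero rather than failing
  set.seed(3)
  d <- sim_crossed_gaussian(8, 3, beta1 = 0.4)
  fit_one <- fit_slope_lmm(d$y, d$x, rep(1, nrow(d)), d$item)
  expect_equal(unname(fit_one$variance_components["subject_var"]), 0)
  expect_true(is.finite(coef(fit_one)["jol"]))
})

test_that("slope recovery is unbiased in simulation", {
  set.seed(6)
  est <- replicate(20, {
    d <- sim_crossed_gaussian(200, 20, beta1 = 0.167)
    unname(coef(fit_slope_lmm(d$y, d$x, d$subj, d$item))["jol"])
  })
  expect_equal(mean(est), 0.167, tolerance = 0.02)
})

make_glmm_toy <- function(seed, S = 6, I = 4) {
  set.seed(seed)
  toy <- expand.grid(subject_id = seq_len(S), item_id = seq_len(I))
  toy <- rbind(toy, toy)
  toy$context <- rep(c("fitting", "unfitting"), length.out = nrow(toy))
  toy$jol <- sample(1:10, nrow(toy), TRUE)
  u <- rnorm(S, 0, 0.6)
  w <- rnorm(I, 0, 0.5)
  jz <- ave(toy$jol, toy$context, FUN = scale)
  eta <- 0.2 + 0.3 * jz + 0.3 * ifelse(toy$context == "fitting", 1, -1) +
    u[toy$subject_id] + w[toy$item_id]
  toy$correct <- rbinom(nrow(toy), 1, plogis(eta))
  toy
}

test_that("pinned-variance GLMM equals plain logistic regression with the same coding", {
  toy <- make_glmm_toy(5)
  fit <- fit_binomial_glmm(toy, pin_variances = TRUE)
  d <- data.frame(
    y = toy$correct,
    jz = ave(toy$jol, toy$context, FUN = scale),
    ctx = ifelse(toy$context == "fitting", 1, -1))
  ref <- glm(y ~ jz * ctx, family = binomial(), data = d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
})

test_that("GLMM Laplace likelihood agrees with exact Gauss-Hermite quadrature", {
  toy <- make_glmm_toy(11)
  fit <- fit_binomial_glmm(toy)
  expect_true(fit$converged)
  vc <- fit$variance_components
  expect_true(all(vc > 0)) # interior fixture: both variances estimated

  b <- coef(fit)
  jz <- ave(toy$jol, toy$context, FUN = scale)
  ctx <- ifelse(toy$context == "fitting", 1, -1)
  d <- data.frame(
    y = toy$correct,
    eta0 = b["intercept"] + b["jol"] * jz + b["context"] * ctx +
      b["jol:context"] * jz * ctx,
    subj = toy$subject_id, item = toy$item_id)
  exact <- oracle_glmm_loglik(d, sqrt(vc[["subject_var"]]),
                              sqrt(vc[["item_var"]]), n_nodes = 12)
  laplace <- as.numeric(logLik(fit$fit))
  expect_lt(abs(laplace - exact), 0.1)

  # near-optimality of the Laplace estimates under the exact likelihood:
  # perturbing any parameter should not improve the exact log-likelihood
  # by more than the Laplace error budget
  perturb_ll <- function(db = c(0, 0, 0, 0), dsu = 0, dsw = 0) {
    bb <- b + db
    dd <- d
    dd$eta0 <- bb["intercept"] + bb["jol"] * jz + bb["context"] * ctx +
      bb["jol:context"] * jz * ctx
    oracle_glmm_loglik(dd, max(sqrt(vc[["subject_var"]]) + dsu, 1e-8),
                       max(sqrt(vc[["item_var"]]) + dsw, 1e-8), n_nodes = 12)
  }
  probes <- c(
    perturb_ll(db = c(0.25, 0, 0, 0)), perturb_ll(db = c(-0.25, 0, 0, 0)),
    perturb_ll(db = c(0, 0.25, 0, 0)), perturb_ll(db = c(0, -0.25, 0, 0)),
    perturb_ll(dsu = 0.25), perturb_ll(dsu = -0.25),
    perturb_ll(dsw = 0.25), perturb_ll(dsw = -0.25))
  expect_true(all(probes < exact + 0.1))
})

test_that("GLMM recovers an injected context effect", {
  cohort <- small_cohort(
    n_subjects = 200, n_items = 16, seed = 12,
    base_accuracy = c(fitting = 0.71, unfitting = 0.50),
    jol_slope = c(fitting = 0, unfitting = 0),
    subject_sd = 0.03, item_sd = 0.03)
  targets <- cohort$recognition[cohort$recognition$role == "target", ]
  trials <- merge(cohort$ratings, targets,
                  by.x = c("unit_id", "item_id", "context"),
                  by.y = c("subject_id", "item_id", "context"))
  names(trials)[names(trials) == "unit_id"] <- "subject_id"
  fit <- fit_binomial_glmm(trials)
  truth <- (qlogis(0.71) - qlogis(0.50)) / 2 # sum-to-zero context coefficient
  expect_lt(abs(unname(coef(fit)["context"]) - truth), 0.1)
})

test_that("degenerate GLMM inputs are refused with clear errors", {
  toy <- make_glmm_toy(5)
  toy$jol <- 5
  expect_error(fit_binomial_glmm(toy), "degenerate predictor")
  one_subj <- make_glmm_toy(5)
  one_subj$subject_id <- 1
  expect_error(fit_binomial_glmm(one_subj), "2 subjects")
})

test_that("type-2 Wald tests match direct matrix arithmetic and car's Anova", {
  toy <- make_glmm_toy(11)
  fit <- fit_binomial_glmm(toy)
  tests <- type2_anova(fit)
  expect_identical(tests$term, c("jol", "context", "jol:context"))
  expect_identical(tests$df, rep(1L, 3))
  # single-coefficient terms: chisq is the squared Wald z
  for (term in tests$term) {
    b <- coef(fit)[term]
    se <- sqrt(fit$vcov[term, term])
    expect_equal(tests$chisq[tests$term == term], unname((b / se)^2),
                 tolerance = 1e-10)
    expect_equal(tests$p_value[tests$term == term],
                 unname(pchisq((b / se)^2, 1, lower.tail = FALSE)),
                 tolerance = 1e-12)
  }
  # independent cross-check against car's Wald chi-square table
  skip_if_not_installed("car")
  ref <- car::Anova(fit$fit, type = 3, test.statistic = "Chisq")
  ref <- ref[rownames(ref) != "(Intercept)", ]
  expect_equal(unname(tests$chisq), unname(ref[["Chisq"]]), tolerance = 1e-6)

  bad <- fit
  bad$converged <- FALSE
  expect_error(type2_anova(bad), "non-converged")
})

test_that("a term with a tiny coefficient yields a near-zero chi-square", {
  fake <- structure(list(
    coefficients = c(intercept = 0.5, jol = 1e-9, context = 0.4,
                     `jol:context` = -0.1),
    vcov = diag(c(0.01, 0.0004, 0.01, 0.01),
                nrow = 4) |>
      `dimnames<-`(list(c("intercept", "jol", "context", "jol:context"),
                        c("intercept", "jol", "context", "jol:context"))),
    converged = TRUE), class = "mixed_fit")
  tests <- type2_anova(fake)
  expect_lt(tests$chisq[tests$term == "jol"], 1e-10)
  expect_gt(tests$p_value[tests$term == "jol"], 0.999)
})
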