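# Crossed random-intercept models: the confirmatory binomial GLMM of
# recognition accuracy on JOL x context, its type-2 Wald table, and the
# Gaussian slope model refitted inside every bootstrap iteration.

new_mixed_fit <- function(coefficients, vcov, variance_components, converged,
                          n_obs, model, reml = NA, degenerate = FALSE,
                          fit = NULL) {
  structure(list(
    coefficients = coefficients,
    vcov = vcov,
    variance_components = variance_components,
    converged = converged,
    n_obs = n_obs,
    model = model,
    reml = reml,
    degenerate = degenerate,
    fit = fit
  ), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s, n = %d, %s\n", x$model, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$coefficients, 4))
  vc <- x$variance_components
  cat("variance components:",
      paste(sprintf("%s = %.4g", names(vc), vc), collapse = ", "), "\n")
  invisible(x)
}

#' Coefficients of a mixed fit
#' @param object a `mixed_fit`.
#' @param ... unused.
#' @export
coef.mixed_fit <- function(object, ...) object$coefficients

#' Coefficient covariance of a mixed fit
#' @param object a `mixed_fit`.
#' @param ... unused.
#' @export
vcov.mixed_fit <- function(object, ...) object$vcov

glmer_quiet_control <- function() {
  lme4::glmerControl(check.conv.singular = "ignore")
}

lmer_fast_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.singular = "ignore",
                    check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore")
}

# Fit with warning capture; lme4 reports convergence trouble via warnings.
fit_capturing_convergence <- function(expr) {
  notes <- character(0)
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  bad <- grepl("failed to converge|unable to evaluate|pwrssUpdate|Downdated",
               notes, ignore.case = TRUE)
  list(fit = fit, converged = !any(bad))
}

#' Fit the confirmatory binomial GLMM of recognition accuracy
#'
#' Logistic mixed model `correct ~ z(jol) * context + (1|subject) + (1|item)`
#' on target (studied-item) trials, maximising the Laplace-approximate
#' marginal likelihood. Context is coded sum-to-zero (fitting = +1,
#' unfitting = -1) and JOL is standardised within context, so the JOL and
#' context main effects stay interpretable alongside their interaction.
#'
#' @param trials tibble/data frame with columns `subject_id`, `item_id`,
#'   `context` ("fitting"/"unfitting"), `jol`, `correct` (logical or 0/1).
#'   Distractor trials must already be excluded: JOLs exist only for studied
#'   items.
#' @param pin_variances if `TRUE`, both random-intercept variances are pinned
#'   to zero and the model degenerates to plain logistic regression on the
#'   same rows (used by reduction tests; also a fallback for data with no
#'   grouping structure).
#' @return a `mixed_fit` with coefficients named `intercept`, `jol`,
#'   `context`, `jol:context`; `variance_components` carries `subject_var`
#'   and `item_var` (logit scale).
#' @export
fit_binomial_glmm <- function(trials, pin_variances = FALSE) {
  check_columns(trials, c("subject_id", "item_id", "context", "jol", "correct"),
                "trials")
  trials <- dplyr::filter(trials, !is.na(.data$correct), !is.na(.data$jol))
  if (length(unique(trials$subject_id)) < 2 && !pin_variances) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  if (length(unique(trials$item_id)) < 2 && !pin_variances) {
    stop("need at least 2 items", call. = FALSE)
  }
  if (stats::sd(trials$jol) == 0) {
    stop("degenerate predictor: `jol` is constant", call. = FALSE)
  }
  d <- data.frame(
    y = as.integer(trials$correct),
    subject = factor(trials$subject_id),
    item = factor(trials$item_id),
    ctx = ifelse(trials$context == "fitting", 1, -1)
  )
  d$jol_z <- stats::ave(as.numeric(trials$jol), trials$context,
                        FUN = z_standardise)

  coef_names <- c("intercept", "jol", "context", "jol:context")
  if (pin_variances) {
    m <- stats::glm(y ~ jol_z * ctx, family = stats::binomial(), data = d)
    beta <- stats::setNames(stats::coef(m), coef_names)
    V <- stats::vcov(m)
    dimnames(V) <- list(coef_names, coef_names)
    return(new_mixed_fit(beta, V, c(subject_var = 0, item_var = 0),
                         converged = m$converged, n_obs = nrow(d),
                         model = "binomial-glm", fit = m))
  }
  res <- fit_capturing_convergence(
    lme4::glmer(y ~ jol_z * ctx + (1 | subject) + (1 | item),
                family = stats::binomial(), data = d,
                control = glmer_quiet_control())
  )
  m <- res$fit
  beta <- stats::setNames(lme4::fixef(m), coef_names)
  V <- as.matrix(stats::vcov(m))
  dimnames(V) <- list(coef_names, coef_names)
  vc <- lme4::VarCorr(m)
  new_mixed_fit(
    beta, V,
    c(subject_var = as.numeric(vc$subject), item_var = as.numeric(vc$item)),
    converged = res$converged && m@optinfo$conv$opt == 0,
    n_obs = nrow(d), model = "binomial-glmm", fit = m
  )
}

#' Type-2 Wald chi-square tests for a mixed fit
#'
#' Each term is tested after all other terms except those containing it: with
#' sum-to-zero context coding and centred JOL this reduces to a Wald
#' chi-square on the term's own coefficients, `chisq = b' V^-1 b` with df =
#' number of coefficients in the term.
#'
#' @param fit a converged `mixed_fit` from [fit_binomial_glmm()] (any fit
#'   whose coefficients are named `intercept`, `jol`, `context`,
#'   `jol:context`).
#' @return tibble with `term`, `chisq`, `df`, `p_value` for the JOL and
#'   context main effects and their interaction.
#' @export
type2_anova <- function(fit) {
  stopifnot(inherits(fit, "mixed_fit"))
  if (!isTRUE(fit$converged)) {
    stop("refusing to test a non-converged fit", call. = FALSE)
  }
  terms <- list(jol = "jol", context = "context",
                `jol:context` = "jol:context")
  rows <- lapply(names(terms), function(tn) {
    idx <- terms[[tn]]
    b <- fit$coefficients[idx]
    V <- fit$vcov[idx, idx, drop = FALSE]
    chisq <- as.numeric(t(b) %*% solve(V) %*% b)
    df <- length(b)
    tibble::tibble(term = tn, chisq = chisq, df = df,
                   p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Fit the crossed random-intercept slope model
#'
#' Gaussian model `y = b0 + b1 * jol_z + u_unit + w_item + e` estimated by
#' REML (the default; set `reml = FALSE` for ML), the per-iteration model of
#' the structured bootstrap. A grouping factor with a single level has its
#' variance fixed at zero (the term is dropped); with both dropped, or with
#' `pin_variances = TRUE`, the fit is ordinary least squares.
#'
#' @param y numeric outcome per row (binary correctness for human pairing,
#'   per-item accuracy for machine pairing).
#' @param jol_z standardised JOL per row; needs >= 2 distinct values.
#' @param subject_ids,item_ids grouping identifiers per row.
#' @param reml use REML (default) or ML.
#' @param pin_variances force both random-intercept variances to zero.
#' @return a `mixed_fit` with coefficients `intercept`, `jol`;
#'   `variance_components` carries `subject_var`, `item_var`, `residual_var`.
#'   An all-equal `y` yields a degenerate fit with slope 0 and zero variance,
#'   flagged via `$degenerate`.
#' @export
fit_slope_lmm <- function(y, jol_z, subject_ids, item_ids, reml = TRUE,
                          pin_variances = FALSE) {
  n <- length(y)
  stopifnot(length(jol_z) == n, length(subject_ids) == n,
            length(item_ids) == n)
  coef_names <- c("intercept", "jol")
  if (n > 0 && all(y == y[[1]])) {
    beta <- stats::setNames(c(y[[1]], 0), coef_names)
    V <- matrix(0, 2, 2, dimnames = list(coef_names, coef_names))
    return(new_mixed_fit(beta, V,
                         c(subject_var = 0, item_var = 0, residual_var = 0),
                         converged = TRUE, n_obs = n, model = "gaussian-lmm",
                         reml = reml, degenerate = TRUE))
  }
  if (length(unique(jol_z)) < 2) {
    stop("degenerate predictor: `jol_z` has fewer than 2 distinct values",
         call. = FALSE)
  }
  d <- data.frame(y = as.numeric(y), jol_z = as.numeric(jol_z),
                  unit = factor(subject_ids), item = factor(item_ids))
  use_unit <- !pin_variances && nlevels(d$unit) > 1
  use_item <- !pin_variances && nlevels(d$item) > 1

  if (!use_unit && !use_item) {
    m <- stats::lm(y ~ jol_z, data = d)
    beta <- stats::setNames(stats::coef(m), coef_names)
    V <- stats::vcov(m)
    dimnames(V) <- list(coef_names, coef_names)
    return(new_mixed_fit(beta, V,
                         c(subject_var = 0, item_var = 0,
                           residual_var = stats::sigma(m)^2),
                         converged = TRUE, n_obs = n, model = "gaussian-lm",
                         reml = reml, fit = m))
  }
  re <- c(if (use_unit) "(1 | unit)", if (use_item) "(1 | item)")
  form <- stats::as.formula(paste("y ~ jol_z +", paste(re, collapse = " + ")))
  res <- fit_capturing_convergence(
    lme4::lmer(form, data = d, REML = reml, control = lmer_fast_control())
  )
  m <- res$fit
  beta <- stats::setNames(lme4::fixef(m), coef_names)
  V <- as.matrix(stats::vcov(m))
  dimnames(V) <- list(coef_names, coef_names)
  vc <- lme4::VarCorr(m)
  new_mixed_fit(
    beta, V,
    c(subject_var = if (use_unit) as.numeric(vc$unit) else 0,
      item_var = if (use_item) as.numeric(vc$item) else 0,
      residual_var = stats::sigma(m)^2),
    converged = res$converged && m@optinfo$conv$opt == 0,
    n_obs = n, model = "gaussian-lmm", reml = reml, fit = m
  )
}
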