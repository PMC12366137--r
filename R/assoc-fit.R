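# Regression fitters reporting per-1-SD instrument effects ---------------

Z_CRIT <- 1.96  # normal critical value for 95% Wald intervals

.new_assoc <- function(estimate, se, ci_low, ci_high, p, n, label, scale,
                       beta = estimate, term = "instrument") {
  structure(list(estimate = estimate, se = se, ci_low = ci_low,
                 ci_high = ci_high, p = p, n = n, model_label = label,
                 scale = scale, beta = beta, term = term),
            class = "adbp_assoc")
}

# design matrix with the instrument straight after the intercept; factors
# expand to treatment contrasts against their first (reference) level
.design <- function(z, covariates, n) {
  if (is.null(covariates) || !length(covariates)) {
    X <- cbind("(Intercept)" = rep(1, n), instrument = z)
    attr(X, "reference_levels") <- character(0)
    return(X)
  }
  covariates <- as.data.frame(covariates)
  df <- cbind(instrument = z, covariates)
  X <- stats::model.matrix(~ ., data = df)
  refs <- vapply(covariates, function(x)
    if (is.factor(x)) levels(x)[1] else NA_character_, character(1))
  attr(X, "reference_levels") <- refs[!is.na(refs)]
  X
}

.check_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) .stop_rank(X, qx)
  invisible(qx)
}

.stop_rank <- function(X, fit) {
  aliased <- colnames(X)[fit$pivot[(fit$rank + 1):ncol(X)]]
  stop("design matrix is rank deficient; collinear column(s): ",
       paste(aliased, collapse = ", "),
       " (check covariates for multicollinearity)", call. = FALSE)
}

#' Linear association of an outcome with a standardized instrument
#'
#' Ordinary least squares of a continuous outcome (mmHg) on the
#' standardized instrument plus covariates.  The reported effect is the
#' instrument coefficient — the difference in mean outcome per 1 SD higher
#' score — with its conventional standard error, Wald 95% CI
#' (estimate +/- 1.96 se) and normal p-value.  Rank-deficient designs are
#' an error naming the collinear columns (the multicollinearity check).
#'
#' @param y Numeric outcome vector.
#' @param z Standardized instrument scores.
#' @param covariates Optional data.frame; factors are expanded to
#'   indicator contrasts against their first level.
#' @param label Model (rung) label carried into the result.
#' @return An `adbp_assoc` object on the `mmHg_per_SD` scale.
#' @export
fit_linear <- function(y, z, covariates = NULL, label = "model") {
  keep <- !is.na(y) & !is.na(z)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  y <- y[keep]; z <- z[keep]
  n <- length(y)
  X <- .design(z, covariates, n)
  if (n <= ncol(X)) stop("too few observations for the design", call. = FALSE)
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) .stop_rank(X, fit)
  sigma2 <- sum(fit$residuals^2) / (n - ncol(X))
  p <- ncol(X)
  R <- fit$qr[seq_len(p), , drop = FALSE]
  R[lower.tri(R)] <- 0
  XtX_inv <- chol2inv(R)
  # undo the pivoting so variances line up with coefficient order
  vars <- numeric(p); vars[fit$pivot] <- diag(XtX_inv)
  cf <- numeric(p); cf[fit$pivot] <- fit$coefficients
  j <- which(colnames(X) == "instrument")
  se <- sqrt(sigma2 * vars[j])
  est <- cf[j]
  p <- if (se == 0) 0 else 2 * stats::pnorm(-abs(est / se))
  out <- .new_assoc(est, se, est - Z_CRIT * se, est + Z_CRIT * se, p, n,
                    label, "mmHg_per_SD")
  attr(out, "reference_levels") <- attr(X, "reference_levels")
  out
}

#' Logistic association of a binary outcome with a standardized instrument
#'
#' Maximum-likelihood logistic regression reported as the odds ratio per
#' 1 SD higher score with a Wald 95% CI on the log-odds scale.
#' Non-convergence or (quasi-)complete separation is an explicit error,
#' never a silent estimate.
#'
#' @inheritParams fit_linear
#' @param y 0/1 outcome vector; both classes must be present.
#' @return An `adbp_assoc` object on the `OR_per_SD` scale (`estimate`,
#'   `ci_low`, `ci_high` are odds ratios; `beta` and `se` are on the
#'   log-odds scale).
#' @export
fit_logistic <- function(y, z, covariates = NULL, label = "model") {
  keep <- !is.na(y) & !is.na(z)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  y <- y[keep]; z <- z[keep]
  if (length(unique(y)) < 2)
    stop("outcome has fewer than 2 classes; cannot fit logistic model",
         call. = FALSE)
  n <- length(y)
  X <- .design(z, covariates, n)
  .check_rank(X)
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (!fit$converged)
    stop("logistic model did not converge", call. = FALSE)
  p1 <- seq_len(fit$rank)
  covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  coefs <- fit$coefficients
  ses <- numeric(length(coefs)); ses[fit$qr$pivot[p1]] <- sqrt(diag(covmat))
  j <- which(colnames(X) == "instrument")
  b <- unname(coefs[j]); se <- ses[j]
  mu <- fit$fitted.values
  extreme <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  if (extreme && (se > 100 || max(abs(coefs)) > 10))
    stop("logistic model shows (quasi-)complete separation; ",
         "estimate not reported", call. = FALSE)
  pval <- 2 * stats::pnorm(-abs(b / se))
  out <- .new_assoc(exp(b), se, exp(b - Z_CRIT * se), exp(b + Z_CRIT * se),
                    pval, n, label, "OR_per_SD", beta = b)
  attr(out, "reference_levels") <- attr(X, "reference_levels")
  out
}

#' @export
print.adbp_assoc <- function(x, ...) {
  unit <- if (x$scale == "OR_per_SD") "OR" else "mmHg"
  cat(sprintf("%s: %s %.4g (95%% CI %.4g to %.4g), p = %.3g, n = %d\n",
              x$model_label, unit, x$estimate, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' @export
coef.adbp_assoc <- function(object, ...) {
  stats::setNames(object$estimate, object$term)
}

#' @export
confint.adbp_assoc <- function(object, parm, level = 0.95, ...) {
  matrix(c(object$ci_low, object$ci_high), nrow = 1,
         dimnames = list(object$term, c("2.5 %", "97.5 %")))
}

#' @export
as.data.frame.adbp_assoc <- function(x, ...) {
  data.frame(model_label = x$model_label, n = x$n, estimate = x$estimate,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             scale = x$scale, stringsAsFactors = FALSE)
}
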