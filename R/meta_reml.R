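## Random-effects meta-regression: z_i ~ N(x_i' beta, se_i^2 + tau^2),
## tau^2 estimated by profiled restricted maximum likelihood.

## Restricted log-likelihood at a given tau2. Includes all constants plus the
## +0.5 log|X'X| term so that values (and AIC = -2 ll + 2 (p + 1)) follow the
## usual reference convention for REML meta-analysis.
.reml_loglik <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X * w, X)
  beta <- solve(XtWX, crossprod(X * w, y))
  rss <- sum(w * (y - X %*% beta)^2)
  k <- length(y); p <- ncol(X)
  as.numeric(
    -0.5 * (k - p) * log(2 * pi) +
      0.5 * determinant(crossprod(X), logarithm = TRUE)$modulus -
      0.5 * sum(log(v + tau2)) -
      0.5 * determinant(XtWX, logarithm = TRUE)$modulus -
      0.5 * rss)
}

## Core fitter on (y, v, X). Handles rank deficiency by dropping non-estimable
## columns (messaged + recorded), profiles tau2 by Brent search on [0, upper].
.reml_fit_core <- function(y, v, X, tau2 = NULL, tol = 1e-10) {
  k <- length(y)
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0))
    stop("effects must be finite with positive sampling variances",
         call. = FALSE)
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    message("dropping non-estimable moderator column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0)
      stop("design matrix has rank 0 after dropping collinear columns",
           call. = FALSE)
  }
  p <- ncol(X)
  if (k < p)
    stop("fewer effects (", k, ") than fixed-effect columns (", p, ")",
         call. = FALSE)
  if (k < p + 2)
    warning("only ", k, " effect(s) for ", p,
            " coefficient(s); between-effect variance is not identifiable",
            call. = FALSE)

  if (is.null(tau2)) {
    if (k == p) {
      tau2 <- 0
    } else {
      upper <- max(100 * max(v), 10 * var(y), 1)
      opt <- optimize(.reml_loglik, c(0, upper), maximum = TRUE,
                      y = y, v = v, X = X, tol = tol)
      ## polish inside a narrow bracket: Brent's absolute precision on wide
      ## intervals is limited by its relative tolerance
      opt2 <- optimize(.reml_loglik, c(max(0, opt$maximum - 1e-4),
                                       opt$maximum + 1e-4),
                       maximum = TRUE, y = y, v = v, X = X, tol = 1e-12)
      if (opt2$objective > opt$objective) opt <- opt2
      tau2 <- if (.reml_loglik(0, y, v, X) >= opt$objective) 0 else opt$maximum
      if (tau2 > 0.999 * upper)
        warning("tau^2 estimate at search boundary (", signif(upper, 3), ")",
                call. = FALSE)
    }
  } else {
    if (!is.numeric(tau2) || length(tau2) != 1 || tau2 < 0)
      stop("'tau2' must be a single non-negative number", call. = FALSE)
  }

  w <- 1 / (v + tau2)
  XtWX <- crossprod(X * w, X)
  cov_b <- solve(XtWX)
  beta <- drop(cov_b %*% crossprod(X * w, y))
  names(beta) <- colnames(X)
  se_b <- sqrt(diag(cov_b))
  fitted <- drop(X %*% beta)

  ## residual heterogeneity (Cochran's Q of the fixed-effect fit, tau2 = 0)
  wfe <- 1 / v
  XtWfeX <- crossprod(X * wfe, X)
  beta_fe <- solve(XtWfeX, crossprod(X * wfe, y))
  QE <- sum(wfe * (y - X %*% beta_fe)^2)

  ## omnibus Wald test of the non-intercept coefficients (or the intercept
  ## for an intercept-only model)
  has_int <- "(Intercept)" %in% colnames(X)
  btt <- if (has_int && p > 1) setdiff(seq_len(p), match("(Intercept)",
                                                         colnames(X)))
         else seq_len(p)
  QM <- drop(t(beta[btt]) %*% solve(cov_b[btt, btt, drop = FALSE],
                                    beta[btt]))

  ## typical within-effect variance via the fixed-effect hat-matrix trace
  trP <- sum(wfe) - sum(diag(solve(XtWfeX, crossprod(X * wfe))))
  s2 <- (k - p) / trP
  I2 <- 100 * tau2 / (tau2 + s2)

  ll <- .reml_loglik(tau2, y, v, X)
  list(beta = beta, se = se_b, cov = cov_b, zval = beta / se_b,
       pval = 2 * pnorm(-abs(beta / se_b)),
       tau2 = tau2, s2 = s2, I2 = I2,
       QE = QE, QE_df = k - p, QE_p = pchisq(QE, k - p, lower.tail = FALSE),
       QM = QM, QM_df = length(btt),
       QM_p = pchisq(QM, length(btt), lower.tail = FALSE),
       loglik = ll, aic = -2 * ll + 2 * (p + 1),
       k = k, p = p, yi = y, vi = v, X = X,
       fitted = fitted, residuals = y - fitted, dropped = dropped)
}

#' Random-effects meta-regression by restricted maximum likelihood
#'
#' Fits the model \eqn{z_i \sim N(x_i'\beta,\; se_i^2 + \tau^2)} to a table of
#' harmonized Fisher-z effects. \eqn{\tau^2} is estimated by maximizing the
#' restricted log-likelihood (profiled in \eqn{\tau^2}, bounded below at 0);
#' \eqn{\beta} is the weighted least-squares solution at the optimum. The fit
#' carries Wald tests (QM), residual heterogeneity (QE, Cochran's Q of the
#' inverse-variance fixed-effect fit), the I-squared heterogeneity percentage,
#' the restricted log-likelihood, and AIC \eqn{= -2\ell + 2(p+1)} counting
#' \eqn{\tau^2} as a parameter.
#'
#' Non-estimable moderator columns (e.g. empty cells in a group-by-tracer
#' interaction) are dropped with a message and recorded in \code{$dropped}.
#'
#' @param table An \code{effect_table} (see [load_effect_table()]), or any
#'   data frame with numeric columns \code{z} and \code{se} plus the moderator
#'   columns named in \code{moderators}.
#' @param moderators A one-sided formula over columns of \code{table}
#'   (default \code{~ 1}, the common-correlation model), or one of the named
#'   model strings \code{"intercept"}, \code{"group"}, \code{"tracer"},
#'   \code{"group_x_tracer"}.
#' @param tau2 Optional fixed value for \eqn{\tau^2}; if supplied, no REML
#'   estimation is done (used mainly for closed-form checks).
#' @return An object of class \code{"reml_meta"} with components
#'   \code{coefficients}, \code{se}, \code{cov}, \code{zval}, \code{pval},
#'   \code{tau2}, \code{I2}, \code{QE}, \code{QM}, \code{loglik}, \code{aic},
#'   \code{k}, \code{p}, \code{dropped} and the fitting frame.
#' @examples
#' tab <- table1_effects()
#' fit <- reml_meta(tab, ~ group)
#' summary(fit)
#' predict_group(fit)
#' @export
reml_meta <- function(table, moderators = ~ 1, tau2 = NULL) {
  if (is.character(moderators)) moderators <- moderator_formula(moderators)
  if (!inherits(moderators, "formula"))
    stop("'moderators' must be a one-sided formula or a model name",
         call. = FALSE)
  if (!all(c("z", "se") %in% names(table)))
    stop("'table' must contain harmonized 'z' and 'se' columns", call. = FALSE)
  mt <- terms(moderators, data = table)
  mf <- stats::model.frame(mt, data = table)
  X <- model.matrix(mt, mf)
  core <- .reml_fit_core(as.numeric(table$z), as.numeric(table$se)^2, X,
                         tau2 = tau2)
  core$coefficients <- core$beta
  core$terms <- mt
  core$xlevels <- stats::.getXlevels(mt, mf)
  core$formula <- moderators
  core$table <- table
  core$call <- match.call()
  class(core) <- "reml_meta"
  core
}

#' I-squared heterogeneity of a fitted meta-regression
#'
#' Percentage of total variance attributable to between-effect heterogeneity,
#' \eqn{100\,\tau^2/(\tau^2 + s^2)}, where \eqn{s^2} is the typical
#' within-effect sampling variance computed from the trace of the
#' inverse-variance hat matrix (so the definition extends to moderated
#' models).
#'
#' @param fit A \code{"reml_meta"} fit.
#' @return A percentage in \eqn{[0, 100]}.
#' @export
i_squared <- function(fit) {
  stopifnot(inherits(fit, "reml_meta"))
  fit$I2
}

#' @export
coef.reml_meta <- function(object, ...) object$coefficients

#' @export
vcov.reml_meta <- function(object, ...) object$cov

#' @export
logLik.reml_meta <- function(object, ...) {
  structure(object$loglik, df = object$p + 1, nobs = object$k,
            class = "logLik")
}

#' @export
fitted.reml_meta <- function(object, ...) object$fitted

#' @export
residuals.reml_meta <- function(object, ...) object$residuals

#' Predictions from a random-effects meta-regression
#'
#' @param object A \code{"reml_meta"} fit.
#' @param newdata Optional data frame of moderator values; defaults to the
#'   fitting table.
#' @param level Confidence level for Wald intervals (default 0.95; the
#'   critical value for 0.95 is fixed at 1.959964).
#' @param ... Unused.
#' @return Data frame with predicted z, its standard error and Wald interval.
#' @export
predict.reml_meta <- function(object, newdata = NULL, level = 0.95, ...) {
  X <- if (is.null(newdata)) object$X else {
    mt <- delete.response(object$terms)
    mm <- model.matrix(mt, stats::model.frame(mt, newdata,
                                              xlev = object$xlevels))
    miss <- setdiff(names(object$coefficients), colnames(mm))
    if (length(miss))
      stop("newdata does not span coefficient(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    mm[, names(object$coefficients), drop = FALSE]
  }
  z_hat <- drop(X %*% object$coefficients)
  se_fit <- sqrt(rowSums((X %*% object$cov) * X))
  crit <- if (identical(level, 0.95)) 1.959964 else qnorm(1 - (1 - level) / 2)
  data.frame(z = z_hat, se = se_fit,
             z_lo = z_hat - crit * se_fit, z_hi = z_hat + crit * se_fit)
}

#' Group-level predictions back-transformed to the correlation scale
#'
#' Predicted Fisher-z for each clinical group under a fit whose moderators
#' involve at most \code{group}, with Wald 95\% intervals, plus the same
#' quantities mapped to the correlation scale through \code{tanh}.
#'
#' @param fit A \code{"reml_meta"} fit of the intercept-only or
#'   group-moderated model.
#' @param group Character vector of group levels (default: all three).
#' @return Data frame with columns \code{group}, \code{z}, \code{z_lo},
#'   \code{z_hi}, \code{r}, \code{r_lo}, \code{r_hi}.
#' @export
predict_group <- function(fit, group = levels(fit$table$group)) {
  stopifnot(inherits(fit, "reml_meta"))
  vars <- all.vars(fit$formula)
  if (length(setdiff(vars, "group")))
    stop("group-level prediction requires a fit with moderators limited to ",
         "'group'; this fit also uses: ",
         paste(setdiff(vars, "group"), collapse = ", "), call. = FALSE)
  known <- fit$xlevels[["group"]]
  if (is.null(known)) known <- .group_levels
  bad <- setdiff(group, known)
  if (length(bad))
    stop("group(s) absent from the design: ", paste(bad, collapse = ", "),
         call. = FALSE)
  nd <- data.frame(group = factor(group, levels = known))
  pr <- predict(fit, nd)
  data.frame(group = group, z = pr$z, z_lo = pr$z_lo, z_hi = pr$z_hi,
             r = tanh(pr$z), r_lo = tanh(pr$z_lo), r_hi = tanh(pr$z_hi))
}

#' Rank meta-regression fits by AIC
#'
#' Orders REML fits of the same effect table by ascending AIC and reports
#' AIC differences. A warning notes that restricted likelihoods of models
#' with different fixed-effect structures are not strictly comparable.
#'
#' @param ... Two or more \code{"reml_meta"} fits, or a single list of them.
#' @param model_names Optional labels; defaults to the moderator formulas.
#' @return Data frame with one row per fit, ordered by AIC, with
#'   \code{delta_aic} relative to the best fit.
#' @export
compare_models <- function(..., model_names = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "reml_meta"))
    fits <- fits[[1]]
  if (length(fits) < 2)
    stop("need at least two fits to compare", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "reml_meta")))
    stop("all arguments must be 'reml_meta' fits", call. = FALSE)
  y0 <- fits[[1]]$yi; v0 <- fits[[1]]$vi
  same <- vapply(fits, function(f)
    isTRUE(all.equal(f$yi, y0)) && isTRUE(all.equal(f$vi, v0)), logical(1))
  if (!all(same))
    stop("fits were not produced from the same effect table", call. = FALSE)
  if (is.null(model_names))
    model_names <- vapply(fits, function(f) deparse(f$formula), character(1))
  out <- data.frame(model = model_names,
                    p = vapply(fits, function(f) f$p, numeric(1)),
                    tau2 = vapply(fits, function(f) f$tau2, numeric(1)),
                    I2 = vapply(fits, function(f) f$I2, numeric(1)),
                    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)))
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  warning("REML AICs of models with different fixed effects are not ",
          "strictly comparable; ranking is heuristic", call. = FALSE)
  out
}

#' @export
print.reml_meta <- function(x, digits = 4, ...) {
  cat("Random-effects meta-regression (REML)\n")
  cat("  moderators:", deparse(x$formula), "  (k =", x$k, "effects)\n")
  cat(sprintf("  tau^2 = %.*f, I^2 = %.1f%%, logLik = %.*f, AIC = %.*f\n",
              digits, x$tau2, x$I2, digits, x$loglik, digits, x$aic))
  print(round(cbind(estimate = x$coefficients, se = x$se, z = x$zval,
                    p = x$pval), digits))
  if (length(x$dropped))
    cat("  dropped non-estimable column(s):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.reml_meta <- function(object, ...) {
  crit <- 1.959964
  ct <- data.frame(estimate = object$coefficients, se = object$se,
                   z = object$zval, p = object$pval,
                   ci_lo = object$coefficients - crit * object$se,
                   ci_hi = object$coefficients + crit * object$se)
  structure(list(fit = object, coef_table = ct), class = "summary.reml_meta")
}

#' @export
print.summary.reml_meta <- function(x, digits = 4, ...) {
  f <- x$fit
  cat("Random-effects meta-regression (REML)\n")
  cat("  moderators:", deparse(f$formula), "\n")
  cat("  k =", f$k, "effects, p =", f$p, "fixed-effect coefficients\n\n")
  print(round(x$coef_table, digits))
  cat(sprintf("\n  tau^2 = %.*f (between-effect variance, z^2 units)\n",
              digits, f$tau2))
  cat(sprintf("  I^2   = %.2f%%\n", f$I2))
  cat(sprintf("  QE (residual heterogeneity) = %.3f, df = %d, p = %.4g\n",
              f$QE, f$QE_df, f$QE_p))
  cat(sprintf("  QM (omnibus moderators)     = %.3f, df = %d, p = %.4g\n",
              f$QM, f$QM_df, f$QM_p))
  cat(sprintf("  logLik (REML) = %.4f, AIC = %.4f\n", f$loglik, f$aic))
  if (length(f$dropped))
    cat("  dropped non-estimable column(s):",
        paste(f$dropped, collapse = ", "), "\n")
  invisible(x)
}
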