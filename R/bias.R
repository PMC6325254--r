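## Small-study / publication-bias diagnostics: a regression (Egger-type) test
## with the effect standard error entering the random-effects meta-regression
## as an extra moderator, and funnel-plot data for the residuals.

#' Egger-type regression test for funnel-plot asymmetry
#'
#' Augments the moderated random-effects meta-regression with each effect's
#' standard error as an additional fixed-effect moderator, refits by REML,
#' and tests the standard-error coefficient (Wald Z). This is the
#' "precision as moderator within the same random-effects model" variant,
#' appropriate when the asymmetry question is posed on a moderated model.
#'
#' @param table An \code{effect_table} with \code{z} and \code{se} columns.
#' @param moderators Moderator formula or named model, as in [reml_meta()].
#' @return Object of class \code{"egger_test"}: \code{slope} (the
#'   standard-error coefficient), \code{se}, \code{zval}, \code{pval}, and
#'   the augmented \code{fit}.
#' @examples
#' egger_test(table1_effects(), ~ group)
#' @export
egger_test <- function(table, moderators = ~ 1) {
  if (is.character(moderators)) moderators <- moderator_formula(moderators)
  if (!all(c("z", "se") %in% names(table)))
    stop("'table' must contain harmonized 'z' and 'se' columns", call. = FALSE)
  mt <- terms(moderators, data = table)
  X <- model.matrix(mt, stats::model.frame(mt, data = table))
  Xa <- cbind(X, precision_se = as.numeric(table$se))
  qa <- qr(Xa)
  if (qa$rank < ncol(Xa)) {
    dropped <- colnames(Xa)[qa$pivot[-seq_len(qa$rank)]]
    if ("precision_se" %in% dropped)
      stop("standard errors are collinear with the moderators (all equal?); ",
           "the asymmetry test is not defined", call. = FALSE)
  }
  core <- .reml_fit_core(as.numeric(table$z), as.numeric(table$se)^2, Xa)
  i <- match("precision_se", names(core$beta))
  out <- list(slope = unname(core$beta[i]), se = unname(core$se[i]),
              zval = unname(core$zval[i]), pval = unname(core$pval[i]),
              moderators = moderators, fit = core, k = core$k)
  class(out) <- "egger_test"
  out
}

#' @export
print.egger_test <- function(x, digits = 3, ...) {
  cat("Egger-type test for small-study asymmetry (SE as REML moderator)\n")
  cat("  base moderators:", deparse(x$moderators), "  (k =", x$k,
      "effects)\n")
  cat(sprintf("  slope = %.*f (SE %.*f), Z = %.*f, p = %.4g\n",
              digits, x$slope, digits, x$se, digits, x$zval, x$pval))
  invisible(x)
}

#' Funnel-plot data for a fitted meta-regression
#'
#' Residuals of each effect from the model-predicted Fisher-z, paired with
#' the effect's standard error, plus pseudo-confidence region boundaries:
#' at a given standard error the two-sided level-\eqn{\alpha} half-width is
#' \eqn{z_{crit} \sqrt{se^2 + \tau^2}}.
#'
#' @param fit A \code{"reml_meta"} fit.
#' @param table Optional \code{effect_table}; must be the table the fit was
#'   produced from (checked), defaults to the stored one.
#' @param levels Two-sided pseudo-confidence levels for the shaded regions.
#' @return Data frame with \code{effect_id}, \code{residual}, \code{se};
#'   attribute \code{"regions"} holds a data frame of \code{level} and
#'   \code{crit} (half-width multiplier), attribute \code{"tau2"} the fitted
#'   between-effect variance.
#' @export
funnel_data <- function(fit, table = NULL, levels = c(0.90, 0.95, 0.99)) {
  stopifnot(inherits(fit, "reml_meta"))
  if (is.null(table)) table <- fit$table
  if (nrow(table) != fit$k ||
      !isTRUE(all.equal(as.numeric(table$z), fit$yi)) ||
      !isTRUE(all.equal(as.numeric(table$se)^2, fit$vi)))
    stop("'table' does not match the table the fit was produced from",
         call. = FALSE)
  ids <- if ("effect_id" %in% names(table)) table$effect_id
         else paste0("effect_", seq_len(fit$k))
  out <- data.frame(effect_id = ids, residual = fit$residuals,
                    se = sqrt(fit$vi))
  attr(out, "regions") <- data.frame(level = levels,
                                     crit = qnorm(1 - (1 - levels) / 2))
  attr(out, "tau2") <- fit$tau2
  out
}

#' Funnel plot of meta-regression residuals
#'
#' Base-graphics funnel plot: residuals on the x axis, standard error on a
#' reversed y axis, with shaded pseudo-confidence regions whose half-widths
#' at standard error \eqn{se} are \eqn{z_{crit}\sqrt{se^2 + \tau^2}}.
#'
#' @param x A \code{"reml_meta"} fit.
#' @param levels Two-sided region levels (default 0.90, 0.95, 0.99).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, the [funnel_data()] frame.
#' @export
plot.reml_meta <- function(x, levels = c(0.90, 0.95, 0.99), ...) {
  fd <- funnel_data(x, levels = levels)
  tau2 <- attr(fd, "tau2")
  se_max <- max(fd$se) * 1.1
  se_grid <- seq(0, se_max, length.out = 100)
  crit <- sort(attr(fd, "regions")$crit, decreasing = TRUE)
  xmax <- max(abs(fd$residual), crit[1] * sqrt(se_max^2 + tau2))
  graphics::plot(NA, xlim = c(-xmax, xmax), ylim = rev(c(0, se_max)),
                 xlab = "residual (Fisher z)", ylab = "standard error", ...)
  ## bands, widest first: p < .01 boundary (dark), .05 (light), > .10 (white)
  shades <- c("grey55", "grey80", "white")
  for (j in seq_along(crit)) {
    hw <- crit[j] * sqrt(se_grid^2 + tau2)
    graphics::polygon(c(-hw, rev(hw)), c(se_grid, rev(se_grid)),
                      col = shades[min(j, length(shades))], border = NA)
  }
  graphics::abline(v = 0, lty = 2)
  graphics::points(fd$residual, fd$se, pch = 19)
  invisible(fd)
}
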