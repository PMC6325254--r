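## Harmonization of published correlation effects onto a signed Fisher-z scale.
##
## Conventions: positive harmonized z means "more of the dopamine measure goes
## with steeper discounting". Indices that *increase* with discounting (k,
## ln(k), proportion of smaller/sooner choices) keep their sign; indices that
## *decrease* with discounting (AUC, proportion of larger/high-effort choices)
## are flipped, as is a drug-occupancy correlate that is inversely related to
## the underlying binding measure.

.group_levels  <- c("healthy", "addiction", "other_psychopathology")
.tracer_levels <- c("d2_receptor", "da_synthesis", "dat")
.index_levels  <- c("k", "ln_k", "auc", "proportion_smaller",
                    "proportion_larger", "occupancy_correlate")
.flip_indices  <- c("auc", "proportion_larger", "occupancy_correlate")

#' Convert a t statistic to a correlation coefficient
#'
#' Recovers the correlation underlying a reported t test of a correlation or
#' single regression slope, \eqn{r = t / \sqrt{t^2 + df}}, preserving the sign
#' of \code{t}.
#'
#' @param t Numeric vector of t statistics.
#' @param df Degrees of freedom (same length as \code{t} or scalar); must be
#'   \eqn{\ge 1}.
#' @return Numeric vector of correlations with \eqn{|r| < 1}.
#' @examples
#' correlation_from_t(-3, 16)  # -0.6
#' @export
correlation_from_t <- function(t, df) {
  if (!is.numeric(t) || !is.numeric(df))
    stop("'t' and 'df' must be numeric", call. = FALSE)
  if (any(!is.finite(df)) || any(df < 1))
    stop("degrees of freedom must be finite and >= 1", call. = FALSE)
  sign(t) * sqrt(t^2 / (t^2 + df))
}

#' Fisher r-to-z transformation
#'
#' @param r Correlation(s), each strictly inside (-1, 1).
#' @return \code{atanh(r)}, the variance-stabilized effect size.
#' @examples
#' fisher_z(-0.700)
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) stop("'r' must be numeric", call. = FALSE)
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("correlations must satisfy |r| < 1", call. = FALSE)
  atanh(r)
}

#' Standard error of a Fisher-z effect
#'
#' Large-sample standard error \eqn{1/\sqrt{n - 3}}. The same convention is
#' applied to partial correlations (no degrees-of-freedom penalty for
#' covariates), matching the source tables this package reproduces.
#'
#' @param n Sample size(s), each \eqn{\ge 4}.
#' @return Standard error(s) on the z scale.
#' @examples
#' fisher_z_se(12)  # 0.333
#' @export
fisher_z_se <- function(n) {
  if (!is.numeric(n)) stop("'n' must be numeric", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 4))
    stop("sample sizes must be finite and >= 4 (SE = 1/sqrt(n - 3))",
         call. = FALSE)
  1 / sqrt(n - 3)
}

#' Align the sign of a Fisher-z effect with the discounting direction
#'
#' Returns \code{z_raw} unchanged for indices that increase with discounting
#' (\code{k}, \code{ln_k}, \code{proportion_smaller}) and \code{-z_raw} for
#' indices that decrease with discounting (\code{auc},
#' \code{proportion_larger}) or for an occupancy correlate inversely related
#' to the binding measure (\code{occupancy_correlate}). After alignment, a
#' positive z always means the dopamine measure increases with discounting.
#'
#' @param z_raw Fisher-z value(s) on the originally reported scale.
#' @param index Discounting index label(s); one of
#'   \code{"k"}, \code{"ln_k"}, \code{"auc"}, \code{"proportion_smaller"},
#'   \code{"proportion_larger"}, \code{"occupancy_correlate"}.
#' @return Sign-aligned Fisher-z value(s).
#' @export
sign_align <- function(z_raw, index) {
  index <- as.character(index)
  bad <- setdiff(unique(index), .index_levels)
  if (length(bad))
    stop("unknown discounting index: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ifelse(index %in% .flip_indices, -z_raw, z_raw)
}

#' Pool sub-condition correlations on the Fisher-z scale
#'
#' Approximates a full-task effect from several within-task sub-condition
#' correlations by averaging their Fisher-z transforms.
#'
#' @param rs Non-empty numeric vector of correlations, all \eqn{|r| < 1}.
#' @return A single pooled Fisher-z value.
#' @export
pool_subcondition_effects <- function(rs) {
  if (length(rs) == 0) stop("'rs' must be non-empty", call. = FALSE)
  mean(fisher_z(rs))
}

#' Partial correlation after residualizing on covariates
#'
#' Pearson correlation of the residuals of \code{x} and \code{y} after linear
#' projection onto the covariates plus an intercept. With no covariates this
#' reduces to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame of covariates
#'   (rows matching \code{x}); must have full column rank together with the
#'   intercept.
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ", call. = FALSE)
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.matrix(covariates) && ncol(covariates) == 0))
    return(stats::cor(x, y))
  Z <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (length(x) < ncol(Z) + 2)
    stop("too few observations for ", ncol(Z) - 1, " covariates",
         call. = FALSE)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    stop("covariate matrix is rank deficient", call. = FALSE)
  stats::cor(qr.resid(qz, x), qr.resid(qz, y))
}

.required_cols <- c("study_id", "group", "tracer_target", "region", "index",
                    "r", "t", "df", "n")

#' Load and harmonize a published effect-size table
#'
#' Reads a CSV/TSV of one row per published correlation effect, validates it,
#' derives the harmonized signed Fisher-z (\code{z}) and its standard error
#' (\code{se}), and returns an \code{effect_table}. Each row must carry either
#' a correlation \code{r} or a pair (\code{t}, \code{df}); if both are present
#' \code{r} is used and a warning is issued. Rows flagged \code{exclude=TRUE}
#' (e.g. a study reporting only a quadratic association) are dropped with a
#' message, never silently.
#'
#' @param path Path to a delimited text file with header columns
#'   \code{study_id, group, tracer_target, region, index, r, t, df, n} and
#'   optionally \code{exclude, note}.
#' @param schema Optional named character vector mapping the canonical column
#'   names above to the file's column names, e.g.
#'   \code{c(r = "effect_r", n = "sample_size")}.
#' @param sep Field separator; \code{","} (default) or \code{"\t"}.
#' @return An \code{effect_table}: a data frame of harmonized effects with
#'   derived \code{z} and \code{se} columns and leveled \code{group} /
#'   \code{tracer_target} factors (reference levels \code{healthy} and
#'   \code{d2_receptor}).
#' @seealso [table1_effects()] for the bundled meta-analysis fixture.
#' @export
load_effect_table <- function(path, schema = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           fill = TRUE, blank.lines.skip = TRUE)
  if (nrow(raw) == 0)
    stop("schema error: '", path, "' contains no effect rows", call. = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw))
        stop("schema error: mapped column '", schema[[canon]],
             "' not found in file", call. = FALSE)
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(.required_cols, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"exclude" %in% names(raw)) raw$exclude <- FALSE
  if (!"note" %in% names(raw)) raw$note <- ""
  raw$exclude <- as.logical(raw$exclude)
  raw$exclude[is.na(raw$exclude)] <- FALSE

  if (any(raw$exclude)) {
    message("excluding ", sum(raw$exclude), " flagged effect row(s): ",
            paste(raw$study_id[raw$exclude], collapse = ", "))
    raw <- raw[!raw$exclude, , drop = FALSE]
  }
  if (nrow(raw) == 0)
    stop("schema error: no effect rows remain after exclusions", call. = FALSE)
  as_effect_table(raw)
}

#' Construct an effect table from a data frame
#'
#' Validates a data frame of published effects (same columns as
#' [load_effect_table()]) and derives harmonized \code{z} and \code{se}.
#'
#' @param df Data frame of effects, one row per effect.
#' @return An \code{effect_table}.
#' @export
as_effect_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  problems <- character(0)
  note_row <- function(i, msg) sprintf("row %d (%s): %s", i,
                                       as.character(df$study_id[i]), msg)
  for (nm in c("r", "t", "df", "n"))
    if (!nm %in% names(df)) df[[nm]] <- NA_real_
  for (i in seq_len(nrow(df))) {
    has_r <- is.finite(suppressWarnings(as.numeric(df$r[i])))
    has_t <- is.finite(suppressWarnings(as.numeric(df$t[i]))) &&
             is.finite(suppressWarnings(as.numeric(df$df[i])))
    if (!has_r && !has_t)
      problems <- c(problems, note_row(i, "needs either r or (t, df)"))
    if (has_r && abs(as.numeric(df$r[i])) >= 1)
      problems <- c(problems, note_row(i, "|r| must be < 1"))
    n_i <- suppressWarnings(as.numeric(df$n[i]))
    if (!is.finite(n_i) || n_i < 4)
      problems <- c(problems, note_row(i, "n must be >= 4"))
    if (!df$group[i] %in% .group_levels)
      problems <- c(problems, note_row(i, paste0("unknown group '",
                                                 df$group[i], "'")))
    if (!df$tracer_target[i] %in% .tracer_levels)
      problems <- c(problems, note_row(i, paste0("unknown tracer_target '",
                                                 df$tracer_target[i], "'")))
    if (!df$index[i] %in% .index_levels)
      problems <- c(problems, note_row(i, paste0("unknown index '",
                                                 df$index[i], "'")))
  }
  if (length(problems))
    stop("schema error in effect table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  df$r <- as.numeric(df$r); df$t <- as.numeric(df$t)
  df$df <- as.numeric(df$df); df$n <- as.numeric(df$n)
  both <- is.finite(df$r) & is.finite(df$t)
  if (any(both))
    warning("both r and (t, df) supplied for row(s) ",
            paste(which(both), collapse = ", "), "; using r", call. = FALSE)
  use_t <- !is.finite(df$r)
  df$r[use_t] <- correlation_from_t(df$t[use_t], df$df[use_t])

  df$group <- factor(df$group, levels = .group_levels)
  df$tracer_target <- factor(df$tracer_target, levels = .tracer_levels)
  df$z <- sign_align(fisher_z(df$r), df$index)
  df$se <- fisher_z_se(df$n)
  df$effect_id <- make.unique(paste(df$study_id, df$group, sep = "."))
  rownames(df) <- NULL
  structure(df, class = c("effect_table", "data.frame"))
}

#' Bundled meta-analysis fixture: time-discounting PET effects
#'
#' Loads the package's bundled table of published time-discounting effects
#' (14 harmonized correlation effects from 7 studies of striatal dopamine PET
#' measures, including the present-study partial correlation), the dataset on
#' which all reproduction functions operate.
#'
#' @return An \code{effect_table} with 14 rows.
#' @examples
#' tab <- table1_effects()
#' table(tab$group)
#' @export
table1_effects <- function() {
  path <- system.file("extdata", "table1_time_effects.csv",
                      package = "metadisc", mustWork = TRUE)
  suppressMessages(load_effect_table(path))
}

#' Moderator design matrix for an effect table
#'
#' Builds the dummy-coded fixed-effect design for one of the four named
#' moderator structures. Reference levels (no column): \code{healthy} for
#' group, \code{d2_receptor} for tracer target.
#'
#' @param table An \code{effect_table}.
#' @param model One of \code{"intercept"}, \code{"group"}, \code{"tracer"},
#'   \code{"group_x_tracer"}.
#' @return Numeric design matrix with one row per effect.
#' @export
design_matrix <- function(table,
                          model = c("intercept", "group", "tracer",
                                    "group_x_tracer")) {
  model <- match.arg(model)
  stats::model.matrix(moderator_formula(model), data = table)
}

#' Moderator formula for a named meta-regression model
#'
#' @param model One of \code{"intercept"}, \code{"group"}, \code{"tracer"},
#'   \code{"group_x_tracer"}.
#' @return A one-sided formula over \code{group} and \code{tracer_target}.
#' @export
moderator_formula <- function(model = c("intercept", "group", "tracer",
                                        "group_x_tracer")) {
  model <- match.arg(model)
  switch(model,
         intercept      = ~ 1,
         group          = ~ group,
         tracer         = ~ tracer_target,
         group_x_tracer = ~ group * tracer_target)
}

#' @export
print.effect_table <- function(x, ...) {
  cat("Harmonized effect table: ", nrow(x), " effects from ",
      length(unique(x$study_id)), " studies\n", sep = "")
  cat("Groups: ", paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                        collapse = ", "), "\n", sep = "")
  print.data.frame(x[, c("study_id", "group", "tracer_target", "region",
                         "index", "r", "n", "z", "se")],
                   digits = 3, row.names = FALSE)
  invisible(x)
}
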