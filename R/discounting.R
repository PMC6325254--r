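## Hyperbolic discounting of delayed / risky / effortful rewards with a
## softmax choice rule. SV = R / (1 + k C), where C is the domain-specific
## cost: delay in days (time), odds against winning (1 - p)/p (probability),
## or proportion of maximum press rate (effort).

.domains <- c("time", "probability", "effort")

#' Domain-specific cost transform
#'
#' Maps a raw cost to the common cost scale entering the hyperbolic model:
#' identity for time (delay in days) and effort (proportion of maximum press
#' rate in (0, 1]); odds against winning \eqn{(1 - p)/p} for probability
#' (win probability in (0, 1]).
#'
#' @param raw Numeric vector of raw costs.
#' @param domain \code{"time"}, \code{"probability"}, or \code{"effort"}
#'   (scalar or vector).
#' @return Transformed cost(s) C \eqn{\ge 0}.
#' @examples
#' cost_transform(0.25, "probability")  # odds against = 3
#' @export
cost_transform <- function(raw, domain) {
  domain <- match.arg(as.character(domain), .domains, several.ok = TRUE)
  if (length(domain) == 1) domain <- rep(domain, length(raw))
  if (any(!is.finite(raw))) stop("costs must be finite", call. = FALSE)
  tm <- domain == "time"; pr <- domain == "probability"; ef <- domain == "effort"
  if (any(raw[tm] < 0)) stop("delays must be >= 0 days", call. = FALSE)
  if (any(raw[pr] <= 0 | raw[pr] > 1))
    stop("win probabilities must lie in (0, 1]", call. = FALSE)
  if (any(raw[ef] <= 0 | raw[ef] > 1))
    stop("effort proportions must lie in (0, 1]", call. = FALSE)
  out <- raw
  out[pr] <- (1 - raw[pr]) / raw[pr]
  out
}

#' Hyperbolic subjective value
#'
#' \eqn{SV = R / (1 + k C)} for reward magnitude R, transformed cost C and
#' discount rate k. Equals R when k = 0 or C = 0 and decreases in both k
#' and C.
#'
#' @param R Reward magnitude(s), currency units, \eqn{\ge 0}.
#' @param C Transformed cost(s), \eqn{\ge 0}.
#' @param k Discount rate \eqn{\ge 0} (per unit transformed cost).
#' @return Subjective value(s).
#' @export
subjective_value <- function(R, C, k) {
  if (any(R < 0) || any(C < 0) || any(k < 0))
    stop("'R', 'C' and 'k' must all be non-negative", call. = FALSE)
  R / (1 + k * C)
}

#' Validate trial-level two-option choice data
#'
#' A choice dataset holds trials of one cost domain in which a smaller reward
#' at a smaller cost is pitted against a larger reward at a larger cost.
#' Validation enforces \code{r_small < r_large}, domain-valid raw costs, and
#' strictly increasing transformed cost from the smaller- to the larger-cost
#' option.
#'
#' @param trials Data frame with columns \code{r_small}, \code{r_large},
#'   \code{cost_small}, \code{cost_large} and optionally \code{choice}
#'   (values \code{"smaller"} / \code{"larger"}, NA allowed).
#' @param domain Cost domain of all trials.
#' @param subject_id Label for the subject.
#' @return A \code{choice_dataset} (data frame with attributes
#'   \code{domain} and \code{subject_id}).
#' @export
choice_dataset <- function(trials, domain = c("time", "probability", "effort"),
                           subject_id = "s01") {
  domain <- match.arg(domain)
  trials <- as.data.frame(trials)
  need <- c("r_small", "r_large", "cost_small", "cost_large")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(trials) == 0) stop("trial list is empty", call. = FALSE)
  if (any(trials$r_small >= trials$r_large))
    stop("each trial needs r_small < r_large", call. = FALSE)
  cs <- cost_transform(trials$cost_small, domain)
  cl <- cost_transform(trials$cost_large, domain)
  if (any(cs >= cl))
    stop("transformed cost of the smaller-reward option must be strictly ",
         "below that of the larger-reward option on every trial",
         call. = FALSE)
  if (!"choice" %in% names(trials)) trials$choice <- NA_character_
  ok <- trials$choice %in% c("smaller", "larger") | is.na(trials$choice)
  if (!all(ok))
    stop("choices must be 'smaller', 'larger', or NA (rows ",
         paste(which(!ok), collapse = ", "), ")", call. = FALSE)
  structure(trials, domain = domain, subject_id = subject_id,
            class = c("choice_dataset", "data.frame"))
}

#' Softmax probability of choosing the smaller-cost option
#'
#' \eqn{P(\mathrm{smaller}) = \mathrm{logistic}(\beta\,(SV_s - SV_l))} with
#' softmax slope (inverse temperature) \eqn{\beta}. Equals 0.5 at
#' indifference or when the slope is 0.
#'
#' @param trials A \code{choice_dataset} or data frame of trials (see
#'   [choice_dataset()]).
#' @param k Discount rate \eqn{\ge 0}.
#' @param slope Softmax slope \eqn{\ge 0}, per currency unit of SV
#'   difference.
#' @param domain Cost domain; taken from \code{trials} if absent.
#' @return Vector of probabilities in (0, 1).
#' @export
choice_probability <- function(trials, k, slope, domain = NULL) {
  if (slope < 0) stop("'slope' must be >= 0", call. = FALSE)
  if (is.null(domain)) domain <- attr(trials, "domain")
  if (is.null(domain)) stop("cost 'domain' must be supplied", call. = FALSE)
  sv_s <- subjective_value(trials$r_small,
                           cost_transform(trials$cost_small, domain), k)
  sv_l <- subjective_value(trials$r_large,
                           cost_transform(trials$cost_large, domain), k)
  plogis(slope * (sv_s - sv_l))
}

## Bernoulli log-likelihood of observed choices, numerically stable.
.choice_loglik <- function(par, trials, domain, chose_smaller) {
  k <- par[1]; slope <- par[2]
  sv_s <- trials$r_small / (1 + k * trials$C_small)
  sv_l <- trials$r_large / (1 + k * trials$C_large)
  q <- slope * (sv_s - sv_l)
  sum(plogis(q[chose_smaller], log.p = TRUE)) +
    sum(plogis(-q[!chose_smaller], log.p = TRUE))
}

#' Fit the hyperbolic discounting model to one subject's choices
#'
#' Maximum-likelihood estimation of the discount rate k and softmax slope by
#' deterministic multistart bounded optimization (L-BFGS-B from a fixed
#' log-spaced grid of starting values; \eqn{k \in [0, k_{max}]},
#' \eqn{slope \in [0, s_{max}]}). Solutions on the box edge — including the
#' unidentifiable cases of one-sided choosing or a flat (slope 0)
#' likelihood — are flagged as boundary fits.
#'
#' @param data A \code{choice_dataset} with observed choices on every trial.
#' @param k_max,slope_max Upper box constraints (defaults 5 and 50).
#' @param n_starts Starts per parameter (default 8, i.e. an 8 x 8 grid).
#' @return Object of class \code{"discount_fit"}: \code{k}, \code{slope},
#'   \code{loglik}, \code{ln_k_plus_1} \eqn{= \log(k + 1)},
#'   \code{prop_smaller} (fraction of smaller-cost choices),
#'   \code{boundary} flag, and the data.
#' @examples
#' grid <- task_grid("time")
#' d <- generate_choice_dataset(grid, k = 0.01, slope = 0.5, seed = 7)
#' fit_discount(d)
#' @export
fit_discount <- function(data, k_max = 5, slope_max = 50, n_starts = 8) {
  stopifnot(inherits(data, "choice_dataset"))
  if (any(is.na(data$choice)))
    stop("all trials must have an observed choice", call. = FALSE)
  domain <- attr(data, "domain")
  tr <- as.data.frame(data)
  tr$C_small <- cost_transform(tr$cost_small, domain)
  tr$C_large <- cost_transform(tr$cost_large, domain)
  chose_smaller <- tr$choice == "smaller"
  one_sided <- length(unique(tr$choice)) == 1

  nll <- function(par) -.choice_loglik(par, tr, domain, chose_smaller)
  k_starts <- c(0, exp(seq(log(1e-4), log(k_max), length.out = n_starts - 1)))
  s_starts <- exp(seq(log(1e-2), log(slope_max), length.out = n_starts))
  best <- NULL
  for (k0 in k_starts) for (s0 in s_starts) {
    o <- suppressWarnings(
      optim(c(k0, s0), nll, method = "L-BFGS-B",
            lower = c(0, 0), upper = c(k_max, slope_max),
            control = list(maxit = 500)))
    if (is.null(best) || o$value < best$value - 1e-10) best <- o
  }
  k_hat <- best$par[1]; s_hat <- best$par[2]
  tol <- 1e-6
  ## if the fit does not beat a random responder (slope = 0, all p = 0.5) by
  ## a 2-df likelihood-ratio margin, the likelihood is flat and (k, slope)
  ## are not identifiable
  flat <- 2 * (-best$value - nrow(tr) * log(0.5)) < stats::qchisq(0.95, 2)
  edges <- c(if (k_hat <= tol) "k=0", if (k_hat >= k_max - tol) "k=k_max",
             if (s_hat <= tol) "slope=0",
             if (s_hat >= slope_max - tol) "slope=slope_max",
             if (flat) "flat_likelihood")
  boundary <- one_sided || length(edges) > 0
  if (one_sided)
    warning("all choices are identical; parameters are not jointly ",
            "identifiable (boundary fit)", call. = FALSE)
  out <- list(k = k_hat, slope = s_hat, loglik = -best$value,
              ln_k_plus_1 = log1p(k_hat),
              prop_smaller = mean(chose_smaller),
              boundary = boundary, boundary_edges = as.character(edges),
              n_trials = nrow(tr), domain = domain,
              subject_id = attr(data, "subject_id"),
              k_max = k_max, slope_max = slope_max, data = data)
  class(out) <- "discount_fit"
  out
}

#' Proportion of smaller-cost choices
#'
#' The model-free summary index: the fraction of trials on which the
#' smaller (less delayed / higher probability / lower effort) reward was
#' chosen.
#'
#' @param data A \code{choice_dataset} with observed choices.
#' @return A proportion in \eqn{[0, 1]}.
#' @export
summarize_choices <- function(data) {
  stopifnot(inherits(data, "choice_dataset"))
  ch <- data$choice[!is.na(data$choice)]
  if (length(ch) == 0) stop("no observed choices", call. = FALSE)
  mean(ch == "smaller")
}

#' @export
coef.discount_fit <- function(object, ...)
  c(k = object$k, slope = object$slope)

#' @export
logLik.discount_fit <- function(object, ...)
  structure(object$loglik, df = 2, nobs = object$n_trials, class = "logLik")

#' @export
fitted.discount_fit <- function(object, ...)
  choice_probability(object$data, object$k, object$slope)

#' @export
residuals.discount_fit <- function(object, ...) {
  obs <- as.numeric(object$data$choice == "smaller")
  obs - fitted(object)
}

#' @export
predict.discount_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  choice_probability(newdata, object$k, object$slope,
                     domain = attr(newdata, "domain") %||% object$domain)
}

#' Simulate choices from a fitted discounting model
#'
#' Draws Bernoulli choices on the fitted subject's own trials using the
#' estimated (k, slope).
#'
#' @param object A \code{"discount_fit"}.
#' @param nsim Number of simulated datasets.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return A list of \code{choice_dataset}s of length \code{nsim}.
#' @export
simulate.discount_fit <- function(object, nsim = 1, seed = NULL, ...) {
  .with_seed(seed, {
    p <- fitted(object)
    lapply(seq_len(nsim), function(i) {
      d <- object$data
      d$choice <- ifelse(rbinom(length(p), 1, p) == 1, "smaller", "larger")
      d
    })
  })
}

#' @export
print.discount_fit <- function(x, digits = 4, ...) {
  cat("Hyperbolic discounting fit (", x$domain, " domain, subject ",
      x$subject_id, ", ", x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  k = %.*g  (Ln(k+1) = %.*g),  softmax slope = %.*g\n",
              digits, x$k, digits, x$ln_k_plus_1, digits, x$slope))
  cat(sprintf("  logLik = %.*f,  proportion smaller-cost choices = %.3f\n",
              digits, x$loglik, x$prop_smaller))
  if (x$boundary)
    cat("  NOTE: boundary solution (",
        paste(x$boundary_edges, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Read a trial-level choice log
#'
#' Reads a CSV with columns \code{subject_id, domain, r_small, r_large,
#' cost_small, cost_large, choice} and returns one validated
#' \code{choice_dataset} per subject-domain combination.
#'
#' @param path Path to the CSV file.
#' @return Named list of \code{choice_dataset}s.
#' @export
read_choice_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "domain", "r_small", "r_large", "cost_small",
            "cost_large")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("choice log is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- interaction(raw$subject_id, raw$domain, drop = TRUE)
  lapply(split(raw, key), function(d)
    choice_dataset(d, domain = d$domain[1], subject_id = d$subject_id[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate expr with a temporarily seeded RNG, restoring state afterwards.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  expr
}
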