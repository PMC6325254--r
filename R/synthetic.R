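## Generators emulating (a) the three discounting tasks' factorial trial
## grids and (b) effect-size collections with known Fisher-z means, tau^2
## and moderator structure, so every pipeline stage has ground truth.

#' Factorial trial grid of a discounting task
#'
#' Encodes the cost structure of the three tasks. Time: the sooner reward is
#' available today / 2 weeks / 1 month against 2 weeks / 1 month / 6 weeks
#' (\code{variant = "young_adult"}, 84 trials) or today / 2 months / 4 months
#' against 2 / 4 / 6 months (\code{variant = "adult_lifespan"}, 82 trials),
#' with months counted as 30 days and weeks as 7. Probability: the higher win
#' probability is 0.50 / 0.75 / 1.00, the lower one 0.25 or 0.50 below it.
#' Effort: the smaller requirement is 35 / 55 / 75 percent of maximum press
#' rate, the larger 20 or 40 points above it. The smaller reward magnitude is
#' drawn 1--50 percent below the larger, which is drawn uniformly from
#' \code{magnitude_range} (currency units).
#'
#' @param domain \code{"time"}, \code{"probability"}, or \code{"effort"}.
#' @param variant Delay structure for the time task; ignored otherwise.
#' @param n_trials Trial count; defaults to the task's count (82, or 84 for
#'   the young-adult time variant).
#' @param magnitude_range Range of the larger reward magnitude.
#' @return Object of class \code{"task_grid"}.
#' @export
task_grid <- function(domain = c("time", "probability", "effort"),
                      variant = c("adult_lifespan", "young_adult"),
                      n_trials = NULL, magnitude_range = c(10, 50)) {
  domain <- match.arg(domain)
  variant <- match.arg(variant)
  pairs <- switch(domain,
    time = {
      lev <- if (variant == "young_adult")
        list(small = c(0, 14, 30), large = c(14, 30, 42))
      else
        list(small = c(0, 60, 120), large = c(60, 120, 180))
      g <- expand.grid(cost_small = lev$small, cost_large = lev$large)
      g[g$cost_small < g$cost_large, ]
    },
    probability = {
      g <- expand.grid(p_high = c(0.50, 0.75, 1.00), drop = c(0.25, 0.50))
      g$cost_small <- g$p_high          # higher win prob = lower cost
      g$cost_large <- g$p_high - g$drop
      g[g$cost_large > 0, c("cost_small", "cost_large")]
    },
    effort = {
      g <- expand.grid(cost_small = c(0.35, 0.55, 0.75), step = c(0.20, 0.40))
      g$cost_large <- g$cost_small + g$step
      g[g$cost_large <= 0.95 + 1e-12, c("cost_small", "cost_large")]
    })
  rownames(pairs) <- NULL
  if (is.null(n_trials))
    n_trials <- if (domain == "time" && variant == "young_adult") 84L else 82L
  structure(list(domain = domain, variant = variant,
                 pairs = pairs[, c("cost_small", "cost_large")],
                 n_trials = as.integer(n_trials),
                 magnitude_range = magnitude_range,
                 discount_range = c(0.01, 0.50)),
            class = "task_grid")
}

#' @export
print.task_grid <- function(x, ...) {
  cat("Task grid:", x$domain, "domain (", x$variant, "),", x$n_trials,
      "trials,", nrow(x$pairs), "cost pairs\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Simulate a choice dataset from known discounting parameters
#'
#' Draws trials from a task grid (cost pair uniform over the grid's factorial
#' pairs, larger magnitude uniform over the grid's magnitude range, smaller
#' magnitude 1--50 percent below it) and samples each choice Bernoulli with
#' the softmax probability under the hyperbolic model at the supplied
#' (k, slope). Deterministic given \code{seed}; the global RNG state is
#' restored afterwards.
#'
#' @param grid A [task_grid()].
#' @param k True discount rate \eqn{\ge 0}.
#' @param slope True softmax slope \eqn{\ge 0}.
#' @param seed Optional integer seed.
#' @param subject_id Label for the simulated subject.
#' @return A \code{choice_dataset} with observed choices.
#' @export
generate_choice_dataset <- function(grid, k, slope, seed = NULL,
                                    subject_id = "sim01") {
  stopifnot(inherits(grid, "task_grid"))
  if (k < 0 || slope < 0)
    stop("'k' and 'slope' must be >= 0", call. = FALSE)
  .with_seed(seed, {
    n <- grid$n_trials
    i <- sample.int(nrow(grid$pairs), n, replace = TRUE)
    r_large <- runif(n, grid$magnitude_range[1], grid$magnitude_range[2])
    disc <- runif(n, grid$discount_range[1], grid$discount_range[2])
    trials <- data.frame(r_small = r_large * (1 - disc), r_large = r_large,
                         cost_small = grid$pairs$cost_small[i],
                         cost_large = grid$pairs$cost_large[i])
    d <- choice_dataset(trials, domain = grid$domain,
                        subject_id = subject_id)
    p <- choice_probability(d, k, slope)
    d$choice <- ifelse(rbinom(n, 1, p) == 1, "smaller", "larger")
    d
  })
}

#' Simulate an effect-size collection with known structure
#'
#' Generates an \code{effect_table} of Fisher-z effects: per effect, a group
#' label drawn with the given proportions (or fixed counts), a sample size n
#' uniform on \code{n_range}, a true effect \eqn{\beta_{group} +
#' N(0, \tau^2)}, and an observed effect adding sampling noise
#' \eqn{N(0, 1/(n-3))}. Deterministic given \code{seed}.
#'
#' @param n_effects Number of effects.
#' @param true_betas Length-3 vector of true group means on the z scale,
#'   ordered healthy, addiction, other_psychopathology.
#' @param tau2 True between-effect variance \eqn{\ge 0}.
#' @param group_props Proportions over the three groups (summing to 1);
#'   ignored if \code{group_counts} is given.
#' @param group_counts Optional fixed counts per group (length 3, summing to
#'   \code{n_effects}).
#' @param n_range Integer range of per-effect sample sizes (lower bound
#'   \eqn{\ge 4}).
#' @param noise_scale Multiplier on the sampling noise standard deviation
#'   (0 turns sampling noise off; default 1).
#' @param seed Optional integer seed.
#' @return An \code{effect_table} accepted by [reml_meta()].
#' @export
generate_effect_collection <- function(n_effects,
                                       true_betas = c(0, 0, 0),
                                       tau2 = 0,
                                       group_props = c(0.5, 0.3, 0.2),
                                       group_counts = NULL,
                                       n_range = c(10, 30),
                                       noise_scale = 1,
                                       seed = NULL) {
  if (tau2 < 0) stop("'tau2' must be >= 0", call. = FALSE)
  if (n_range[1] < 4)
    stop("'n_range' lower bound must be >= 4", call. = FALSE)
  if (is.null(group_counts) && abs(sum(group_props) - 1) > 1e-8)
    stop("'group_props' must sum to 1", call. = FALSE)
  stopifnot(length(true_betas) == 3)
  .with_seed(seed, {
    grp <- if (!is.null(group_counts)) {
      stopifnot(length(group_counts) == 3, sum(group_counts) == n_effects)
      sample(rep(.group_levels, times = group_counts))
    } else {
      sample(.group_levels, n_effects, replace = TRUE, prob = group_props)
    }
    n <- n_range[1] +
      sample.int(n_range[2] - n_range[1] + 1, n_effects, replace = TRUE) - 1
    beta <- true_betas[match(grp, .group_levels)]
    z_true <- beta + rnorm(n_effects, 0, sqrt(tau2))
    z_obs <- z_true + rnorm(n_effects, 0, noise_scale / sqrt(n - 3))
    df <- data.frame(study_id = sprintf("sim%03d", seq_len(n_effects)),
                     group = grp, tracer_target = "d2_receptor",
                     region = "whole_striatum", index = "k",
                     r = tanh(z_obs), t = NA_real_, df = NA_real_, n = n,
                     exclude = FALSE, note = "synthetic",
                     stringsAsFactors = FALSE)
    as_effect_table(df)
  })
}
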