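test_that("cost transforms follow the domain conventions", {
  expect_equal(cost_transform(30, "time"), 30)
  expect_equal(cost_transform(1.0, "probability"), 0)
  expect_equal(cost_transform(0.5, "probability"), 1)
  expect_equal(cost_transform(0.25, "probability"), 3)
  expect_equal(cost_transform(0.55, "effort"), 0.55)
  expect_error(cost_transform(0, "probability"), "\\(0, 1\\]")
  expect_error(cost_transform(1.2, "effort"), "\\(0, 1\\]")
  expect_error(cost_transform(-1, "time"), ">= 0")
})

test_that("hyperbolic subjective value discounts as R/(1 + kC)", {
  expect_equal(subjective_value(10, 100, 0), 10)
  expect_equal(subjective_value(10, 100, 0.01), 5)
  expect_equal(subjective_value(20, 3, 0.5), 8)
  expect_equal(subjective_value(7, 0, 2), 7)
  C <- seq(0, 50, by = 5)
  expect_true(all(diff(subjective_value(10, C, 0.1)) < 0))
  ks <- seq(0, 2, by = 0.2)
  expect_true(all(diff(subjective_value(10, 5, ks)) < 0))
  expect_error(subjective_value(10, 5, -0.1), "non-negative")
})

test_that("softmax choice probabilities behave like a logistic in SV", {
  # one trial engineered so SV_small - SV_large = 1 at k = 0
  trial <- data.frame(r_small = 11, r_large = 10,
                      cost_small = 1, cost_large = 30)
  expect_equal(choice_probability(trial, k = 0, slope = log(3),
                                  domain = "time"), 0.75)
  expect_equal(choice_probability(trial, k = 0, slope = 0, domain = "time"),
               0.5)
  # indifference: equal subjective values
  tie <- data.frame(r_small = 10, r_large = 20,
                    cost_small = 0, cost_large = 100)
  expect_equal(choice_probability(tie, k = 0.01, slope = 3, domain = "time"),
               0.5)
  # P(smaller) + P(larger) = 1 exactly
  grid <- task_grid("probability")
  d <- generate_choice_dataset(grid, k = 1, slope = 0.4, seed = 5)
  p_small <- choice_probability(d, 1, 0.4)
  d_swap <- d
  d_swap[, c("r_small", "r_large")] <- d[, c("r_large", "r_small")]
  d_swap[, c("cost_small", "cost_large")] <- d[, c("cost_large", "cost_small")]
  p_large <- choice_probability(d_swap, 1, 0.4)
  expect_equal(p_small + p_large, rep(1, nrow(d)))
  expect_true(all(p_small > 0 & p_small < 1))
})

test_that("the MLE matches an exhaustive 2-D likelihood grid oracle", {
  cases <- list(list(domain = "time", k = 0.01, slope = 0.5, seed = 11),
                list(domain = "probability", k = 1.2, slope = 0.6, seed = 12),
                list(domain = "effort", k = 0.8, slope = 0.7, seed = 13))
  for (cs in cases) {
    d <- generate_choice_dataset(task_grid(cs$domain), cs$k, cs$slope,
                                 seed = cs$seed)
    fit <- fit_discount(d)
    oracle <- oracle_discount_grid(d)
    # optimizer must do at least as well as the best grid cell...
    expect_gte(fit$loglik, oracle$loglik - 1e-6)
    # ...and land within one (log-spaced) grid cell of its argmax
    expect_true(fit$k >= oracle$k / oracle$k_ratio - 1e-4 &&
                  fit$k <= oracle$k * oracle$k_ratio + 1e-4,
                label = paste(cs$domain, "k within one oracle cell"))
    expect_true(fit$slope >= oracle$slope / oracle$slope_ratio - 1e-3 &&
                  fit$slope <= oracle$slope * oracle$slope_ratio + 1e-3,
                label = paste(cs$domain, "slope within one oracle cell"))
    expect_equal(fit$ln_k_plus_1, log(fit$k + 1), tolerance = 1e-12)
  }
})

test_that("one-sided and flat-likelihood fits are flagged as boundary", {
  grid <- task_grid("time")
  d <- generate_choice_dataset(grid, k = 0, slope = 50, seed = 3)
  # k = 0 with a steep slope: the larger-later reward dominates every trial
  expect_true(all(d$choice == "larger"))
  expect_warning(fit <- fit_discount(d), "identical")
  expect_true(fit$boundary)
  expect_equal(fit$k, 0, tolerance = 1e-6)
  expect_equal(fit$prop_smaller, 0)

  # slope 0 generates coin-flip choices: flat likelihood, not identifiable
  d0 <- generate_choice_dataset(grid, k = 0.05, slope = 0, seed = 4)
  fit0 <- fit_discount(d0)
  expect_true(fit0$boundary)
  expect_true("flat_likelihood" %in% fit0$boundary_edges ||
                "slope=0" %in% fit0$boundary_edges)
})

test_that("expected smaller-cost share rises strictly with the true rate", {
  grid <- task_grid("time")
  d <- generate_choice_dataset(grid, k = 0.01, slope = 0.5, seed = 21)
  # over the range the task's subjects occupy (k of order 0.01); with both
  # options delayed the SV difference is not globally monotone in k (both
  # SVs collapse toward zero), so the expected share peaks near k = 0.03 on
  # this grid and then declines slowly
  ks <- c(0, 0.001, 0.002, 0.005, 0.01, 0.02)
  expected_share <- sapply(ks, function(k)
    mean(choice_probability(d, k, slope = 0.5)))
  expect_true(all(diff(expected_share) > 0))
})

test_that("choice summaries count smaller-cost selections", {
  grid <- task_grid("time")
  d <- generate_choice_dataset(grid, k = 0.02, slope = 0.5, seed = 31)
  expect_equal(summarize_choices(d), mean(d$choice == "smaller"))
  d$choice <- rep("smaller", nrow(d))
  expect_equal(summarize_choices(d), 1)
  d$choice <- rep("larger", nrow(d))
  expect_equal(summarize_choices(d), 0)
  d$choice[seq_len(41)] <- "smaller"
  expect_equal(summarize_choices(d), 0.5)
})

test_that("dataset validation enforces magnitude and cost ordering", {
  bad <- data.frame(r_small = 10, r_large = 9, cost_small = 1,
                    cost_large = 30)
  expect_error(choice_dataset(bad, "time"), "r_small < r_large")
  bad2 <- data.frame(r_small = 9, r_large = 10, cost_small = 30,
                     cost_large = 30)
  expect_error(choice_dataset(bad2, "time"), "strictly below")
  bad3 <- data.frame(r_small = 9, r_large = 10, cost_small = 1,
                     cost_large = 30, choice = "maybe")
  expect_error(choice_dataset(bad3, "time"), "choices must be")
})

test_that("fit methods expose coefficients, likelihood and simulation", {
  grid <- task_grid("effort")
  d <- generate_choice_dataset(grid, k = 0.5, slope = 1, seed = 41)
  fit <- fit_discount(d)
  expect_named(coef(fit), c("k", "slope"))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(length(fitted(fit)), nrow(d))
  expect_true(all(abs(residuals(fit)) <= 1))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$choice %in% c("smaller", "larger")))
  sims_again <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sims[[1]]$choice, sims_again[[1]]$choice)
})

test_that("choice logs round-trip through CSV per subject", {
  grid <- task_grid("time")
  d1 <- generate_choice_dataset(grid, 0.01, 0.5, seed = 51, subject_id = "a")
  d2 <- generate_choice_dataset(grid, 0.10, 0.5, seed = 52, subject_id = "b")
  log_df <- rbind(cbind(subject_id = "a", domain = "time",
                        as.data.frame(d1)),
                  cbind(subject_id = "b", domain = "time",
                        as.data.frame(d2)))
  path <- tempfile(fileext = ".csv")
  write.csv(log_df, path, row.names = FALSE)
  sets <- read_choice_log(path)
  expect_length(sets, 2)
  expect_equal(nrow(sets[[1]]), 82)
  expect_equal(sort(unname(vapply(sets, attr, "", "subject_id"))),
               c("a", "b"))
})
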