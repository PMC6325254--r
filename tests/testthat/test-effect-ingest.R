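test_that("t-to-r conversion is exact, odd in t, and monotone in |t|", {
  expect_equal(correlation_from_t(0, 20), 0)
  expect_equal(correlation_from_t(1, 1), sqrt(0.5))
  expect_equal(correlation_from_t(-3, 16), -0.6)
  ts <- seq(-6, 6, by = 0.5)
  expect_equal(correlation_from_t(-ts, 11), -correlation_from_t(ts, 11))
  r_abs <- correlation_from_t(seq(0.1, 10, by = 0.1), 25)
  expect_true(all(diff(r_abs) > 0))
  expect_true(all(abs(correlation_from_t(ts, 7)) < 1))
  expect_error(correlation_from_t(2, 0.5), "degrees of freedom")
})

test_that("Fisher transform matches published conversions and round-trips", {
  expect_equal(fisher_z(-0.700), -0.867, tolerance = 0.001)
  expect_equal(fisher_z(0.640), 0.758, tolerance = 0.001)
  expect_equal(fisher_z(0), 0)
  r <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("Fisher-z standard errors follow 1/sqrt(n - 3)", {
  expect_lt(abs(fisher_z_se(12) - 0.333), 0.001)
  expect_lt(abs(fisher_z_se(27) - 0.204), 0.001)
  expect_equal(fisher_z_se(4), 1.0)
  expect_equal(fisher_z_se(c(10, 109)), 1 / sqrt(c(7, 106)))
  expect_error(fisher_z_se(3), ">= 4")
})

test_that("sign alignment flips exactly the discounting-decreasing indices", {
  expect_equal(sign_align(atanh(0.650), "auc"), -0.775, tolerance = 0.001)
  expect_equal(sign_align(-0.356, "ln_k"), -0.356)
  expect_equal(sign_align(0, "proportion_larger"), 0)
  keep <- c("k", "ln_k", "proportion_smaller")
  flip <- c("auc", "proportion_larger", "occupancy_correlate")
  expect_equal(sign_align(rep(0.4, 3), keep), rep(0.4, 3))
  expect_equal(sign_align(rep(0.4, 3), flip), rep(-0.4, 3))
  # flipping twice with the same index is the identity
  z <- rnorm(6)
  idx <- c(keep, flip)
  expect_equal(sign_align(sign_align(z, idx), idx), z)
  expect_error(sign_align(0.2, "gini"), "unknown discounting index")
})

test_that("sub-condition pooling averages on the Fisher-z scale", {
  expect_equal(pool_subcondition_effects(c(0.3, 0.3, 0.3)), atanh(0.3))
  expect_equal(pool_subcondition_effects(c(0.5, -0.5)), 0)
  expect_equal(pool_subcondition_effects(c(0.1, 0.2, 0.3)),
               mean(atanh(c(0.1, 0.2, 0.3))))
  expect_equal(pool_subcondition_effects(c(0.1, 0.2, 0.3)), 0.2042,
               tolerance = 5e-4)
  expect_error(pool_subcondition_effects(numeric(0)), "non-empty")
})

test_that("partial correlation matches a brute-force residualization oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    q <- sample(1:3, 1)
    Z <- matrix(rnorm(n * q), n, q)
    x <- rnorm(n) + Z %*% rnorm(q)
    y <- rnorm(n) + Z %*% rnorm(q)
    expect_equal(partial_correlation(x, y, Z), oracle_partial_cor(x, y, Z),
                 tolerance = 1e-10)
  }
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  expect_equal(partial_correlation(x, y), cor(x, y))
  expect_equal(partial_correlation(x, x, cbind(z)), 1)
  expect_error(partial_correlation(x, y, cbind(z, z)), "rank deficient")
})

test_that("the bundled table loads to 14 harmonized effects from 7 studies", {
  path <- system.file("extdata", "table1_time_effects.csv",
                      package = "metadisc")
  expect_message(tab <- load_effect_table(path), "excluding 1")
  expect_s3_class(tab, "effect_table")
  expect_equal(nrow(tab), 14)
  expect_equal(length(unique(tab$study_id)), 7)
  expect_equal(as.vector(table(tab$group)), c(7, 4, 3))
  expect_equal(levels(tab$group),
               c("healthy", "addiction", "other_psychopathology"))
  expect_true(all(tab$se > 0))
  expect_equal(tab$se, 1 / sqrt(tab$n - 3), tolerance = 1e-12)
})

test_that("recomputed z and SE reproduce the printed table row-for-row", {
  tab <- table1_effects()
  ref <- printed_table1()
  for (i in seq_len(nrow(ref))) {
    expect_lt(abs(tab$z[i] - ref$z[i]), ref$tol_z[i] + 1e-9,
              label = sprintf("|z[%d] - printed|", i))
    expect_lt(abs(tab$se[i] - ref$se[i]), 0.001,
              label = sprintf("|se[%d] - printed|", i))
  }
})

test_that("the loader rejects malformed tables with row-level diagnostics", {
  empty <- tempfile(fileext = ".csv")
  writeLines("study_id,group,tracer_target,region,index,r,t,df,n", empty)
  expect_error(load_effect_table(empty), "no effect rows")

  df <- minimal_effects()
  expect_error(load_effect_table(write_fixture_csv(df[, -match("n", names(df))])),
               "missing required column")

  bad <- df; bad$r[2] <- 1.5
  expect_error(suppressWarnings(load_effect_table(write_fixture_csv(bad))),
               "row 2.*\\|r\\| must be < 1")

  bad <- df; bad$n[3] <- 3
  expect_error(load_effect_table(write_fixture_csv(bad)), "row 3.*n must be")

  bad <- df; bad$group[4] <- "patients"
  expect_error(load_effect_table(write_fixture_csv(bad)), "unknown group")

  bad <- df; bad$r[1] <- NA
  expect_error(load_effect_table(write_fixture_csv(bad)),
               "needs either r or \\(t, df\\)")
})

test_that("r wins with a warning when both r and (t, df) are given", {
  df <- minimal_effects()
  df$t[1] <- 2.5; df$df[1] <- 18
  expect_warning(tab <- load_effect_table(write_fixture_csv(df)), "using r")
  expect_equal(tab$z[1], atanh(df$r[1]))
})

test_that("t statistics are converted when r is absent", {
  df <- minimal_effects()
  df$r[1] <- NA; df$t[1] <- -3; df$df[1] <- 16
  tab <- load_effect_table(write_fixture_csv(df))
  expect_equal(tab$r[1], -0.6)
  expect_equal(tab$z[1], atanh(-0.6))
})

test_that("schema mapping renames file columns to the canonical names", {
  df <- minimal_effects()
  names(df)[names(df) == "r"] <- "effect_r"
  tab <- load_effect_table(write_fixture_csv(df), schema = c(r = "effect_r"))
  expect_equal(nrow(tab), nrow(df))
  expect_error(load_effect_table(write_fixture_csv(df),
                                 schema = c(r = "nope")),
               "schema error")
})

test_that("design matrices dummy-code with healthy/D2 reference levels", {
  tab <- table1_effects()
  X <- design_matrix(tab, "group")
  expect_equal(colnames(X), c("(Intercept)", "groupaddiction",
                              "groupother_psychopathology"))
  expect_true(all(X[, -1] %in% c(0, 1)))
  expect_equal(nrow(X), nrow(tab))
  expect_equal(ncol(design_matrix(tab, "intercept")), 1)
  Xt <- design_matrix(tab, "tracer")
  expect_false("tracer_targetd2_receptor" %in% colnames(Xt))
})
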