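# Brute-force Holm oracle: reject while p_(i) <= alpha / (m - i + 1); the
# adjusted p equals the smallest alpha at which each hypothesis is rejected.
holm_oracle_reject <- function(p, alpha) {
  o <- order(p)
  m <- length(p)
  rej <- logical(m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) rej[o[i]] <- TRUE else break
  }
  rej
}

test_that("Holm adjustment equals the step-down oracle and p.adjust", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(60)
  for (r in 1:50) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    adj <- holm_adjust(p)
    expect_equal(adj, p.adjust(p, "holm"), tolerance = 1e-12)
    for (alpha in c(0.01, 0.05, 0.1, 0.5))
      expect_identical(adj <= alpha, holm_oracle_reject(p, alpha))
  }
})

test_that("trial tables collapse or drop categories per model", {
  rows <- data.frame(
    patient = "P1", group = "O", hemisphere = "L", region = "amygdala",
    channel = "AM1", trial = 1:12,
    category = rep(c("caucasian", "dark_skinned", "famous", "veiled",
                     "masks", "mosaic"), 2),
    peak = "N240", amplitude_uV = rnorm(12))
  t1 <- build_trial_table(rows, model = 1)
  expect_equal(levels(t1$category), c("mosaic", "face"))
  expect_equal(nrow(t1), 12)
  expect_equal(sum(t1$category == "face"), 10)
  t2 <- build_trial_table(rows, model = 2)
  expect_equal(nrow(t2), 10)
  expect_equal(nlevels(t2$category), 5)
  rows$patient <- NA
  expect_error(build_trial_table(rows), "missing metadata")
})

test_that("degenerate random effects collapse to ordinary regression", {
  set.seed(61)
  n <- 120
  rows <- data.frame(
    patient = rep(paste0("P", 1:6), each = n / 6),
    group = rep(c("O", "M"), each = n / 2),
    hemisphere = "L", region = "amygdala", channel = "A",
    category = sample(c("mosaic", "famous"), n, TRUE),
    gamma_db = rnorm(n))
  rows$gamma_db <- rows$gamma_db + 2 * (rows$group == "O")
  tab <- build_trial_table(rows, model = 1)
  ft <- suppressWarnings(suppressMessages(fit_lme(tab)))
  lmfit <- lm(value ~ group + category + group:category, data = tab)
  bsel <- grep("^groupO$", ft$coefficients$coef)
  expect_equal(ft$coefficients$beta[bsel], coef(lmfit)[["groupO"]],
               tolerance = 0.05)
  ## row order does not change the estimates
  ft2 <- suppressWarnings(suppressMessages(
    fit_lme(tab[sample(nrow(tab)), ])))
  expect_equal(ft2$coefficients$beta, ft$coefficients$beta,
               tolerance = 1e-6)
  ## Holm column dominates the raw p-values
  expect_true(all(ft$terms$p_holm >= ft$terms$p_raw - 1e-12))
})

test_that("responsiveness flags follow the injected effect type", {
  set.seed(62)
  erp_only <- data.frame(category = "famous",
                         peak = rep(c("N110", "N240", "N360"), each = 60),
                         amplitude_uV = c(rnorm(60, 6), rnorm(120, 0)))
  gam_null <- data.frame(category = "famous", gamma_db = rnorm(60, 0))
  fl <- classify_responsive(erp_only, gam_null)
  expect_true(fl$erp_responsive)
  expect_false(fl$gamma_responsive)
  gam_only <- data.frame(category = "famous", gamma_db = rnorm(60, 2))
  fl2 <- classify_responsive(data.frame(
    category = "famous", peak = rep(c("N110", "N240", "N360"), each = 60),
    amplitude_uV = rnorm(180, 0)), gam_only)
  expect_true(fl2$gamma_responsive)
  ## pure-noise contacts trip each flag at roughly its nominal error rate
  flags <- t(replicate(40, unlist(classify_responsive(
    data.frame(category = "famous",
               peak = rep(c("N110", "N240", "N360"), each = 60),
               amplitude_uV = rnorm(180, 0)),
    data.frame(category = "famous", gamma_db = rnorm(60, 0))))))
  expect_lte(mean(flags[, "erp_responsive"]), 0.2)
  expect_lte(mean(flags[, "gamma_responsive"]), 0.2)
  expect_error(classify_responsive(gam_only[0, ], gam_only), "face trials")
})
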