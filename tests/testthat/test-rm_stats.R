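test_that("degenerate table: all means equal the constant, F = 0", {
  tab <- make_mpp_table(n_per_dose = 3, cell_means = matrix(42, 2, 3),
                        sd_animal = 0, sd_resid = 0)
  fit <- fit_rm_anova(tab)
  expect_true(all(fit$means$mean == 42))
  expect_true(all(fit$omnibus$F == 0))
  expect_false(fit$omnibus_significant)
  expect_error(check_residual_normality(fit), "degenerate")
  # and no comparison can be flagged
  cmp <- lsd_compare(fit, "E1", 1)
  expect_false(cmp$significant)
})

test_that("two doses, one epoch: F = t^2 and LSD p = pooled t-test p", {
  tab <- make_mpp_table(n_per_dose = 8, doses = c(0, 1), epochs = "E1",
                        cell_means = matrix(c(70, 60), 2, 1), seed = 2)
  fit <- fit_rm_anova(tab)
  tt <- t.test(mpp ~ dose, tab, var.equal = TRUE)
  Fd <- fit$omnibus$F[fit$omnibus$term == "dose"]
  expect_equal(Fd, unname(tt$statistic)^2, tolerance = 1e-8)
  cmp <- lsd_compare(fit, "E1", 1, 0)
  expect_equal(cmp$p, tt$p.value, tolerance = 1e-8)
  expect_equal(abs(cmp$t), abs(unname(tt$statistic)), tolerance = 1e-8)
  expect_equal(cmp$df, 14)
  # model-based means equal raw cell means in the balanced design
  raw <- aggregate(mpp ~ dose, tab, mean)
  expect_equal(fit$means$mean, raw$mpp, tolerance = 1e-10)
})

test_that("mixed fit: cell means, pooled SEs, self-comparison, lookups", {
  mu <- rbind(c(32, 79, 66), c(32, 79, 55))
  tab <- make_mpp_table(n_per_dose = 6, doses = c(0, 1),
                        epochs = c("B", "H1", "E1"), cell_means = mu, seed = 3)
  fit <- fit_rm_anova(tab)
  expect_equal(nrow(fit$means), 2 * 3)            # doses x epochs
  expect_true(all(fit$means$se > 0))
  expect_length(fit$residuals, nrow(tab))
  raw <- aggregate(mpp ~ dose + epoch, tab, mean)
  m <- merge(fit$means, raw, by = c("dose", "epoch"))
  expect_equal(m$mean, m$mpp, tolerance = 1e-6)   # balanced: model = raw means
  self <- lsd_compare(fit, "E1", 1, 1)
  expect_identical(self$diff, 0); expect_identical(self$p, 1)
  expect_error(lsd_compare(fit, "E4", 1), "epoch not in fit")
  expect_error(lsd_compare(fit, "E1", 99), "dose not in fit")
  nr <- check_residual_normality(fit)
  expect_true(nr$W > 0 && nr$W <= 1)
  expect_true(nr$p_value >= 0 && nr$p_value <= 1)
  expect_identical(nrow(nr$qq), nrow(tab))
})

test_that("validation: unbalanced and malformed tables are rejected", {
  tab <- make_mpp_table(n_per_dose = 3)
  expect_error(fit_rm_anova(tab[-1, ]), "unbalanced")
  tab2 <- tab; tab2$dose[1] <- 99    # animal in two dose groups
  expect_error(fit_rm_anova(tab2), "more than one dose")
  expect_error(fit_rm_anova(tab[tab$dose == 0, ]), ">= 2 doses")
  expect_error(fit_rm_anova(tab[, -1]), "missing column")
  one <- make_mpp_table(n_per_dose = 1)
  expect_error(fit_rm_anova(one), ">= 2 animals|unbalanced")
  bad <- tab; bad$epoch[1] <- "Z9"
  expect_error(fit_rm_anova(bad), "unknown epoch")
})

test_that("fit outputs are invariant to row permutation", {
  tab <- make_mpp_table(n_per_dose = 4, seed = 9)
  fit1 <- fit_rm_anova(tab)
  set.seed(1)
  fit2 <- fit_rm_anova(tab[sample(nrow(tab)), ])
  expect_identical(fit1$means, fit2$means)
  expect_identical(fit1$omnibus, fit2$omnibus)
  expect_identical(fit1$residuals, fit2$residuals)
  expect_identical(lsd_compare(fit1, "E1", 1)[], lsd_compare(fit2, "E1", 1)[])
})

test_that("LSD p-values are calibrated on Gaussian null tables", {
  # null: no dose effect anywhere; 200 simulated tables
  ps <- vapply(1:200, function(seed) {
    tab <- make_mpp_table(n_per_dose = 12, doses = c(0, 1, 2, 3),
                          epochs = c("B", "H1", "H2", "E1", "E2"),
                          cell_means = matrix(79, 4, 5), sd_animal = 7,
                          sd_resid = 2, seed = 6000 + seed)
    fit <- fit_rm_anova(tab)
    c(lsd_compare(fit, "E1", 3)$p, lsd_compare(fit, "E1", 3)$significant)
  }, numeric(2))
  expect_equal(mean(ps[1, ] <= 0.05), 0.05, tolerance = 0.03 / 0.05)
  expect_lte(mean(ps[2, ]), 0.07)   # protected LSD
})

test_that("Shapiro-Wilk diagnostics have level and power", {
  pn <- vapply(1:100, function(i) {
    set.seed(3000 + i); shapiro.test(rnorm(300))$p.value
  }, numeric(1))
  expect_gte(mean(pn >= 0.05), 0.90)
  pe <- vapply(1:100, function(i) {
    set.seed(4000 + i); shapiro.test(rexp(300))$p.value
  }, numeric(1))
  expect_gte(mean(pe <= 0.05), 0.99)
  # smoke case: symmetric 3-point sample through the report path
  tab <- make_mpp_table(n_per_dose = 2, doses = c(0, 1), epochs = "E1",
                        sd_animal = 0, sd_resid = 1, seed = 5)
  fit <- fit_rm_anova(tab)
  nr <- check_residual_normality(fit)
  expect_true(nr$p_value > 0 && nr$p_value < 1)
})

test_that("E1 cell means order with dose in simulated WT alcohol cohorts", {
  # averaged over 20 seeds: vehicle ~ 0.40 > 0.50 > 0.575 g/kg
  sched <- epoch_schedule(c("B", "H1", "E1"), 60)
  e1_means <- sapply(1:20, function(seed) {
    d <- cohort_design(drug_model("alcohol"), list(genotype("WT")),
                       group_sizes = 6, schedule = sched, master_seed = seed)
    tab <- mpp_table(simulate_cohort(d)$traces)
    fit <- fit_rm_anova(tab)
    m <- fit$means[fit$means$epoch == "E1", ]
    m$mean[order(m$dose)]
  })
  avg <- rowMeans(e1_means)
  expect_gt(avg[1], avg[3] + 3)   # vehicle >> 0.50
  expect_gt(avg[2], avg[3] + 3)   # 0.40 ~ vehicle, >> 0.50
  expect_gt(avg[3], avg[4] + 3)   # 0.50 > 0.575
  expect_lt(abs(avg[1] - avg[2]), 5)  # 0.40 near-null
})

test_that("summarize_experiment formats comparisons and stars", {
  mu <- rbind(c(32, 79, 79), c(32, 79, 55))
  tab <- make_mpp_table(n_per_dose = 8, doses = c(0, 1),
                        epochs = c("B", "H1", "E1"), cell_means = mu,
                        sd_animal = 3, sd_resid = 2, seed = 8)
  fit <- fit_rm_anova(tab)
  cmp <- list(lsd_compare(fit, "E1", 1))
  out <- summarize_experiment(fit, cmp)
  expect_identical(nrow(out), 1L)
  expect_true(out$significant)
  expect_identical(out$stars, "***")
  expect_equal(out$mean,
               fit$means$mean[fit$means$dose == 1 & fit$means$epoch == "E1"])
  # empty comparison list -> header-only table
  empty <- summarize_experiment(fit, list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("epoch", "dose", "p", "stars") %in% names(empty)))
  # constant table -> nothing significant
  const <- make_mpp_table(n_per_dose = 3, cell_means = matrix(10, 2, 3),
                          sd_animal = 0, sd_resid = 0)
  cfit <- fit_rm_anova(const)
  csum <- summarize_experiment(cfit, list(lsd_compare(cfit, "E1", 1)))
  expect_false(any(csum$significant))
  expect_true(all(csum$stars == ""))
})
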