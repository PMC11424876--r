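test_that("power-model slope is exact on noise-free power-law data", {
  d <- c(2, 6, 12, 24)
  f1 <- fit_power_model(d, 2 * d, "y")
  expect_equal(f1$beta, 1, tolerance = 1e-12)
  expect_equal(f1$beta_se, 0, tolerance = 1e-10)
  f2 <- fit_power_model(d, 5 * sqrt(d), "y")
  expect_equal(f2$beta, 0.5, tolerance = 1e-12)
})

test_that("degenerate inputs to the power model are rejected", {
  expect_error(fit_power_model(c(2, 2, 2), c(1, 2, 3)), "rank deficiency")
  expect_error(fit_power_model(c(2, 6, 12), c(1, -2, 3)), "positive")
  expect_error(fit_power_model(c(2, 6), c(1, 2)), ">= 3")
})

test_that("group-geomean fit reproduces the published slope point estimates", {
  tab <- nh130_group_summary()
  beta <- function(col) {
    round(fit_power_model_from_summaries(tab$dose_mg, tab[[col]], tab$n)$beta, 2)
  }
  expect_equal(beta("cmax_geomean"), 0.97)
  expect_equal(beta("auc_0t_geomean"), 1.04)
  expect_equal(beta("auc_0inf_geomean"), 1.02)
  flat <- fit_power_model_from_summaries(c(2, 6, 12), c(4, 4, 4), c(8, 8, 8))
  expect_equal(flat$beta, 0, tolerance = 1e-12)
})

test_that("summary-level and individual-level slopes agree to machine precision", {
  groups <- generate_cohort(cohort_spec(seed = 17))
  res <- suppressWarnings(nca_study(groups))
  s <- suppressWarnings(summarize_group(res))
  for (p in c("cmax", "auc_0t")) {
    ind <- fit_power_model(res$dose_mg, res[[p]], p)
    grp <- fit_power_model_from_summaries(s$dose_mg, s[[paste0(p, "_geomean")]],
                                          s$n, p)
    expect_equal(ind$beta, grp$beta, tolerance = 1e-10)
  }
})

test_that("acceptance range follows the rescaled bioequivalence limits", {
  r45 <- acceptance_range(0.8, 1.25, 45)
  expect_equal(round(r45$low, 2), 0.94)
  expect_equal(round(r45$high, 2), 1.06)
  re <- acceptance_range(0.5, 2, exp(1))
  expect_equal(re$low, 1 + log(0.5))
  expect_equal(re$high, 1 + log(2))
  # theta_l * theta_h = 1 gives symmetry about 1
  expect_equal(r45$low + r45$high, 2)
  expect_error(acceptance_range(0.8, 1.25, 1), "r must be > 1")
  expect_error(acceptance_range(1.2, 1.25, 45), "theta")
})

test_that("acceptance range narrows with the dose ratio and collapses to 1", {
  widths <- sapply(c(2, 10, 45, 1e6), function(r) {
    a <- acceptance_range(r = r); a$high - a$low
  })
  expect_true(all(diff(widths) < 0))
  a <- acceptance_range(r = 1e12)
  expect_equal(c(a$low, a$high), c(1, 1), tolerance = 1e-2)
})

test_that("verdicts follow the CI/range set relations", {
  rng <- acceptance_range(r = 45)
  fit <- function(lo, hi) {
    structure(list(parameter_name = "y", beta = (lo + hi) / 2,
                   ci = c(lo, hi), ci_level = 0.9),
              class = "power_model_fit")
  }
  wide <- assess_proportionality(fit(0.86, 1.08), rng)
  expect_equal(wide$verdict, "inconclusive")
  expect_match(wide$rationale, "wider than and covering")
  expect_equal(assess_proportionality(fit(0.95, 1.05), rng)$verdict,
               "proportional")
  expect_equal(assess_proportionality(fit(1.20, 1.40), rng)$verdict,
               "nonproportional")
  expect_error(assess_proportionality(fit(NA, 1), rng), "confidence interval")
})

test_that("the verdict is invariant under dose-unit changes", {
  set.seed(3)
  d <- rep(c(2, 6, 12, 24, 40, 60, 90), each = 4)
  y <- 2 * d * exp(rnorm(length(d), 0, 0.3))
  f_mg <- fit_power_model(d, y)
  f_ug <- fit_power_model(d * 1000, y)
  expect_equal(f_mg$beta, f_ug$beta, tolerance = 1e-12)
  expect_equal(f_mg$ci, f_ug$ci, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(f_mg$alpha, f_ug$alpha)))
})

test_that("fold-range ratios reproduce the published exposure spans", {
  tab <- nh130_group_summary()
  fr <- fold_range_ratio(tab$dose_mg, tab$cmax_geomean)
  expect_equal(fr$dose_fold, 45)
  expect_equal(round(fr$parameter_fold), 28)
  expect_equal(round(fold_range_ratio(tab$dose_mg,
                                      tab$auc_0t_geomean)$parameter_fold, 1),
               33.7)
  expect_equal(fold_range_ratio(c(2, 90), c(3, 3))$parameter_fold, 1)
  expect_error(fold_range_ratio(2, 5), ">= 2")
})

test_that("slope CI coverage is near nominal on proportional cohorts", {
  # modest replicate count here; the full-scale check lives with the
  # acceptance suite
  cover <- 0; n_seeds <- 60
  for (i in seq_len(n_seeds)) {
    g <- generate_cohort(cohort_spec(seed = 300 + i))
    r <- suppressWarnings(nca_study(g))
    ok <- !is.na(r$auc_0inf)
    f <- fit_power_model(r$dose_mg[ok], r$auc_0inf[ok])
    cover <- cover + (f$ci[1] <= 1 && f$ci[2] >= 1)
  }
  expect_gte(cover / n_seeds, 0.8)
  expect_lte(cover / n_seeds, 0.99)
})
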