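test_that("stable age distribution solves toy and degenerate matrices", {
  A <- rbind(c(0, 2), c(0.5, 0))
  s <- stable_age_distribution(A)
  expect_equal(s$lambda, 1)
  expect_equal(s$proportions, c(2 / 3, 1 / 3))
  # scaling invariance
  s2 <- stable_age_distribution(3.7 * A)
  expect_equal(s2$proportions, s$proportions)
  expect_equal(s2$lambda, 3.7)
  # nilpotent (all survival 0, no reproduction) has no usable eigenvalue
  expect_error(stable_age_distribution(rbind(c(0, 0), c(0.5, 0))),
               "dominant eigenvalue")
})

test_that("the literature parameter table builds the expected Leslie matrix", {
  A <- build_leslie(demographic_params())
  expect_equal(dim(A), c(17L, 17L))
  sub <- A[cbind(2:17, 1:16)]
  expect_equal(sub, c(0.45, 0.825, rep(0.94, 5), rep(0.875, 6), rep(0.60, 3)))
  expect_equal(sum(sub > 0), 16L)
  expect_equal(unname(A[1, ]),
               c(0, 0, 0.15, rep(0.475, 11), rep(0.20, 3)))
  expect_true(all(A[-1, ][lower.tri(A[-1, ], diag = FALSE)] >= 0))
  s <- stable_age_distribution(A, age_cutoff = 6)
  expect_equal(sum(s$proportions), 1)
  expect_true(all(s$proportions >= 0))
  expect_gt(s$lambda, 1)  # growing population under mean parameters
  # the alternative fecundity mapping shifts reproduction one class earlier
  A2 <- build_leslie(demographic_params(fecundity_mapping = "shift"))
  expect_equal(unname(A2[1, 2]), 0.15)
  expect_gt(stable_age_distribution(A2)$lambda, s$lambda)
})

test_that("census adjustment and expected-hybrid window reproduce the arithmetic", {
  expect_equal(round(adjusted_population_size(175, 0.72)), 126)
  expect_equal(round(adjusted_population_size(250, 0.72)), 180)
  expect_equal(adjusted_population_size(250, 1), 250)
  eh <- expected_hybrids(11 / 47, 180)
  expect_equal(round(eh$expected, 1), 42.1)
  expect_equal(round(eh$lower, 1), 37.9)
  expect_equal(round(eh$upper, 1), 46.3)
  expect_equal(expected_hybrids(0, 500), list(expected = 0, lower = 0, upper = 0))
  eh2 <- expected_hybrids(9 / 44, 126)
  expect_equal(round(eh2$expected, 1), 25.8)
})

test_that("forced-parameter runs match the deterministic bookkeeping oracle", {
  # all survival and fecundity 1, all lambs female, one founder aged 2
  run <- simulate_supplementation(ewe_ages = 2L, years = 6L, sex_ratio = 1,
                                  forced = list(survival = 1, fecundity = 1),
                                  seed = 71)
  expect_equal(run$final_count, bookkeeping_oracle(2L, 6L))
  expect_equal(run$n_pure_offspring, 1L)   # the single in-utero litter
  expect_equal(run$n_founders_alive, 1L)
  # zero survival kills every line
  run0 <- simulate_supplementation(ewe_ages = c(2L, 4L), years = 6L,
                                   forced = list(survival = 0, fecundity = 1),
                                   seed = 72)
  expect_equal(run0$final_count, 0L)
  # founders are never counted even when they are the only survivors
  runf <- simulate_supplementation(ewe_ages = c(2L, 3L), years = 6L,
                                   forced = list(survival = 1, fecundity = 0),
                                   seed = 73)
  expect_equal(runf$final_count, 0L)
  expect_equal(runf$n_founders_alive, 2L)
  # several founder age structures against the oracle
  for (ages in list(c(1L, 2L), c(2L, 2L, 5L), c(1L, 3L, 6L, 7L))) {
    r <- simulate_supplementation(ages, years = 6L, sex_ratio = 1,
                                  forced = list(survival = 1, fecundity = 1),
                                  seed = 74L)
    expect_equal(r$final_count, bookkeeping_oracle(ages, 6L))
  }
})

test_that("Monte-Carlo mean matches the expectation recursion", {
  params <- demographic_params()
  # fix the draws at their means by zeroing the spread
  p0 <- demographic_params(
    survival = transform(params$survival, sd = 0),
    fecundity = transform(params$fecundity, sd = 0))
  ens0 <- run_ensemble(ewe_ages = c(2L, 3L, 4L), params = p0,
                       n_runs = 10000L, years = 6L, seed = 76)
  s_by_age <- params$s
  f_by_age <- params$f
  expected <- expectation_oracle(c(2L, 3L, 4L), 6L, s_by_age, f_by_age)
  se <- sd(ens0$final_count) / sqrt(nrow(ens0))
  expect_lt(abs(mean(ens0$final_count) - expected), 3 * se)
  # all-female deterministic limit equals the expectation path exactly in mean
  ens1 <- run_ensemble(ewe_ages = c(2L, 3L, 4L), params = p0,
                       n_runs = 8000L, years = 6L, sex_ratio = 1, seed = 77)
  expected1 <- expectation_oracle(c(2L, 3L, 4L), 6L, s_by_age, f_by_age,
                                  sex_ratio = 1)
  se1 <- sd(ens1$final_count) / sqrt(nrow(ens1))
  expect_lt(abs(mean(ens1$final_count) - expected1), 3 * se1)
})

test_that("ensembles are reproducible and lamb survival drives the count", {
  e1 <- run_ensemble(default_ewe_ages(), n_runs = 3000L, seed = 78)
  e2 <- run_ensemble(default_ewe_ages(), n_runs = 3000L, seed = 78)
  expect_identical(e1, e2)
  expect_equal(nrow(run_ensemble(default_ewe_ages(), n_runs = 1L, seed = 79)), 1L)
  rho <- cor(e1$lamb_survival_draw, e1$final_count, method = "spearman")
  expect_gt(rho, 0)
  expect_true(all(e1$final_count >= 0))
})

test_that("lamb-survival interval recovery on a constructed ensemble", {
  draws <- seq(0, 1, by = 0.01)
  ens <- data.frame(run = seq_along(draws), lamb_survival_draw = draws,
                    final_count = as.integer(round(100 * draws)))
  iv <- infer_lamb_survival(ens, list(lower = 45, upper = 55))
  expect_equal(iv$n_accepted, 11L)
  expect_equal(iv$mean, 0.50)
  expect_equal(range(ens$lamb_survival_draw[ens$final_count >= 45 &
                                              ens$final_count <= 55]),
               c(0.45, 0.55))
  expect_error(infer_lamb_survival(ens, list(lower = 200, upper = 300)),
               "no runs in the acceptance window")
  # widening the window is monotone in accepted runs
  n_acc <- vapply(c(5, 10, 20, 40), function(w)
    infer_lamb_survival(ens, list(lower = 50 - w, upper = 50 + w))$n_accepted,
    integer(1))
  expect_true(all(diff(n_acc) >= 0))
  # an all-accepting window recovers the full draw distribution
  full <- infer_lamb_survival(ens, list(lower = 0, upper = Inf))
  expect_equal(full$n_accepted, length(draws))
})

test_that("an unconstrained ensemble centres lamb survival on its prior mean", {
  ens <- run_ensemble(default_ewe_ages(), n_runs = 10000L, seed = 80)
  full <- infer_lamb_survival(ens, list(lower = 0, upper = Inf))
  expect_lt(abs(full$mean - 0.45), 0.01)
})

test_that("baseline comparison issues the documented verdicts", {
  iv <- structure(list(mean = 0.45, sd = 0.075, lower = 0.30, upper = 0.60,
                       n_accepted = 100L, window = c(0, Inf)),
                  class = "lamb_survival_interval")
  expect_equal(compare_to_baseline(iv, 11:26)$verdict, "at or above baseline")
  expect_equal(compare_to_baseline(iv, 7:24)$baseline_max, 0.24)
  low <- structure(list(mean = 0.03, sd = 0.01, lower = 0.01, upper = 0.05,
                        n_accepted = 10L, window = c(0, Inf)),
                   class = "lamb_survival_interval")
  expect_equal(compare_to_baseline(low, 11:26)$verdict,
               "below baseline (possible outbreeding depression signal)")
  mid <- structure(list(mean = 0.2, sd = 0.05, lower = 0.1, upper = 0.3,
                        n_accepted = 10L, window = c(0, Inf)),
                   class = "lamb_survival_interval")
  expect_equal(compare_to_baseline(mid, 11:26)$verdict, "overlaps baseline")
})
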