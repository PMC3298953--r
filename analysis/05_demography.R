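# Outbreeding-depression screen: bound the lamb survival of hybrid
# lineages. For each treatment scenario the stable age distribution of the
# literature-parameter Leslie matrix converts the census into the number of
# animals young enough to postdate supplementation; the hybrid proportion
# scales that into an expected hybrid count with a +/-10% window; a
# 100,000-run stochastic ensemble of the supplemented ewes' demography is
# filtered to that window and the accepted runs' lamb-survival draws give a
# mean +/- 2 SD interval compared against the pre-supplementation
# lambs-per-100-ewes baselines.

source("analysis/00_setup.R")
rv_logging(TRUE)

params <- demographic_params()
sad <- stable_age_distribution(build_leslie(params), age_cutoff = 6L)
cat(sprintf("Stable age distribution: lambda = %.3f, %.1f%% of the population aged 0-6\n",
            sad$lambda, 100 * sad$proportion_le_cutoff))

census <- jsonlite::read_json(file.path(RESULTS, "hybrid_census.json"))
prop <- census$proportion
cat(sprintf("Hybrid proportion from 02_classify: %.1f%%\n", 100 * prop))

rows <- list(); ensembles <- list()
for (nm in names(SCENARIOS)) {
  sc <- SCENARIOS[[nm]]
  adj <- adjusted_population_size(sc$census_size_post, sad$proportion_le_cutoff)
  eh <- expected_hybrids(prop, adj)
  ens <- run_ensemble(sc$supplemented_ewe_ages, params, n_runs = 1e5,
                      years = 6L, age_cutoff = 6L, seed = SEED + match(nm, names(SCENARIOS)))
  iv <- infer_lamb_survival(ens, eh)
  cmp <- compare_to_baseline(iv, sc$baseline_lambs_per_100_ewes)
  ensembles[[nm]] <- ens
  rows[[nm]] <- data.frame(
    scenario = nm, census = sc$census_size_post, adjusted = round(adj),
    expected_hybrids = round(eh$expected, 1),
    window_low = round(eh$lower, 1), window_high = round(eh$upper, 1),
    n_accepted = iv$n_accepted,
    lamb_survival_mean = round(iv$mean, 3),
    interval_low = round(iv$lower, 3), interval_high = round(iv$upper, 3),
    baseline_max = cmp$baseline_max, verdict = cmp$verdict)
  write.csv(ens, file.path(RESULTS, paste0("ensemble_", nm, ".csv")),
            row.names = FALSE)
}
out <- do.call(rbind, rows)
write.csv(out, file.path(RESULTS, "demography_summary.csv"), row.names = FALSE)

cat("\nLamb-survival screen:\n")
print(out, row.names = FALSE)
cat("\nAn interval at or above the baseline range indicates no immediate\n",
    "signal of outbreeding depression in the hybrid lineages.\n")
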