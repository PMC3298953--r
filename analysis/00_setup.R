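# Shared settings for the numbered analysis scripts. Each script can be run
# from the repository root, in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_classify.R
#   ...
# Outputs accumulate under results/.

library(rescueval)

SEED <- 20260101L
RESULTS <- "results"
STUDY_DIR <- file.path(RESULTS, "study")
dir.create(RESULTS, showWarnings = FALSE)

# Study-shaped generator: 16 microsatellite loci, resident pre-sample of 20,
# the 31 supplemented ewes, and a post-supplementation sample of 48 whose
# composition mirrors the first treatment herd's printed census (9 hybrids,
# 3 pure-supplemented, 1 over-age animal).
study_generator <- function(seed = SEED) generator_spec(seed = seed)

# Classifier sweep lengths used throughout the workflow. Full-length runs
# (1e4 burn-in / 1e5 sweeps) give indistinguishable posteriors on this
# problem size; these lengths keep the whole workflow in minutes.
WORKFLOW_MCMC <- mcmc_settings(burn_in = 2e3, sweeps = 2e4, n_chains = 3L)

# Demographic scenario: printed censuses and baseline lamb:100-ewe ranges
# for the two treatment herds; release-age lists are demonstration defaults
# (the true ages were not published).
SCENARIOS <- list(
  SMP = list(census_size_post = 175, baseline_lambs_per_100_ewes = 11:26,
             supplemented_ewe_ages = default_ewe_ages()),
  LGP = list(census_size_post = 250, baseline_lambs_per_100_ewes = 7:24,
             supplemented_ewe_ages = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L,
                                       4L, 4L, 5L, 5L, 6L, 6L, 7L))
)
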