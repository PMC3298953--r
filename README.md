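# rescueval

Tools to evaluate **genetic-rescue supplementation experiments** in
reintroduced wildlife populations — written for wildlife geneticists and
managers who have microsatellite genotypes and mtDNA control-region
sequences from before and after a supplementation and need to answer three
questions:

1. **Did the supplemented animals interbreed with residents?** A Bayesian
   six-category classifier of descent assigns each post-supplementation
   individual a posterior over {pure resident, pure supplemented, F1, F2,
   backcross-to-resident, backcross-to-supplemented} from its multilocus
   genotype, with a maternal-line override from source-private mtDNA
   haplotypes.
2. **Is there any sign of outbreeding depression?** A stochastic
   age-structured simulation of the released ewes bounds the lamb survival
   of hybrid lineages implied by the observed hybrid proportion, for
   comparison against pre-supplementation baselines.
3. **Did genetic diversity rise?** Pre/post comparisons of observed and
   Nei unbiased expected heterozygosity, rarefacted allelic richness,
   pairwise relatedness (Lynch–Ritland, bootstrap CIs), haplotype
   diversity and mean pairwise nucleotide differences.

The package was developed around a two-herd bighorn sheep
(*Ovis canadensis californiana*) supplementation experiment and ships a
synthetic-data generator that reproduces that study's data shape (16
microsatellite loci, diverged parental pools, known hybrid composition,
source-private haplotypes) with ground truth, so every method is testable
end to end.

## The core model

At any locus, an individual of descent category *c* carries two gene
copies whose origins (resident/resident, one-each, supplemented/
supplemented) follow a fixed distribution φ*c* — e.g. (¼, ½, ¼) for an F2,
(½, ½, 0) for a backcross to resident. The genotype likelihood under *c*
sums Hardy–Weinberg terms over those origins:

P(g = {x,y} | c) = φc1·HWE_res(g) + φc2·[p_res(x)p_sup(y) + p_res(y)p_sup(x)] + φc3·HWE_sup(g)

A data-augmented Gibbs sampler (C++ inner loop) updates latent categories,
per-locus gene origins, pool allele frequencies (conjugate Dirichlet,
Jeffreys-like priors) and mixing proportions, with parental samples held
at known origin. An individual is a **hybrid** when its posterior mass on
the four admixed categories exceeds 0.50; carriers of source-private
haplotypes assigned pure-resident are overridden to hybrid, and the hybrid
proportion is taken over the sample net of over-age and pure-supplemented
exclusions.

The demographic screen projects the released ewes through the years to
re-sampling: one truncated-normal draw per stage parameter per run
(survival into ages 1, 2, 3–7, 8–13, 14–16: means 0.45, 0.825, 0.94,
0.875, 0.60; fecundity 0.30 at age 2, 0.95 at 3–13, 0.40 at 14–16),
survival-then-birth event order, Bernoulli(½) lamb sex, in-utero pure
litters excluded. Runs whose hybrid-lineage count lands within ±10% of the
expected hybrid number (hybrid proportion × stable-age-adjusted census)
contribute their lamb-survival draws to a mean ± 2 SD interval.

## Worked example

```r
library(rescueval)

# synthetic study: 20 residents pre, 31 source ewes, 48 post (9 true hybrids)
study <- build_study(generator_spec(seed = 42))

fit <- run_gibbs(study$samples$POST, list(study$samples$RES, study$samples$SRC),
                 mcmc_settings(burn_in = 2e3, sweeps = 2e4, n_chains = 3))
census <- apply_mtdna_override(fit$posteriors, study$metadata,
                               study$private_haplotypes, age_cutoff = 6)
sad <- stable_age_distribution(build_leslie(demographic_params()), age_cutoff = 6)
adj <- adjusted_population_size(175, sad$proportion_le_cutoff)
eh  <- expected_hybrids(census$proportion, adj)
ens <- run_ensemble(default_ewe_ages(), n_runs = 1e5, seed = 42)
iv  <- infer_lamb_survival(ens, eh)
cmp <- compare_to_baseline(iv, 11:26)
```

This prints, via the cat() calls in `analysis/`-style drivers:

```
Hybrids: 8 of 43 (18.6%)
Adjusted size: 129; expected hybrids 23.9 (window 21.6-26.3)
Lamb survival 0.392 [0.184, 0.601] from 17392 accepted runs -> overlaps baseline
```

Read: the classifier calls 8 hybrids among the 43 countable
post-supplementation animals (the generator's truth is 9 of 44 — one
hybrid was missed and one decoy excluded differently); 73.6% of a stable
population is young enough to postdate supplementation, so a census of 175
leaves ~129 candidates and an expected 23.9 hybrids; the simulation runs
that produce 22–26 hybrid-lineage animals had lamb-survival draws of
0.392 ± 0.209, at and above the 0.11–0.26 baseline range — no
outbreeding-depression signal. Haplotype diversity of the published
haplotype counts reproduces the published values exactly:

```r
round(c(source = haplotype_diversity(c(12, 3, 15, 1)),
        herd1_post = haplotype_diversity(c(8, 1, 39)),
        herd2_post = haplotype_diversity(c(6, 5, 37))), 3)
#>     source herd1_post herd2_post
#>      0.626      0.318      0.387
```

## The analysis workflow

Numbered drivers under `analysis/` run the full evaluation and write
tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | build and write the synthetic study (Genepop, FASTA, metadata, truth) |
| `02_classify.R` | Gibbs classification, hybrid decision rule, mtDNA override, census |
| `03_power.R` | power table from simulated known-class genotypes |
| `04_diversity.R` | per-locus/per-population diversity, paired t-tests, relatedness CIs, mtDNA summary |
| `05_demography.R` | Leslie adjustment, expected-hybrid windows, 1e5-run ensembles, survival intervals vs baselines |
| `06_report.R` | one-config end-to-end report (JSON + figures) via `run_pipeline()` |

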