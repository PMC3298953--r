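test_that("genotype likelihood matches hand enumeration over the category table", {
  fres <- c("101" = 1); fsup <- c("102" = 1)
  het <- c(101L, 102L)
  expect_equal(genotype_likelihood(het, "F1", fres, fsup), 1)
  expect_equal(genotype_likelihood(het, "F2", fres, fsup), 0.5)
  expect_equal(genotype_likelihood(het, "BX_res", fres, fsup), 0.5)
  expect_equal(genotype_likelihood(het, "BX_sup", fres, fsup), 0.5)
  expect_equal(genotype_likelihood(het, "pure_res", fres, fsup), 0)
  expect_equal(genotype_likelihood(het, "pure_sup", fres, fsup), 0)
  # homozygote under mixed frequencies: check one general case by hand
  fr <- c("101" = 0.7, "102" = 0.3); fs <- c("101" = 0.2, "102" = 0.8)
  hom <- c(101L, 101L)
  expect_equal(genotype_likelihood(hom, "F2", fr, fs),
               0.25 * 0.7^2 + 0.5 * 0.7 * 0.2 + 0.25 * 0.2^2)
  # missing genotype drops the locus for every category
  for (cl in rownames(descent_phi()))
    expect_equal(genotype_likelihood(c(NA, NA), cl, fres, fsup), 1)
  # identical pools make categories indistinguishable
  for (cl in rownames(descent_phi()))
    expect_equal(genotype_likelihood(c(101L, 102L), cl, fr, fr),
                 2 * 0.7 * 0.3)
  expect_error(genotype_likelihood(c(999L, 101L), "F1", fres, fsup),
               "allele absent")
  expect_error(genotype_likelihood(het, "F3", fres, fsup), "unknown category")
})

test_that("fixed-frequency posteriors match brute-force normalisation to 1e-6", {
  set.seed(41)
  spec <- generator_spec(sample_sizes = list(resident_pre = 15L, source = 15L,
                                             post = 12L),
                         hybrid_composition = c(F1 = 3, F2 = 3, BX_res = 2),
                         n_overage = 0L, missing_rate = 0.05, seed = 41)
  st <- build_study(spec)
  post <- st$samples$POST
  fit <- run_gibbs(post, list(st$samples$RES, st$samples$SRC),
                   mcmc_settings(burn_in = 10, sweeps = 50, n_chains = 1),
                   fix_frequencies = TRUE, fix_mixing = TRUE)
  # with frequencies and mixing fixed the category posterior is available
  # in closed form from the smoothed parental frequencies the sampler used
  allele_sets <- rescueval:::allele_universe(
    list(post, st$samples$RES, st$samples$SRC), post$loci)
  k_l <- lengths(allele_sets)
  fr <- rescueval:::empirical_frequencies(st$samples$RES, allele_sets,
                                          pseudo = 1 / k_l)
  fs <- rescueval:::empirical_frequencies(st$samples$SRC, allele_sets,
                                          pseudo = 1 / k_l)
  cats <- rownames(descent_phi())
  for (i in seq_along(post$ids)) {
    oracle <- brute_force_posterior(post$genotypes[i, ], post$loci, fr, fs)
    got <- as.numeric(fit$posteriors[i, cats])
    expect_equal(got, unname(oracle), tolerance = 1e-6)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("single diagnostic locus recovers the closed-form posterior", {
  loci <- "Loc01"
  res_par <- fixed_sample("RESP", "pre", c(101L, 101L), 30L, loci)
  sup_par <- fixed_sample("SUPP", "source", c(102L, 102L), 30L, loci)
  het <- fixed_sample("Q", "post", c(101L, 102L), 1L, loci)
  fit <- run_gibbs(het, list(res_par, sup_par),
                   mcmc_settings(burn_in = 10, sweeps = 20, n_chains = 1),
                   fix_frequencies = TRUE, fix_mixing = TRUE)
  p <- fit$posteriors
  # likelihoods (1, .5, .5, .5, ~0, ~0) normalise to (.4, .2, .2, .2, 0, 0);
  # the prior smoothing of the parental frequencies perturbs this slightly
  expect_lt(abs(p$F1 - 0.4), 0.02)
  expect_lt(abs(p$F2 - 0.2), 0.02)
  expect_lt(abs(p$BX_res - 0.2), 0.02)
  expect_lt(abs(p$BX_sup - 0.2), 0.02)
  expect_gt(p$p_hybrid, 0.97)
  expect_true(p$hybrid_flag)
})

test_that("chains from over-dispersed seeds agree and posteriors are proper", {
  st <- build_study(generator_spec(seed = 43))
  fit <- run_gibbs(st$samples$POST, list(st$samples$RES, st$samples$SRC),
                   mcmc_settings(burn_in = 1000, sweeps = 8000, n_chains = 2,
                                 seeds = c(101L, 99991L)))
  expect_lt(fit$diagnostics$max_chain_discrepancy, 0.05)
  cats <- rownames(descent_phi())
  pm <- as.matrix(fit$posteriors[, cats])
  expect_true(all(pm >= 0))
  expect_equal(rowSums(pm), rep(1, nrow(pm)), tolerance = 1e-9)
  # strongly diverged pure residents are confidently recovered
  truth <- st$truth[match(st$samples$POST$ids, st$truth$id), ]
  pres <- truth$class == "pure_res"
  expect_gt(mean(fit$posteriors$pure_res[pres] > 0.5), 0.8)
})

test_that("swapping the parental samples mirrors the posterior labels", {
  spec <- generator_spec(sample_sizes = list(resident_pre = 25L, source = 25L,
                                             post = 10L),
                         hybrid_composition = c(F1 = 2, F2 = 2, BX_res = 2,
                                                BX_sup = 2),
                         n_overage = 0L, missing_rate = 0, seed = 44,
                         diversity_asymmetry = 0)
  st <- build_study(spec)
  s <- mcmc_settings(burn_in = 2000, sweeps = 20000, n_chains = 2)
  fwd <- run_gibbs(st$samples$POST, list(st$samples$RES, st$samples$SRC), s)
  rev <- run_gibbs(st$samples$POST, list(st$samples$SRC, st$samples$RES), s)
  expect_lt(max(abs(fwd$posteriors$pure_res - rev$posteriors$pure_sup)), 0.02)
  expect_lt(max(abs(fwd$posteriors$BX_res - rev$posteriors$BX_sup)), 0.02)
  expect_lt(max(abs(fwd$posteriors$F1 - rev$posteriors$F1)), 0.02)
  expect_lt(max(abs(fwd$posteriors$F2 - rev$posteriors$F2)), 0.02)
})

test_that("mtDNA override reproduces the printed census arithmetic", {
  cats <- rownames(descent_phi())
  mk_post <- function(n, n_hyb, n_sup, n_overage) {
    # deterministic posterior table: hybrids flagged by nuclear rule,
    # pure-supplemented and residents assigned confidently
    post <- matrix(0, n, 6, dimnames = list(NULL, cats))
    kind <- c(rep("hyb", n_hyb), rep("sup", n_sup), rep("old", n_overage),
              rep("res", n - n_hyb - n_sup - n_overage))
    for (i in seq_len(n)) {
      post[i, ] <- switch(kind[i],
        hyb = c(0.2, 0, 0.2, 0.6, 0, 0)[c(1, 2, 3, 4, 5, 6)],
        sup = c(0.05, 0.9, 0, 0.05, 0, 0),
        old = c(0.95, 0, 0, 0.05, 0, 0),
        res = c(0.95, 0, 0, 0.05, 0, 0))
    }
    p_hyb <- rowSums(post[, c("F1", "F2", "BX_res", "BX_sup")])
    data.frame(id = sprintf("i%03d", seq_len(n)), post, p_hybrid = p_hyb,
               hybrid_flag = p_hyb > 0.5, kind = kind,
               stringsAsFactors = FALSE)
  }
  census_of <- function(n, n_hyb, n_sup, n_overage) {
    posts <- mk_post(n, n_hyb, n_sup, n_overage)
    md <- data.frame(id = posts$id,
                     age = ifelse(posts$kind == "old", 8L, 3L),
                     mt_haplotype = ifelse(posts$kind == "sup", "A", "E"),
                     stringsAsFactors = FALSE)
    apply_mtdna_override(posts[, setdiff(names(posts), "kind")], md,
                         source_private_haplotypes = c("A", "B", "C", "D"),
                         age_cutoff = 6L)
  }
  # 48 sampled, 1 over-age, 3 pure-supplemented, 9 hybrids -> 9/44 = 20.5%
  a <- census_of(48, 9, 3, 1)
  expect_equal(a$n_hybrids, 9L)
  expect_equal(a$denominator, 44L)
  expect_equal(round(100 * a$proportion, 1), 20.5)
  # 50 sampled, 2 over-age, 1 pure-supplemented, 11 hybrids -> 11/47 = 23.4%
  b <- census_of(50, 11, 1, 2)
  expect_equal(b$denominator, 47L)
  expect_equal(round(100 * b$proportion, 1), 23.4)
  # no hybrids, no source haplotypes -> proportion 0
  z <- census_of(40, 0, 0, 0)
  expect_equal(z$proportion, 0)
})

test_that("source-haplotype carriers assigned pure-resident are overridden to hybrid", {
  cats <- rownames(descent_phi())
  post <- matrix(rep(c(0.9, 0, 0, 0.1, 0, 0), 3), 3, byrow = TRUE,
                 dimnames = list(NULL, cats))
  posts <- data.frame(id = c("x1", "x2", "x3"), post,
                      p_hybrid = rep(0.1, 3), hybrid_flag = FALSE,
                      stringsAsFactors = FALSE)
  md <- data.frame(id = c("x1", "x2", "x3"),
                   age = c(2L, 2L, 2L),
                   mt_haplotype = c("A", "E", NA),  # private, shared, missing
                   stringsAsFactors = FALSE)
  cen <- apply_mtdna_override(posts, md, c("A", "B"), age_cutoff = 6L)
  expect_equal(cen$table$status, c("hybrid", "resident", "resident"))
  expect_equal(cen$table$basis[1], "mtDNA_override")
  expect_equal(cen$proportion, 1 / 3)
})

test_that("perfectly diagnostic loci give zero F1 hybrid error", {
  loci <- paste0("L", 1:6)
  res_par <- fixed_sample("RESP", "pre",
                          rep(c(101L, 101L), 6L), 20L, loci)
  sup_par <- fixed_sample("SUPP", "source",
                          rep(c(102L, 102L), 6L), 20L, loci)
  set.seed(45)
  pw <- power_simulation(list(res_par, sup_par), n_per_class = 50L,
                         settings = mcmc_settings(burn_in = 200, sweeps = 2000,
                                                  n_chains = 1))
  s <- pw$summary
  expect_equal(s$hybrid_error[s$class == "F1"], 0)
  expect_equal(s$class_error[s$class == "F1"], 0)  # F1 is unambiguous here
  expect_error(power_simulation(list(res_par, sup_par), n_per_class = 0L),
               "n_per_class")
})
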