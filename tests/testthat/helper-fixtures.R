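# Shared fixtures and small independent oracles.

# two pools fixed for distinct alleles at every locus (perfectly diagnostic)
diagnostic_freqs <- function(n_loci = 4L) {
  res <- lapply(seq_len(n_loci), function(l) c("101" = 1))
  sup <- lapply(seq_len(n_loci), function(l) c("102" = 1))
  names(res) <- names(sup) <- paste0("Loc", sprintf("%02d", seq_len(n_loci)))
  list(res = res, sup = sup)
}

# build a pop_sample of n copies of one fixed genotype
fixed_sample <- function(label, epoch, genotype, n, loci) {
  geno <- matrix(rep(genotype, each = n), nrow = n)
  pop_sample(label, epoch, sprintf("%s_%02d", label, seq_len(n)), loci, geno)
}

# brute-force posterior over the six categories with frequencies and
# mixing held fixed: normalised product of per-locus likelihoods
brute_force_posterior <- function(genotype_row, loci, freqs_res, freqs_sup,
                                  prior = rep(1 / 6, 6)) {
  cats <- rownames(descent_phi())
  lik <- vapply(cats, function(cl) {
    v <- prior[match(cl, cats)]
    for (l in seq_along(loci)) {
      g <- genotype_row[c(2L * l - 1L, 2L * l)]
      v <- v * genotype_likelihood(g, cl, freqs_res[[l]], freqs_sup[[l]])
    }
    v
  }, numeric(1L))
  lik / sum(lik)
}

# deterministic bookkeeping oracle for the supplementation simulator:
# integer recursion with all survival/fecundity probabilities fixed and
# all lambs female; mirrors the model rules (age first, then breed; year-1
# lambs of founders released at age >= 2 are pure and non-breeding)
bookkeeping_oracle <- function(ewe_ages, years, s = 1, f = 1, max_age = 16L) {
  founders <- rep(0L, max_age + 1L)
  for (a in ewe_ages) founders[a + 1L] <- founders[a + 1L] + 1L
  hyb <- rep(0L, max_age + 1L)
  advance <- function(v) c(0L, (v * s)[seq_len(max_age)])
  for (y in seq_len(years)) {
    founders <- advance(founders)
    hyb <- advance(hyb)
    lambs_f <- founders * f; lambs_f[1L] <- 0     # age-0 ewes never lamb
    lambs_h <- hyb * f; lambs_h[1L] <- 0
    if (y == 1L) lambs_f[(3L:max_age) + 1L] <- 0  # pure in-utero litters
    born <- sum(lambs_f) + sum(lambs_h)
    hyb[1L] <- hyb[1L] + born
  }
  sum(hyb)
}

# expectation recursion for the simulator with fixed parameter values:
# expected hybrid counts by age and sex under the same event order
expectation_oracle <- function(ewe_ages, years, s_by_age, f_by_age,
                               sex_ratio = 0.5, max_age = 16L) {
  founders <- rep(0, max_age + 1L)
  for (a in ewe_ages) founders[a + 1L] <- founders[a + 1L] + 1
  hybF <- hybM <- rep(0, max_age + 1L)
  advance <- function(v) c(0, v[seq_len(max_age)] * s_by_age)
  for (y in seq_len(years)) {
    founders <- advance(founders)
    hybF <- advance(hybF); hybM <- advance(hybM)
    lambs <- founders * f_by_age
    if (y == 1L) lambs[(3L:max_age) + 1L] <- 0
    lambs <- sum(lambs) + sum(hybF * f_by_age)
    hybF[1L] <- hybF[1L] + lambs * sex_ratio
    hybM[1L] <- hybM[1L] + lambs * (1 - sex_ratio)
  }
  sum(hybF) + sum(hybM)
}
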