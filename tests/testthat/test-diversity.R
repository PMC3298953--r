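test_that("unbiased expected heterozygosity has its closed form and bounds", {
  expect_equal(expected_heterozygosity_unbiased(c(20)), 0)
  expect_equal(expected_heterozygosity_unbiased(c(10, 10)), (20 / 19) * 0.5)
  expect_equal(expected_heterozygosity_unbiased(c(A = 3, B = 7)),
               expected_heterozygosity_unbiased(c(B = 7, A = 3)))
  expect_true(is.na(expected_heterozygosity_unbiased(c(1))))
  # unbiased estimate always exceeds plain gene diversity
  set.seed(61)
  for (i in 1:20) {
    cnt <- rmultinom(1, size = sample(4:60, 1), prob = rdirich <- {
      x <- rgamma(sample(2:6, 1), 1); x / sum(x)
    })[, 1]
    cnt <- cnt[cnt > 0]
    if (sum(cnt) < 2 || length(cnt) < 2) next
    p <- cnt / sum(cnt)
    expect_gt(expected_heterozygosity_unbiased(cnt), 1 - sum(p^2) - 1e-12)
  }
})

test_that("rarefacted allelic richness matches exhaustive subsampling", {
  # full-sample identity
  expect_equal(allelic_richness(c(5, 3, 2), g = 10), 3)
  # counts (3,1), g = 2: enumerate all 6 unordered pairs of gene copies
  expect_equal(allelic_richness(c(3, 1), g = 2), 1.5)
  copies <- c(1, 1, 1, 2)
  pairs <- utils::combn(4, 2)
  mean_alleles <- mean(apply(pairs, 2, function(ix) length(unique(copies[ix]))))
  expect_equal(allelic_richness(c(3, 1), g = 2), mean_alleles)
  # brute-force oracle on a larger configuration, g = 3
  cnt <- c(4, 2, 1)
  copies <- rep(seq_along(cnt), cnt)
  trips <- utils::combn(length(copies), 3)
  oracle <- mean(apply(trips, 2, function(ix) length(unique(copies[ix]))))
  expect_equal(allelic_richness(cnt, g = 3), oracle)
  # A_R at g=2 equals 1 + probability two copies drawn without
  # replacement differ
  n2 <- sum(cnt); p_same <- sum(cnt * (cnt - 1)) / (n2 * (n2 - 1))
  expect_equal(allelic_richness(cnt, g = 2), 1 + (1 - p_same))
  # monotone in g
  ar <- vapply(1:7, function(g) allelic_richness(cnt, g), numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  expect_error(allelic_richness(c(3, 1), g = 5), "exceeds")
})

test_that("exact Hardy-Weinberg test agrees with enumeration and Monte Carlo", {
  # perfect small case: every array is at least as extreme
  r <- hwe_exact_test(c("A/A" = 1, "A/B" = 2, "B/B" = 1))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1)
  # monomorphic locus is not testable
  expect_true(is.na(hwe_exact_test(c("A/A" = 10))$p_value))
  # heterozygote deficit: compare with the 1-df closed enumeration
  # (alleles 6/6 over n = 6: arrays indexed by heterozygote count 0,2,4,6)
  r2 <- hwe_exact_test(c("A/A" = 3, "B/B" = 3))
  het <- c(0, 2, 4, 6)
  lp <- vapply(het, function(h) {
    naa <- (6 - h) / 2
    lfactorial(6) + 2 * lfactorial(6) + h * log(2) -
      lfactorial(12) - (lfactorial(naa) + lfactorial(h) + lfactorial(naa))
  }, numeric(1))
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  p_oracle <- sum(pr[lp <= lp[1] + 1e-9])
  expect_equal(r2$p_value, p_oracle, tolerance = 1e-10)
  # Monte-Carlo agrees with enumeration within 3 binomial standard errors
  set.seed(62)
  r3 <- hwe_exact_test(c("A/A" = 3, "B/B" = 3), mc_steps = 20000, enum_cap = 1)
  expect_equal(r3$method, "monte_carlo")
  se <- sqrt(p_oracle * (1 - p_oracle) / 20000)
  expect_lt(abs(r3$p_value - p_oracle), 3 * se)
  # matrix interface
  g <- rbind(c(1L, 1L), c(1L, 2L), c(1L, 2L), c(2L, 2L))
  expect_equal(hwe_exact_test(g)$p_value, 1)
})

test_that("relatedness is centred at zero among unrelated individuals", {
  set.seed(63)
  st <- build_study(generator_spec(
    sample_sizes = list(resident_pre = 200L, source = 2L, post = 2L),
    hybrid_composition = c(F1 = 0), n_overage = 0L, missing_rate = 0,
    seed = 63))
  for (est in c("lynch_ritland", "queller_goodnight")) {
    r <- pairwise_relatedness(st$samples$RES, estimator = est, n_boot = 199L)
    expect_lt(abs(r$mean), 0.02)
    expect_true(r$ci[1] < r$mean && r$mean < r$ci[2])
    expect_equal(r$n_pairs, 200 * 199 / 2)
  }
})

test_that("relatedness recovers parent-offspring pairs and ranks duplicates", {
  set.seed(64)
  st <- build_study(generator_spec(seed = 64))
  fr <- st$frequencies$res
  loci <- names(fr)
  npair <- 200L
  G <- matrix(NA_integer_, 2L * npair, 2L * length(fr))
  for (k in seq_len(npair)) {
    par <- simulate_individual("pure_res", fr, fr, "resident")$genotype
    off <- integer(length(par))
    for (l in seq_along(fr)) {
      inherited <- par[2L * l - 1L + (runif(1) < 0.5)]
      f <- fr[[l]]
      off[c(2L * l - 1L, 2L * l)] <-
        c(inherited, as.integer(names(f))[sample.int(length(f), 1L, prob = f)])
    }
    G[2L * k - 1L, ] <- par
    G[2L * k, ] <- off
  }
  ps <- pop_sample("PO", "pre", sprintf("i%04d", seq_len(2L * npair)), loci, G)
  r <- pairwise_relatedness(ps, fr, n_boot = 0L)
  ii <- as.integer(sub("i", "", r$pairs$id1))
  jj <- as.integer(sub("i", "", r$pairs$id2))
  po <- (ii %% 2L == 1L) & (jj == ii + 1L)
  expect_equal(mean(r$pairs$r[po]), 0.5, tolerance = 0.1)
  expect_lt(abs(mean(r$pairs$r[po]) - 0.5), 0.05)
  expect_lt(abs(mean(r$pairs$r[!po])), 0.02)

  # a duplicated individual scores far above the unrelated mean
  dup <- pop_sample("DUP", "pre", c("d1", "d2", "d3"), loci,
                    rbind(G[1, ], G[1, ], G[3, ]))
  rd <- pairwise_relatedness(dup, fr, n_boot = 0L)
  r_dup <- rd$pairs$r[rd$pairs$id1 == "d1" & rd$pairs$id2 == "d2"]
  expect_gt(r_dup, 0.7)
})

test_that("paired t across loci matches hand computation and symmetry", {
  same <- paired_t_across_loci(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  r <- paired_t_across_loci(c(0.4, 0.5), c(0.5, 0.7))
  expect_equal(r$t, 3)
  expect_equal(r$df, 1L)
  flip <- paired_t_across_loci(c(0.5, 0.7), c(0.4, 0.5))
  expect_equal(flip$t, -3)
  expect_equal(flip$p_value, r$p_value)
  degen <- paired_t_across_loci(c(0.1, 0.2), c(0.2, 0.3))
  expect_true(is.infinite(degen$t) && degen$t > 0)
  expect_equal(degen$p_value, 0)
  expect_true(degen$degenerate)
  expect_error(paired_t_across_loci(c(0.1), c(0.1, 0.2)), "equal length")
})

test_that("post-supplementation samples gain diversity and lose relatedness", {
  # directional property on generator replicates: H_E and A_R rise, mean
  # relatedness falls after admixture of the two pools
  wins <- c(he = 0L, ar = 0L, r = 0L)
  n_rep <- 6L
  for (i in seq_len(n_rep)) {
    st <- build_study(generator_spec(seed = 700 + i))
    ds <- diversity_summary(list(RES = st$samples$RES, POST = st$samples$POST),
                            hwe = FALSE)
    pl <- ds$per_locus
    he <- tapply(pl$H_E, pl$population, mean, na.rm = TRUE)
    ar <- tapply(pl$A_R, pl$population, mean, na.rm = TRUE)
    pool <- pop_sample("POOL", "pre",
                       c(st$samples$RES$ids, st$samples$POST$ids),
                       st$samples$RES$loci,
                       rbind(st$samples$RES$genotypes, st$samples$POST$genotypes))
    fr <- rescueval:::empirical_frequencies(pool)
    rpre <- pairwise_relatedness(st$samples$RES, fr, n_boot = 0L)
    rpost <- pairwise_relatedness(st$samples$POST, fr, n_boot = 0L)
    wins["he"] <- wins["he"] + (he["POST"] > he["RES"])
    wins["ar"] <- wins["ar"] + (ar["POST"] > ar["RES"])
    wins["r"] <- wins["r"] + (rpost$mean < rpre$mean)
  }
  expect_gte(wins[["he"]], n_rep - 1L)
  expect_gte(wins[["ar"]], n_rep - 1L)
  expect_gte(wins[["r"]], n_rep - 1L)
})

test_that("diversity summary applies the rarefaction and correction conventions", {
  st <- build_study(generator_spec(seed = 66))
  ds <- diversity_summary(list(RES = st$samples$RES, POST = st$samples$POST),
                          hwe = TRUE, mc_steps = 2000)
  pl <- ds$per_locus
  # g is twice the smallest complete-genotype count across populations
  for (l in unique(pl$locus)) {
    rows <- pl[pl$locus == l, ]
    expect_equal(unique(rows$g), 2L * min(rows$n_typed))
  }
  expect_true(all(pl$H_O >= 0 & pl$H_O <= 1, na.rm = TRUE))
  expect_true(all(pl$H_E >= 0 & pl$H_E <= 1, na.rm = TRUE))
  expect_true(all(pl$A_R >= 1, na.rm = TRUE))
  # Holm correction never lowers a p-value
  ok <- !is.na(pl$hwe_p)
  expect_true(all(pl$hwe_p_holm[ok] >= pl$hwe_p[ok] - 1e-12))
  expect_setequal(ds$per_population$population, c("RES", "POST"))
})
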