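# Nuclear diversity and relatedness: observed and Nei unbiased expected
# heterozygosity, rarefacted allelic richness, exact Hardy-Weinberg tests,
# Lynch-Ritland / Queller-Goodnight pairwise relatedness with bootstrap
# confidence intervals, and paired t-tests across loci.

locus_allele_counts <- function(sample, l) {
  a <- sample$genotypes[, c(2L * l - 1L, 2L * l)]
  table(a[!is.na(a)])
}

#' Nei's unbiased expected heterozygosity
#'
#' `H_E = (2n / (2n - 1)) (1 - sum p_i^2)` from allele counts at one locus
#' (`2n` gene copies).
#'
#' @param allele_counts Integer allele counts.
#' @return `H_E`, or `NA` when fewer than 2 gene copies.
#' @export
expected_heterozygosity_unbiased <- function(allele_counts) {
  allele_counts <- allele_counts[allele_counts > 0]
  n2 <- sum(allele_counts)
  if (n2 < 2) return(NA_real_)
  p <- allele_counts / n2
  (n2 / (n2 - 1)) * (1 - sum(p^2))
}

#' Rarefacted allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` gene copies
#' drawn without replacement:
#' `A_R = sum_a [1 - choose(2N - N_a, g) / choose(2N, g)]`.
#'
#' @param allele_counts Integer allele counts (`2N` gene copies total).
#' @param g Rarefaction size in gene copies, `1 <= g <= 2N`.
#' @return `A_R`.
#' @export
allelic_richness <- function(allele_counts, g) {
  allele_counts <- allele_counts[allele_counts > 0]
  N2 <- sum(allele_counts)
  if (g > N2) stop("rarefaction size g exceeds the number of gene copies")
  if (g < 1) stop("g must be at least 1")
  # hypergeometric tail via lchoose; choose(m, g) = 0 when m < g
  term <- vapply(allele_counts, function(na) {
    m <- N2 - na
    if (m < g) 1 else 1 - exp(lchoose(m, g) - lchoose(N2, g))
  }, numeric(1L))
  sum(term)
}

# conditional probability of a genotype array given allele counts
# (Levene's distribution): P = n! prod(n_a!) 2^h / ((2n)! prod(n_ab!))
log_array_prob <- function(geno_counts, allele_counts) {
  n <- sum(geno_counts)
  h <- sum(geno_counts[lower_upper_het(names(geno_counts))])
  lfactorial(n) + sum(lfactorial(allele_counts)) + h * log(2) -
    lfactorial(2 * n) - sum(lfactorial(geno_counts))
}
lower_upper_het <- function(gnames) {
  parts <- strsplit(gnames, "/", fixed = TRUE)
  vapply(parts, function(p) p[1L] != p[2L], logical(1L))
}

enumerate_arrays <- function(allele_counts, cap = 1e6) {
  # enumerate all genotype-count arrays consistent with the allele counts
  k <- length(allele_counts)
  pairs <- list()
  for (a in 1:k) for (b in a:k) pairs[[length(pairs) + 1L]] <- c(a, b)
  out <- list(); nodes <- 0L
  rec <- function(idx, remaining, counts) {
    nodes <<- nodes + 1L
    if (nodes > cap) stop("enumeration cap exceeded")
    if (idx > length(pairs)) {
      if (all(remaining == 0)) out[[length(out) + 1L]] <<- counts
      return(invisible())
    }
    p <- pairs[[idx]]
    maxc <- if (p[1L] == p[2L]) remaining[p[1L]] %/% 2L
            else min(remaining[p[1L]], remaining[p[2L]])
    # feasibility prune: copies consumed later can't exceed what's left
    for (cnt in 0:maxc) {
      rem <- remaining
      rem[p[1L]] <- rem[p[1L]] - cnt
      rem[p[2L]] <- rem[p[2L]] - cnt
      rec(idx + 1L, rem, c(counts, cnt))
    }
  }
  rec(1L, allele_counts, integer())
  gnames <- vapply(pairs, function(p) paste0(p[1L], "/", p[2L]), character(1L))
  lapply(out, function(cnt) setNames(cnt, gnames))
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test on the observed allele counts. The p-value is the
#' total probability, under Levene's conditional distribution, of genotype
#' arrays no more probable than the observed one. Complete enumeration is
#' used while the array space stays below `enum_cap` visited nodes;
#' otherwise a Monte-Carlo version permutes the gene copies (`mc_steps`
#' random pairings).
#'
#' @param genotype_counts Named integer vector of genotype counts, names
#'   `"a/b"` with allele labels `a <= b` (e.g. `c("1/1" = 3, "1/2" = 2)`),
#'   or an `n x 2` matrix of per-individual genotypes.
#' @param mc_steps Monte-Carlo steps when enumeration is infeasible.
#' @param enum_cap Node budget for complete enumeration.
#' @return List: `p_value`, `method` (`"exact"` or `"monte_carlo"`),
#'   `n_arrays` (exact only). Monomorphic input returns `p_value = NA`.
#' @export
hwe_exact_test <- function(genotype_counts, mc_steps = 1e5, enum_cap = 1e6) {
  if (is.matrix(genotype_counts)) {
    g <- genotype_counts[!is.na(genotype_counts[, 1L]) &
                           !is.na(genotype_counts[, 2L]), , drop = FALSE]
    key <- apply(g, 1L, function(r) paste0(sort(r), collapse = "/"))
    genotype_counts <- table(key)
  }
  gc <- genotype_counts[genotype_counts > 0]
  alleles <- sort(unique(unlist(strsplit(names(gc), "/", fixed = TRUE))))
  if (length(alleles) < 2L)
    return(list(p_value = NA_real_, method = "not_available", n_arrays = NA_integer_))
  n <- sum(gc)
  if (n < 2L)
    return(list(p_value = NA_real_, method = "not_available", n_arrays = NA_integer_))
  # allele counts and canonical integer naming
  amap <- setNames(seq_along(alleles), alleles)
  canon <- vapply(names(gc), function(nm) {
    p <- sort(amap[strsplit(nm, "/", fixed = TRUE)[[1L]]])
    paste0(p[1L], "/", p[2L])
  }, character(1L))
  gc_i <- setNames(as.integer(gc), canon)
  ac <- integer(length(alleles))
  for (i in seq_along(gc_i)) {
    p <- as.integer(strsplit(names(gc_i)[i], "/", fixed = TRUE)[[1L]])
    ac[p[1L]] <- ac[p[1L]] + gc_i[i]
    ac[p[2L]] <- ac[p[2L]] + gc_i[i]
  }
  obs_lp <- log_array_prob(gc_i, ac)

  arrays <- tryCatch(enumerate_arrays(ac, cap = enum_cap), error = function(e) NULL)
  if (!is.null(arrays)) {
    lps <- vapply(arrays, log_array_prob, numeric(1L), allele_counts = ac)
    probs <- exp(lps - max(lps)); probs <- probs / sum(probs)
    p_val <- sum(probs[lps <= obs_lp + 1e-9])
    return(list(p_value = p_val, method = "exact", n_arrays = length(arrays)))
  }
  # Monte-Carlo: random pairing of the gene copies
  copies <- rep(seq_along(ac), ac)
  hits <- 0L
  for (s in seq_len(mc_steps)) {
    perm <- sample(copies)
    g <- matrix(perm, ncol = 2L)
    key <- paste0(pmin(g[, 1L], g[, 2L]), "/", pmax(g[, 1L], g[, 2L]))
    sim <- table(key)
    lp <- log_array_prob(setNames(as.integer(sim), names(sim)), ac)
    if (lp <= obs_lp + 1e-9) hits <- hits + 1L
  }
  list(p_value = hits / mc_steps, method = "monte_carlo", n_arrays = NA_integer_)
}

# ---- relatedness -----------------------------------------------------------

# Vectorised single-locus relatedness terms over many pairs at once.
# Reference individual carries alleles (a, b), proband (c, d); pa/pb are
# the reference-population frequencies of a and b. Both return num/den
# pairs so multilocus estimates are ratios of sums with the estimators'
# locus-information weights.
lr_locus_terms <- function(a, b, c_, d, pa, pb) {
  # Lynch & Ritland (1999) regression estimator; locus weight is the
  # denominator over 2*pa*pb, so weighted numerator simplifies
  den <- (1 + (a == b)) * (pa + pb) - 4 * pa * pb
  ok <- den > 0 & pa > 0 & pb > 0
  w <- ifelse(ok, den / (2 * pa * pb), 0)
  num <- pa * ((b == c_) + (b == d)) + pb * ((a == c_) + (a == d)) - 4 * pa * pb
  list(num = ifelse(ok, num / (2 * pa * pb), 0), den = w)
}

qg_locus_terms <- function(a, b, c_, d, pa, pb) {
  # Queller & Goodnight (1989)
  den <- 1 + (a == b) - pa - pb
  num <- 0.5 * ((a == c_) + (a == d) + (b == c_) + (b == d)) - pa - pb
  list(num = ifelse(den != 0, num, 0), den = ifelse(den != 0, den, 0))
}

#' Pairwise relatedness with bootstrap confidence interval
#'
#' Computes pairwise relatedness for all unordered pairs using the Lynch &
#' Ritland (1999) regression estimator (default) or the Queller &
#' Goodnight (1989) estimator. Each estimator is evaluated in both
#' reference directions with its locus-information weights and the two
#' directions averaged. The population mean is accompanied by a percentile
#' bootstrap confidence interval from resampling the pairwise values.
#'
#' @param sample A [pop_sample()].
#' @param reference_frequencies Per-locus named allele-frequency vectors;
#'   defaults to frequencies estimated from `sample` itself.
#' @param estimator `"lynch_ritland"` or `"queller_goodnight"`.
#' @param n_boot Bootstrap resamples (study analyses use 9999).
#' @param conf Confidence level.
#' @return List: `pairs` (data.frame id1, id2, r), `mean`, `ci`
#'   (length-2), `n_pairs`, `n_excluded_pairs`, `estimator`.
#' @export
pairwise_relatedness <- function(sample, reference_frequencies = NULL,
                                 estimator = c("lynch_ritland", "queller_goodnight"),
                                 n_boot = 9999L, conf = 0.95) {
  estimator <- match.arg(estimator)
  loci <- sample$loci
  if (is.null(reference_frequencies))
    reference_frequencies <- empirical_frequencies(sample)
  n <- length(sample$ids)
  if (n < 2L) stop("need at least 2 individuals")
  locus_fun <- if (estimator == "lynch_ritland") lr_locus_terms else qg_locus_terms
  G <- sample$genotypes
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pair_idx)
  I <- pair_idx[, 1L]; J <- pair_idx[, 2L]
  num_ij <- den_ij <- num_ji <- den_ji <- numeric(np)
  shared <- integer(np)
  for (l in seq_along(loci)) {
    cols <- c(2L * l - 1L, 2L * l)
    f <- reference_frequencies[[l]]
    codes <- as.integer(names(f))
    pf <- function(x) as.numeric(f[match(x, codes)])
    a <- G[I, cols[1L]]; b <- G[I, cols[2L]]
    cc <- G[J, cols[1L]]; dd <- G[J, cols[2L]]
    ok <- !(is.na(a) | is.na(cc))
    if (!any(ok)) next
    pa <- pf(a); pb <- pf(b); pc <- pf(cc); pd <- pf(dd)
    if (anyNA(pa[ok]) || anyNA(pc[ok]))
      stop("allele at locus ", loci[l], " missing from reference frequencies")
    v1 <- locus_fun(a, b, cc, dd, pa, pb)
    v2 <- locus_fun(cc, dd, a, b, pc, pd)
    use <- which(ok)
    informative <- (v1$den[use] > 0) | (v2$den[use] > 0)
    shared[use] <- shared[use] + as.integer(informative)
    num_ij[use] <- num_ij[use] + v1$num[use]
    den_ij[use] <- den_ij[use] + v1$den[use]
    num_ji[use] <- num_ji[use] + v2$num[use]
    den_ji[use] <- den_ji[use] + v2$den[use]
  }
  r_fwd <- ifelse(den_ij > 0, num_ij / den_ij, NA_real_)
  r_rev <- ifelse(den_ji > 0, num_ji / den_ji, NA_real_)
  r_vals <- rowMeans(cbind(r_fwd, r_rev), na.rm = TRUE)
  r_vals[shared == 0L] <- NA_real_
  excluded <- sum(shared == 0L)
  keep <- !is.na(r_vals)
  if (excluded > 0L)
    rv_log("diversity", excluded, " pairs excluded (no shared typed loci)")
  pairs <- data.frame(id1 = sample$ids[pair_idx[keep, 1L]],
                      id2 = sample$ids[pair_idx[keep, 2L]],
                      r = r_vals[keep], stringsAsFactors = FALSE)
  m <- mean(pairs$r)
  ci <- if (n_boot > 0L && nrow(pairs) > 1L) {
    boots <- vapply(seq_len(n_boot), function(b)
      mean(pairs$r[sample.int(nrow(pairs), replace = TRUE)]), numeric(1L))
    quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  } else c(NA_real_, NA_real_)
  list(pairs = pairs, mean = m, ci = ci, n_pairs = nrow(pairs),
       n_excluded_pairs = excluded, estimator = estimator)
}

#' Paired t-test across loci
#'
#' Standard paired t-test of per-locus values (`df = n_loci - 1`),
#' two-sided; positive `t` means the post values are larger. Zero variance
#' of the differences is reported as infinite `t` with `p = 0` and a flag.
#'
#' @param pre_values,post_values Equal-length per-locus vectors.
#' @return List: `t`, `df`, `p_value`, `mean_difference`, `degenerate`.
#' @export
paired_t_across_loci <- function(pre_values, post_values) {
  if (length(pre_values) != length(post_values))
    stop("pre and post vectors must have equal length")
  ok <- !is.na(pre_values) & !is.na(post_values)
  d <- post_values[ok] - pre_values[ok]
  if (length(d) < 2L) stop("need at least 2 loci")
  df <- length(d) - 1L
  if (sd(d) <= 1e-12 * max(1, mean(abs(d)))) {
    if (abs(mean(d)) <= 1e-12)
      return(list(t = 0, df = df, p_value = 1, mean_difference = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = df, p_value = 0,
                mean_difference = mean(d), degenerate = TRUE))
  }
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t_stat, df = df, p_value = 2 * pt(-abs(t_stat), df),
       mean_difference = mean(d), degenerate = FALSE)
}

#' Per-population, per-locus diversity summary
#'
#' Computes observed heterozygosity, Nei unbiased expected heterozygosity,
#' rarefacted allelic richness and `F_IS = 1 - H_O / H_E` per locus, with
#' rarefaction size `g` set to twice the smallest number of complete
#' genotypes at that locus across the populations being compared. Exact
#' Hardy-Weinberg tests are run per locus x population with Holm
#' correction across all tests.
#'
#' @param samples Named list of [pop_sample()] objects (same loci).
#' @param hwe If `TRUE`, run the exact Hardy-Weinberg tests.
#' @param mc_steps Monte-Carlo steps for large Hardy-Weinberg tables.
#' @return List: `per_locus` data.frame (population, locus, n_typed, H_O,
#'   H_E, A_R, F_IS, hwe_p, hwe_p_holm), `per_population` data.frame of
#'   means across loci.
#' @export
diversity_summary <- function(samples, hwe = TRUE, mc_steps = 1e4) {
  loci <- samples[[1L]]$loci
  rows <- list()
  for (l in seq_along(loci)) {
    n_typed <- vapply(samples, function(s)
      sum(!is.na(s$genotypes[, 2L * l - 1L])), integer(1L))
    g <- 2L * min(n_typed)
    for (p in names(samples)) {
      s <- samples[[p]]
      cols <- c(2L * l - 1L, 2L * l)
      gmat <- s$genotypes[, cols, drop = FALSE]
      typed <- !is.na(gmat[, 1L])
      ac <- locus_allele_counts(s, l)
      ho <- if (sum(typed)) mean(gmat[typed, 1L] != gmat[typed, 2L]) else NA_real_
      he <- expected_heterozygosity_unbiased(ac)
      ar <- if (sum(ac) >= g && g >= 1L) allelic_richness(ac, g) else NA_real_
      fis <- if (!is.na(he) && he > 0) 1 - ho / he else NA_real_
      pv <- if (hwe && length(ac[ac > 0]) >= 2L)
        hwe_exact_test(gmat, mc_steps = mc_steps)$p_value else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, locus = loci[l], n_typed = sum(typed), g = g,
        H_O = ho, H_E = he, A_R = ar, F_IS = fis, hwe_p = pv,
        stringsAsFactors = FALSE)
    }
  }
  per_locus <- do.call(rbind, rows)
  per_locus$hwe_p_holm <- NA_real_
  ok <- !is.na(per_locus$hwe_p)
  per_locus$hwe_p_holm[ok] <- p.adjust(per_locus$hwe_p[ok], method = "holm")
  per_population <- do.call(rbind, lapply(split(per_locus, per_locus$population),
    function(d) data.frame(population = d$population[1L],
                           n = length(samples[[d$population[1L]]]$ids),
                           H_O = mean(d$H_O, na.rm = TRUE),
                           H_E = mean(d$H_E, na.rm = TRUE),
                           A_R = mean(d$A_R, na.rm = TRUE),
                           stringsAsFactors = FALSE)))
  per_population <- per_population[match(names(samples), per_population$population), ]
  rownames(per_population) <- NULL
  list(per_locus = per_locus, per_population = per_population)
}
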