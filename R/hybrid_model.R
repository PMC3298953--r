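# Six-category Bayesian classification of descent from multilocus
# codominant genotypes, the >0.50 hybrid decision rule with the
# mitochondrial override, and simulation-based power assessment.

#' Gene-origin proportions of the six categories of descent
#'
#' Each category fixes the probability that, at a locus, an individual's
#' two gene copies are (both resident, one from each pool, both
#' supplemented).
#'
#' @return 6 x 3 numeric matrix, rows `pure_res`, `pure_sup`, `F1`, `F2`,
#'   `BX_res`, `BX_sup`.
#' @export
descent_phi <- function() {
  phi <- rbind(pure_res = c(1, 0, 0),
               pure_sup = c(0, 0, 1),
               F1       = c(0, 1, 0),
               F2       = c(0.25, 0.5, 0.25),
               BX_res   = c(0.5, 0.5, 0),
               BX_sup   = c(0, 0.5, 0.5))
  colnames(phi) <- c("both_res", "one_each", "both_sup")
  phi
}

#' MCMC settings for the descent classifier
#'
#' @param burn_in Burn-in sweeps.
#' @param sweeps Post-burn-in sweeps on which posteriors are averaged.
#' @param n_chains Number of independent chains.
#' @param seeds Distinct (over-dispersed) integer seeds, one per chain.
#' @param prior `"jeffreys"` (Dirichlet(1/k) allele frequencies,
#'   Dirichlet(1/6) mixing proportions) or `"uniform"` (Dirichlet(1)).
#' @param convergence_tol Maximum allowed across-chain discrepancy in any
#'   posterior mean; exceeding it triggers one rerun at doubled sweeps,
#'   then a warning flag.
#' @return `mcmc_settings` list.
#' @export
mcmc_settings <- function(burn_in = 1e4, sweeps = 1e5, n_chains = 3L,
                          seeds = NULL, prior = c("jeffreys", "uniform"),
                          convergence_tol = 0.05) {
  stopifnot(burn_in > 0, sweeps > 0, n_chains >= 1)
  prior <- match.arg(prior)
  if (is.null(seeds)) seeds <- 1000L + 7919L * seq_len(n_chains)
  if (anyDuplicated(seeds)) stop("chain seeds must be distinct")
  structure(list(burn_in = as.integer(burn_in), sweeps = as.integer(sweeps),
                 n_chains = as.integer(n_chains), seeds = as.integer(seeds),
                 prior = prior, convergence_tol = convergence_tol),
            class = "mcmc_settings")
}

#' Single-locus genotype likelihood under a category of descent
#'
#' Sums over gene-origin configurations: `sum_o phi_c(o) P(genotype | o)`,
#' where the both-resident and both-supplemented terms are Hardy–Weinberg
#' probabilities under the respective pool frequencies and the one-each
#' term is `p_res(x) p_sup(y) + p_res(y) p_sup(x)` for a heterozygote
#' `{x, y}` and `p_res(x) p_sup(x)` for a homozygote. A missing genotype
#' contributes 1 (the locus is dropped).
#'
#' @param genotype Integer vector of length 2 (allele codes) or `NA`.
#' @param category Category name (see [descent_phi()]).
#' @param freqs_res,freqs_sup Named allele-frequency vectors for this locus.
#' @return Probability.
#' @export
genotype_likelihood <- function(genotype, category, freqs_res, freqs_sup) {
  phi <- descent_phi()
  if (!category %in% rownames(phi)) stop("unknown category '", category, "'")
  if (any(is.na(genotype))) return(1)
  x <- as.character(genotype[1L]); y <- as.character(genotype[2L])
  if ((!x %in% names(freqs_res) && !x %in% names(freqs_sup)) ||
      (!y %in% names(freqs_res) && !y %in% names(freqs_sup)))
    stop("allele absent from both frequency maps: ",
         paste(setdiff(c(x, y), union(names(freqs_res), names(freqs_sup))),
               collapse = ", "))
  p <- function(f, a) if (a %in% names(f)) unname(f[a]) else 0
  prx <- p(freqs_res, x); pry <- p(freqs_res, y)
  psx <- p(freqs_sup, x); psy <- p(freqs_sup, y)
  if (x == y) {
    lrr <- prx^2; lss <- psx^2; lrs <- prx * psx
  } else {
    lrr <- 2 * prx * pry; lss <- 2 * psx * psy
    lrs <- prx * psy + pry * psx
  }
  ph <- phi[category, ]
  unname(ph[1L] * lrr + ph[2L] * lrs + ph[3L] * lss)
}

# map genotypes onto 1..K allele indices per locus; 0 = missing
index_genotypes <- function(geno, allele_sets) {
  L <- length(allele_sets)
  out <- matrix(0L, nrow(geno), 2L * L)
  for (l in seq_len(L)) {
    for (c in c(2L * l - 1L, 2L * l)) {
      idx <- match(geno[, c], allele_sets[[l]])
      if (any(!is.na(geno[, c]) & is.na(idx)))
        stop("allele outside the locus allele universe at locus ", l)
      idx[is.na(idx)] <- 0L
      out[, c] <- idx
    }
  }
  out
}

allele_universe <- function(samples, loci) {
  lapply(seq_along(loci), function(l) {
    vals <- unlist(lapply(samples, function(s)
      s$genotypes[, c(2L * l - 1L, 2L * l)]))
    sort(unique(vals[!is.na(vals)]))
  })
}

freq_matrix <- function(freqs, allele_sets) {
  Kmax <- max(lengths(allele_sets))
  m <- matrix(0, length(allele_sets), Kmax)
  for (l in seq_along(allele_sets)) {
    f <- freqs[[l]][as.character(allele_sets[[l]])]
    f[is.na(f)] <- 0
    m[l, seq_along(f)] <- f / sum(f)
  }
  m
}

empirical_frequencies <- function(sample, allele_sets = NULL, pseudo = 0) {
  loci <- sample$loci
  if (is.null(allele_sets)) allele_sets <- allele_universe(list(sample), loci)
  pseudo <- rep_len(pseudo, length(loci))  # per-locus smoothing mass
  out <- lapply(seq_along(loci), function(l) {
    a <- sample$genotypes[, c(2L * l - 1L, 2L * l)]
    cnt <- table(factor(a[!is.na(a)], levels = allele_sets[[l]])) + pseudo[l]
    setNames(as.numeric(cnt) / sum(cnt), as.character(allele_sets[[l]]))
  })
  names(out) <- loci
  out
}

#' Classify individuals into categories of descent (Gibbs sampler)
#'
#' Runs the data-augmented Gibbs sampler: parental individuals are held
#' fixed at their pure category and only inform the pool allele
#' frequencies; unknown individuals' categories, per-locus gene origins,
#' the pool frequencies and the mixing proportions are updated in turn.
#' Several chains are run from over-dispersed seeds and their posterior
#' means averaged; if any posterior mean differs across chains by more than
#' `convergence_tol` the run is repeated once with doubled sweeps and, if
#' still discordant, flagged.
#'
#' @param post_sample [pop_sample()] of individuals of unknown descent.
#' @param parental_samples List of two [pop_sample()] objects:
#'   `resident` then `supplemented` (known-origin).
#' @param settings [mcmc_settings()].
#' @param fix_frequencies If `TRUE`, hold allele frequencies at the
#'   parental empirical values (no updating).
#' @param fix_mixing If `TRUE`, hold mixing proportions uniform.
#' @return List: `posteriors` (data.frame: id, six category columns,
#'   `p_hybrid`, `hybrid_flag`), `diagnostics` (list with
#'   `max_chain_discrepancy`, `converged`, `reran`), `pi`, `settings`.
#' @export
run_gibbs <- function(post_sample, parental_samples, settings = mcmc_settings(),
                      fix_frequencies = FALSE, fix_mixing = FALSE) {
  res_par <- parental_samples[[1L]]; sup_par <- parental_samples[[2L]]
  loci <- post_sample$loci
  if (!identical(res_par$loci, loci) || !identical(sup_par$loci, loci))
    stop("parental and post samples must share the same loci")
  allele_sets <- allele_universe(list(post_sample, res_par, sup_par), loci)
  poly <- lengths(allele_sets) >= 2L
  if (!any(poly)) stop("no polymorphic shared loci")
  k_l <- pmax(lengths(allele_sets), 1L)
  prior_freq <- if (settings$prior == "jeffreys") 1 / k_l else rep(1, length(k_l))
  prior_pi <- if (settings$prior == "jeffreys") 1 / 6 else 1

  gU <- index_genotypes(post_sample$genotypes, allele_sets)
  gR <- index_genotypes(res_par$genotypes, allele_sets)
  gS <- index_genotypes(sup_par$genotypes, allele_sets)
  fR <- freq_matrix(empirical_frequencies(res_par, allele_sets, pseudo = prior_freq),
                    allele_sets)
  fS <- freq_matrix(empirical_frequencies(sup_par, allele_sets, pseudo = prior_freq),
                    allele_sets)

  one_pass <- function(burn, sweeps) {
    chains <- lapply(seq_len(settings$n_chains), function(ch) {
      set.seed(settings$seeds[ch])
      gibbs_hybrid_cpp(gU, gR, gS, lengths(allele_sets), descent_phi(),
                       as.integer(burn), as.integer(sweeps), fR, fS,
                       fix_frequencies, fix_mixing, prior_pi, prior_freq)
    })
    posts <- lapply(chains, `[[`, "post")
    disc <- 0
    if (length(posts) > 1L)
      for (a in 2:length(posts))
        disc <- max(disc, max(abs(posts[[a]] - posts[[1L]])))
    list(post = Reduce(`+`, posts) / length(posts),
         pi = Reduce(`+`, lapply(chains, `[[`, "pi")) / length(chains),
         disc = disc)
  }

  pass <- one_pass(settings$burn_in, settings$sweeps)
  reran <- FALSE
  if (pass$disc > settings$convergence_tol && settings$n_chains > 1L) {
    reran <- TRUE
    pass <- one_pass(2L * settings$burn_in, 2L * settings$sweeps)
  }
  converged <- pass$disc <= settings$convergence_tol
  if (!converged)
    warning("chains disagree beyond tolerance (max discrepancy ",
            signif(pass$disc, 3), ")")

  post <- pass$post
  colnames(post) <- rownames(descent_phi())
  p_hybrid <- rowSums(post[, c("F1", "F2", "BX_res", "BX_sup"), drop = FALSE])
  posteriors <- data.frame(id = post_sample$ids, post,
                           p_hybrid = p_hybrid,
                           hybrid_flag = p_hybrid > 0.50,
                           stringsAsFactors = FALSE, row.names = NULL)
  rv_log("classify", nrow(posteriors), " individuals, ",
         sum(posteriors$hybrid_flag), " nuclear hybrids; discrepancy ",
         signif(pass$disc, 3))
  list(posteriors = posteriors,
       diagnostics = list(max_chain_discrepancy = pass$disc,
                          converged = converged, reran = reran),
       pi = setNames(as.numeric(pass$pi), rownames(descent_phi())),
       settings = settings)
}

#' Apply the mitochondrial override and build the hybrid census
#'
#' Individuals above the age cutoff are excluded (conceived before
#' supplementation). An individual carrying a source-private haplotype
#' whose nuclear assignment is pure-resident is counted as a hybrid
#' (`mtDNA_override`): the nuclear call is taken to be a miss of real
#' introgression. An individual with a source-private haplotype assigned
#' pure-supplemented is counted pure-supplemented and excluded from the
#' denominator. A missing haplotype triggers no override.
#'
#' @param posteriors `posteriors` data.frame from [run_gibbs()].
#' @param metadata data.frame with `id`, `age`, `mt_haplotype`.
#' @param source_private_haplotypes Character vector of haplotype labels
#'   private to the source population.
#' @param age_cutoff Age above which individuals are excluded.
#' @return List: `table` (per-individual basis/status), `n_sampled`,
#'   `n_excluded_age`, `n_excluded_pure_sup`, `n_hybrids`, `denominator`,
#'   `proportion`.
#' @export
apply_mtdna_override <- function(posteriors, metadata, source_private_haplotypes,
                                 age_cutoff = 6L) {
  md <- metadata[match(posteriors$id, metadata$id), , drop = FALSE]
  over_age <- !is.na(md$age) & md$age > age_cutoff
  has_src_hap <- !is.na(md$mt_haplotype) &
    md$mt_haplotype %in% source_private_haplotypes
  cats <- rownames(descent_phi())
  nuclear <- cats[max.col(as.matrix(posteriors[, cats]))]
  nuclear_hybrid <- posteriors$hybrid_flag
  pure_sup <- !nuclear_hybrid & nuclear == "pure_sup" & has_src_hap
  override <- !nuclear_hybrid & nuclear == "pure_res" & has_src_hap
  hybrid <- (nuclear_hybrid | override) & !over_age & !pure_sup
  basis <- rep("none", nrow(posteriors))
  basis[hybrid & nuclear_hybrid & !has_src_hap] <- "nuclear"
  basis[hybrid & nuclear_hybrid & has_src_hap] <- "both"
  basis[hybrid & !nuclear_hybrid] <- "mtDNA_override"
  status <- ifelse(over_age, "excluded_age",
            ifelse(pure_sup, "excluded_pure_sup",
            ifelse(hybrid, "hybrid", "resident")))
  tab <- data.frame(id = posteriors$id, nuclear_assignment = nuclear,
                    p_hybrid = posteriors$p_hybrid,
                    mt_haplotype = md$mt_haplotype, age = md$age,
                    source_haplotype = has_src_hap,
                    status = status, basis = basis,
                    stringsAsFactors = FALSE)
  n_sampled <- nrow(tab)
  n_age <- sum(over_age)
  n_ps <- sum(pure_sup & !over_age)
  denom <- n_sampled - n_age - n_ps
  n_hyb <- sum(hybrid)
  list(table = tab, n_sampled = n_sampled, n_excluded_age = n_age,
       n_excluded_pure_sup = n_ps, n_hybrids = n_hyb, denominator = denom,
       proportion = if (denom > 0) n_hyb / denom else NA_real_)
}

#' Power assessment of the descent classifier
#'
#' Simulates `n_per_class` multilocus genotypes in each of the four hybrid
#' categories by gamete sampling from the parental pools' empirical allele
#' frequencies, classifies them together, and tabulates assignments
#' (assignment = highest-posterior category). The hybrid error for a class
#' is the proportion of its simulated genotypes assigned to either pure
#' category (false negatives); the class error is the proportion not
#' assigned to the simulated class.
#'
#' @param parental_samples As in [run_gibbs()].
#' @param n_per_class Simulated genotypes per hybrid class.
#' @param settings [mcmc_settings()].
#' @param classes Hybrid classes to simulate.
#' @return List: `assignment` (class x assigned-category count matrix),
#'   `summary` data.frame (per class + `Total`: n, hybrid_error,
#'   class_error), `posteriors`.
#' @export
power_simulation <- function(parental_samples, n_per_class = 1000L,
                             settings = mcmc_settings(),
                             classes = c("F1", "F2", "BX_res", "BX_sup")) {
  if (n_per_class < 1L) stop("n_per_class must be at least 1")
  res_par <- parental_samples[[1L]]; sup_par <- parental_samples[[2L]]
  loci <- res_par$loci
  allele_sets <- allele_universe(parental_samples, loci)
  fr <- empirical_frequencies(res_par, allele_sets)
  fs <- empirical_frequencies(sup_par, allele_sets)
  n_tot <- n_per_class * length(classes)
  truth <- rep(classes, each = n_per_class)
  geno <- matrix(NA_integer_, n_tot, 2L * length(loci))
  for (i in seq_len(n_tot))
    geno[i, ] <- simulate_individual(truth[i], fr, fs, "supplemented")$genotype
  sim <- pop_sample("SIMHYB", "post", sprintf("sim_%05d", seq_len(n_tot)),
                    loci, geno)
  fit <- run_gibbs(sim, parental_samples, settings)
  cats <- rownames(descent_phi())
  assigned <- cats[max.col(as.matrix(fit$posteriors[, cats]))]
  assignment <- table(factor(truth, levels = classes),
                      factor(assigned, levels = cats))
  hybrid_cols <- c("F1", "F2", "BX_res", "BX_sup")
  per_class <- data.frame(
    class = classes,
    n = as.integer(rowSums(assignment)),
    hybrid_error = rowSums(assignment[, c("pure_res", "pure_sup"), drop = FALSE]) /
      rowSums(assignment),
    class_error = 1 - diag(as.matrix(assignment[, classes, drop = FALSE])) /
      rowSums(assignment),
    stringsAsFactors = FALSE, row.names = NULL)
  total <- data.frame(class = "Total", n = sum(per_class$n),
                      hybrid_error = sum(assignment[, c("pure_res", "pure_sup")]) /
                        sum(assignment),
                      class_error = NA_real_, stringsAsFactors = FALSE)
  rv_log("power", "overall hybrid error ",
         signif(100 * total$hybrid_error, 3), "%")
  list(assignment = unclass(assignment), summary = rbind(per_class, total),
       posteriors = fit$posteriors, truth = truth)
}
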