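# Study-shaped synthetic data with known ground truth.
#
# Two diverged parental gene pools are drawn from a Dirichlet F-model around
# a common ancestral frequency vector; admixed individuals of known class
# are built by explicit gamete sampling; mitochondrial haplotypes follow the
# maternal line, with the source pool carrying private haplotypes and the
# resident pool a single shared one.

DESCENT_CLASSES <- c("pure_res", "pure_sup", "F1", "F2", "BX_res", "BX_sup")

#' Specify the synthetic-study generator
#'
#' Defaults emulate the motivating study: 16 polymorphic microsatellite
#' loci, a resident herd sampled before supplementation (n = 20), a source
#' sample of 31 supplemented ewes, and a post-supplementation sample of 48
#' whose composition mirrors the printed hybrid census (9 hybrids, 3
#' pure-supplemented, 1 over-age resident, remainder pure residents). The
#' source pool carries 4 private mitochondrial haplotypes at printed
#' frequencies (12, 3, 15, 1)/31; residents carry one shared haplotype.
#'
#' @param n_loci Number of microsatellite loci.
#' @param alleles_per_locus Integer, or integer vector per locus.
#' @param divergence Drift parameter in (0, 1); expected Weir–Cockerham
#'   F_ST between the pools is approximately this value.
#' @param diversity_asymmetry In `[0, 1)`: how much harder the resident
#'   pool drifts than the source pool (resident drift
#'   `divergence * (1 + a)`, source `divergence * (1 - a)`). The default
#'   0.5 emulates the study premise of a serially bottlenecked,
#'   low-diversity resident herd supplemented from a more diverse source;
#'   0 gives symmetric pools.
#' @param sample_sizes Named list: `resident_pre`, `source`, `post`.
#' @param hybrid_composition Named counts within the post sample for classes
#'   other than `pure_res` (which fills the remainder).
#' @param n_overage Number of over-age pure-resident decoys in the post
#'   sample (aged above `age_cutoff`).
#' @param age_cutoff Post-supplementation sampling targets individuals at or
#'   below this age.
#' @param mt_private_haplotypes Number of source-private haplotypes.
#' @param mt_hap_freqs Source haplotype frequencies (length
#'   `mt_private_haplotypes`; normalised internally).
#' @param mt_seq_length Control-region alignment length (bp).
#' @param mt_steps Substitution distances of each private haplotype from the
#'   shared haplotype.
#' @param mt_missing_rate Probability an individual's haplotype is
#'   unresolved (recorded missing).
#' @param missing_rate Per-locus genotype missing probability.
#' @param seed Integer seed; the build is reproducible given the seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_loci = 16L,
                           alleles_per_locus = 4L,
                           divergence = 0.2,
                           diversity_asymmetry = 0.5,
                           sample_sizes = list(resident_pre = 20L, source = 31L,
                                               post = 48L),
                           hybrid_composition = c(pure_sup = 3L, F1 = 3L, F2 = 3L,
                                                  BX_res = 2L, BX_sup = 1L),
                           n_overage = 1L,
                           age_cutoff = 6L,
                           mt_private_haplotypes = 4L,
                           mt_hap_freqs = c(12, 3, 15, 1),
                           mt_seq_length = 515L,
                           mt_steps = c(9L, 16L, 24L, 31L),
                           mt_missing_rate = 0.05,
                           missing_rate = 0.005,
                           seed = 1L) {
  if (divergence <= 0 || divergence >= 1) stop("divergence must be in (0, 1)")
  if (diversity_asymmetry < 0 || diversity_asymmetry >= 1 ||
      divergence * (1 + diversity_asymmetry) >= 1)
    stop("diversity_asymmetry must be in [0, 1) with divergence * (1 + a) < 1")
  k <- rep_len(as.integer(alleles_per_locus), n_loci)
  if (any(k < 2L)) stop("need at least 2 alleles per locus")
  comp <- setNames(integer(length(DESCENT_CLASSES)), DESCENT_CLASSES)
  comp[names(hybrid_composition)] <- as.integer(hybrid_composition)
  if (any(comp < 0L)) stop("negative class counts")
  n_post <- as.integer(sample_sizes$post)
  if (sum(comp[-1L]) + n_overage > n_post)
    stop("hybrid composition plus over-age decoys exceed the post sample size")
  comp["pure_res"] <- n_post - sum(comp[-1L])
  mt_hap_freqs <- rep_len(mt_hap_freqs, mt_private_haplotypes)
  mt_steps <- rep_len(as.integer(mt_steps), mt_private_haplotypes)
  structure(list(n_loci = as.integer(n_loci), alleles_per_locus = k,
                 divergence = divergence,
                 diversity_asymmetry = diversity_asymmetry,
                 sample_sizes = lapply(sample_sizes, as.integer),
                 composition = comp, n_overage = as.integer(n_overage),
                 age_cutoff = as.integer(age_cutoff),
                 mt_private_haplotypes = as.integer(mt_private_haplotypes),
                 mt_hap_freqs = mt_hap_freqs / sum(mt_hap_freqs),
                 mt_seq_length = as.integer(mt_seq_length),
                 mt_steps = mt_steps,
                 mt_missing_rate = mt_missing_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "generator_spec")
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Draw diverged parental allele frequencies
#'
#' Per locus, an ancestral frequency vector is drawn from a flat Dirichlet
#' and each pool's frequencies from `Dirichlet(p_anc * (1 - theta) / theta)`
#' with pool-specific drift `theta`: the resident pool uses
#' `divergence * (1 + a)` and the source pool `divergence * (1 - a)`
#' (`a` = `diversity_asymmetry`), so expected F_ST between the pools
#' increases with `divergence`, the pools coincide as `divergence -> 0`,
#' and the resident pool is the less diverse of the two when `a > 0`.
#'
#' @param spec A [generator_spec()].
#' @return List with elements `res` and `sup`, each a list (per locus) of
#'   allele-frequency vectors named by allele code.
#' @export
draw_parental_frequencies <- function(spec) {
  a <- spec$diversity_asymmetry
  theta_res <- spec$divergence * (1 + a)
  theta_sup <- spec$divergence * (1 - a)
  if (theta_sup <= 0) theta_sup <- .Machine$double.eps
  res <- sup <- vector("list", spec$n_loci)
  for (l in seq_len(spec$n_loci)) {
    k <- spec$alleles_per_locus[l]
    anc <- rdirichlet1(rep(1, k))
    codes <- as.character(100L + seq_len(k))  # fragment-size-style codes
    p_res <- rdirichlet1(anc * (1 - theta_res) / theta_res)
    p_sup <- rdirichlet1(anc * (1 - theta_sup) / theta_sup)
    res[[l]] <- setNames(p_res, codes)
    sup[[l]] <- setNames(p_sup, codes)
  }
  names(res) <- names(sup) <- paste0("Loc", sprintf("%02d", seq_len(spec$n_loci)))
  list(res = res, sup = sup)
}

draw_gamete <- function(class, freqs_res_l, freqs_sup_l) {
  # returns one allele code under the gamete distribution of the class
  pool_allele <- function(p) as.integer(names(p))[sample.int(length(p), 1L, prob = p)]
  switch(class,
         res = pool_allele(freqs_res_l),
         sup = pool_allele(freqs_sup_l),
         F1 = if (runif(1) < 0.5) pool_allele(freqs_res_l) else pool_allele(freqs_sup_l),
         stop("unknown gamete class ", class))
}

#' Simulate one individual of known descent class
#'
#' Pure individuals are two gamete draws from one pool per locus (so pure
#' samples are in Hardy–Weinberg equilibrium); an F1 receives one gamete
#' from each pool; an F2 receives two gametes from the F1 gamete
#' distribution; a backcross one F1 gamete and one pure gamete. The
#' mitochondrial haplotype is inherited from the dam's lineage.
#'
#' @param class One of `pure_res`, `pure_sup`, `F1`, `F2`, `BX_res`, `BX_sup`.
#' @param freqs_res,freqs_sup Per-locus allele-frequency lists
#'   (as from [draw_parental_frequencies()]).
#' @param dam_lineage `"resident"` or `"supplemented"`.
#' @return List with `genotype` (integer vector length 2L, locus-major) and
#'   `maternal_lineage`.
#' @export
simulate_individual <- function(class, freqs_res, freqs_sup, dam_lineage) {
  if (!class %in% DESCENT_CLASSES) stop("unknown descent class '", class, "'")
  dam_lineage <- match.arg(dam_lineage, c("resident", "supplemented"))
  L <- length(freqs_res)
  g <- integer(2L * L)
  for (l in seq_len(L)) {
    pr <- freqs_res[[l]]; ps <- freqs_sup[[l]]
    al <- switch(class,
      pure_res = c(draw_gamete("res", pr, ps), draw_gamete("res", pr, ps)),
      pure_sup = c(draw_gamete("sup", pr, ps), draw_gamete("sup", pr, ps)),
      F1       = c(draw_gamete("res", pr, ps), draw_gamete("sup", pr, ps)),
      F2       = c(draw_gamete("F1", pr, ps), draw_gamete("F1", pr, ps)),
      BX_res   = c(draw_gamete("F1", pr, ps), draw_gamete("res", pr, ps)),
      BX_sup   = c(draw_gamete("F1", pr, ps), draw_gamete("sup", pr, ps)))
    g[c(2L * l - 1L, 2L * l)] <- al
  }
  list(genotype = g, maternal_lineage = dam_lineage)
}

mutate_backbone <- function(backbone, n_subs, used_positions) {
  bases <- c("A", "C", "G", "T")
  pos <- sample(setdiff(seq_len(nchar(backbone)), used_positions), n_subs)
  s <- strsplit(backbone, "")[[1L]]
  for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1L)
  list(seq = paste0(s, collapse = ""), positions = pos)
}

#' Build a complete synthetic study
#'
#' Generates the pre-supplementation resident sample, the source sample, and
#' the post-supplementation sample with the requested descent-class
#' composition, together with an aligned control-region FASTA, the sidecar
#' metadata table and a truth table. Source-private haplotypes occur only in
#' the source sample and in post individuals of supplemented maternal
#' lineage; post individuals are aged at or below the cutoff except the
#' requested over-age decoys.
#'
#' @param spec A [generator_spec()].
#' @return List of class `synthetic_study`: `samples` (named list of
#'   [pop_sample()]: `RES`, `SRC`, `POST`), `frequencies`, `sequences`
#'   (named character vector incl. per-haplotype reference sequences),
#'   `metadata`, `truth` (data.frame id, class, maternal_lineage),
#'   `haplotype_names`, `spec`.
#' @export
build_study <- function(spec = generator_spec()) {
  set.seed(spec$seed)
  freqs <- draw_parental_frequencies(spec)
  loci <- names(freqs$res)

  # mitochondrial reference sequences: shared haplotype "E" plus private A..D
  backbone <- paste0(sample(c("A", "C", "G", "T"), spec$mt_seq_length,
                            replace = TRUE), collapse = "")
  hap_names <- c(LETTERS[seq_len(spec$mt_private_haplotypes)],
                 LETTERS[spec$mt_private_haplotypes + 1L])
  shared_hap <- hap_names[length(hap_names)]
  hap_seqs <- setNames(character(length(hap_names)), hap_names)
  hap_seqs[shared_hap] <- backbone
  used <- integer()
  for (i in seq_len(spec$mt_private_haplotypes)) {
    m <- mutate_backbone(backbone, spec$mt_steps[i], used)
    hap_seqs[hap_names[i]] <- m$seq
    used <- c(used, m$positions)  # keep private haplotypes mutually distinct
  }

  draw_hap <- function(lineage) {
    if (lineage == "resident") shared_hap
    else hap_names[sample.int(spec$mt_private_haplotypes, 1L,
                              prob = spec$mt_hap_freqs)]
  }
  # the source sample carries the private haplotypes at their configured
  # frequencies exactly (quota assignment, then shuffled), mirroring an
  # observed per-population haplotype frequency table
  quota_haps <- function(n) {
    cnt <- diff(c(0L, round(cumsum(spec$mt_hap_freqs) * n)))
    sample(rep(hap_names[seq_len(spec$mt_private_haplotypes)], cnt))
  }

  make_block <- function(prefix, classes, lineages, ages, pop, epoch,
                         haps = NULL) {
    n <- length(classes)
    ids <- sprintf("%s_%03d", prefix, seq_len(n))
    geno <- matrix(NA_integer_, n, 2L * spec$n_loci)
    if (is.null(haps)) haps <- vapply(lineages, draw_hap, character(1L))
    for (i in seq_len(n)) {
      ind <- simulate_individual(classes[i], freqs$res, freqs$sup, lineages[i])
      geno[i, ] <- ind$genotype
    }
    # inject genotype missingness
    drop <- matrix(runif(n * spec$n_loci) < spec$missing_rate, n, spec$n_loci)
    for (l in seq_len(spec$n_loci)) geno[drop[, l], c(2L * l - 1L, 2L * l)] <- NA_integer_
    hap_missing <- runif(n) < spec$mt_missing_rate
    haps[hap_missing] <- NA_character_
    md <- data.frame(id = ids, population = pop,
                     sex = sample(c("ewe", "ram"), n, replace = TRUE),
                     age = ages, mt_haplotype = haps,
                     stringsAsFactors = FALSE)
    smp <- pop_sample(pop, epoch, ids, loci, geno, md)
    truth <- data.frame(id = ids, class = classes, maternal_lineage = lineages,
                        stringsAsFactors = FALSE)
    list(sample = smp, truth = truth, haps = haps)
  }

  sz <- spec$sample_sizes
  res_block <- make_block("RES", rep("pure_res", sz$resident_pre),
                          rep("resident", sz$resident_pre),
                          sample(1:9, sz$resident_pre, replace = TRUE),
                          "RES", "pre")
  src_block <- make_block("SRC", rep("pure_sup", sz$source),
                          rep("supplemented", sz$source),
                          sample(1:9, sz$source, replace = TRUE),
                          "SRC", "source", haps = quota_haps(sz$source))

  comp <- spec$composition
  n_overage <- spec$n_overage
  classes <- c(rep("pure_res", comp["pure_res"]),
               rep("pure_sup", comp["pure_sup"]),
               rep("F1", comp["F1"]), rep("F2", comp["F2"]),
               rep("BX_res", comp["BX_res"]), rep("BX_sup", comp["BX_sup"]))
  # maternal lineage by pedigree: only ewes were supplemented, so F1, F2 and
  # BX_sup matrilines trace to a supplemented dam; BX_res dams are F1 or
  # resident with equal chance
  lineages <- vapply(classes, function(cl) switch(cl,
      pure_res = "resident", pure_sup = "supplemented",
      F1 = "supplemented", F2 = "supplemented", BX_sup = "supplemented",
      BX_res = if (runif(1) < 0.5) "supplemented" else "resident"),
    character(1L))
  ord <- sample.int(length(classes))
  classes <- classes[ord]; lineages <- lineages[ord]
  ages <- sample(0:spec$age_cutoff, length(classes), replace = TRUE)
  if (n_overage > 0L) {
    overage_idx <- sample(which(classes == "pure_res"), n_overage)
    ages[overage_idx] <- sample((spec$age_cutoff + 1L):(spec$age_cutoff + 3L),
                                n_overage, replace = TRUE)
  }
  post_block <- make_block("POST", classes, lineages, ages, "POST", "post")

  metadata <- rbind(res_block$sample$metadata, src_block$sample$metadata,
                    post_block$sample$metadata)
  truth <- rbind(res_block$truth, src_block$truth, post_block$truth)
  sequenced <- !is.na(metadata$mt_haplotype)
  sequences <- setNames(hap_seqs[metadata$mt_haplotype[sequenced]],
                        metadata$id[sequenced])

  structure(list(samples = list(RES = res_block$sample, SRC = src_block$sample,
                                POST = post_block$sample),
                 frequencies = freqs, sequences = sequences,
                 haplotype_refs = hap_seqs, metadata = metadata, truth = truth,
                 shared_haplotype = shared_hap,
                 private_haplotypes = hap_names[seq_len(spec$mt_private_haplotypes)],
                 spec = spec),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Writes the Genepop genotype file, aligned FASTA, sidecar metadata CSV and
#' truth-table CSV into a directory.
#'
#' @param study A [build_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(genepop = file.path(dir, "genotypes.gen"),
                fasta = file.path(dir, "control_region.fasta"),
                metadata = file.path(dir, "metadata.csv"),
                truth = file.path(dir, "truth.csv"))
  write_genepop(study$samples, paths$genepop)
  write_fasta_alignment(study$sequences, paths$fasta)
  write.csv(study$metadata, paths$metadata, row.names = FALSE, na = "")
  write.csv(study$truth, paths$truth, row.names = FALSE)
  rv_log("simulate", "wrote study to ", dir,
         " (seed ", study$spec$seed, ", digest ",
         substr(tools::md5sum(paths$genepop), 1, 8), ")")
  invisible(paths)
}
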