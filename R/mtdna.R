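# Haplotype collapsing of aligned control-region sequences, private-
# haplotype identification, haplotype diversity and mean pairwise
# nucleotide differences.

#' Collapse an alignment into haplotypes
#'
#' Haplotypes are equivalence classes under exact identity, ignoring
#' positions where a sequence carries `N` or a gap. Fully resolved
#' sequences define the haplotypes; an ambiguous sequence is assigned to
#' the unique haplotype it is compatible with, and left unassigned
#' (missing) when it matches none or several. Labels are `A`, `B`, ... by
#' descending overall count, ties broken by first occurrence.
#'
#' @param alignment Named character vector of equal-length sequences
#'   (see [read_fasta_alignment()]).
#' @param populations Optional named character vector mapping sequence id
#'   to population, used to build per-population counts.
#' @return List of class `haplotype_table`: `haplotypes` (label ->
#'   representative sequence), `assignment` (id -> label, `NA` if
#'   unresolved), `counts` (population x haplotype matrix, or overall),
#'   `n_variable_sites`, `distances` (pairwise substitution steps between
#'   haplotypes).
#' @export
collapse_haplotypes <- function(alignment, populations = NULL) {
  if (!length(alignment)) stop("empty alignment")
  if (length(unique(nchar(alignment))) > 1L) stop("sequences must be aligned")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  ambig <- !(mat %in% c("A", "C", "G", "T"))
  dim(ambig) <- dim(mat)

  resolved <- rowSums(ambig) == 0L
  if (!any(resolved)) stop("no fully resolved sequences in alignment")
  key <- apply(mat[resolved, , drop = FALSE], 1L, paste0, collapse = "")
  reps <- key[!duplicated(key)]
  assignment <- rep(NA_integer_, length(alignment))
  assignment[resolved] <- match(key, reps)
  # ambiguous sequences: unique compatible haplotype or unresolved
  rep_mat <- do.call(rbind, strsplit(reps, ""))
  for (i in which(!resolved)) {
    ok <- vapply(seq_len(nrow(rep_mat)), function(h) {
      use <- !ambig[i, ]
      all(mat[i, use] == rep_mat[h, use])
    }, logical(1L))
    if (sum(ok) == 1L) assignment[i] <- which(ok)
  }

  # label by descending count, ties by first occurrence
  cnt <- tabulate(assignment, nbins = length(reps))
  ord <- order(-cnt, seq_along(reps))
  relabel <- match(seq_along(reps), ord)
  assignment <- relabel[assignment]
  reps <- reps[ord]
  labels <- LETTERS[seq_along(reps)]
  if (length(reps) > 26L)
    labels <- c(LETTERS, paste0("A", LETTERS))[seq_along(reps)]
  names(reps) <- labels
  assignment_lab <- labels[assignment]
  names(assignment_lab) <- names(alignment)

  # variable sites: columns with >= 2 distinct unambiguous bases
  n_var <- sum(apply(mat, 2L, function(col)
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2L))

  # pairwise substitution steps between haplotype representatives
  H <- length(reps)
  d <- matrix(0L, H, H, dimnames = list(labels, labels))
  rep_mat <- rep_mat[ord, , drop = FALSE]
  if (H > 1L)
    for (a in 1:(H - 1L)) for (b in (a + 1L):H)
      d[a, b] <- d[b, a] <- sum(rep_mat[a, ] != rep_mat[b, ])

  counts <- if (is.null(populations)) {
    m <- matrix(tabulate(match(assignment_lab, labels), nbins = H), 1L,
                dimnames = list("overall", labels))
    m
  } else {
    pops <- populations[names(alignment)]
    t(table(factor(assignment_lab, levels = labels),
            factor(pops, levels = unique(pops))))
  }

  structure(list(haplotypes = reps, assignment = assignment_lab,
                 counts = unclass(counts), n_variable_sites = n_var,
                 distances = d),
            class = "haplotype_table")
}

#' Identify population-private haplotypes
#'
#' A haplotype is private to a population if, among the reference
#' populations considered (by design the pre-supplementation and source
#' samples only), it occurs in that population alone.
#'
#' @param counts Population x haplotype count matrix.
#' @param reference_pops Populations against which privacy is judged;
#'   defaults to all rows of `counts`.
#' @return Named character vector haplotype -> population (`NA` when not
#'   private).
#' @export
private_haplotypes <- function(counts, reference_pops = rownames(counts)) {
  m <- counts[reference_pops, , drop = FALSE]
  vapply(colnames(m), function(h) {
    present <- rownames(m)[m[, h] > 0]
    if (length(present) == 1L) present else NA_character_
  }, character(1L))
}

#' Unbiased haplotype (gene) diversity
#'
#' `H_D = (n / (n - 1)) (1 - sum p_i^2)`: the probability that two
#' sequences drawn without replacement carry different haplotypes. It is
#' maximised, for a fixed number of haplotypes, when counts are equal.
#'
#' @param counts Integer haplotype counts for one population.
#' @return `H_D`, or `NA` when fewer than 2 sequences.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Mean pairwise nucleotide differences within a population
#'
#' Unbiased estimator `k = (n / (n - 1)) * sum_{i,j} p_i p_j d_ij` over
#' haplotype frequencies and pairwise substitution counts.
#'
#' @param counts Named haplotype counts for one population.
#' @param distances Symmetric matrix of pairwise site differences with zero
#'   diagonal, dimnames covering `names(counts)`.
#' @return `k`, or `NA` when fewer than 2 sequences.
#' @export
mean_pairwise_differences <- function(counts, distances) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  h <- names(counts)
  d <- distances[h, h, drop = FALSE]
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0))
    stop("distances must be symmetric with zero diagonal")
  p <- counts / n
  (n / (n - 1)) * as.numeric(t(p) %*% d %*% p)
}

#' Per-population mitochondrial diversity summary
#'
#' @param hap_table A [collapse_haplotypes()] result with per-population
#'   counts.
#' @return data.frame: population, n, n_haplotypes, H_D, k.
#' @export
mtdna_summary <- function(hap_table) {
  pops <- rownames(hap_table$counts)
  do.call(rbind, lapply(pops, function(p) {
    cnt <- hap_table$counts[p, ]
    cnt <- cnt[cnt > 0]
    data.frame(population = p, n = sum(cnt), n_haplotypes = length(cnt),
               H_D = haplotype_diversity(cnt),
               k = if (length(cnt)) mean_pairwise_differences(cnt, hap_table$distances)
                   else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
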