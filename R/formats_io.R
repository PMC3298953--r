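# Genepop, aligned-FASTA and sidecar-CSV input/output, plus run configuration.
#
# A population sample is held as a "pop_sample" list:
#   label     : population label
#   epoch     : "pre", "post" or "source"
#   ids       : character vector of individual ids
#   loci      : character vector of locus names
#   genotypes : integer matrix n x 2L; columns "<locus>.1", "<locus>.2";
#               NA encodes a missing genotype (both columns NA together)
#   metadata  : data.frame(id, population, sex, age, mt_haplotype) or NULL
# Allele identity is the integer code itself; fragment-size binning is
# assumed done upstream.

#' Construct a population sample
#'
#' @param label Population label.
#' @param epoch One of `"pre"`, `"post"`, `"source"`.
#' @param ids Character vector of individual ids (unique).
#' @param loci Character vector of locus names.
#' @param genotypes Integer matrix with `length(ids)` rows and
#'   `2 * length(loci)` columns (allele pairs per locus, `NA` = missing).
#' @param metadata Optional data.frame with columns `id`, `population`,
#'   `sex`, `age`, `mt_haplotype` (one row per individual).
#' @return An object of class `pop_sample`.
#' @export
pop_sample <- function(label, epoch, ids, loci, genotypes, metadata = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  epoch <- match.arg(epoch, c("pre", "post", "source"))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate individual ids in sample '", label, "'")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != length(ids) || ncol(genotypes) != 2L * length(loci))
    stop("genotype matrix dimensions do not match ids/loci")
  colnames(genotypes) <- paste0(rep(loci, each = 2L), c(".1", ".2"))
  rownames(genotypes) <- ids
  # a half-called genotype is treated as fully missing
  for (l in seq_along(loci)) {
    cols <- c(2L * l - 1L, 2L * l)
    miss <- is.na(genotypes[, cols[1L]]) | is.na(genotypes[, cols[2L]])
    genotypes[miss, cols] <- NA_integer_
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    need <- c("id", "population", "sex", "age", "mt_haplotype")
    missing_cols <- setdiff(need, names(metadata))
    if (length(missing_cols))
      stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
    metadata <- metadata[match(ids, metadata$id), need]
    if (anyNA(metadata$id)) stop("metadata does not cover all individuals")
    if (!all(metadata$population == label))
      stop("metadata population must equal sample label '", label, "'")
    if (any(!is.na(metadata$age) & metadata$age < 0)) stop("negative age in metadata")
  }
  structure(list(label = label, epoch = epoch, ids = ids, loci = loci,
                 genotypes = genotypes, metadata = metadata),
            class = "pop_sample")
}

#' @export
print.pop_sample <- function(x, ...) {
  nmiss <- sum(is.na(x$genotypes[, seq(1L, ncol(x$genotypes), by = 2L)]))
  cat("pop_sample '", x$label, "' (", x$epoch, "): ",
      length(x$ids), " individuals, ", length(x$loci), " loci, ",
      nmiss, " missing genotypes\n", sep = "")
  invisible(x)
}

#' Per-individual genotype missing rate
#'
#' @param sample A [pop_sample()].
#' @return Named numeric vector in `[0, 1]`, one entry per individual.
#' @export
missing_rate <- function(sample) {
  first <- sample$genotypes[, seq(1L, ncol(sample$genotypes), by = 2L), drop = FALSE]
  setNames(rowMeans(is.na(first)), sample$ids)
}

# ---- Genepop ---------------------------------------------------------------

#' Read a Genepop file
#'
#' Accepts the common Genepop dialect with 2- or 3-digit allele codes,
#' comma-separated or one-per-line locus names, and `POP`-delimited
#' populations. `000000`/`0000` (or any pair containing a zero code) is
#' treated as a missing genotype. Genepop itself carries no population
#' labels, so blocks are named `pop1`, `pop2`, ... unless `labels` is given
#' (the sidecar metadata CSV is the canonical source of labels).
#'
#' @param path Path to the Genepop file.
#' @param labels Optional character vector of population labels, one per
#'   `POP` block.
#' @param epochs Optional character vector of epochs matching `labels`;
#'   defaults to `"pre"`.
#' @return Named list of [pop_sample()] objects.
#' @export
read_genepop <- function(path, labels = NULL, epochs = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed Genepop file (too short): ", path)
  body <- lines[-1L]  # first line is a title/comment
  is_pop <- toupper(trimws(body)) %in% c("POP")
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("malformed Genepop header: no POP line in ", path)
  locus_lines <- trimws(body[seq_len(first_pop - 1L)])
  loci <- unlist(strsplit(locus_lines[nzchar(locus_lines)], "\\s*,\\s*"))
  loci <- trimws(loci[nzchar(loci)])
  if (!length(loci)) stop("malformed Genepop header: no loci in ", path)
  pop_breaks <- which(is_pop)
  samples <- list()
  for (b in seq_along(pop_breaks)) {
    from <- pop_breaks[b] + 1L
    to <- if (b < length(pop_breaks)) pop_breaks[b + 1L] - 1L else length(body)
    rows <- body[seq(from, length.out = max(0L, to - from + 1L))]
    rows <- rows[nzchar(trimws(rows))]
    if (!length(rows)) stop("empty POP block ", b, " in ", path)
    ids <- character(length(rows))
    geno <- matrix(NA_integer_, length(rows), 2L * length(loci))
    for (r in seq_along(rows)) {
      line_no <- which(lines == rows[r])[1L]
      parts <- strsplit(rows[r], ",")[[1L]]
      if (length(parts) < 2L)
        stop("parse error at line ", line_no, ": expected 'id , genotypes'")
      ids[r] <- trimws(parts[1L])
      fields <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1L]]
      if (length(fields) != length(loci))
        stop("parse error at line ", line_no, ": ", length(fields),
             " genotype fields for ", length(loci), " loci")
      for (l in seq_along(fields)) {
        f <- fields[l]
        if (!grepl("^[0-9]+$", f) || !(nchar(f) %in% c(4L, 6L)))
          stop("parse error at line ", line_no, ": unknown allele encoding '", f, "'")
        w <- nchar(f) / 2L
        a1 <- as.integer(substr(f, 1L, w))
        a2 <- as.integer(substr(f, w + 1L, 2L * w))
        if (a1 > 0L && a2 > 0L) geno[r, c(2L * l - 1L, 2L * l)] <- c(a1, a2)
      }
    }
    lab <- if (!is.null(labels) && !is.na(labels[b])) labels[b] else paste0("pop", b)
    ep <- if (!is.null(epochs)) epochs[b] else "pre"
    samples[[lab]] <- pop_sample(lab, ep, ids, loci, geno)
  }
  samples
}

#' Write samples to a Genepop file
#'
#' Writes 3-digit allele codes; missing genotypes become `000000`.
#'
#' @param samples Named list of [pop_sample()] objects sharing one locus set.
#' @param path Output path.
#' @param title First (comment) line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(samples, path, title = "rescueval genepop export") {
  loci <- samples[[1L]]$loci
  for (s in samples) if (!identical(s$loci, loci))
    stop("all samples must share the same loci in the same order")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, loci), con)
  for (s in samples) {
    writeLines("POP", con)
    for (r in seq_along(s$ids)) {
      g <- s$genotypes[r, ]
      g[is.na(g)] <- 0L
      fields <- vapply(seq_along(loci), function(l)
        sprintf("%03d%03d", g[2L * l - 1L], g[2L * l]), character(1L))
      writeLines(paste0(s$ids[r], " , ", paste(fields, collapse = " ")), con)
    }
  }
  invisible(path)
}

# ---- FASTA -----------------------------------------------------------------

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (equal-length sequences;
#'   IUPAC bases plus `-` and `N`). Lowercase is normalised to uppercase.
#' @return Named character vector of sequences.
#' @export
read_fasta_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(dna), paste0, character(1L), collapse = ""))
  names(seqs) <- names(dna)
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1L])
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment error in ", path, ": unequal sequence lengths (",
         paste(sort(unique(nchar(seqs))), collapse = ", "), ")")
  seqs
}

#' Write an aligned FASTA file
#'
#' @param seqs Named character vector of equal-length sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(seqs, path) {
  if (length(unique(nchar(seqs))) > 1L) stop("sequences must be aligned (equal length)")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), toupper(seqs[[i]])), con)
  invisible(path)
}

# ---- sidecar metadata ------------------------------------------------------

#' Read the per-individual metadata sidecar CSV
#'
#' Columns: `id`, `population`, `sex` (`ewe`/`ram`/`unknown`), `age`
#' (integer years, empty = unknown), `mt_haplotype` (empty = missing).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "population", "sex", "age", "mt_haplotype")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols))
    stop("metadata file ", path, " missing columns: ",
         paste(missing_cols, collapse = ", "))
  md$id <- as.character(md$id)
  md$age <- suppressWarnings(as.integer(md$age))
  md$mt_haplotype[!is.na(md$mt_haplotype) & md$mt_haplotype == ""] <- NA_character_
  bad_sex <- !md$sex %in% c("ewe", "ram", "unknown")
  if (any(bad_sex)) stop("invalid sex values: ", paste(unique(md$sex[bad_sex]), collapse = ", "))
  if (any(!is.na(md$age) & md$age < 0)) stop("negative ages in ", path)
  md[, need]
}

#' Attach sidecar metadata to samples
#'
#' @param samples Named list of [pop_sample()] objects.
#' @param metadata data.frame from [read_metadata()].
#' @return The samples, each with its `metadata` slot filled.
#' @export
attach_metadata <- function(samples, metadata) {
  lapply(samples, function(s)
    pop_sample(s$label, s$epoch, s$ids, s$loci, s$genotypes,
               metadata[metadata$population == s$label, , drop = FALSE]))
}

# ---- configuration ---------------------------------------------------------

#' Load a study configuration
#'
#' Reads a YAML study configuration and applies defaults
#' (`years_elapsed = 6`, `age_cutoff = 6`). Expected keys:
#' `populations` (map: per treatment population `census_size_post`,
#' `supplemented_ewe_ages`, optional `baseline_lambs_per_100_ewes`),
#' `rng_seed`, and optional `paths` (`genepop`, `fasta`, `metadata`).
#'
#' @param path YAML file path. Alternatively pass a pre-parsed list via
#'   `config`.
#' @param config Optional list overriding `path`.
#' @return A validated list of class `study_config`.
#' @export
load_config <- function(path = NULL, config = NULL) {
  if (is.null(config)) {
    if (is.null(path)) stop("config error: provide a path or a config list")
    config <- yaml::read_yaml(path)
  }
  defaults <- list(years_elapsed = 6L, age_cutoff = 6L, rng_seed = 1L,
                   paths = list(), populations = list())
  cfg <- modifyList(defaults, config)
  bad <- character()
  if (cfg$years_elapsed < 1L) bad <- c(bad, "years_elapsed")
  if (cfg$age_cutoff < 0L) bad <- c(bad, "age_cutoff")
  for (p in names(cfg$populations)) {
    pop <- cfg$populations[[p]]
    if (is.null(pop$census_size_post) || pop$census_size_post <= 0)
      bad <- c(bad, paste0("populations.", p, ".census_size_post"))
    if (!is.null(pop$supplemented_ewe_ages) && any(pop$supplemented_ewe_ages < 0))
      bad <- c(bad, paste0("populations.", p, ".supplemented_ewe_ages"))
  }
  if (length(bad))
    stop("config error: invalid or missing keys: ", paste(bad, collapse = ", "))
  structure(cfg, class = c("study_config", "list"))
}
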