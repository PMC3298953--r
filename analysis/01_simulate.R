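# Build the synthetic study standing in for the undeposited genotypes:
# two diverged parental gene pools (the resident herd less diverse than the
# source, F_ST near 0.2), a post-supplementation sample with known descent
# classes, control-region haplotypes on the maternal lines, and sidecar
# metadata. Writes Genepop/FASTA/CSV inputs plus the truth table.

source("analysis/00_setup.R")
rv_logging(TRUE)

study <- build_study(study_generator())
paths <- write_study(study, STUDY_DIR)

truth_post <- study$truth[study$truth$id %in% study$samples$POST$ids, ]
cat("\nSynthetic study written to", STUDY_DIR, "\n")
cat("Samples:", paste(sprintf("%s n=%d", names(study$samples),
                              vapply(study$samples, function(s) length(s$ids),
                                     integer(1))), collapse = ", "), "\n")
cat("Post-supplementation truth:\n")
print(table(truth_post$class))
cat("Haplotypes: shared", study$shared_haplotype, "+ private",
    paste(study$private_haplotypes, collapse = ","), "\n")
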