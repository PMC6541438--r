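#!/usr/bin/env Rscript
# Stage 2: strain pseudo-genomes and 0-mismatch allelic assignment.
#
# Substitutes the maternal and paternal SNP alleles into the reference to
# build the two in-silico strain genomes, derives strain transcriptomes,
# and assigns every read by exact full-length matching against both. A read
# matching a single locus in only one strain is allelic; a SNP-free span
# matches both (shared); multi-locus hits are excluded as multi-mappers.

suppressMessages(library(xciallele))

outdir <- "results/run"
config <- read_run_config(file.path(outdir, "config.yaml"))
stage_pseudogenomes(outdir)
stage_assign(outdir, k = config$k)

samples <- read.delim(file.path(outdir, "samples.tsv"))
summ <- do.call(rbind, lapply(samples$embryo_id, function(id) {
  s <- read.delim(file.path(outdir, "assignments", paste0(id, "_summary.tsv")))
  setNames(s$n, s$status)
}))
tot <- colSums(summ)
message(sprintf(
  "assigned %d reads: %.1f%% allelic, %.1f%% shared, %.1f%% unmapped",
  sum(tot[c("maternal","paternal","shared","multimapped","unmapped")]),
  100 * (tot[["maternal"]] + tot[["paternal"]]) / sum(tot[1:5]),
  100 * tot[["shared"]] / sum(tot[1:5]),
  100 * tot[["unmapped"]] / sum(tot[1:5])))
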