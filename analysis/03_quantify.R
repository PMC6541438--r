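#!/usr/bin/env Rscript
# Stage 3: per-SNP and per-gene allelic quantification.
#
# Counts maternal/paternal reads at every exonic SNP, retains SNPs with at
# least 10 allelic reads, averages retained SNPs (unweighted) to gene-level
# paternal percentages, and splits reads-per-million expression into
# maternal and paternal components.

suppressMessages(library(xciallele))

outdir <- "results/run"
config <- read_run_config(file.path(outdir, "config.yaml"))
stage_quantify(outdir, min_snp_reads = config$min_snp_reads)

samples <- read.delim(file.path(outdir, "samples.tsv"))
inf <- vapply(samples$embryo_id, function(id) {
  tb <- read.delim(file.path(outdir, "quant", paste0(id, "_gene_table.tsv")))
  sum(tb$n_informative_snps >= 1)
}, numeric(1))
message(sprintf("informative genes per embryo: median %d of 60",
                as.integer(median(inf))))
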