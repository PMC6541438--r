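#!/usr/bin/env Rscript
# Stage 1: simulate the hybrid-cross experiment.
#
# Generates the toy reference (40 X-linked + 20 autosomal genes, ~1 exonic
# SNP / 250 bp between the maternal 129/S1-like and paternal JF1/Ms-like
# haplotypes) and RNA-seq reads for 20 embryos: 4 each of fl/fl, fl/- and
# -/- (imprinted XCI), 5 m-/- (random XCI mosaic) and 3 mz-/- (random XCI
# plus biallelic-Xist cells). Reads carry full allele-of-origin truth.

suppressMessages(library(xciallele))

outdir <- "results/run"
config <- default_run_config(seed = 1L)
samples <- stage_simulate(config, outdir)

message(sprintf("simulated %d embryos across %d genotype groups into %s",
                nrow(samples), length(unique(samples$genotype)), outdir))
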