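#!/usr/bin/env Rscript
# Stage 5: allele-specific Xist FISH probe panel.
#
# Designs the 5-SNP panel against the run's Xist-like gene: per SNP, two
# 28-nt detection oligos (one per strain allele, polymorphic base at
# position 5 from the 5' end; Quasar 570 maternal / Quasar 670 paternal)
# and one shared mask oligo leaving a 10-nt free hybridization window.

suppressMessages(library(xciallele))

outdir <- "results/run"
# Xist is a multi-kilobase transcript; probe design targets a dedicated
# 4 kb Xist-like gene so a 5-SNP panel exists at ~1 SNP / 250 bp.
ref <- make_toy_reference(n_autosomal_genes = 1, n_x_genes = 2,
                          gene_len = 4000, seed = 2001)
snp_t <- transcript_snp_positions(ref$genes, ref$variants)
xist <- ref$genes$gene_id[ref$genes$is_xist_like]
mat_tx <- strain_transcriptome(
  substitute_snps(ref$genome, ref$variants, "maternal"), ref$genes)
pat_tx <- strain_transcriptome(
  substitute_snps(ref$genome, ref$variants, "paternal"), ref$genes)

panel <- suppressWarnings(
  design_probe_panel(as.character(mat_tx[[xist]]),
                     as.character(pat_tx[[xist]]),
                     snp_t[snp_t$gene_id == xist, ]))
val <- validate_discrimination(panel, as.character(mat_tx[[xist]]),
                               as.character(pat_tx[[xist]]))
dir.create(file.path(outdir, "probes"), showWarnings = FALSE)
write_probe_panel(panel, file.path(outdir, "probes", "xist_allele_panel"))
message(sprintf(
  "designed %d detection oligos + %d masks on %s; discrimination failures: %d",
  nrow(panel$probes), nrow(panel$masks), xist, attr(val, "n_failures")))
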