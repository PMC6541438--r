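#!/usr/bin/env Rscript
# Stage 4: genotype-group statistics and the allelic heat map.
#
# Restricts to X-linked genes informative in every sample, computes each
# embryo's mean paternal percentage, compares genotype groups pairwise
# (Welch on allelic ratios; Student on normalized maternal/paternal
# expression), and draws the heat map ordered by allelic expression in
# fl/fl embryos.

suppressMessages(library(xciallele))

outdir <- "results/run"
config <- read_run_config(file.path(outdir, "config.yaml"))
summary <- stage_stats(outdir, reference_group = config$reference_group)

gm <- unlist(summary$group_mean_paternal_pct)
message("group mean paternal %: ",
        paste(sprintf("%s = %.1f", names(gm), gm), collapse = ", "))
welch <- summary$pairwise_welch
key <- welch$group_a == "fl/fl" & welch$group_b == "m-/-" |
  welch$group_a == "m-/-" & welch$group_b == "fl/fl"
message(sprintf("m-/- vs fl/fl Welch p = %.3g (imprinted -> random shift)",
                welch$p_value[key]))

if (requireNamespace("pheatmap", quietly = TRUE)) {
  mat <- as.matrix(read.delim(file.path(outdir, "results", "gene_matrix.tsv"),
                              row.names = 1, check.names = FALSE))
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  pheatmap::pheatmap(
    mat, cluster_rows = FALSE, cluster_cols = FALSE,
    main = "% paternal-X expression (genes ordered by fl/fl)",
    filename = "results/figures/allelic_heatmap.pdf", width = 9, height = 8)
  message("wrote results/figures/allelic_heatmap.pdf")
}
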