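#' Count maternal and paternal reads per SNP site
#'
#' Intersects each allelically assigned read's transcript span with the
#' exonic SNP positions of its gene and increments every covered SNP on
#' the read's haplotype. Shared (SNP-free) reads contribute to no SNP;
#' multimapped and unmapped reads are excluded entirely. SNPs with zero
#' coverage are reported with counts (0, 0) and an undefined paternal
#' percentage. A SNP is retained when its total allelic coverage reaches
#' `min_reads` (inclusive boundary; default 10).
#'
#' @param assignments output of [assign_all()].
#' @param genes,variants gene models and strain variants.
#' @param min_reads retention threshold on maternal + paternal reads.
#' @return data.frame: gene_id, chrom, pos, tpos, maternal_reads,
#'   paternal_reads, total_reads, paternal_pct (NA when uncovered),
#'   retained.
#' @export
count_snp_alleles <- function(assignments, genes, variants, min_reads = 10L) {
  snp_t <- transcript_snp_positions(genes, variants)
  snp_t$maternal_reads <- 0L
  snp_t$paternal_reads <- 0L
  a <- assignments[assignments$status %in% c("maternal", "paternal") &
                     !is.na(assignments$gene_id), , drop = FALSE]
  if (nrow(a) > 0L && nrow(snp_t) > 0L) {
    for (col in c("maternal", "paternal")) {
      ar <- a[a$status == col, , drop = FALSE]
      if (nrow(ar) == 0L) next
      for (gene_id in unique(ar$gene_id)) {
        rows <- which(snp_t$gene_id == gene_id)
        if (length(rows) == 0L) next
        r <- ar[ar$gene_id == gene_id, , drop = FALSE]
        tp <- snp_t$tpos[rows]
        # overlap counts: SNP covered when tpos in [start, start+len-1]
        cov <- vapply(tp, function(p)
          sum(r$tpos <= p & r$tpos + r$read_len - 1L >= p), integer(1))
        snp_t[rows, paste0(col, "_reads")] <-
          snp_t[rows, paste0(col, "_reads")] + cov
      }
    }
  }
  snp_t$total_reads <- snp_t$maternal_reads + snp_t$paternal_reads
  snp_t$paternal_pct <- ifelse(snp_t$total_reads > 0,
                               100 * snp_t$paternal_reads / snp_t$total_reads,
                               NA_real_)
  snp_t$retained <- snp_t$total_reads >= min_reads
  snp_t
}

#' Gene-level allelic ratio from retained SNPs
#'
#' Averages the paternal percentage over a gene's retained SNPs,
#' unweighted: each SNP counts equally regardless of its coverage. A gene
#' is informative when it has at least one retained SNP; non-informative
#' genes carry `NA` and are excluded from downstream allelic analyses
#' (that is a state, not an error).
#'
#' @param snp_counts output of [count_snp_alleles()].
#' @return data.frame: gene_id, n_informative_snps, mean_paternal_pct
#'   (NA for non-informative genes), informative.
#' @export
gene_allelic_ratio <- function(snp_counts) {
  genes <- unique(snp_counts$gene_id)
  n_inf <- vapply(genes, function(g)
    sum(snp_counts$retained[snp_counts$gene_id == g]), integer(1))
  mean_pct <- vapply(genes, function(g) {
    s <- snp_counts[snp_counts$gene_id == g & snp_counts$retained, ]
    if (nrow(s) == 0L) NA_real_ else mean(s$paternal_pct)
  }, numeric(1))
  data.frame(gene_id = genes, n_informative_snps = unname(n_inf),
             mean_paternal_pct = unname(mean_pct),
             informative = unname(n_inf) >= 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Split normalized gene expression into maternal and paternal components
#'
#' Normalizes each gene's total read count to reads per million mapped
#' reads, then multiplies by the gene's SNP-derived paternal proportion:
#' `paternal_norm = total_norm * mean_paternal_pct / 100` and
#' `maternal_norm = total_norm - paternal_norm`, i.e. the total is
#' apportioned by `paternalreads / (maternalreads + paternalreads)`.
#'
#' @param gene_totals named integer vector: reads per gene with status
#'   maternal, paternal or shared.
#' @param mapped_total total mapped reads (maternal + paternal + shared
#'   over the whole sample); must be positive.
#' @param ratios output of [gene_allelic_ratio()].
#' @param scale normalization scale (default reads per million).
#' @return data.frame: gene_id, total_reads, total_norm, maternal_norm,
#'   paternal_norm (allelic columns NA for non-informative genes).
#' @export
allelic_expression <- function(gene_totals, mapped_total, ratios,
                               scale = 1e6) {
  if (!is.numeric(mapped_total) || mapped_total <= 0)
    stop("mapped_total must be positive")
  df <- data.frame(gene_id = names(gene_totals),
                   total_reads = as.integer(gene_totals),
                   stringsAsFactors = FALSE)
  df$total_norm <- scale * df$total_reads / mapped_total
  m <- match(df$gene_id, ratios$gene_id)
  pct <- ratios$mean_paternal_pct[m]
  df$paternal_norm <- df$total_norm * pct / 100
  df$maternal_norm <- df$total_norm - df$paternal_norm
  df
}

#' Quantify one embryo: per-SNP counts and the per-gene allelic table
#'
#' Convenience wrapper chaining [count_snp_alleles()],
#' [gene_allelic_ratio()] and [allelic_expression()]. Gene totals count
#' reads with status maternal, paternal or shared at their uniquely
#' assigned gene; the mapped-read total is the sum of those statuses.
#'
#' @inheritParams count_snp_alleles
#' @return List: `snp_counts`, `gene_table` (gene_id, chrom_class,
#'   n_informative_snps, mean_paternal_pct, total_reads, total_norm,
#'   maternal_norm, paternal_norm), `mapped_total`.
#' @export
quantify_embryo <- function(assignments, genes, variants, min_reads = 10L) {
  snp_counts <- count_snp_alleles(assignments, genes, variants, min_reads)
  ratios <- gene_allelic_ratio(snp_counts)
  counted <- assignments$status %in% c("maternal", "paternal", "shared")
  tot <- table(factor(assignments$gene_id[counted], levels = genes$gene_id))
  mapped_total <- sum(tot)
  gene_totals <- setNames(as.integer(tot), genes$gene_id)
  expr <- allelic_expression(gene_totals, mapped_total, ratios)
  m <- match(genes$gene_id, ratios$gene_id)
  gene_table <- data.frame(
    gene_id = genes$gene_id, chrom_class = genes$chrom_class,
    silencing_class = genes$silencing_class,
    is_xist_like = genes$is_xist_like,
    n_informative_snps = ifelse(is.na(m), 0L, ratios$n_informative_snps[m]),
    mean_paternal_pct = ratios$mean_paternal_pct[m],
    stringsAsFactors = FALSE)
  gene_table <- cbind(gene_table,
                      expr[match(genes$gene_id, expr$gene_id),
                           c("total_reads", "total_norm", "maternal_norm",
                             "paternal_norm")])
  rownames(gene_table) <- NULL
  list(snp_counts = snp_counts, gene_table = gene_table,
       mapped_total = mapped_total)
}

#' Genes informative in every sample
#'
#' Intersects the informative gene sets (at least one retained SNP) of
#' several per-sample gene tables, preserving the gene order of the first
#' table. Heat maps and group comparisons only use genes informative in
#' all samples.
#'
#' @param gene_tables list of per-sample gene tables
#'   (from [quantify_embryo()]).
#' @return Character vector of gene ids; empty (with a warning) when the
#'   intersection is empty.
#' @export
informative_across_samples <- function(gene_tables) {
  stopifnot(length(gene_tables) >= 1L)
  informative <- lapply(gene_tables, function(tb)
    tb$gene_id[tb$n_informative_snps >= 1L])
  out <- informative[[1L]]
  for (s in informative[-1L]) out <- out[out %in% s]
  if (length(out) == 0L)
    warning("no gene is informative in all samples")
  out
}
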