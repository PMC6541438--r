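#' Per-embryo mean paternal percentage over a gene subset
#'
#' The sample-level summary used for genotype-group comparisons: the
#' unweighted mean of `mean_paternal_pct` over the supplied genes
#' (typically the X-linked genes informative in all samples).
#'
#' @param gene_table per-gene table from [quantify_embryo()].
#' @param gene_subset character vector of gene ids; must be non-empty and
#'   quantified in the table.
#' @return A single number (percent).
#' @export
embryo_mean_paternal <- function(gene_table, gene_subset) {
  if (length(gene_subset) == 0L) stop("gene subset is empty")
  m <- match(gene_subset, gene_table$gene_id)
  if (anyNA(m)) stop("genes absent from table: ",
                     paste(gene_subset[is.na(m)], collapse = ", "))
  vals <- gene_table$mean_paternal_pct[m]
  if (anyNA(vals))
    stop("gene subset contains non-informative genes")
  mean(vals)
}

new_test_result <- function(statistic, df, p, test_name, labels) {
  structure(list(statistic = unname(statistic),
                 degrees_of_freedom = unname(df),
                 p_value = unname(p), test_name = test_name,
                 group_labels = labels),
            class = "allelic_test")
}

#' @export
print.allelic_test <- function(x, ...) {
  cat(sprintf("%s (%s vs %s): t = %.4g, df = %.4g, p = %.4g\n",
              x$test_name, x$group_labels[1], x$group_labels[2],
              x$statistic, x$degrees_of_freedom, x$p_value))
  invisible(x)
}

check_test_input <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (anyNA(a) || anyNA(b) || !all(is.finite(c(a, b))))
    stop("groups must be finite and complete")
}

#' Welch's two-sample t test (unequal variances)
#'
#' The test used to compare mean allelic expression between genotype
#' groups, chosen because group sizes and variances differ. Two-tailed,
#' with the Welch–Satterthwaite degrees of freedom. When both groups are
#' constant and equal, the statistic is defined as 0 with p = 1.
#'
#' @param a,b numeric vectors (per-embryo summaries), each of length >= 2.
#' @param labels length-2 character vector naming the groups.
#' @return An `allelic_test` with statistic, degrees_of_freedom, p_value.
#' @export
welch_test <- function(a, b, labels = c("a", "b")) {
  check_test_input(a, b)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(new_test_result(0, length(a) + length(b) - 2, 1,
                             "welch_two_sample", labels))
    stop("zero variance in both groups with unequal means: ",
         "t statistic undefined")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  new_test_result(tt$statistic, tt$parameter, tt$p.value,
                  "welch_two_sample", labels)
}

#' Two-tailed Student's t test (pooled variance)
#'
#' Used for proportion and intensity comparisons between two groups
#' (e.g. percent of nuclei with a FISH pattern, per-embryo IF means).
#' Pooled-variance statistic with `n_a + n_b - 2` degrees of freedom.
#'
#' @inheritParams welch_test
#' @return An `allelic_test`.
#' @export
student_test_two_tailed <- function(a, b, labels = c("a", "b")) {
  check_test_input(a, b)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(new_test_result(0, length(a) + length(b) - 2, 1,
                             "student_two_tailed", labels))
    stop("zero variance in both groups with unequal means: ",
         "t statistic undefined")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  new_test_result(tt$statistic, tt$parameter, tt$p.value,
                  "student_two_tailed", labels)
}

#' All pairwise genotype-group comparisons
#'
#' Runs the chosen two-sample test for every unordered pair of groups and
#' tabulates the results, mirroring the structure of a supplementary
#' pairwise-comparison table. Raw p-values are the primary output; a
#' Bonferroni-adjusted column is appended as clearly optional extra
#' output.
#'
#' @param values named list: one numeric vector of per-embryo summaries
#'   per group label.
#' @param test `"welch"` or `"student"`.
#' @return data.frame: group_a, group_b, mean_a, mean_b, statistic, df,
#'   p_value, p_bonferroni.
#' @export
pairwise_group_tests <- function(values, test = c("welch", "student")) {
  test <- match.arg(test)
  fun <- if (test == "welch") welch_test else student_test_two_tailed
  labs <- names(values)
  stopifnot(length(labs) >= 2L)
  pairs <- utils::combn(labs, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    r <- fun(values[[g1]], values[[g2]], labels = c(g1, g2))
    data.frame(group_a = g1, group_b = g2,
               mean_a = mean(values[[g1]]), mean_b = mean(values[[g2]]),
               statistic = r$statistic, df = r$degrees_of_freedom,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out
}

#' Order genes by allelic ratio in a reference genotype group
#'
#' Heat-map row order: genes sorted (ascending) by their mean paternal
#' percentage across the reference group's samples, ties broken by
#' lexicographic gene id. The result is invariant to row permutation of
#' the input.
#'
#' @param mat numeric matrix, genes x samples, of mean paternal
#'   percentages (rownames = gene ids, colnames = sample ids).
#' @param sample_groups named character vector mapping sample id to group
#'   label.
#' @param reference_label group whose samples define the order.
#' @return Character vector of gene ids in display order.
#' @export
order_genes_by_reference_group <- function(mat, sample_groups,
                                           reference_label) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  ref_samples <- names(sample_groups)[sample_groups == reference_label]
  ref_samples <- intersect(colnames(mat), ref_samples)
  if (length(ref_samples) == 0L)
    stop("reference group not present: ", reference_label)
  key <- rowMeans(mat[, ref_samples, drop = FALSE])
  rownames(mat)[order(key, rownames(mat), method = "radix")]
}
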