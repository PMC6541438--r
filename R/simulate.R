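XCI_STATES <- c("paternal_X_inactive", "maternal_X_inactive",
                "both_Xist", "no_Xist")

GENOTYPES <- c("fl/fl", "fl/-", "-/-", "m-/-", "mz-/-")

#' Default per-cell X-inactivation state mixture for a genotype
#'
#' Encodes the regimes the pipeline models. Embryos with zygotic-only Eed
#' perturbations (fl/fl, fl/-, -/-) maintain imprinted XCI: every XX cell
#' has the paternal X inactive (and Xist-coated). Loss of maternal EED
#' (m-/-) converts imprinted XCI to random XCI, modelled as an equal
#' mosaic of paternal-X-inactive and maternal-X-inactive cells. Maternal-
#' zygotic loss (mz-/-) additionally shows cells with biallelic Xist,
#' silencing both X's. XY embryos carry a single maternal X; in mutants
#' about half of the nuclei ectopically express Xist from (and silence)
#' that maternal X.
#'
#' @param genotype one of `"fl/fl"`, `"fl/-"`, `"-/-"`, `"m-/-"`,
#'   `"mz-/-"`.
#' @param sex `"XX"` or `"XY"`.
#' @return Named numeric over the four per-cell states, summing to 1.
#' @export
default_xci_mix <- function(genotype, sex = "XX") {
  genotype <- match.arg(genotype, GENOTYPES)
  sex <- match.arg(sex, c("XX", "XY"))
  mix <- setNames(numeric(4), XCI_STATES)
  if (sex == "XX") {
    if (genotype %in% c("fl/fl", "fl/-", "-/-")) {
      mix["paternal_X_inactive"] <- 1
    } else if (genotype == "m-/-") {
      mix["paternal_X_inactive"] <- 0.5
      mix["maternal_X_inactive"] <- 0.5
    } else { # mz-/-
      mix["paternal_X_inactive"] <- 0.35
      mix["maternal_X_inactive"] <- 0.35
      mix["both_Xist"] <- 0.30
    }
  } else {
    if (genotype %in% c("fl/fl", "fl/-", "-/-")) {
      mix["no_Xist"] <- 1
    } else {
      mix["maternal_X_inactive"] <- 0.5
      mix["no_Xist"] <- 0.5
    }
  }
  mix
}

#' Specify one simulated embryo
#'
#' Bundles and validates everything [simulate_embryo()] needs: genotype,
#' sex, cell count, the per-cell X-inactivation state mixture, per-class
#' silencing efficiencies, sequencing depth and error model, and a seed.
#'
#' @param embryo_id sample label.
#' @param genotype one of `"fl/fl"`, `"fl/-"`, `"-/-"`, `"m-/-"`,
#'   `"mz-/-"`.
#' @param sex `"XX"` or `"XY"`. XY embryos carry only the maternal X, so
#'   states involving a paternal X must have zero weight.
#' @param n_cells embryo cell count (used for staging-style metadata).
#' @param xci_mix named proportions over
#'   `paternal_X_inactive, maternal_X_inactive, both_Xist, no_Xist`;
#'   defaults to [default_xci_mix()].
#' @param silencing_efficiency named fractions in `[0, 1]` per silencing
#'   class: fraction of an inactive-X allele's expression removed.
#'   Escapers keep most of their inactive-X expression.
#' @param mean_depth expected reads per fully active biallelic gene.
#' @param error_rate per-base substitution probability.
#' @param dispersion negative-binomial dispersion of per-gene counts.
#' @param read_len read length in bases.
#' @param seed integer seed for this embryo.
#' @return An object of class `embryo_spec`.
#' @export
embryo_spec <- function(embryo_id, genotype, sex = "XX", n_cells = 64,
                        xci_mix = default_xci_mix(genotype, sex),
                        silencing_efficiency = c(subject = 0.92,
                                                 escaper = 0.25,
                                                 autosomal = 0),
                        mean_depth = 600, error_rate = 0.001,
                        dispersion = 0.1, read_len = 50, seed = 1) {
  genotype <- match.arg(genotype, GENOTYPES)
  sex <- match.arg(sex, c("XX", "XY"))
  stopifnot(n_cells >= 1, mean_depth > 0, error_rate >= 0, error_rate < 1,
            dispersion >= 0, read_len >= 20)
  if (!setequal(names(xci_mix), XCI_STATES))
    stop("xci_mix must be named over the four per-cell states")
  xci_mix <- xci_mix[XCI_STATES]
  if (abs(sum(xci_mix) - 1) > 1e-8) stop("xci_mix proportions must sum to 1")
  if (any(xci_mix < 0)) stop("xci_mix proportions must be non-negative")
  if (sex == "XY" &&
      (xci_mix["paternal_X_inactive"] > 0 || xci_mix["both_Xist"] > 0))
    stop("XY embryos have no paternal X: paternal_X_inactive and both_Xist ",
         "must be 0")
  need <- c("subject", "escaper", "autosomal")
  if (!all(need %in% names(silencing_efficiency)))
    stop("silencing_efficiency must name classes: ",
         paste(need, collapse = ", "))
  if (any(silencing_efficiency < 0 | silencing_efficiency > 1))
    stop("silencing_efficiency values must lie in [0, 1]")
  structure(list(embryo_id = embryo_id, genotype = genotype, sex = sex,
                 n_cells = n_cells, xci_mix = xci_mix,
                 silencing_efficiency = silencing_efficiency[need],
                 mean_depth = mean_depth, error_rate = error_rate,
                 dispersion = dispersion, read_len = read_len,
                 seed = as.integer(seed)),
            class = "embryo_spec")
}

#' @export
print.embryo_spec <- function(x, ...) {
  cat(sprintf("embryo_spec %s: %s %s, %d cells, depth %g, error %g\n",
              x$embryo_id, x$genotype, x$sex, x$n_cells, x$mean_depth,
              x$error_rate))
  invisible(x)
}

# Expected maternal/paternal expression weights of one gene given the
# per-cell state mixture. A fully active allele contributes weight 1 per
# cell; an inactive-X allele contributes (1 - silencing efficiency). The
# Xist-like gene is expressed only from inactive (coated) X's.
allele_weights <- function(gene, xci_mix, silencing_efficiency, sex) {
  if (gene$chrom_class == "autosome") return(c(maternal = 1, paternal = 1))
  m <- xci_mix
  if (isTRUE(gene$is_xist_like)) {
    if (sex == "XY")
      return(c(maternal = unname(m["maternal_X_inactive"]), paternal = 0))
    return(c(maternal = unname(m["maternal_X_inactive"] + m["both_Xist"]),
             paternal = unname(m["paternal_X_inactive"] + m["both_Xist"])))
  }
  s <- unname(silencing_efficiency[gene$silencing_class])
  if (sex == "XY") {
    mat <- m["maternal_X_inactive"] * (1 - s) + m["no_Xist"] * 1
    return(c(maternal = unname(mat), paternal = 0))
  }
  mat <- m["paternal_X_inactive"] * 1 + m["maternal_X_inactive"] * (1 - s) +
    m["both_Xist"] * (1 - s) + m["no_Xist"] * 1
  pat <- m["paternal_X_inactive"] * (1 - s) + m["maternal_X_inactive"] * 1 +
    m["both_Xist"] * (1 - s) + m["no_Xist"] * 1
  c(maternal = unname(mat), paternal = unname(pat))
}

# sprinkle uniform substitution errors over fixed-length reads
perturb_reads <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1])
  hits <- which(runif(length(seqs) * L) < error_rate)
  for (h in hits) {
    r <- (h - 1L) %/% L + 1L
    p <- (h - 1L) %% L + 1L
    old <- substr(seqs[r], p, p)
    substr(seqs[r], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
  }
  seqs
}

#' Simulate one hybrid embryo's RNA-seq reads with ground truth
#'
#' Draws per-gene read counts from a negative binomial around
#' `mean_depth`, assigns each read a haplotype of origin according to the
#' expression weights implied by the embryo's X-inactivation state mixture
#' and silencing efficiencies, samples the read as an exact substring of
#' the corresponding strain transcript, and finally perturbs bases at
#' `error_rate`. The Xist-like gene is expressed only from inactive
#' (coated) X alleles; autosomal genes are always 50:50 biallelic; XY
#' embryos only ever emit maternal X-linked reads.
#'
#' @param spec an [embryo_spec()].
#' @param reference the reference `toy_genome`.
#' @param genes,variants gene models and strain variants
#'   (from [make_toy_reference()] or read from GTF/VCF).
#' @return List: `reads` (named character vector), `truth` (data.frame:
#'   read_id, gene_id, allele_of_origin, overlaps_variant) and
#'   `gene_truth` (per-gene expected paternal fraction and realized
#'   maternal/paternal read counts).
#' @export
simulate_embryo <- function(spec, reference, genes, variants) {
  stopifnot(inherits(spec, "embryo_spec"))
  set.seed(spec$seed)
  mat_tx <- as.character(strain_transcriptome(
    substitute_snps(reference, variants, "maternal"), genes))
  pat_tx <- as.character(strain_transcriptome(
    substitute_snps(reference, variants, "paternal"), genes))
  snp_t <- transcript_snp_positions(genes, variants)

  reads <- character(0)
  ids <- character(0)
  truth_rows <- list()
  gene_rows <- list()
  counter <- 0L
  L <- spec$read_len

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    w <- allele_weights(g, spec$xci_mix, spec$silencing_efficiency, spec$sex)
    total_w <- sum(w)
    # baseline: biallelic fully active gene at mean_depth; the Xist-like
    # gene gets full depth from a single coated X
    f <- if (isTRUE(g$is_xist_like)) total_w else total_w / 2
    mu <- spec$mean_depth * f
    n <- if (mu <= 0) 0L else if (spec$dispersion > 0)
      rnbinom(1L, mu = mu, size = 1 / spec$dispersion) else
      stats::rpois(1L, mu)
    exp_pat <- if (total_w > 0) unname(w["paternal"]) / total_w else NA_real_
    if (n == 0L) {
      gene_rows[[i]] <- data.frame(
        gene_id = g$gene_id, chrom_class = g$chrom_class,
        silencing_class = g$silencing_class,
        is_xist_like = g$is_xist_like,
        expected_paternal_fraction = exp_pat,
        n_reads = 0L, n_maternal = 0L, n_paternal = 0L,
        stringsAsFactors = FALSE)
      next
    }
    if (g$tx_len < L)
      stop("transcript of ", g$gene_id, " shorter than read length")
    is_pat <- runif(n) < exp_pat
    starts <- sample.int(g$tx_len - L + 1L, n, replace = TRUE)
    tx <- ifelse(is_pat, pat_tx[g$gene_id], mat_tx[g$gene_id])
    seqs <- substring(tx, starts, starts + L - 1L)
    seqs <- perturb_reads(seqs, spec$error_rate)
    tp <- snp_t$tpos[snp_t$gene_id == g$gene_id]
    overlaps <- vapply(starts, function(s)
      any(tp >= s & tp <= s + L - 1L), logical(1))
    new_ids <- sprintf("%s_r%06d", spec$embryo_id, counter + seq_len(n))
    counter <- counter + n
    reads <- c(reads, seqs)
    ids <- c(ids, new_ids)
    truth_rows[[i]] <- data.frame(
      read_id = new_ids, gene_id = g$gene_id,
      allele_of_origin = ifelse(is_pat, "paternal", "maternal"),
      overlaps_variant = overlaps, stringsAsFactors = FALSE)
    gene_rows[[i]] <- data.frame(
      gene_id = g$gene_id, chrom_class = g$chrom_class,
      silencing_class = g$silencing_class, is_xist_like = g$is_xist_like,
      expected_paternal_fraction = exp_pat,
      n_reads = n, n_maternal = sum(!is_pat), n_paternal = sum(is_pat),
      stringsAsFactors = FALSE)
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(read_id = character(0), gene_id = character(0),
               allele_of_origin = character(0),
               overlaps_variant = logical(0))
  rownames(truth) <- NULL
  gene_truth <- do.call(rbind, gene_rows)
  rownames(gene_truth) <- NULL
  list(reads = setNames(reads, ids), truth = truth, gene_truth = gene_truth)
}
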