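#' Generate a toy hybrid-cross reference: genome, strain SNPs and gene models
#'
#' Builds a small two-chromosome reference (one autosome, one X), a set of
#' biallelic strain-discriminating SNPs restricted to exons, and simple
#' two-exon gene models. The SNP density default mirrors the ~1 SNP / 250 bp
#' observed in transcribed RNA between the 129/S1 and JF1/Ms strains. One
#' X-linked gene is flagged as Xist-like: in downstream simulation it is
#' expressed exclusively from the inactive X. A subset of the remaining
#' X-linked genes are marked as escapers (partially expressed from the
#' inactive X); all others on the X are silencing subjects.
#'
#' Every gene is guaranteed at least one exonic SNP: if the Bernoulli
#' placement at `snp_rate` leaves a gene without one, placement is redrawn
#' for that gene until it has one.
#'
#' @param n_autosomal_genes,n_x_genes number of genes per chromosome class.
#' @param gene_len transcript length in bases (split over two exons).
#' @param snp_rate per-exonic-base probability of a strain SNP.
#' @param seed integer seed; the whole bundle is reproducible given it.
#' @param intron_len,spacer intron size and intergenic spacing in bases.
#' @param p_maternal_is_ref probability that the maternal (129/S1-like)
#'   allele equals the reference base; otherwise the maternal allele is a
#'   non-reference base. The paternal (JF1/Ms-like) allele always differs
#'   from the maternal one.
#' @param escaper_every every k-th non-Xist X-linked gene is an escaper.
#'
#' @return A list with elements `genome` (a `toy_genome`: DNAStringSet plus
#'   per-chromosome class), `variants` (data.frame: chrom, pos, ref,
#'   maternal, paternal) and `genes` (data.frame with list columns
#'   `exon_start`/`exon_end`, plus strand, class flags and transcript
#'   length).
#' @export
make_toy_reference <- function(n_autosomal_genes = 20, n_x_genes = 40,
                               gene_len = 800, snp_rate = 1 / 250,
                               seed = 1, intron_len = 100, spacer = 100,
                               p_maternal_is_ref = 0.8, escaper_every = 5) {
  stopifnot(n_autosomal_genes >= 1, n_x_genes >= 1, gene_len >= 60,
            snp_rate > 0, snp_rate < 1)
  set.seed(seed)

  chroms <- list(
    chrX = list(class = "X", n = n_x_genes),
    chr1 = list(class = "autosome", n = n_autosomal_genes)
  )

  seqs <- character(0)
  gene_rows <- list()
  var_rows <- list()

  for (chrom in names(chroms)) {
    n <- chroms[[chrom]]$n
    cls <- chroms[[chrom]]$class
    gene_len <- as.integer(gene_len)
    intron_len <- as.integer(intron_len)
    spacer <- as.integer(spacer)
    e1 <- as.integer(ceiling(0.6 * gene_len))
    e2 <- gene_len - e1
    unit <- e1 + intron_len + e2 + spacer
    chrom_len <- spacer + n * unit
    seq_chr <- sample(DNA_BASES, chrom_len, replace = TRUE)

    for (i in seq_len(n)) {
      g_start <- spacer + (i - 1L) * unit + 1L
      ex_start <- c(g_start, g_start + e1 + intron_len)
      ex_end <- c(g_start + e1 - 1L, g_start + e1 + intron_len + e2 - 1L)
      strand <- sample(c("+", "-"), 1L)
      is_xist <- (cls == "X" && i == 1L)
      gene_id <- if (is_xist) "XistL" else
        sprintf("%sg%02d", if (cls == "X") "X" else "A", i)
      sclass <- if (cls == "autosome") "autosomal"
        else if (!is_xist && i %% escaper_every == 0L) "escaper"
        else "subject"

      exonic <- c(seq.int(ex_start[1], ex_end[1]),
                  seq.int(ex_start[2], ex_end[2]))
      repeat {
        hit <- exonic[runif(length(exonic)) < snp_rate]
        if (length(hit) > 0L) break
      }
      for (p in hit) {
        ref <- seq_chr[p]
        if (runif(1) < p_maternal_is_ref) {
          mat <- ref
          pat <- sample(setdiff(DNA_BASES, ref), 1L)
        } else {
          mat <- sample(setdiff(DNA_BASES, ref), 1L)
          pat <- sample(setdiff(DNA_BASES, mat), 1L)
        }
        var_rows[[length(var_rows) + 1L]] <-
          data.frame(chrom = chrom, pos = p, ref = ref,
                     maternal = mat, paternal = pat,
                     stringsAsFactors = FALSE)
      }

      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = g_start, end = ex_end[2], tx_len = gene_len,
        is_xist_like = is_xist, silencing_class = sclass,
        chrom_class = cls, stringsAsFactors = FALSE
      )
      gene_rows[[length(gene_rows)]]$exon_start <- I(list(ex_start))
      gene_rows[[length(gene_rows)]]$exon_end <- I(list(ex_end))
    }
    seqs[chrom] <- paste(seq_chr, collapse = "")
  }

  genome <- toy_genome(
    Biostrings::DNAStringSet(seqs),
    vapply(chroms, `[[`, "", "class")
  )
  variants <- do.call(rbind, var_rows)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL

  validate_variants(genome, variants)
  list(genome = genome, variants = variants, genes = genes)
}

#' Construct a toy genome container
#'
#' @param seq named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param chrom_class named character, `"X"` or `"autosome"` per chromosome.
#' @param strain_label `"reference"`, `"maternal_strain"` or
#'   `"paternal_strain"`.
#' @return An object of class `toy_genome`.
#' @export
toy_genome <- function(seq, chrom_class, strain_label = "reference") {
  stopifnot(methods::is(seq, "DNAStringSet"), !is.null(names(seq)),
            all(names(seq) %in% names(chrom_class)))
  if (any(Biostrings::width(seq) == 0L))
    stop("chromosome sequences must be non-empty")
  structure(list(seq = seq, chrom_class = chrom_class[names(seq)],
                 strain_label = strain_label),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome (%s): %d chromosome(s), %s bp\n",
              x$strain_label, length(x$seq),
              format(sum(Biostrings::width(x$seq)), big.mark = ",")))
  invisible(x)
}

#' Validate strain variants against a genome
#'
#' Checks that every record is a biallelic SNV with single-base alleles,
#' a discriminating maternal/paternal pair, a position inside its
#' chromosome, a reference allele matching the genome base (and not an
#' ambiguity code), and no duplicated site.
#'
#' @param genome a `toy_genome`.
#' @param variants variant data.frame (chrom, pos, ref, maternal, paternal).
#' @return Invisibly `TRUE`; otherwise a hard error naming the first
#'   offending chrom/pos.
#' @export
validate_variants <- function(genome, variants) {
  need <- c("chrom", "pos", "ref", "maternal", "paternal")
  stopifnot(all(need %in% names(variants)))
  one_base <- function(x) nchar(x) == 1L & x %in% DNA_BASES
  bad <- !(one_base(variants$ref) & one_base(variants$maternal) &
             one_base(variants$paternal))
  if (any(bad))
    stop("non-SNV or ambiguous allele at ", variants$chrom[bad][1], ":",
         variants$pos[bad][1])
  same <- variants$maternal == variants$paternal
  if (any(same))
    stop("non-discriminating site (maternal == paternal) at ",
         variants$chrom[same][1], ":", variants$pos[same][1])
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key))
    stop("duplicate variant position at ", key[duplicated(key)][1])
  for (chrom in unique(variants$chrom)) {
    if (!chrom %in% names(genome$seq))
      stop("variant chromosome not in genome: ", chrom)
    v <- variants[variants$chrom == chrom, ]
    len <- Biostrings::width(genome$seq[chrom])
    if (any(v$pos < 1L | v$pos > len))
      stop("variant position out of range on ", chrom)
    ref <- strsplit(as.character(genome$seq[[chrom]]), "")[[1]][v$pos]
    mism <- ref != v$ref
    if (any(mism))
      stop("reference allele mismatch at ", chrom, ":", v$pos[mism][1],
           " (genome ", ref[mism][1], ", variant ", v$ref[mism][1], ")")
  }
  invisible(TRUE)
}
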