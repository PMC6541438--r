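#' Build a strain-specific pseudo-genome by SNP substitution
#'
#' Substitutes one strain's alleles into the reference genome, producing an
#' in-silico strain genome of identical length that differs from the
#' reference exactly at the substituted SNV positions. This is the
#' dual-genome construction that makes strain-resolved read mapping
#' possible: reads overlapping a SNP match exactly one of the two
#' pseudo-genomes under a 0-mismatch rule.
#'
#' Only single-nucleotide substitutions are accepted ([validate_variants()]
#' rejects everything else); a reference-allele mismatch or a duplicated
#' position is a hard error, since either signals inconsistent inputs.
#'
#' @param reference a `toy_genome` (the reference build).
#' @param variants variant data.frame (chrom, pos, ref, maternal, paternal).
#' @param which `"maternal"` or `"paternal"`: which strain's alleles to
#'   substitute.
#' @return A `toy_genome` with `strain_label` set to
#'   `"maternal_strain"`/`"paternal_strain"`.
#' @examples
#' g <- toy_genome(Biostrings::DNAStringSet(c(chr1 = "AAAA")),
#'                 c(chr1 = "autosome"))
#' v <- data.frame(chrom = "chr1", pos = 3, ref = "A",
#'                 maternal = "C", paternal = "G")
#' as.character(substitute_snps(g, v, "maternal")$seq) # "AACA"
#' @export
substitute_snps <- function(reference, variants, which = c("maternal", "paternal")) {
  which <- match.arg(which)
  stopifnot(inherits(reference, "toy_genome"))
  if (nrow(variants) > 0L) validate_variants(reference, variants)
  seqs <- reference$seq
  if (nrow(variants) > 0L) {
    for (chrom in unique(variants$chrom)) {
      v <- variants[variants$chrom == chrom, ]
      at <- IRanges::IRanges(start = v$pos, width = 1L)
      seqs[[chrom]] <- Biostrings::replaceAt(
        seqs[[chrom]], at, Biostrings::DNAStringSet(v[[which]]))
    }
  }
  toy_genome(seqs, reference$chrom_class,
             strain_label = paste0(which, "_strain"))
}

#' Extract per-gene transcript sequences from a (strain) genome
#'
#' Concatenates each gene's exons in genomic order and reverse-complements
#' minus-strand genes, yielding mature sense-strand transcript sequences.
#' Applied to both strain pseudo-genomes this gives the two strain
#' transcriptomes; their per-gene Hamming distance equals the gene's exonic
#' SNP count.
#'
#' @param genome a `toy_genome`.
#' @param genes gene-model data.frame from [make_toy_reference()].
#' @return A named [Biostrings::DNAStringSet], one transcript per gene.
#' @export
strain_transcriptome <- function(genome, genes) {
  stopifnot(inherits(genome, "toy_genome"))
  txs <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    if (!chrom %in% names(genome$seq))
      stop("gene ", genes$gene_id[i], " on unknown chromosome ", chrom)
    len <- Biostrings::width(genome$seq[chrom])
    es <- genes$exon_start[[i]]
    ee <- genes$exon_end[[i]]
    if (any(es < 1L) || any(ee > len))
      stop("exon out of chromosome bounds for gene ", genes$gene_id[i])
    parts <- Biostrings::extractAt(
      genome$seq[[chrom]], IRanges::IRanges(start = es, end = ee))
    tx <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
    if (genes$strand[i] == "-") tx <- Biostrings::reverseComplement(tx)
    txs[i] <- as.character(tx)
  }
  Biostrings::DNAStringSet(setNames(txs, genes$gene_id))
}

#' Map exonic variants into transcript coordinates
#'
#' For each gene, locates the strain SNPs falling inside its exons and
#' reports their 1-based position along the mature transcript, together
#' with the transcript-strand (sense) version of each allele: minus-strand
#' genes have complemented alleles.
#'
#' @inheritParams strain_transcriptome
#' @param variants variant data.frame.
#' @return data.frame: gene_id, chrom, pos (genomic), tpos (transcript),
#'   ref_t, maternal_t, paternal_t (transcript-strand alleles).
#' @export
transcript_snp_positions <- function(genes, variants) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- list()
  for (i in seq_len(nrow(genes))) {
    v <- variants[variants$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(v) == 0L) next
    es <- genes$exon_start[[i]]
    ee <- genes$exon_end[[i]]
    widths <- ee - es + 1L
    cum <- cumsum(c(0L, widths[-length(widths)]))
    for (j in seq_len(nrow(v))) {
      k <- which(v$pos[j] >= es & v$pos[j] <= ee)
      if (length(k) != 1L) next
      plus_t <- cum[k] + (v$pos[j] - es[k]) + 1L
      if (genes$strand[i] == "+") {
        tpos <- plus_t
        al <- c(v$ref[j], v$maternal[j], v$paternal[j])
      } else {
        tpos <- genes$tx_len[i] - plus_t + 1L
        al <- unname(comp[c(v$ref[j], v$maternal[j], v$paternal[j])])
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = genes$gene_id[i], chrom = v$chrom[j],
        pos = as.integer(v$pos[j]), tpos = as.integer(tpos),
        ref_t = al[1], maternal_t = al[2], paternal_t = al[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      pos = integer(0), tpos = integer(0),
                      ref_t = character(0), maternal_t = character(0),
                      paternal_t = character(0)))
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$tpos), , drop = FALSE]
}
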