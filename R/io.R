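# File I/O for the standard formats the pipeline exchanges:
# FASTA via Biostrings, GTF via rtracklayer, FASTQ via Biostrings,
# VCF parsed with vcfR (writing is plain formatted text: records are
# simple biallelic SNVs with per-strain alleles in INFO).

#' Write / read a toy genome as FASTA
#'
#' Chromosome class ("X" or "autosome") and strain label are carried in the
#' FASTA description line so the genome round-trips through plain FASTA.
#'
#' @param genome a `toy_genome`.
#' @param path output file.
#' @return `write_genome_fasta`: the path, invisibly. `read_genome_fasta`:
#'   a `toy_genome`.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- genome$seq
  names(seqs) <- sprintf("%s chrom_class=%s strain=%s", names(seqs),
                         genome$chrom_class, genome$strain_label)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  desc <- names(seqs)
  chrom <- sub(" .*", "", desc)
  cls <- sub(".*chrom_class=(\\S+).*", "\\1", desc)
  strain <- sub(".*strain=(\\S+).*", "\\1", desc)
  names(seqs) <- chrom
  toy_genome(seqs, setNames(cls, chrom), strain_label = strain[1])
}

#' Write / read strain SNPs as VCF v4.2
#'
#' Records are biallelic SNVs. REF is the reference-genome base; ALT lists
#' the non-reference allele(s); the maternal (129/S1-like) and paternal
#' (JF1/Ms-like) strain bases are stored explicitly in the INFO fields
#' `MA` and `PA`, a convention documented in the header. Reading uses
#' vcfR and rejects indels and records lacking MA/PA.
#'
#' @param variants variant data.frame (chrom, pos, ref, maternal, paternal).
#' @param genome `toy_genome`, used for contig lengths in the header.
#' @param path file path.
#' @return `write_strain_vcf`: the path, invisibly; `read_strain_vcf`: the
#'   variant data.frame.
#' @export
write_strain_vcf <- function(variants, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=xciallele",
    sprintf("##contig=<ID=%s,length=%d>", names(genome$seq),
            Biostrings::width(genome$seq)),
    "##INFO=<ID=MA,Number=1,Type=String,Description=\"Maternal strain (129/S1-like) allele\">",
    "##INFO=<ID=PA,Number=1,Type=String,Description=\"Paternal strain (JF1/Ms-like) allele\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(variants) > 0L) {
    alt <- mapply(function(r, m, p) {
      a <- unique(setdiff(c(m, p), r))
      if (length(a) == 0L) "." else paste(a, collapse = ",")
    }, variants$ref, variants$maternal, variants$paternal)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMA=%s;PA=%s",
                       variants$chrom, variants$pos, variants$ref, alt,
                       variants$maternal, variants$paternal), con)
  }
  invisible(path)
}

#' @rdname write_strain_vcf
#' @export
read_strain_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), maternal = character(0),
                      paternal = character(0)))
  ma <- vcfR::extract.info(v, "MA")
  pa <- vcfR::extract.info(v, "PA")
  if (any(is.na(ma)) || any(is.na(pa)))
    stop("VCF records must carry MA and PA INFO fields")
  if (any(nchar(fix$REF) != 1L) || any(nchar(ma) != 1L) || any(nchar(pa) != 1L))
    stop("only biallelic SNVs are supported; indel-like record at ",
         fix$CHROM[1], ":", fix$POS[1])
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             maternal = ma, paternal = pa, stringsAsFactors = FALSE)
}

#' Write / read gene models as GTF
#'
#' One `exon` feature per exon; `gene_id`, `silencing_class`,
#' `is_xist_like` and `chrom_class` travel as GTF attributes via
#' rtracklayer.
#'
#' @param genes gene-model data.frame.
#' @param path file path.
#' @return `write_gene_gtf`: the path, invisibly; `read_gene_gtf`: the
#'   gene-model data.frame.
#' @export
write_gene_gtf <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_start[[i]]
    ee <- genes$exon_end[[i]]
    rows[[i]] <- data.frame(
      chrom = genes$chrom[i], start = es, end = ee,
      strand = genes$strand[i], gene_id = genes$gene_id[i],
      exon_number = seq_along(es),
      silencing_class = genes$silencing_class[i],
      is_xist_like = genes$is_xist_like[i],
      chrom_class = genes$chrom_class[i], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "xciallele", type = "exon",
    gene_id = df$gene_id, transcript_id = df$gene_id,
    exon_number = df$exon_number,
    silencing_class = df$silencing_class,
    is_xist_like = as.character(df$is_xist_like),
    chrom_class = df$chrom_class)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_gene_gtf
#' @export
read_gene_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  df <- as.data.frame(gr)
  rows <- list()
  for (gid in unique(df$gene_id)) {
    d <- df[df$gene_id == gid, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    row <- data.frame(
      gene_id = gid, chrom = as.character(d$seqnames[1]),
      strand = as.character(d$strand[1]),
      start = min(d$start), end = max(d$end),
      tx_len = sum(d$end - d$start + 1L),
      is_xist_like = as.logical(d$is_xist_like[1]),
      silencing_class = d$silencing_class[1],
      chrom_class = d$chrom_class[1], stringsAsFactors = FALSE)
    row$exon_start <- I(list(as.integer(d$start)))
    row$exon_end <- I(list(as.integer(d$end)))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read reads as FASTQ (Phred+33)
#'
#' Simulated reads carry no quality model; a uniform Q40 ("I") string is
#' written. Reading returns sequences as a named character vector.
#'
#' @param reads named character vector of read sequences (names = read ids).
#' @param path file path.
#' @return `write_fastq`: the path, invisibly; `read_fastq`: named
#'   character vector.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(unname(reads))
  names(seqs) <- names(reads)
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(seqs), sub(" .*", "", names(seqs)))
}

# plain TSV helpers with fixed, deterministic formatting
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
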