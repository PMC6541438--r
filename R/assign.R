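#' Build an exact-match index over a strain transcriptome
#'
#' Indexes every k-mer of every transcript by (gene, offset) so that any
#' read can be looked up by its leading k-mer and then verified by full
#' exact comparison. This supports the strict 0-mismatch haplotype
#' assignment: a read is only ever credited to a locus it matches
#' perfectly, in either orientation.
#'
#' @param transcripts named [Biostrings::DNAStringSet] or named character
#'   vector of per-gene transcript sequences.
#' @param k seed length; must not exceed the query read length.
#' @return An object of class `tx_index`.
#' @export
index_transcriptome <- function(transcripts, k = 25L) {
  tx <- if (is.character(transcripts)) transcripts else
    setNames(as.character(transcripts), names(transcripts))
  stopifnot(!is.null(names(tx)), k >= 8L)
  kmer <- character(0)
  gene <- integer(0)
  pos <- integer(0)
  for (i in seq_along(tx)) {
    L <- nchar(tx[i])
    if (L < k) next
    p <- seq_len(L - k + 1L)
    kmer <- c(kmer, substring(tx[i], p, p + k - 1L))
    gene <- c(gene, rep.int(i, length(p)))
    pos <- c(pos, p)
  }
  ord <- order(kmer, gene, pos, method = "radix")
  kmer <- kmer[ord]
  gene <- gene[ord]
  pos <- pos[ord]
  keys <- unique(kmer)
  first <- match(keys, kmer)
  count <- c(first[-1L], length(kmer) + 1L) - first
  structure(list(tx = tx, k = as.integer(k), keys = keys, first = first,
                 count = count, gene = gene, pos = pos),
            class = "tx_index")
}

#' @export
print.tx_index <- function(x, ...) {
  cat(sprintf("tx_index: %d transcripts, k = %d, %d distinct seeds\n",
              length(x$tx), x$k, length(x$keys)))
  invisible(x)
}

# All exact full-length occurrences of `queries` (character vector) in the
# indexed transcriptome, one orientation. Returns data.frame(query, gene,
# pos). Queries shorter than k never match.
index_lookup <- function(index, queries) {
  n <- length(queries)
  len <- nchar(queries)
  ok <- which(len >= index$k)
  if (length(ok) == 0L)
    return(data.frame(query = integer(0), gene = integer(0),
                      pos = integer(0)))
  seed <- substr(queries[ok], 1L, index$k)
  hit <- match(seed, index$keys)
  has <- which(!is.na(hit))
  if (length(has) == 0L)
    return(data.frame(query = integer(0), gene = integer(0),
                      pos = integer(0)))
  qi <- ok[has]
  hi <- hit[has]
  reps <- index$count[hi]
  rows <- sequence(reps) - 1L + rep.int(index$first[hi], reps)
  q <- rep.int(qi, reps)
  g <- index$gene[rows]
  p <- index$pos[rows]
  # verify the full read beyond the seed
  qlen <- len[q]
  cand_seq <- substring(index$tx[g], p, p + qlen - 1L)
  keep <- cand_seq == queries[q]
  data.frame(query = q[keep], gene = g[keep], pos = p[keep])
}

#' All exact occurrences of one read in an indexed transcriptome
#'
#' Looks the read up in both orientations and reports every full-length
#' 0-mismatch occurrence.
#'
#' @param index a `tx_index`.
#' @param read a single read sequence.
#' @return data.frame: `gene` (transcript name), `pos` (1-based offset),
#'   `orient` (`"F"`/`"R"`).
#' @export
index_lookup_both <- function(index, read) {
  stopifnot(inherits(index, "tx_index"), length(read) == 1L)
  out <- list()
  for (orient in c("F", "R")) {
    q <- if (orient == "F") read else revcomp(read)
    h <- index_lookup(index, q)
    if (nrow(h) > 0L)
      out[[orient]] <- data.frame(gene = names(index$tx)[h$gene],
                                  pos = h$pos, orient = orient,
                                  stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(gene = character(0), pos = integer(0),
                      orient = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign reads to the maternal or paternal haplotype by exact matching
#'
#' Each read is searched, in both orientations, for exact (0-mismatch)
#' full-length occurrences in the maternal and the paternal strain
#' transcriptomes. Classification follows the strict allele-specific
#' mapping contract:
#'
#' * `maternal` / `paternal` — exactly one locus hit, in that strain only
#'   (the read spans at least one SNP and carries that strain's alleles);
#' * `shared` — exactly one locus, hit in both strains (a SNP-free span;
#'   counts toward totals, never toward allelic counts);
#' * `multimapped` — more than one distinct locus (gene, offset) across
#'   the strains; excluded from all counting;
#' * `unmapped` — no exact hit anywhere (e.g. a sequencing error or an
#'   `N` under the 0-mismatch rule).
#'
#' @param reads named character vector of read sequences.
#' @param maternal_index,paternal_index `tx_index` objects built with
#'   [index_transcriptome()] from the two strain transcriptomes over the
#'   same gene set.
#' @return data.frame with one row per read: `read_id`, `status`,
#'   `gene_id` (NA unless uniquely placed), `tpos` (1-based transcript
#'   offset), `orientation` (`"F"`/`"R"`), `read_len`, `maternal_hits`,
#'   `paternal_hits`. The attribute `mapped_total` holds the count of
#'   reads with status in maternal/paternal/shared.
#' @export
assign_all <- function(reads, maternal_index, paternal_index) {
  stopifnot(inherits(maternal_index, "tx_index"),
            inherits(paternal_index, "tx_index"))
  if (!setequal(names(maternal_index$tx), names(paternal_index$tx)))
    stop("indices must be built from the same gene set")
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))
  out <- data.frame(read_id = ids,
                    status = rep("unmapped", n),
                    gene_id = rep(NA_character_, n),
                    tpos = rep(NA_integer_, n),
                    orientation = rep(NA_character_, n),
                    read_len = nchar(reads),
                    maternal_hits = integer(n),
                    paternal_hits = integer(n),
                    stringsAsFactors = FALSE)
  attr(out, "mapped_total") <- 0L
  if (n == 0L) return(out)
  if (any(out$read_len == 0L)) stop("empty read sequence")

  seqs <- unname(toupper(reads))
  rc <- revcomp(seqs)
  hits <- list()
  for (strain in c("maternal", "paternal")) {
    index <- if (strain == "maternal") maternal_index else paternal_index
    for (orient in c("F", "R")) {
      h <- index_lookup(index, if (orient == "F") seqs else rc)
      if (nrow(h) > 0L) {
        h$strain <- strain
        h$orient <- orient
        hits[[paste(strain, orient)]] <- h
      }
    }
  }
  if (length(hits) == 0L) return(out)
  h <- do.call(rbind, hits)
  gene_names <- names(maternal_index$tx)

  out$maternal_hits <- tabulate(h$query[h$strain == "maternal"], nbins = n)
  out$paternal_hits <- tabulate(h$query[h$strain == "paternal"], nbins = n)

  # distinct loci per read, ignoring strain/orientation
  locus <- paste0(h$gene, ":", h$pos)
  n_loci <- tabulate(h$query[!duplicated(paste0(h$query, "|", locus))],
                     nbins = n)
  n_strains <- tabulate(h$query[!duplicated(paste0(h$query, "|", h$strain))],
                        nbins = n)
  first <- which(!duplicated(h$query))
  q1 <- h$query[first]
  out$status[n_loci > 1L] <- "multimapped"
  uniq <- which(n_loci == 1L)
  st <- ifelse(n_strains[uniq] == 2L, "shared",
               ifelse(out$maternal_hits[uniq] > 0L, "maternal", "paternal"))
  out$status[uniq] <- st
  out$gene_id[uniq] <- gene_names[h$gene[first]][match(uniq, q1)]
  out$tpos[uniq] <- h$pos[first][match(uniq, q1)]
  out$orientation[uniq] <- h$orient[first][match(uniq, q1)]
  attr(out, "mapped_total") <-
    sum(out$status %in% c("maternal", "paternal", "shared"))
  out
}

#' Assign a single read
#'
#' Convenience wrapper around [assign_all()] for one sequence.
#'
#' @param read a single read sequence.
#' @param maternal_index,paternal_index `tx_index` objects.
#' @return One-row assignment data.frame (see [assign_all()]).
#' @export
assign_read <- function(read, maternal_index, paternal_index) {
  stopifnot(length(read) == 1L)
  if (nchar(read) == 0L) stop("empty read sequence")
  assign_all(setNames(read, "read"), maternal_index, paternal_index)
}

#' Summarize assignment statuses
#'
#' @param assignments output of [assign_all()].
#' @return data.frame of status counts plus the mapped-read total
#'   (maternal + paternal + shared).
#' @export
assignment_summary <- function(assignments) {
  lv <- c("maternal", "paternal", "shared", "multimapped", "unmapped")
  counts <- table(factor(assignments$status, levels = lv))
  data.frame(status = c(lv, "mapped_total"),
             n = c(as.integer(counts),
                   sum(counts[c("maternal", "paternal", "shared")])),
             stringsAsFactors = FALSE)
}
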