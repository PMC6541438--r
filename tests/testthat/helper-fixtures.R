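# Shared fixtures and independent brute-force oracles. The oracles never
# reuse the package's index/assignment code paths: they scan every
# transcript at every offset with plain string comparison.

tiny_reference <- function(seed = 7, n_autosomal_genes = 3, n_x_genes = 6,
                           gene_len = 400, snp_rate = 1 / 250) {
  make_toy_reference(n_autosomal_genes = n_autosomal_genes,
                     n_x_genes = n_x_genes, gene_len = gene_len,
                     snp_rate = snp_rate, seed = seed)
}

strain_txs <- function(ref) {
  list(
    maternal = strain_transcriptome(
      substitute_snps(ref$genome, ref$variants, "maternal"), ref$genes),
    paternal = strain_transcriptome(
      substitute_snps(ref$genome, ref$variants, "paternal"), ref$genes))
}

rc_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# every exact occurrence of `read` in `txs` (named character), both
# orientations, by scanning all offsets
bf_find_all <- function(read, txs) {
  hits <- list()
  for (orient in c("F", "R")) {
    q <- if (orient == "F") read else rc_chr(read)
    qlen <- nchar(q)
    for (g in names(txs)) {
      tx <- txs[[g]]
      L <- nchar(tx)
      if (L < qlen) next
      for (p in seq_len(L - qlen + 1L)) {
        if (substr(tx, p, p + qlen - 1L) == q)
          hits[[length(hits) + 1L]] <- data.frame(
            gene = g, pos = p, orient = orient,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(gene = character(0), pos = integer(0),
                      orient = character(0)))
  unique(do.call(rbind, hits))
}

# brute-force status classification mirroring the 0-mismatch contract
bf_status <- function(read, mat_txs, pat_txs) {
  hm <- bf_find_all(read, mat_txs)
  hp <- bf_find_all(read, pat_txs)
  loci <- unique(rbind(hm[, c("gene", "pos")], hp[, c("gene", "pos")]))
  if (nrow(loci) == 0L) return("unmapped")
  if (nrow(loci) > 1L) return("multimapped")
  if (nrow(hm) > 0L && nrow(hp) > 0L) return("shared")
  if (nrow(hm) > 0L) "maternal" else "paternal"
}

as_chr <- function(xss) setNames(as.character(xss), names(xss))

# Independent textbook-formula oracles for the two-sample t tests; never
# call the package or stats::t.test.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

student_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# Exact-occurrence oracle over a whole read set using Biostrings matchPDict
# (an established exact matcher, independent of the package's k-mer index).
# Returns data.frame(read_id, gene, pos, strain, orient).
pdict_hits <- function(reads, txs_by_strain) {
  out <- list()
  for (orient in c("F", "R")) {
    seqs <- Biostrings::DNAStringSet(unname(reads))
    if (orient == "R") seqs <- Biostrings::reverseComplement(seqs)
    pd <- Biostrings::PDict(seqs)
    for (strain in names(txs_by_strain)) {
      txs <- txs_by_strain[[strain]]
      for (g in names(txs)) {
        m <- Biostrings::matchPDict(pd, txs[[g]])
        starts <- Biostrings::startIndex(m)
        cnt <- lengths(starts)
        if (sum(cnt) == 0L) next
        out[[length(out) + 1L]] <- data.frame(
          read_id = rep(names(reads), cnt), gene = g,
          pos = as.integer(unlist(starts)), strain = strain,
          orient = orient, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), gene = character(0),
                      pos = integer(0), strain = character(0),
                      orient = character(0)))
  do.call(rbind, out)
}

# classify every read from oracle hits under the 0-mismatch contract
oracle_statuses <- function(reads, hits) {
  status <- setNames(rep("unmapped", length(reads)), names(reads))
  if (nrow(hits) == 0L) return(status)
  locus <- paste0(hits$gene, ":", hits$pos)
  n_loci <- tapply(locus, hits$read_id,
                   function(x) length(unique(x)))
  n_strains <- tapply(hits$strain, hits$read_id,
                      function(x) length(unique(x)))
  first_strain <- tapply(hits$strain, hits$read_id, `[`, 1L)
  st <- ifelse(n_loci > 1L, "multimapped",
               ifelse(n_strains == 2L, "shared", first_strain))
  status[names(st)] <- st
  status
}
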