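#' Design allele-specific SNP-discriminating FISH probe panel
#'
#' Designs short detection oligonucleotides that discriminate the
#' maternal-strain from the paternal-strain transcript of a target gene
#' (an Xist-like gene in the intended use). Each chosen SNP yields two
#' detection oligos, one per strain allele, that are reverse-complementary
#' to the target transcript window and differ from each other only at the
#' polymorphic base, which sits at the fifth position from the oligo's 5'
#' end. Each SNP additionally gets one unlabeled mask oligo complementary
#' to the 3' portion of the detection oligos (identical between strains,
#' since it lies outside the SNP), leaving only a 9-10 nt free window
#' around the polymorphism available to hybridize: a single mismatch in
#' so short a duplex destabilizes binding to the wrong allele. Both
#' strains use the identical SNP panel. Maternal-strain oligos are
#' labeled "Quasar 570" and paternal-strain oligos "Quasar 670"
#' (metadata only).
#'
#' SNPs are usable when the full probe window fits inside the transcript
#' and contains no second SNP (a second polymorphism would break the
#' position-5-only discrimination and the shared mask). When more usable
#' SNPs exist than requested, a greedy maximum-spacing rule spreads the
#' panel along the transcript.
#'
#' @param maternal_tx,paternal_tx the target gene's transcript sequence in
#'   each strain (single character string or DNAString).
#' @param snps data.frame of the gene's transcript-space SNPs, as from
#'   [transcript_snp_positions()] (columns tpos, maternal_t, paternal_t).
#' @param n_probes number of SNPs in the panel (default 5).
#' @param probe_len detection oligo length in nt (default 28).
#' @param free_window unmasked window in nt, 9 or 10 (default 10).
#' @param dye_labels named character: dye per strain.
#' @return List of class `probe_panel`: `probes` (one row per strain per
#'   SNP), `masks` (one per SNP), `mix` (detection 5 nM per oligo, mask
#'   10 nM; 1:1 mask:detection pairing), `probe_len`, `free_window`.
#' @export
design_probe_panel <- function(maternal_tx, paternal_tx, snps,
                               n_probes = 5L, probe_len = 28L,
                               free_window = 10L,
                               dye_labels = c(maternal = "Quasar 570",
                                              paternal = "Quasar 670")) {
  maternal_tx <- as.character(maternal_tx)
  paternal_tx <- as.character(paternal_tx)
  free_window <- as.integer(free_window)
  probe_len <- as.integer(probe_len)
  stopifnot(nchar(maternal_tx) == nchar(paternal_tx),
            free_window %in% c(9L, 10L), probe_len > free_window,
            n_probes >= 1L)
  L <- nchar(maternal_tx)
  tp <- sort(unique(snps$tpos))

  usable <- logical(length(tp))
  for (i in seq_along(tp)) {
    p <- tp[i]
    lo <- p - probe_len + 5L
    hi <- p + 4L
    if (lo < 1L || hi > L) next           # too close to a transcript end
    usable[i] <- !any(tp >= lo & tp <= hi & tp != p)
  }
  if (any(!usable))
    warning(sum(!usable), " SNP(s) skipped: too close to a transcript end ",
            "or to another SNP")
  cand <- tp[usable]
  if (length(cand) < n_probes)
    stop("insufficient usable SNPs: need ", n_probes, ", have ",
         length(cand), " (deficit ", n_probes - length(cand), ")")

  # greedy max-spacing selection along the transcript
  if (length(cand) == n_probes) {
    chosen <- cand
  } else if (n_probes == 1L) {
    chosen <- cand[ceiling(length(cand) / 2)]
  } else {
    chosen <- range(cand)
    while (length(chosen) < n_probes) {
      rest <- setdiff(cand, chosen)
      d <- vapply(rest, function(p) min(abs(p - chosen)), numeric(1))
      chosen <- sort(c(chosen, rest[which.max(d)]))
    }
  }

  tx <- c(maternal = maternal_tx, paternal = paternal_tx)
  probe_rows <- list()
  mask_rows <- list()
  for (p in chosen) {
    s <- p - probe_len + 5L
    for (strain in c("maternal", "paternal")) {
      window <- substr(tx[[strain]], s, s + probe_len - 1L)
      probe <- revcomp(window)
      probe_rows[[length(probe_rows) + 1L]] <- data.frame(
        name = sprintf("det_%s_t%d", substr(strain, 1, 3), p),
        snp_tpos = p, strain = strain, sequence = probe,
        snp_index_from_5p = 5L,
        dye_label = unname(dye_labels[strain]),
        stringsAsFactors = FALSE)
    }
    det <- probe_rows[[length(probe_rows)]]$sequence
    mask_seq <- revcomp(substr(det, free_window + 1L, probe_len))
    mask_rows[[length(mask_rows) + 1L]] <- data.frame(
      name = sprintf("mask_t%d", p), snp_tpos = p, sequence = mask_seq,
      free_window = free_window, mask_len = probe_len - free_window,
      stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, probe_rows)
  masks <- do.call(rbind, mask_rows)
  structure(list(
    probes = probes, masks = masks,
    mix = list(detection_nM = 5, mask_nM = 10, mask_detection_ratio = 1),
    probe_len = as.integer(probe_len),
    free_window = as.integer(free_window)),
    class = "probe_panel")
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf(
    "probe_panel: %d SNPs, %d detection oligos (%d nt), %d masks (free window %d nt)\n",
    nrow(x$masks), nrow(x$probes), x$probe_len, nrow(x$masks),
    x$free_window))
  invisible(x)
}

#' Validate allele discrimination of a probe panel
#'
#' For every detection oligo, checks that its free (unmasked) region — the
#' 5'-most `free_window` bases, containing the SNP at position 5 — is a
#' perfect reverse-complement match to its own strain's transcript, and
#' mismatches the alternate strain's transcript at exactly one position,
#' the SNP.
#'
#' @param panel a `probe_panel` from [design_probe_panel()].
#' @param maternal_tx,paternal_tx the two strain transcripts the panel was
#'   designed against.
#' @return data.frame with per-oligo mismatch counts against both strains
#'   and a `pass` flag; attribute `n_failures` counts failing oligos.
#' @export
validate_discrimination <- function(panel, maternal_tx, paternal_tx) {
  stopifnot(inherits(panel, "probe_panel"))
  tx <- c(maternal = as.character(maternal_tx),
          paternal = as.character(paternal_tx))
  fw <- panel$free_window
  rows <- lapply(seq_len(nrow(panel$probes)), function(i) {
    pr <- panel$probes[i, ]
    p <- pr$snp_tpos
    target <- revcomp(substr(pr$sequence, 1L, fw)) # transcript-sense window
    lo <- p + 5L - fw
    own <- substr(tx[[pr$strain]], lo, p + 4L)
    alt_strain <- if (pr$strain == "maternal") "paternal" else "maternal"
    alt <- substr(tx[[alt_strain]], lo, p + 4L)
    mm <- function(x, y) {
      a <- strsplit(x, "")[[1]]; b <- strsplit(y, "")[[1]]
      which(a != b)
    }
    own_mm <- mm(target, own)
    alt_mm <- mm(target, alt)
    snp_at <- fw - 4L  # window index of the SNP
    data.frame(name = pr$name, strain = pr$strain, snp_tpos = p,
               own_mismatches = length(own_mm),
               alt_mismatches = length(alt_mm),
               alt_mismatch_at_snp = identical(alt_mm, as.integer(snp_at)),
               pass = length(own_mm) == 0L &&
                 length(alt_mm) == 1L && alt_mm == snp_at,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_failures") <- sum(!out$pass)
  out
}

#' Write probe panel artifacts
#'
#' Emits the oligos as FASTA plus an order sheet (name, sequence, dye,
#' role) and a hybridization mix sheet as TSV.
#'
#' @param panel a `probe_panel`.
#' @param prefix output path prefix; files `<prefix>.fasta`,
#'   `<prefix>_order.tsv` and `<prefix>_mix.tsv` are written.
#' @return Invisibly, the three paths.
#' @export
write_probe_panel <- function(panel, prefix) {
  order_sheet <- rbind(
    data.frame(name = panel$probes$name, sequence = panel$probes$sequence,
               dye = panel$probes$dye_label, role = "detection",
               stringsAsFactors = FALSE),
    data.frame(name = panel$masks$name, sequence = panel$masks$sequence,
               dye = "none", role = "mask", stringsAsFactors = FALSE))
  fasta <- Biostrings::DNAStringSet(
    setNames(order_sheet$sequence, order_sheet$name))
  paths <- paste0(prefix, c(".fasta", "_order.tsv", "_mix.tsv"))
  Biostrings::writeXStringSet(fasta, paths[1])
  write_tsv(order_sheet, paths[2])
  write_tsv(data.frame(component = c("detection_oligo", "mask_oligo"),
                       concentration_nM = c(panel$mix$detection_nM,
                                            panel$mix$mask_nM),
                       mask_detection_ratio = panel$mix$mask_detection_ratio),
            paths[3])
  invisible(paths)
}
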