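test_that("every gene carries at least one exonic SNP, even at low SNP rates", {
  ref <- make_toy_reference(n_autosomal_genes = 2, n_x_genes = 1,
                            gene_len = 250, snp_rate = 1 / 250, seed = 7)
  snp_t <- transcript_snp_positions(ref$genes, ref$variants)
  expect_true(all(ref$genes$gene_id %in% snp_t$gene_id))
})

test_that("exonic SNP density matches the configured rate", {
  ref <- make_toy_reference(n_autosomal_genes = 30, n_x_genes = 30,
                            gene_len = 1000, seed = 11)
  snp_t <- transcript_snp_positions(ref$genes, ref$variants)
  per_gene <- table(factor(snp_t$gene_id, levels = ref$genes$gene_id))
  # ~1 SNP / 250 bp over 1 kb transcripts: expect ~4 per gene on average
  expect_gt(mean(per_gene), 2.5)
  expect_lt(mean(per_gene), 5.5)
})

test_that("reference bundle is byte-reproducible for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    ref <- make_toy_reference(n_autosomal_genes = 2, n_x_genes = 3,
                              gene_len = 300, seed = 5)
    write_genome_fasta(ref$genome, file.path(d, "g.fa"))
    write_strain_vcf(ref$variants, ref$genome, file.path(d, "v.vcf"))
    write_gene_gtf(ref$genes, file.path(d, "genes.gtf"))
  }
  for (f in c("g.fa", "v.vcf", "genes.gtf"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("reference structure is valid: one Xist-like X gene, classes, alphabet", {
  ref <- tiny_reference()
  expect_s3_class(ref$genes, "data.frame")
  expect_identical(sum(ref$genes$is_xist_like), 1L)
  xist <- ref$genes[ref$genes$is_xist_like, ]
  expect_identical(xist$chrom_class, "X")
  expect_true(all(ref$genes$silencing_class[ref$genes$chrom_class == "autosome"]
                  == "autosomal"))
  expect_true(all(strsplit(as.character(ref$genome$seq[["chrX"]]), "")[[1]]
                  %in% c("A", "C", "G", "T")))
  expect_true(all(ref$variants$maternal != ref$variants$paternal))
})

test_that("FASTA/VCF/GTF round-trip preserves the bundle", {
  ref <- tiny_reference()
  d <- withr::local_tempdir()
  write_genome_fasta(ref$genome, file.path(d, "g.fa"))
  write_strain_vcf(ref$variants, ref$genome, file.path(d, "v.vcf"))
  write_gene_gtf(ref$genes, file.path(d, "genes.gtf"))
  g2 <- read_genome_fasta(file.path(d, "g.fa"))
  expect_identical(as.character(g2$seq), as.character(ref$genome$seq))
  expect_identical(g2$chrom_class, ref$genome$chrom_class)
  v2 <- read_strain_vcf(file.path(d, "v.vcf"))
  expect_identical(v2, ref$variants)
  genes2 <- read_gene_gtf(file.path(d, "genes.gtf"))
  genes2 <- genes2[match(ref$genes$gene_id, genes2$gene_id), ]
  expect_identical(genes2$strand, ref$genes$strand)
  expect_identical(unclass(genes2$exon_start), unclass(ref$genes$exon_start),
                   ignore_attr = TRUE)
  expect_identical(genes2$silencing_class, ref$genes$silencing_class)
})

test_that("imprinted fl/fl regime: subject X reads maternal, Xist reads paternal", {
  ref <- tiny_reference()
  spec <- embryo_spec("e_imp", "fl/fl", sex = "XX",
                      silencing_efficiency = c(subject = 1, escaper = 0.25,
                                               autosomal = 0),
                      mean_depth = 120, error_rate = 0, seed = 2)
  sim <- simulate_embryo(spec, ref$genome, ref$genes, ref$variants)
  cls <- setNames(ref$genes$silencing_class, ref$genes$gene_id)
  xist <- ref$genes$gene_id[ref$genes$is_xist_like]
  subj <- sim$truth[cls[sim$truth$gene_id] == "subject" &
                      sim$truth$gene_id != xist, ]
  expect_true(all(subj$allele_of_origin == "maternal"))
  expect_true(all(sim$truth$allele_of_origin[sim$truth$gene_id == xist]
                  == "paternal"))
})

test_that("random-XCI m-/- regime: realized paternal fraction tracks the 50/50 mix", {
  ref <- tiny_reference()
  spec <- embryo_spec("e_rand", "m-/-", sex = "XX",
                      xci_mix = c(paternal_X_inactive = 0.5,
                                  maternal_X_inactive = 0.5,
                                  both_Xist = 0, no_Xist = 0),
                      mean_depth = 2000, error_rate = 0, seed = 3)
  sim <- simulate_embryo(spec, ref$genome, ref$genes, ref$variants)
  gt <- sim$gene_truth
  subj <- gt[gt$silencing_class == "subject" & !gt$is_xist_like, ]
  for (i in seq_len(nrow(subj))) {
    p_hat <- subj$n_paternal[i] / subj$n_reads[i]
    tol <- 3 * sqrt(0.5 * 0.5 / subj$n_reads[i])
    expect_lt(abs(p_hat - subj$expected_paternal_fraction[i]), tol)
    expect_equal(subj$expected_paternal_fraction[i], 0.5)
  }
  auto <- gt[gt$chrom_class == "autosome", ]
  expect_true(all(auto$expected_paternal_fraction == 0.5))
})

test_that("XY mutant embryos express Xist only from the maternal X", {
  ref <- tiny_reference()
  spec <- embryo_spec("e_male", "m-/-", sex = "XY",
                      xci_mix = c(paternal_X_inactive = 0,
                                  maternal_X_inactive = 0.5,
                                  both_Xist = 0, no_Xist = 0.5),
                      mean_depth = 300, error_rate = 0, seed = 4)
  sim <- simulate_embryo(spec, ref$genome, ref$genes, ref$variants)
  xist <- ref$genes$gene_id[ref$genes$is_xist_like]
  xist_reads <- sim$truth[sim$truth$gene_id == xist, ]
  expect_gt(nrow(xist_reads), 0)
  expect_true(all(xist_reads$allele_of_origin == "maternal"))
  # no X-linked paternal reads at all in an XY embryo
  xg <- ref$genes$gene_id[ref$genes$chrom_class == "X"]
  xreads <- sim$truth[sim$truth$gene_id %in% xg, ]
  expect_true(all(xreads$allele_of_origin == "maternal"))
})

test_that("error-free reads are perfect substrings of exactly one or both parental transcripts", {
  ref <- make_toy_reference(n_autosomal_genes = 2, n_x_genes = 2,
                            gene_len = 200, seed = 9)
  txs <- strain_txs(ref)
  spec <- embryo_spec("e_sub", "fl/fl", mean_depth = 30, error_rate = 0,
                      seed = 5)
  sim <- simulate_embryo(spec, ref$genome, ref$genes, ref$variants)
  mat <- as_chr(txs$maternal)
  pat <- as_chr(txs$paternal)
  for (i in seq_along(sim$reads)) {
    r <- unname(sim$reads[i])
    in_mat <- nrow(bf_find_all(r, mat)) > 0
    in_pat <- nrow(bf_find_all(r, pat)) > 0
    expect_true(in_mat || in_pat)
    if (sim$truth$overlaps_variant[i])
      expect_false(in_mat && in_pat)
  }
})

test_that("XY specs reject paternal-X states and bad mixtures are refused", {
  expect_error(embryo_spec("e", "m-/-", sex = "XY",
                           xci_mix = c(paternal_X_inactive = 0.5,
                                       maternal_X_inactive = 0.5,
                                       both_Xist = 0, no_Xist = 0)),
               "no paternal X")
  expect_error(embryo_spec("e", "fl/fl",
                           xci_mix = c(paternal_X_inactive = 0.6,
                                       maternal_X_inactive = 0.6,
                                       both_Xist = 0, no_Xist = 0)),
               "sum to 1")
  expect_error(embryo_spec("e", "fl/fl",
                           silencing_efficiency = c(subject = 1.2,
                                                    escaper = 0,
                                                    autosomal = 0)),
               "0, 1")
})
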