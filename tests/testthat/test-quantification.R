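# hand-built assignment tables: one gene, explicit tpos/read_len rows
fake_assignments <- function(gene, statuses, tpos, read_len = 50L) {
  data.frame(read_id = sprintf("r%03d", seq_along(statuses)),
             status = statuses, gene_id = gene, tpos = tpos,
             orientation = "F", read_len = read_len,
             maternal_hits = as.integer(statuses == "maternal"),
             paternal_hits = as.integer(statuses == "paternal"),
             stringsAsFactors = FALSE)
}

one_gene_fixture <- function(tx_len = 200L, snp_pos = c(60L, 90L)) {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      start = 1L, end = tx_len, tx_len = tx_len,
                      is_xist_like = FALSE, silencing_class = "subject",
                      chrom_class = "X", stringsAsFactors = FALSE)
  genes$exon_start <- I(list(1L))
  genes$exon_end <- I(list(tx_len))
  variants <- data.frame(chrom = "chr1", pos = snp_pos, ref = "A",
                         maternal = "A", paternal = "G",
                         stringsAsFactors = FALSE)
  list(genes = genes, variants = variants)
}

test_that("per-SNP counting: balanced coverage gives 50% paternal", {
  fx <- one_gene_fixture(snp_pos = 60L)
  asg <- fake_assignments("g1", rep(c("maternal", "paternal"), each = 5),
                          tpos = rep(40L, 10))
  sc <- count_snp_alleles(asg, fx$genes, fx$variants)
  expect_identical(sc$maternal_reads, 5L)
  expect_identical(sc$paternal_reads, 5L)
  expect_equal(sc$paternal_pct, 50)
  expect_true(sc$retained)
})

test_that("the SNP retention boundary is inclusive at 10 reads", {
  fx <- one_gene_fixture(tx_len = 400L, snp_pos = c(60L, 180L, 300L))
  asg <- rbind(
    fake_assignments("g1", rep("maternal", 9), tpos = rep(41L, 9)),
    fake_assignments("g1", rep("maternal", 10), tpos = rep(161L, 10)),
    fake_assignments("g1", rep("paternal", 11), tpos = rep(281L, 11)))
  sc <- count_snp_alleles(asg, fx$genes, fx$variants)
  sc <- sc[order(sc$tpos), ]
  expect_identical(sc$total_reads, c(9L, 10L, 11L))
  expect_identical(sc$retained, c(FALSE, TRUE, TRUE))
  # lowering the threshold never drops a retained SNP
  sc9 <- count_snp_alleles(asg, fx$genes, fx$variants, min_reads = 9L)
  expect_true(all(sc$retained <= sc9$retained[order(sc9$tpos)]))
})

test_that("a read spanning two SNPs increments both; totals match a brute-force overlap count", {
  fx <- one_gene_fixture(snp_pos = c(60L, 90L))
  asg <- fake_assignments("g1", c("maternal", "paternal", "maternal"),
                          tpos = c(55L, 80L, 100L))
  sc <- count_snp_alleles(asg, fx$genes, fx$variants)
  sc <- sc[order(sc$tpos), ]
  # brute force: read spans [tpos, tpos+49]
  for (i in seq_len(nrow(sc))) {
    p <- sc$tpos[i]
    cover <- asg[asg$tpos <= p & asg$tpos + 49 >= p, ]
    expect_identical(sc$maternal_reads[i], sum(cover$status == "maternal"))
    expect_identical(sc$paternal_reads[i], sum(cover$status == "paternal"))
  }
  expect_identical(sc$maternal_reads + sc$paternal_reads, c(1L, 2L))
})

test_that("shared reads and uncovered SNPs are handled: no allelic contribution, (0,0) rows", {
  fx <- one_gene_fixture(snp_pos = c(60L, 150L))
  asg <- fake_assignments("g1", rep("shared", 12), tpos = rep(40L, 12))
  sc <- count_snp_alleles(asg, fx$genes, fx$variants)
  expect_identical(sc$total_reads, c(0L, 0L))
  expect_true(all(is.na(sc$paternal_pct)))
  expect_false(any(sc$retained))
})

test_that("gene-level ratio is the unweighted mean over retained SNPs", {
  fx <- one_gene_fixture(tx_len = 400L, snp_pos = c(60L, 300L))
  asg <- rbind(
    # SNP 1: 10 reads, 10% paternal; SNP 2: 20 reads, 30% paternal
    fake_assignments("g1", c(rep("maternal", 9), "paternal"),
                     tpos = rep(41L, 10)),
    fake_assignments("g1", c(rep("maternal", 14), rep("paternal", 6)),
                     tpos = rep(281L, 20)))
  sc <- count_snp_alleles(asg, fx$genes, fx$variants)
  gr <- gene_allelic_ratio(sc)
  expect_identical(gr$n_informative_snps, 2L)
  expect_equal(gr$mean_paternal_pct, 20)  # (10 + 30) / 2, not read-weighted
})

test_that("maternal% + paternal% identity and single-SNP genes", {
  fx <- one_gene_fixture(snp_pos = 60L)
  asg <- fake_assignments("g1", c(rep("maternal", 7), rep("paternal", 3)),
                          tpos = rep(40L, 10))
  sc <- count_snp_alleles(asg, fx$genes, fx$variants)
  expect_equal(100 * sc$maternal_reads / sc$total_reads + sc$paternal_pct,
               100)
  gr <- gene_allelic_ratio(sc)
  expect_equal(gr$mean_paternal_pct, sc$paternal_pct)
})

test_that("normalized expression split follows the totalreads x paternal-proportion formula", {
  ratios <- data.frame(gene_id = "g1", n_informative_snps = 1L,
                       mean_paternal_pct = 25, informative = TRUE)
  out <- allelic_expression(c(g1 = 200L), mapped_total = 1e6, ratios)
  expect_equal(out$total_norm, 200)
  expect_equal(out$paternal_norm, 50)
  expect_equal(out$maternal_norm, 150)
  ratios$mean_paternal_pct <- 0
  out0 <- allelic_expression(c(g1 = 200L), 1e6, ratios)
  expect_equal(out0$paternal_norm, 0)
  expect_equal(out0$maternal_norm, out0$total_norm)
  expect_error(allelic_expression(c(g1 = 200L), 0, ratios), "positive")
})

test_that("maternal + paternal components conserve the normalized total", {
  ref <- tiny_reference()
  txs <- strain_txs(ref)
  mi <- index_transcriptome(txs$maternal)
  pi <- index_transcriptome(txs$paternal)
  spec <- embryo_spec("e_cons", "m-/-", mean_depth = 150, error_rate = 0,
                      seed = 12)
  sim <- simulate_embryo(spec, ref$genome, ref$genes, ref$variants)
  asg <- assign_all(sim$reads, mi, pi)
  q <- quantify_embryo(asg, ref$genes, ref$variants)
  tb <- q$gene_table[!is.na(q$gene_table$mean_paternal_pct), ]
  expect_true(all(abs(tb$maternal_norm + tb$paternal_norm - tb$total_norm)
                  <= 1e-9 * pmax(tb$total_norm, 1)))
  # totals conservation across the sample
  expect_equal(sum(q$gene_table$total_norm),
               1e6 * sum(q$gene_table$total_reads) / q$mapped_total)
})

test_that("allelic ratios recover the XCI mixture at high depth", {
  ref <- tiny_reference(seed = 31, n_x_genes = 8, n_autosomal_genes = 4)
  txs <- strain_txs(ref)
  mi <- index_transcriptome(txs$maternal)
  pi <- index_transcriptome(txs$paternal)

  run_one <- function(genotype, mix, sil_subject) {
    spec <- embryo_spec("e_rec", genotype, xci_mix = mix,
                        silencing_efficiency = c(subject = sil_subject,
                                                 escaper = 0.25,
                                                 autosomal = 0),
                        mean_depth = 500, error_rate = 0, seed = 13)
    sim <- simulate_embryo(spec, ref$genome, ref$genes, ref$variants)
    asg <- assign_all(sim$reads, mi, pi)
    q <- quantify_embryo(asg, ref$genes, ref$variants)
    merge(q$gene_table, sim$gene_truth[, c("gene_id", "n_maternal",
                                           "n_paternal")], by = "gene_id")
  }

  check_recovery <- function(tb, classes) {
    tb <- tb[tb$silencing_class %in% classes & !tb$is_xist_like &
               !is.na(tb$mean_paternal_pct), ]
    expect_gt(nrow(tb), 0)
    for (i in seq_len(nrow(tb))) {
      n <- tb$n_maternal[i] + tb$n_paternal[i]
      p_true <- tb$n_paternal[i] / n
      # binomial SD of the SNP-read estimate around the realized truth
      n_allelic <- max(n * 50 / 351, 10)  # 400 bp transcripts, 50 bp reads
      tol <- 100 * 3 * sqrt(max(p_true * (1 - p_true), 0.01) / n_allelic)
      expect_lt(abs(tb$mean_paternal_pct[i] - 100 * p_true), tol + 2)
    }
  }

  # imprinted, full silencing: subject X genes ~0% paternal
  tb <- run_one("fl/fl", c(paternal_X_inactive = 1, maternal_X_inactive = 0,
                           both_Xist = 0, no_Xist = 0), 1)
  subj <- tb[tb$silencing_class == "subject" & !tb$is_xist_like &
               !is.na(tb$mean_paternal_pct), ]
  expect_true(all(subj$mean_paternal_pct < 5))
  xist <- tb[tb$is_xist_like, ]
  expect_gt(xist$mean_paternal_pct, 95)

  # random 50/50: subject X ~50%
  tb2 <- run_one("m-/-", c(paternal_X_inactive = 0.5,
                           maternal_X_inactive = 0.5,
                           both_Xist = 0, no_Xist = 0), 0.92)
  check_recovery(tb2, "subject")
  # autosomes always ~50%
  check_recovery(tb2[tb2$chrom_class == "autosome", ], "autosomal")
})

test_that("informative-in-all-samples equals brute-force set intersection on random fixtures", {
  set.seed(99)
  all_genes <- sprintf("g%02d", 1:12)
  for (rep in 1:5) {
    tables <- lapply(1:4, function(i) {
      inf <- rbinom(12, 1, 0.7)
      data.frame(gene_id = all_genes, n_informative_snps = inf,
                 stringsAsFactors = FALSE)
    })
    got <- informative_across_samples(tables)
    want <- Reduce(intersect, lapply(tables, function(tb)
      tb$gene_id[tb$n_informative_snps >= 1]))
    expect_identical(got, want)
  }
  # single sample: its own informative set, order preserved
  one <- list(data.frame(gene_id = c("b", "a"), n_informative_snps = c(1, 1)))
  expect_identical(informative_across_samples(one), c("b", "a"))
  # gene informative in 3 of 4 samples is excluded
  t4 <- lapply(1:4, function(i)
    data.frame(gene_id = "g1", n_informative_snps = as.integer(i < 4)))
  expect_warning(out <- informative_across_samples(t4), "no gene")
  expect_identical(out, character(0))
})
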