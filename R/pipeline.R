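GENOTYPE_SLUGS <- c("fl/fl" = "fl_fl", "fl/-" = "fl_del", "-/-" = "del_del",
                    "m-/-" = "mat_del", "mz-/-" = "matzyg_del")

#' Default end-to-end run configuration
#'
#' Mirrors the scale of the modelled experiment: four embryos each of the
#' fl/fl, fl/- and -/- genotypes, five m-/- and three mz-/- embryos, all
#' female, over a toy reference of 40 X-linked and 20 autosomal genes
#' with ~1 exonic SNP / 250 bp. Every stochastic stage derives its seed
#' from the single master seed, so a rerun with the same config is
#' byte-identical.
#'
#' @param seed master integer seed.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    reference = list(n_autosomal_genes = 20L, n_x_genes = 40L,
                     gene_len = 800L, snp_rate = 1 / 250),
    groups = list("fl/fl" = 4L, "fl/-" = 4L, "-/-" = 4L,
                  "m-/-" = 5L, "mz-/-" = 3L),
    sex = "XX",
    mean_depth = 600, error_rate = 0.001, dispersion = 0.1,
    read_len = 50L,
    silencing_efficiency = list(subject = 0.92, escaper = 0.25,
                                autosomal = 0),
    min_snp_reads = 10L,
    k = 25L,
    reference_group = "fl/fl")
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config a `run_config` list.
#' @return Invisibly `TRUE`, or a hard error.
#' @export
validate_run_config <- function(config) {
  need <- c("seed", "reference", "groups", "sex", "mean_depth",
            "error_rate", "dispersion", "read_len",
            "silencing_efficiency", "min_snp_reads", "k",
            "reference_group")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config missing fields: ", paste(missing, collapse = ", "))
  if (!all(names(config$groups) %in% GENOTYPES))
    stop("unknown genotype label in groups")
  if (!config$reference_group %in% names(config$groups))
    stop("reference_group must be one of the configured groups")
  stopifnot(config$min_snp_reads >= 1, config$k >= 8,
            config$mean_depth > 0)
  invisible(TRUE)
}

#' Write / read a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_run_config`: the path, invisibly; `read_run_config`:
#'   a validated `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

# the per-embryo sample sheet implied by a config
config_samples <- function(config) {
  rows <- list()
  idx <- 0L
  for (gt in names(config$groups)) {
    for (i in seq_len(config$groups[[gt]])) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        embryo_id = sprintf("%s_e%d", GENOTYPE_SLUGS[[gt]], i),
        genotype = gt, sex = config$sex,
        seed = derive_seed(config$seed, 100L + idx),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Pipeline stage: simulate reference and embryo reads
#'
#' Generates the toy reference bundle (FASTA/VCF/GTF) and, per embryo in
#' the configured genotype groups, a FASTQ of simulated reads plus truth
#' tables, under `outdir`.
#'
#' @param config a `run_config`.
#' @param outdir run directory (created if needed).
#' @return Invisibly, the sample sheet data.frame.
#' @export
stage_simulate <- function(config, outdir) {
  validate_run_config(config)
  dir.create(file.path(outdir, "reference"), recursive = TRUE,
             showWarnings = FALSE)
  write_run_config(config, file.path(outdir, "config.yaml"))
  ref <- make_toy_reference(
    n_autosomal_genes = config$reference$n_autosomal_genes,
    n_x_genes = config$reference$n_x_genes,
    gene_len = config$reference$gene_len,
    snp_rate = config$reference$snp_rate,
    seed = derive_seed(config$seed, 1L))
  write_genome_fasta(ref$genome, file.path(outdir, "reference", "genome.fa"))
  write_strain_vcf(ref$variants, ref$genome,
                   file.path(outdir, "reference", "variants.vcf"))
  write_gene_gtf(ref$genes, file.path(outdir, "reference", "genes.gtf"))

  samples <- config_samples(config)
  write_tsv(samples, file.path(outdir, "samples.tsv"))
  sil <- unlist(config$silencing_efficiency)
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    spec <- embryo_spec(
      embryo_id = s$embryo_id, genotype = s$genotype, sex = s$sex,
      silencing_efficiency = sil, mean_depth = config$mean_depth,
      error_rate = config$error_rate, dispersion = config$dispersion,
      read_len = config$read_len, seed = s$seed)
    sim <- simulate_embryo(spec, ref$genome, ref$genes, ref$variants)
    edir <- file.path(outdir, "embryos", s$embryo_id)
    dir.create(edir, recursive = TRUE, showWarnings = FALSE)
    write_fastq(sim$reads, file.path(edir, "reads.fastq"))
    write_tsv(sim$truth, file.path(edir, "truth.tsv"))
    write_tsv(sim$gene_truth, file.path(edir, "gene_truth.tsv"))
    message(sprintf("simulated %s (%s): %d reads", s$embryo_id, s$genotype,
                    length(sim$reads)))
  }
  invisible(samples)
}

#' Pipeline stage: build strain pseudo-genomes and transcriptomes
#'
#' Reads the reference FASTA and strain VCF written by [stage_simulate()],
#' substitutes each strain's SNP alleles, and writes the two strain
#' genomes and strain transcriptomes as FASTA.
#'
#' @param outdir run directory.
#' @return Invisibly `TRUE`.
#' @export
stage_pseudogenomes <- function(outdir) {
  ref <- read_genome_fasta(file.path(outdir, "reference", "genome.fa"))
  variants <- read_strain_vcf(file.path(outdir, "reference", "variants.vcf"))
  genes <- read_gene_gtf(file.path(outdir, "reference", "genes.gtf"))
  pdir <- file.path(outdir, "pseudogenomes")
  dir.create(pdir, showWarnings = FALSE)
  for (strain in c("maternal", "paternal")) {
    g <- substitute_snps(ref, variants, strain)
    write_genome_fasta(g, file.path(pdir, paste0(strain, "_genome.fa")))
    tx <- strain_transcriptome(g, genes)
    Biostrings::writeXStringSet(
      tx, file.path(pdir, paste0(strain, "_transcriptome.fa")))
    message("built ", strain, " pseudo-genome and transcriptome (",
            length(tx), " genes)")
  }
  invisible(TRUE)
}

#' Pipeline stage: 0-mismatch allelic assignment of all embryos
#'
#' Indexes both strain transcriptomes and assigns every embryo's reads,
#' writing a per-read assignment TSV and a status summary per embryo.
#'
#' @param outdir run directory.
#' @param k seed length for the exact-match index.
#' @return Invisibly `TRUE`.
#' @export
stage_assign <- function(outdir, k = 25L) {
  pdir <- file.path(outdir, "pseudogenomes")
  mat_idx <- index_transcriptome(
    Biostrings::readDNAStringSet(file.path(pdir, "maternal_transcriptome.fa")),
    k = k)
  pat_idx <- index_transcriptome(
    Biostrings::readDNAStringSet(file.path(pdir, "paternal_transcriptome.fa")),
    k = k)
  adir <- file.path(outdir, "assignments")
  dir.create(adir, showWarnings = FALSE)
  samples <- read_tsv(file.path(outdir, "samples.tsv"))
  for (id in samples$embryo_id) {
    reads <- read_fastq(file.path(outdir, "embryos", id, "reads.fastq"))
    asg <- assign_all(reads, mat_idx, pat_idx)
    write_tsv(asg, file.path(adir, paste0(id, "_assignments.tsv")))
    write_tsv(assignment_summary(asg),
              file.path(adir, paste0(id, "_summary.tsv")))
    message(sprintf("assigned %s: %d reads, %d mapped", id, nrow(asg),
                    attr(asg, "mapped_total")))
  }
  invisible(TRUE)
}

#' Pipeline stage: per-SNP and per-gene allelic quantification
#'
#' Applies the SNP coverage filter, gene-level averaging and the
#' normalized maternal/paternal expression split to every embryo's
#' assignments.
#'
#' @param outdir run directory.
#' @param min_snp_reads SNP retention threshold.
#' @return Invisibly `TRUE`.
#' @export
stage_quantify <- function(outdir, min_snp_reads = 10L) {
  variants <- read_strain_vcf(file.path(outdir, "reference", "variants.vcf"))
  genes <- read_gene_gtf(file.path(outdir, "reference", "genes.gtf"))
  qdir <- file.path(outdir, "quant")
  dir.create(qdir, showWarnings = FALSE)
  samples <- read_tsv(file.path(outdir, "samples.tsv"))
  for (id in samples$embryo_id) {
    asg <- read_tsv(file.path(outdir, "assignments",
                              paste0(id, "_assignments.tsv")))
    q <- quantify_embryo(asg, genes, variants, min_reads = min_snp_reads)
    write_tsv(q$snp_counts, file.path(qdir, paste0(id, "_snp_counts.tsv")))
    write_tsv(q$gene_table, file.path(qdir, paste0(id, "_gene_table.tsv")))
    message(sprintf("quantified %s: %d/%d informative genes", id,
                    sum(q$gene_table$n_informative_snps >= 1),
                    nrow(q$gene_table)))
  }
  invisible(TRUE)
}

#' Pipeline stage: group statistics and heat-map matrix
#'
#' Restricts to X-linked genes informative in all samples, computes each
#' embryo's mean paternal percentage and mean normalized maternal and
#' paternal expression, runs all pairwise Welch tests on the allelic
#' ratios and Student tests on the normalized maternal/paternal
#' expression, and writes the heat-map-ready matrix ordered by the
#' reference group.
#'
#' @param outdir run directory.
#' @param reference_group genotype whose samples define gene order.
#' @return Invisibly, the run summary list.
#' @export
stage_stats <- function(outdir, reference_group = "fl/fl") {
  samples <- read_tsv(file.path(outdir, "samples.tsv"))
  tables <- lapply(samples$embryo_id, function(id)
    read_tsv(file.path(outdir, "quant", paste0(id, "_gene_table.tsv"))))
  names(tables) <- samples$embryo_id

  inf <- informative_across_samples(tables)
  chrom_class <- setNames(tables[[1]]$chrom_class, tables[[1]]$gene_id)
  x_inf <- inf[chrom_class[inf] == "X"]
  if (length(x_inf) == 0L)
    stop("no X-linked gene is informative in all samples")

  mat <- sapply(tables, function(tb)
    tb$mean_paternal_pct[match(x_inf, tb$gene_id)])
  rownames(mat) <- x_inf
  sample_groups <- setNames(samples$genotype, samples$embryo_id)
  ord <- order_genes_by_reference_group(mat, sample_groups, reference_group)
  mat <- mat[ord, , drop = FALSE]

  per_embryo <- data.frame(
    embryo_id = samples$embryo_id, genotype = samples$genotype,
    mean_paternal_pct = vapply(tables, embryo_mean_paternal,
                               numeric(1), gene_subset = x_inf),
    maternal_norm = vapply(tables, function(tb)
      mean(tb$maternal_norm[match(x_inf, tb$gene_id)]), numeric(1)),
    paternal_norm = vapply(tables, function(tb)
      mean(tb$paternal_norm[match(x_inf, tb$gene_id)]), numeric(1)),
    stringsAsFactors = FALSE)

  by_group <- split(per_embryo$mean_paternal_pct, per_embryo$genotype)
  welch <- pairwise_group_tests(by_group, test = "welch")
  student_mat <- pairwise_group_tests(
    split(per_embryo$maternal_norm, per_embryo$genotype), test = "student")
  student_pat <- pairwise_group_tests(
    split(per_embryo$paternal_norm, per_embryo$genotype), test = "student")

  rdir <- file.path(outdir, "results")
  dir.create(rdir, showWarnings = FALSE)
  write_tsv(data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
            file.path(rdir, "gene_matrix.tsv"))
  write_tsv(per_embryo, file.path(rdir, "embryo_summary.tsv"))
  write_tsv(welch, file.path(rdir, "pairwise_welch_paternal_pct.tsv"))
  write_tsv(student_mat, file.path(rdir, "pairwise_student_maternal_norm.tsv"))
  write_tsv(student_pat, file.path(rdir, "pairwise_student_paternal_norm.tsv"))

  group_means <- vapply(by_group, mean, numeric(1))
  summary <- list(
    n_samples = nrow(samples),
    n_informative_x_genes = length(x_inf),
    group_mean_paternal_pct = as.list(group_means),
    pairwise_welch = welch)
  jsonlite::write_json(summary, file.path(rdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("group mean paternal %: ",
          paste(sprintf("%s=%.1f", names(group_means), group_means),
                collapse = ", "))
  invisible(summary)
}

#' Run the full pipeline end to end
#'
#' simulate -> build pseudo-genomes -> assign -> quantify -> stats, in one
#' run directory. Rerunning with the same config into a fresh directory
#' produces byte-identical outputs; `checksums.txt` records the md5 of
#' every written file so this is auditable.
#'
#' @param config a `run_config` (default [default_run_config()]).
#' @param outdir run directory.
#' @return The run summary list from [stage_stats()], invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), outdir) {
  t0 <- Sys.time()
  stage_simulate(config, outdir)
  stage_pseudogenomes(outdir)
  stage_assign(outdir, k = config$k)
  stage_quantify(outdir, min_snp_reads = config$min_snp_reads)
  summary <- stage_stats(outdir, reference_group = config$reference_group)

  files <- sort(setdiff(
    list.files(outdir, recursive = TRUE, full.names = FALSE),
    "checksums.txt"))
  md5 <- tools::md5sum(file.path(outdir, files))
  writeLines(paste(unname(md5), files), file.path(outdir, "checksums.txt"))
  message(sprintf("pipeline finished in %.1f min",
                  as.numeric(difftime(Sys.time(), t0, units = "mins"))))
  invisible(summary)
}
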