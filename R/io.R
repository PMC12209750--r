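# Plain-text interchange for panels, cohorts and configuration: PLINK .traw
# dialect and minimal VCF for genotypes, TSV for phenotypes and result
# tables, YAML for the analysis configuration.

#' Write a reference panel as PLINK-style .traw text
#'
#' One row per SNP: CHR, SNP, (C)M, POS, COUNTED, ALT, then one dosage
#' column per individual (count of the COUNTED allele).
#'
#' @param panel A `reference_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_traw <- function(panel, path) {
  n <- nrow(panel$dosages)
  ids <- sprintf("0_I%d", seq_len(n))
  body <- data.frame(CHR = panel$snps$chrom, SNP = panel$snps$snp_id,
                     `(C)M` = 0, POS = panel$snps$pos,
                     COUNTED = panel$snps$effect_allele,
                     ALT = panel$snps$other_allele, check.names = FALSE)
  dt <- cbind(body, as.data.frame(t(panel$dosages)))
  names(dt)[-(1:6)] <- ids
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read genotypes from PLINK-style .traw text
#'
#' @param path File path.
#' @return List with `snps` (snp_id, chrom, pos, effect_allele,
#'   other_allele) and `dosages` (individuals x SNPs).
#' @export
read_panel_traw <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          check.names = FALSE)
  need <- c("CHR", "SNP", "POS", "COUNTED", "ALT")
  missing_cols <- setdiff(need, names(dt))
  assert_that(length(missing_cols) == 0, ".traw file missing column(s): ",
              paste(missing_cols, collapse = ", "))
  snps <- data.frame(snp_id = dt$SNP, chrom = as.character(dt$CHR),
                     pos = dt$POS, effect_allele = dt$COUNTED,
                     other_allele = dt$ALT, stringsAsFactors = FALSE)
  gcols <- setdiff(names(dt), c(need, "(C)M"))
  dos <- t(as.matrix(dt[, gcols, drop = FALSE]))
  colnames(dos) <- snps$snp_id
  rownames(dos) <- gcols
  list(snps = snps, dosages = dos)
}

#' Write a reference panel as VCF
#'
#' Minimal VCFv4.2 with GT genotypes (dosages are integer allele counts of
#' the ALT = counted allele). Readable back with
#' [read_panel_vcf()] (which uses VariantAnnotation) or any VCF tool.
#'
#' @param panel A `reference_panel`.
#' @param path Output path (plain text, uncompressed).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  n <- nrow(panel$dosages)
  ids <- sprintf("I%d", seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gatescores",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(panel$snps))) {
    gt <- gt_codes[panel$dosages[, j] + 1L]
    writeLines(paste(c(panel$snps$chrom[j], panel$snps$pos[j],
                       panel$snps$snp_id[j], panel$snps$other_allele[j],
                       panel$snps$effect_allele[j], ".", "PASS", ".", "GT",
                       gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read panel genotypes from a VCF file
#'
#' Uses VariantAnnotation to parse the VCF; dosages count the ALT allele.
#'
#' @param path VCF file path.
#' @return List with `snps` and `dosages` as in [read_panel_traw()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_panel_vcf requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- apply(gt, c(1, 2), function(g) {
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  snps <- data.frame(snp_id = rownames(gt),
                     chrom = as.character(GenomicRanges::seqnames(rr)),
                     pos = GenomicRanges::start(rr),
                     effect_allele = as.character(unlist(rr$ALT)),
                     other_allele = as.character(rr$REF),
                     stringsAsFactors = FALSE)
  list(snps = snps, dosages = t(dos))
}

#' Write / read a cohort phenotype table
#'
#' TSV with sample_id, outcome, sex, pc1..pcK, incident_flag,
#' proteomics_subset_flag.
#'
#' @param cohort A `gate_cohort`.
#' @param path File path.
#' @return `write_phenotypes` returns `path` invisibly; `read_phenotypes`
#'   returns a data frame.
#' @export
write_phenotypes <- function(cohort, path) {
  dt <- data.frame(sample_id = cohort$sample_ids, outcome = cohort$outcome,
                   cohort$covariates,
                   incident_flag = cohort$incident_flag,
                   proteomics_subset_flag = cohort$proteomics_subset_flag)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

#' Analysis configuration
#'
#' All thresholds of the pipeline in one object: extraction and anchor
#' p-values, clumping r2 and window, cis window, HLA mask, effective-number
#' and association thresholds, GWAS proximity window, MR instrument and
#' significance rules, the protein magnitude multiple, and the SVD cutoff.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `gate_config`.
#' @export
gate_config <- function(...) {
  cfg <- list(extraction_p = 1e-5, anchor_p = 1e-6, r2_threshold = 0.1,
              clump_window = 1e6, cis_window = 1e6,
              hla_chrom = "6", hla_start = 25e6, hla_end = 34e6,
              min_effective_n = 5, gate_p = 1e-5, secondary_p = 1e-3,
              gwas_window = 2e5, mr_min_instruments = 10L, mr_p = 0.01,
              protein_ratio = 2, svd_rtol = 1e-6)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0, "unknown config field(s): ",
              paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "gate_config")
}

#' @rdname gate_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname gate_config
#' @param cfg A `gate_config` (for writing).
#' @export
read_config <- function(path) {
  do.call(gate_config, yaml::read_yaml(path))
}
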