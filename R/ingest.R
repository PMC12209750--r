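# Ingestion of QTL summary statistics: TSV loading with validation, p-value
# filtering, HLA masking, cis/trans classification, allele harmonization and
# PLINK-style greedy clumping against the reference panel.

qtl_required_cols <- c("snp_id", "chrom", "pos", "effect_allele",
                       "other_allele", "gene_id", "beta", "se", "pvalue", "n")

#' Load QTL summary statistics from TSV
#'
#' Reads the tab-separated summary-statistic dialect written by
#' [write_summary_stats()] (columns: snp_id, chrom, pos, effect_allele,
#' other_allele, gene_id, beta, se, pvalue, n, study). Rows with missing or
#' invalid beta/se/p are dropped with a logged count, and each row's p-value
#' is cross-checked against the normal approximation 2*pnorm(-|beta/se|);
#' discrepancies beyond 10% relative trigger a warning, not an error.
#'
#' @param path TSV file path.
#' @param study Study label; overrides any `study` column if given.
#' @param qtl_type `"transcript"` or `"protein"`.
#' @return Data frame of QTL associations.
#' @export
load_summary_stats <- function(path, study = NULL, qtl_type = "transcript") {
  qtl_type <- match.arg(qtl_type, c("transcript", "protein"))
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  missing_cols <- setdiff(qtl_required_cols, names(dt))
  if (length(missing_cols)) {
    stop("summary-statistic file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt$chrom <- as.character(dt$chrom)
  ok <- is.finite(dt$beta) & is.finite(dt$se) & dt$se > 0 &
    is.finite(dt$pvalue) & dt$pvalue > 0 & dt$pvalue <= 1
  if (any(!ok)) {
    warning(sum(!ok), " row(s) with missing or invalid beta/se/p dropped",
            call. = FALSE)
    dt <- dt[ok, , drop = FALSE]
  }
  p_norm <- 2 * pnorm(-abs(dt$beta / dt$se))
  inconsistent <- abs(p_norm - dt$pvalue) > 0.1 * pmax(dt$pvalue, p_norm) &
    pmax(dt$pvalue, p_norm) > 1e-300
  if (any(inconsistent)) {
    warning(sum(inconsistent),
            " row(s) with p-value inconsistent with beta/se beyond 10% relative",
            call. = FALSE)
  }
  if (!is.null(study)) dt$study <- study
  if (is.null(dt$study)) dt$study <- "unknown"
  if (is.null(dt$qtl_type)) dt$qtl_type <- qtl_type
  rownames(dt) <- NULL
  dt
}

#' Write QTL summary statistics to TSV
#'
#' @param assocs Data frame of QTL associations.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(assocs, path) {
  data.table::fwrite(assocs, path, sep = "\t")
  invisible(path)
}

#' Filter associations by p-value
#'
#' Retains rows with p strictly below `threshold` (the extraction filter for
#' summary statistics entering score construction; default 1e-5).
#'
#' @param assocs Data frame with a `pvalue` column.
#' @param threshold P-value threshold in (0, 1].
#' @return Filtered data frame.
#' @export
filter_by_pvalue <- function(assocs, threshold = 1e-5) {
  assert_that(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
  keep <- assocs$pvalue < threshold
  msg(sum(keep), " of ", nrow(assocs), " associations pass p < ",
      format(threshold))
  assocs[keep, , drop = FALSE]
}

#' Mask the HLA region
#'
#' Removes SNPs in the extended HLA region, chromosome 6 from 25 to 34 Mb
#' (closed interval). The HLA region is a trans-QTL hotspot for immune genes
#' and its associations with autoimmune disease are confounded by direct HLA
#' effects, so it is excluded from aggregated trans scores.
#'
#' @param assocs Data frame with `chrom` and `pos` columns.
#' @param chrom_label HLA chromosome label (default "6").
#' @param start,end Mask interval in base pairs (default 25-34 Mb).
#' @return Filtered data frame.
#' @export
mask_hla <- function(assocs, chrom_label = "6", start = 25e6, end = 34e6) {
  drop <- as.character(assocs$chrom) == chrom_label &
    assocs$pos >= start & assocs$pos <= end
  if (any(drop)) msg(sum(drop), " SNP association(s) removed in HLA mask")
  assocs[!drop, , drop = FALSE]
}

#' Classify associations as cis or trans
#'
#' A SNP is cis to its target gene when it lies on the same chromosome within
#' `cis_window` base pairs of the transcription start site (closed interval:
#' a SNP exactly at the window boundary is cis); otherwise trans.
#'
#' @param assocs Data frame with `chrom`, `pos`, `gene_id` columns.
#' @param genes Gene annotation data frame (gene_id, chrom, tss_pos).
#' @param cis_window Window in base pairs (default 1 Mb).
#' @return Logical vector `is_cis`, aligned with `assocs` rows.
#' @export
classify_cis_trans <- function(assocs, genes, cis_window = 1e6) {
  idx <- match(assocs$gene_id, genes$gene_id)
  if (anyNA(idx)) {
    stop("unknown gene_id(s): ",
         paste(unique(assocs$gene_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  as.character(assocs$chrom) == as.character(genes$chrom[idx]) &
    abs(assocs$pos - genes$tss_pos[idx]) <= cis_window
}

ambiguous_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize association alleles to a reference panel
#'
#' Re-signs betas so every effect refers to the panel's counted (effect)
#' allele. Rows whose alleles match the panel in swapped order get their beta
#' sign flipped; strand-ambiguous A/T and C/G SNPs and rows whose alleles do
#' not match the panel at all are dropped with a warning.
#'
#' @param assocs Data frame of QTL associations.
#' @param panel_snps Panel SNP table (snp_id, effect_allele, other_allele).
#' @return Harmonized data frame with a logical `flipped` column.
#' @export
harmonize_alleles <- function(assocs, panel_snps) {
  idx <- match(assocs$snp_id, panel_snps$snp_id)
  known <- !is.na(idx)
  if (any(!known)) {
    warning(sum(!known), " SNP(s) absent from the panel dropped", call. = FALSE)
  }
  a <- assocs[known, , drop = FALSE]
  ps <- panel_snps[idx[known], , drop = FALSE]
  amb <- ambiguous_pair(a$effect_allele, a$other_allele)
  if (any(amb)) {
    warning(sum(amb), " strand-ambiguous (A/T or C/G) SNP(s) dropped",
            call. = FALSE)
  }
  same <- a$effect_allele == ps$effect_allele & a$other_allele == ps$other_allele
  swap <- a$effect_allele == ps$other_allele & a$other_allele == ps$effect_allele
  mismatch <- !amb & !same & !swap
  if (any(mismatch)) {
    warning(sum(mismatch), " SNP(s) with alleles incompatible with the panel dropped",
            call. = FALSE)
  }
  keep <- !amb & (same | swap)
  a <- a[keep, , drop = FALSE]
  flip <- swap[keep]
  a$beta[flip] <- -a$beta[flip]
  a$effect_allele[flip] <- ps$effect_allele[keep][flip]
  a$other_allele[flip] <- ps$other_allele[keep][flip]
  a$flipped <- flip
  a
}

#' Clump associated SNPs for one gene
#'
#' PLINK-style greedy, p-ordered clumping. SNPs are sorted by ascending
#' p-value (ties broken by chromosome then position); the best unassigned SNP
#' with p below `anchor_p` becomes a lead, and every unassigned SNP on the
#' same chromosome within `window` base pairs with panel r-squared at least
#' `r2_threshold` joins its clump; this repeats until no eligible lead
#' remains. Every clump therefore contains at least one SNP below the anchor
#' threshold (1e-6 by default; relaxed to 1e-5 for designs restricted to
#' preselected trait-associated SNPs, whose prior probability of a true
#' effect is higher). Member SNPs must already pass the extraction filter.
#'
#' @param assocs Associations for a single gene (already p-filtered,
#'   HLA-masked and allele-harmonized).
#' @param panel A `reference_panel` covering the SNPs.
#' @param anchor_p Lead-SNP p-value threshold (default 1e-6).
#' @param r2_threshold Minimum r-squared with the lead (default 0.1).
#' @param window Base-pair window around the lead (default 1 Mb).
#' @param genes Optional gene annotation to set the clump's cis/trans flag
#'   (from the lead SNP; see `cis_window`).
#' @param cis_window Cis window used when `genes` is supplied.
#' @return List of `gate_clump` objects (gene_id, clump_id, chrom, lead_snp,
#'   members, span, is_cis, study).
#' @export
clump_associations <- function(assocs, panel, anchor_p = 1e-6,
                               r2_threshold = 0.1, window = 1e6,
                               genes = NULL, cis_window = 1e6) {
  assert_that(length(unique(assocs$gene_id)) <= 1,
              "clump_associations expects associations for a single gene")
  if (!nrow(assocs)) return(list())
  in_panel <- assocs$snp_id %in% panel$snps$snp_id
  if (any(!in_panel)) {
    warning(sum(!in_panel), " SNP(s) absent from the panel excluded from clumping",
            call. = FALSE)
    assocs <- assocs[in_panel, , drop = FALSE]
  }
  if (!nrow(assocs)) return(list())
  ord <- order(assocs$pvalue, assocs$chrom, assocs$pos)
  assocs <- assocs[ord, , drop = FALSE]
  assigned <- rep(FALSE, nrow(assocs))
  is_cis_all <- if (!is.null(genes)) {
    classify_cis_trans(assocs, genes, cis_window)
  }
  clumps <- list()
  repeat {
    lead_i <- which(!assigned & assocs$pvalue < anchor_p)[1]
    if (is.na(lead_i)) break
    lead <- assocs[lead_i, ]
    cand <- which(!assigned & assocs$chrom == lead$chrom &
                    abs(assocs$pos - lead$pos) <= window)
    if (length(cand) > 1) {
      r <- snp_correlation(panel, c(lead$snp_id, assocs$snp_id[setdiff(cand, lead_i)]))
      r2 <- r[1, -1]^2
      members_i <- c(lead_i, setdiff(cand, lead_i)[r2 >= r2_threshold])
    } else {
      members_i <- lead_i
    }
    assigned[members_i] <- TRUE
    members <- assocs[members_i, , drop = FALSE]
    members <- members[order(members$pos), , drop = FALSE]
    clumps[[length(clumps) + 1L]] <- structure(list(
      gene_id = if (nrow(assocs)) assocs$gene_id[1] else NA_character_,
      clump_id = sprintf("%s_chr%s_%d", assocs$gene_id[1], lead$chrom, lead$pos),
      chrom = lead$chrom, lead_snp = lead, members = members,
      span = c(min(members$pos), max(members$pos)),
      is_cis = if (!is.null(is_cis_all)) is_cis_all[lead_i] else NA,
      study = lead$study %||% NA_character_), class = "gate_clump")
  }
  clumps
}

#' Tabulate a list of clumps
#'
#' @param clumps List of `gate_clump` objects.
#' @return Data frame: gene_id, clump_id, chrom, lead_snp, lead_p, n_snps,
#'   span_start, span_end, is_cis, study.
#' @export
clump_table <- function(clumps) {
  if (!length(clumps)) {
    return(data.frame(gene_id = character(), clump_id = character(),
                      chrom = character(), lead_snp = character(),
                      lead_p = numeric(), n_snps = integer(),
                      span_start = integer(), span_end = integer(),
                      is_cis = logical(), study = character()))
  }
  do.call(rbind, lapply(clumps, function(cl) data.frame(
    gene_id = cl$gene_id, clump_id = cl$clump_id, chrom = cl$chrom,
    lead_snp = cl$lead_snp$snp_id, lead_p = cl$lead_snp$pvalue,
    n_snps = nrow(cl$members), span_start = cl$span[1], span_end = cl$span[2],
    is_cis = cl$is_cis, study = cl$study, stringsAsFactors = FALSE)))
}
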