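#' Specify an LD block
#'
#' An LD block is a run of `n_snps` SNPs on one chromosome whose adjacent-SNP
#' dosage correlation is `rho` (an AR(1) decay along the block). Blocks are the
#' atoms from which both the LD reference panel and all simulated genotypes
#' are built.
#'
#' @param chrom Chromosome label (character or integer).
#' @param start_pos 1-based base-pair position of the first SNP.
#' @param n_snps Number of SNPs in the block (>= 1).
#' @param rho Target adjacent-SNP dosage correlation, in `[0, 1)`.
#' @param maf_range Length-2 numeric; per-SNP minor allele frequencies are
#'   drawn uniformly from this interval, which must lie in `(0, 0.5]`.
#' @param spacing Base pairs between consecutive SNPs (default 1000).
#' @return An object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(chrom, start_pos, n_snps, rho,
                          maf_range = c(0.1, 0.5), spacing = 1000L) {
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  assert_that(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  assert_that(length(maf_range) == 2 && all(maf_range > 0) &&
                all(maf_range <= 0.5) && maf_range[1] <= maf_range[2],
              "maf_range must lie in (0, 0.5]")
  assert_that(start_pos >= 1, "start_pos must be >= 1")
  structure(list(chrom = as.character(chrom), start_pos = as.integer(start_pos),
                 n_snps = as.integer(n_snps), rho = rho,
                 maf_range = as.numeric(maf_range),
                 spacing = as.integer(spacing)),
            class = "ld_block_spec")
}

block_positions <- function(block) {
  block$start_pos + (seq_len(block$n_snps) - 1L) * block$spacing
}

block_snp_ids <- function(block) {
  sprintf("chr%s_%d", block$chrom, block_positions(block))
}

#' Specify one gene of a synthetic genetic architecture
#'
#' Each gene has a transcription start site, an optional cis LD block and any
#' number of trans LD blocks; every block carries per-SNP effect sizes on the
#' gene's expression (units: expression SD per counted allele). Expression is
#' the sum of genetic effects plus Gaussian noise.
#'
#' @param gene_id Unique gene label.
#' @param chrom,tss_pos Chromosome and 1-based transcription start position.
#' @param cis_block Optional `ld_block_spec` near the TSS.
#' @param cis_effects Numeric vector of per-SNP effects for `cis_block`.
#' @param trans_blocks List of `ld_block_spec` objects on other loci.
#' @param trans_effects List of numeric vectors, one per trans block.
#' @param expression_noise_sd Residual SD of expression (default 1).
#' @return An object of class `gene_spec`.
#' @export
gene_spec <- function(gene_id, chrom, tss_pos, cis_block = NULL,
                      cis_effects = NULL, trans_blocks = list(),
                      trans_effects = list(), expression_noise_sd = 1) {
  if (!is.null(cis_block)) {
    assert_that(inherits(cis_block, "ld_block_spec"), "cis_block must be an ld_block_spec")
    assert_that(length(cis_effects) == cis_block$n_snps,
                "cis_effects must have one value per SNP of cis_block")
  }
  assert_that(length(trans_blocks) == length(trans_effects),
              "trans_blocks and trans_effects must align")
  for (i in seq_along(trans_blocks)) {
    assert_that(inherits(trans_blocks[[i]], "ld_block_spec"),
                "trans_blocks entries must be ld_block_spec")
    assert_that(length(trans_effects[[i]]) == trans_blocks[[i]]$n_snps,
                "trans_effects[[", i, "]] must have one value per SNP")
  }
  assert_that(expression_noise_sd >= 0, "expression_noise_sd must be >= 0")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 tss_pos = as.integer(tss_pos), cis_block = cis_block,
                 cis_effects = as.numeric(cis_effects),
                 trans_blocks = trans_blocks, trans_effects = trans_effects,
                 expression_noise_sd = expression_noise_sd),
            class = "gene_spec")
}

#' Assemble a synthetic genetic architecture
#'
#' The architecture encodes the sparse-effector disease model: a designated
#' subset of "core" genes carries a log-odds coefficient on disease (per SD of
#' expression), optional per-SNP direct (pleiotropic) effects bypass the core
#' genes, and disease prevalence is controlled by a numerically solved
#' intercept.
#'
#' @param genes List of [gene_spec()] objects.
#' @param core_genes Data frame with columns `gene_id`, `coef` (log odds per
#'   SD of expression); `gene_id` must be a subset of `genes`.
#' @param prevalence Target disease prevalence in `(0, 1)`.
#' @param direct_snp_effects Optional named numeric vector of per-allele
#'   log-odds effects, names being SNP ids of the architecture's blocks.
#' @param trait_associated_snps Optional character vector of SNP ids; when
#'   set, simulated QTL studies report summary statistics only for these SNPs
#'   (mirroring trans designs that test a preselected trait-associated set).
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(genes, core_genes = NULL, prevalence = 0.01,
                              direct_snp_effects = NULL,
                              trait_associated_snps = NULL) {
  assert_that(length(genes) > 0, "at least one gene is required")
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  assert_that(!anyDuplicated(ids), "gene ids must be unique")
  if (is.null(core_genes)) {
    core_genes <- data.frame(gene_id = character(), coef = numeric())
  }
  assert_that(all(c("gene_id", "coef") %in% names(core_genes)),
              "core_genes needs columns gene_id, coef")
  assert_that(all(core_genes$gene_id %in% ids),
              "core_genes must be a subset of the architecture's genes")
  assert_that(prevalence > 0 && prevalence < 1, "prevalence must be in (0,1)")
  arch <- structure(list(genes = genes, core_genes = core_genes,
                         prevalence = prevalence,
                         direct_snp_effects = direct_snp_effects,
                         trait_associated_snps = trait_associated_snps),
                    class = "architecture_spec")
  snps <- arch_snp_ids(arch)
  if (!is.null(direct_snp_effects)) {
    assert_that(all(names(direct_snp_effects) %in% snps),
                "direct_snp_effects names must be SNPs of the architecture")
  }
  if (!is.null(trait_associated_snps)) {
    assert_that(all(trait_associated_snps %in% snps),
                "trait_associated_snps must be SNPs of the architecture")
  }
  arch
}

#' LD blocks and SNP ids of an architecture
#'
#' `arch_blocks` collects every distinct LD block referenced by the
#' architecture's genes (cis and trans); `arch_snp_ids` lists their SNP ids.
#' Feed the blocks to [simulate_ld_panel()] to build the matching panel.
#'
#' @param arch An [architecture_spec()].
#' @return A list of `ld_block_spec` / a character vector.
#' @export
arch_blocks <- function(arch) {
  out <- list()
  for (g in arch$genes) {
    if (!is.null(g$cis_block)) out <- c(out, list(g$cis_block))
    out <- c(out, g$trans_blocks)
  }
  ids <- vapply(out, function(b) block_snp_ids(b)[1], character(1))
  out[!duplicated(ids)]
}

#' @rdname arch_blocks
#' @export
arch_snp_ids <- function(arch) {
  unique(unlist(lapply(arch_blocks(arch), block_snp_ids)))
}

# Per-gene table of (snp_id, effect), cis and trans pooled; used by the
# expression simulator.
gene_effect_table <- function(gene) {
  snp <- character(); eff <- numeric()
  if (!is.null(gene$cis_block)) {
    snp <- c(snp, block_snp_ids(gene$cis_block))
    eff <- c(eff, gene$cis_effects)
  }
  for (i in seq_along(gene$trans_blocks)) {
    snp <- c(snp, block_snp_ids(gene$trans_blocks[[i]]))
    eff <- c(eff, gene$trans_effects[[i]])
  }
  data.frame(snp_id = snp, effect = eff, stringsAsFactors = FALSE)
}

#' Gene annotation table of an architecture
#'
#' @param arch An [architecture_spec()].
#' @return Data frame with columns `gene_id`, `chrom`, `tss_pos`.
#' @export
gene_annotation <- function(arch) {
  data.frame(gene_id = vapply(arch$genes, `[[`, character(1), "gene_id"),
             chrom = vapply(arch$genes, `[[`, character(1), "chrom"),
             tss_pos = vapply(arch$genes, `[[`, integer(1), "tss_pos"),
             stringsAsFactors = FALSE)
}

block_to_list <- function(b) {
  list(chrom = b$chrom, start_pos = b$start_pos, n_snps = b$n_snps,
       rho = b$rho, maf_range = b$maf_range, spacing = b$spacing)
}

block_from_list <- function(x) {
  ld_block_spec(x$chrom, x$start_pos, x$n_snps, x$rho,
                unlist(x$maf_range), x$spacing %||% 1000L)
}

#' Write / read an architecture spec as YAML
#'
#' The YAML document is the package's structured-text interchange format for
#' simulation scenarios; [read_architecture()] validates the document field by
#' field and rebuilds a full [architecture_spec()].
#'
#' @param arch An `architecture_spec`.
#' @param path File path.
#' @return `read_architecture` returns an `architecture_spec`;
#'   `write_architecture` returns `path` invisibly.
#' @export
write_architecture <- function(arch, path) {
  doc <- list(
    prevalence = arch$prevalence,
    genes = lapply(arch$genes, function(g) {
      list(gene_id = g$gene_id, chrom = g$chrom, tss_pos = g$tss_pos,
           cis_block = if (!is.null(g$cis_block)) block_to_list(g$cis_block),
           cis_effects = if (length(g$cis_effects)) as.numeric(g$cis_effects),
           trans_blocks = lapply(g$trans_blocks, block_to_list),
           trans_effects = lapply(g$trans_effects, as.numeric),
           expression_noise_sd = g$expression_noise_sd)
    }),
    core_genes = if (nrow(arch$core_genes))
      lapply(seq_len(nrow(arch$core_genes)), function(i)
        list(gene_id = arch$core_genes$gene_id[i],
             coef = arch$core_genes$coef[i])),
    direct_snp_effects = if (!is.null(arch$direct_snp_effects))
      as.list(arch$direct_snp_effects),
    trait_associated_snps = arch$trait_associated_snps
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("prevalence", "genes")) {
    assert_that(!is.null(doc[[field]]),
                "architecture YAML is missing required field '", field, "'")
  }
  genes <- lapply(doc$genes, function(g) {
    for (field in c("gene_id", "chrom", "tss_pos")) {
      assert_that(!is.null(g[[field]]),
                  "gene entry is missing required field '", field, "'")
    }
    gene_spec(g$gene_id, g$chrom, g$tss_pos,
              cis_block = if (!is.null(g$cis_block)) block_from_list(g$cis_block),
              cis_effects = unlist(g$cis_effects),
              trans_blocks = lapply(g$trans_blocks, block_from_list),
              trans_effects = lapply(g$trans_effects, unlist),
              expression_noise_sd = g$expression_noise_sd %||% 1)
  })
  core <- if (length(doc$core_genes)) {
    data.frame(gene_id = vapply(doc$core_genes, `[[`, character(1), "gene_id"),
               coef = vapply(doc$core_genes, function(x) as.numeric(x$coef),
                             numeric(1)),
               stringsAsFactors = FALSE)
  }
  direct <- if (length(doc$direct_snp_effects))
    unlist(doc$direct_snp_effects)
  architecture_spec(genes, core_genes = core, prevalence = doc$prevalence,
                    direct_snp_effects = direct,
                    trait_associated_snps = unlist(doc$trait_associated_snps))
}
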