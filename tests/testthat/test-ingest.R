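# Summary-statistic ingestion: TSV contract, p-value filter, HLA mask,
# cis/trans classification, allele harmonization and greedy clumping.

test_that("well-formed files load; bad rows drop; missing columns error", {
  ss <- make_sumstats(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  loaded <- load_summary_stats(path, study = "fix")
  expect_equal(nrow(loaded), 3)
  expect_equal(loaded$beta, ss$beta)

  ss_bad <- ss; ss_bad$se[2] <- 0
  write_summary_stats(ss_bad, path)
  expect_warning(loaded <- load_summary_stats(path), "dropped")
  expect_equal(nrow(loaded), 2)

  ss_nc <- ss[, setdiff(names(ss), "se")]
  write_summary_stats(ss_nc, path)
  expect_error(load_summary_stats(path), "se")
})

test_that("inconsistent p-values trigger a warning, not an error", {
  ss <- make_sumstats(3)
  ss$pvalue[1] <- ss$pvalue[1] * 2
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  expect_warning(loaded <- load_summary_stats(path), "inconsistent")
  expect_equal(nrow(loaded), 3)
})

test_that("p-value filter is strict and handles edge thresholds", {
  a <- data.frame(pvalue = c(1e-6, 1e-4))
  expect_equal(suppressMessages(filter_by_pvalue(a, 1e-5))$pvalue, 1e-6)
  expect_equal(nrow(suppressMessages(filter_by_pvalue(a, 1))), 2)
  a2 <- data.frame(pvalue = c(0.5, 0.99))
  expect_equal(nrow(suppressMessages(filter_by_pvalue(a2, 1))), 2)
  empty <- a[0, , drop = FALSE]
  expect_equal(nrow(suppressMessages(filter_by_pvalue(empty, 1e-5))), 0)
})

test_that("HLA mask removes chr6:25-34 Mb inclusively and is idempotent", {
  a <- data.frame(chrom = c("6", "6", "6", "6", "7"),
                  pos = c(30e6, 24999999, 25e6, 34e6, 30e6))
  m <- suppressMessages(mask_hla(a))
  expect_equal(nrow(m), 2)
  expect_true(all(m$pos %in% c(24999999, 30e6)))
  expect_true(all(m$chrom[m$pos == 30e6] == "7"))
  expect_identical(suppressMessages(mask_hla(m)), m)
})

test_that("cis/trans classification uses a closed window on |distance|", {
  genes <- data.frame(gene_id = "G1", chrom = "1", tss_pos = 10e6)
  a <- data.frame(chrom = c("1", "2", "1", "1", "1"),
                  pos = c(10e6 + 150e3, 10e6, 10e6 + 1e6, 10e6 + 1e6 + 1,
                          10e6 - 1e6),
                  gene_id = "G1")
  expect_identical(classify_cis_trans(a, genes, cis_window = 1e6),
                   c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(classify_cis_trans(data.frame(chrom = "1", pos = 1,
                                             gene_id = "NOPE"), genes),
               "unknown gene_id")
})

test_that("allele harmonization flips swapped alleles and drops ambiguous SNPs", {
  panel_snps <- data.frame(snp_id = c("s1", "s2", "s3", "s4"),
                           effect_allele = c("A", "A", "A", "C"),
                           other_allele = c("G", "G", "T", "T"))
  a <- data.frame(snp_id = c("s1", "s2", "s3", "s4", "s9"),
                  effect_allele = c("A", "G", "A", "A", "A"),
                  other_allele = c("G", "A", "T", "C", "G"),
                  beta = c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_warning(expect_warning(expect_warning(
    h <- harmonize_alleles(a, panel_snps),
    "absent"), "ambiguous"), "incompatible")
  # s1 unchanged, s2 flipped, s3 ambiguous dropped, s4 incompatible, s9 absent
  expect_equal(h$snp_id, c("s1", "s2"))
  expect_equal(h$beta, c(0.1, -0.2))
  expect_identical(h$flipped, c(FALSE, TRUE))
})

test_that("greedy clumping groups by LD and respects the anchor rule", {
  # two independent anchors 5 Mb apart plus one correlated neighbour
  b1 <- ld_block_spec("1", 1e6, 2, rho = 0.9, maf_range = c(0.35, 0.35))
  b2 <- ld_block_spec("1", 6e6, 1, rho = 0, maf_range = c(0.3, 0.3))
  panel <- simulate_ld_panel(list(b1, b2), 20000, seed = 31)
  r2 <- cor(panel$dosages[, 1], panel$dosages[, 2])^2
  expect_gt(r2, 0.5)
  a <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                  pos = panel$snps$pos, gene_id = "G1",
                  beta = c(0.5, 0.4, 0.3), se = 0.01,
                  pvalue = c(1e-10, 1e-8, 1e-9), study = "fix")
  clumps <- clump_associations(a, panel, anchor_p = 1e-6,
                               r2_threshold = 0.1, window = 1e6)
  expect_length(clumps, 2)
  expect_equal(clumps[[1]]$lead_snp$snp_id, panel$snps$snp_id[1])
  expect_equal(nrow(clumps[[1]]$members), 2)  # correlated neighbour joins
  expect_equal(nrow(clumps[[2]]$members), 1)
  # disjointness and anchor condition
  all_members <- unlist(lapply(clumps, function(cl) cl$members$snp_id))
  expect_false(anyDuplicated(all_members) > 0)
  expect_true(all(vapply(clumps, function(cl)
    min(cl$members$pvalue) < 1e-6, logical(1))))
  # span covers all members
  for (cl in clumps) {
    expect_true(all(cl$members$pos >= cl$span[1] & cl$members$pos <= cl$span[2]))
  }
})

test_that("no clumps form when no SNP passes the anchor threshold", {
  panel <- make_indep_panel(c(0.3, 0.3), n = 500, seed = 32)
  a <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                  pos = panel$snps$pos, gene_id = "G1",
                  beta = 0.1, se = 0.05, pvalue = c(1e-5, 2e-5), study = "fix")
  expect_length(clump_associations(a, panel, anchor_p = 1e-6), 0)
  # relaxed anchor (trait-associated-SNP designs) admits them
  expect_length(clump_associations(a, panel, anchor_p = 1e-4), 2)
})

test_that("SNPs absent from the panel are excluded from clumping with a warning", {
  panel <- make_indep_panel(c(0.3), n = 500, seed = 33)
  a <- data.frame(snp_id = c(panel$snps$snp_id, "ghost"), chrom = "1",
                  pos = c(panel$snps$pos, 2e6), gene_id = "G1",
                  beta = 0.5, se = 0.01, pvalue = c(1e-9, 1e-12), study = "fix")
  expect_warning(clumps <- clump_associations(a, panel, anchor_p = 1e-6),
                 "absent")
  expect_length(clumps, 1)
  expect_equal(clumps[[1]]$members$snp_id, panel$snps$snp_id)
})

test_that("equal p-values break ties toward the lower position", {
  panel <- make_indep_panel(c(0.3, 0.3), n = 500, seed = 34, spacing = 2e6)
  a <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                  pos = panel$snps$pos, gene_id = "G1",
                  beta = 0.5, se = 0.01, pvalue = c(1e-9, 1e-9), study = "fix")
  clumps <- clump_associations(a, panel, anchor_p = 1e-6)
  expect_equal(clumps[[1]]$lead_snp$pos, min(panel$snps$pos))
})
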