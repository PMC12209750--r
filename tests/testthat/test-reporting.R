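# Filtering and validation criteria: strict thresholds, GWAS proximity,
# protein direction/magnitude rule, attenuation prediction, table assembly.

test_that("core-gene filter applies strict inequalities on both criteria", {
  res <- data.frame(gene_id = paste0("G", 1:6),
                    effective_n = c(5.0, 5.01, 7, 7, 4, 7),
                    pvalue = c(1e-7, 1e-7, 1e-5, 0.9e-5, 1e-7, 2e-3),
                    log_or_std = 0.1)
  kept <- suppressMessages(filter_core_genes(res))
  # effective_n = 5 exactly excluded; p = 1e-5 exactly excluded
  expect_setequal(kept$gene_id, c("G2", "G4"))
})

test_that("a constructed 10-gene fixture recovers exactly its known pass-set", {
  set.seed(91)
  res <- data.frame(gene_id = sprintf("G%02d", 1:10),
                    effective_n = c(8, 3, 9, 5.5, 2, 6.5, 12, 4.9, 7.1, 5.2),
                    pvalue = c(1e-8, 1e-9, 1e-3, 1e-6, 1e-9, 1e-7,
                               0.2, 1e-8, 1e-4, 1e-6),
                    log_or_std = rnorm(10, 0, 0.1))
  kept <- suppressMessages(filter_core_genes(res))
  expect_setequal(kept$gene_id, c("G01", "G04", "G06", "G10"))
  # order-independence: filtering a shuffled table gives the same set
  kept2 <- suppressMessages(filter_core_genes(res[sample(10), ]))
  expect_setequal(kept2$gene_id, kept$gene_id)
})

test_that("GWAS proximity uses a closed 200-kb window on the same chromosome", {
  genes <- data.frame(gene_id = c("A", "B", "C"),
                      chrom = c("1", "1", "2"), tss_pos = c(1e6, 5e6, 1e6))
  hits <- data.frame(chrom = c("1", "1", "1"),
                     pos = c(1e6 + 199999, 5e6 + 200001, 1e6),
                     attributed_genes = c("NEAR", "FAR", "EXACT"))
  prox <- gwas_proximity(genes, hits, window = 2e5)
  expect_identical(prox$gwas_hit_within_window, c(TRUE, FALSE, FALSE))
  expect_match(prox$hit_labels[1], "NEAR")
  # boundary: exactly 200,000 bp is within the closed window
  hits2 <- data.frame(chrom = "1", pos = 5e6 + 200000)
  expect_true(gwas_proximity(genes[2, ], hits2)$gwas_hit_within_window)
})

test_that("secondary candidates need both the relaxed p and a nearby hit", {
  res <- data.frame(gene_id = c("A", "B", "C", "D"),
                    pvalue = c(5e-4, 1e-3, 5e-4, 1e-2))
  prox <- data.frame(gene_id = c("A", "B", "C", "D"),
                     gwas_hit_within_window = c(TRUE, TRUE, FALSE, TRUE),
                     hit_labels = "")
  out <- secondary_candidates(res, prox, max_p = 1e-3)
  expect_setequal(out$gene_id, "A")  # B at boundary excluded, C no hit, D too weak
})

test_that("protein validation needs same direction and twice the magnitude", {
  expect_true(protein_validation(0.10, 0.60))
  expect_false(protein_validation(0.10, -0.60))
  expect_false(protein_validation(0.10, 0.15))
  expect_true(protein_validation(-0.10, -0.20))   # boundary: exactly 2x passes
  expect_false(protein_validation(-0.10, -0.19))
})

test_that("attenuation prediction is 1/sqrt(r2) and monotone decreasing", {
  chk <- attenuation_check(0.02, 0.1, 0.7)
  expect_equal(chk$predicted_ratio, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(chk$observed_ratio, 7, tolerance = 1e-12)
  expect_true(chk$consistent)
  expect_equal(attenuation_check(1, 0.1, 0.1)$predicted_ratio, 1)
  chk2 <- attenuation_check(0.25, 0.1, 0.2)
  expect_equal(chk2$predicted_ratio, 2)
  expect_true(chk2$consistent)
  r2s <- seq(0.01, 1, by = 0.01)
  preds <- vapply(r2s, function(r) attenuation_check(r, 0.1, 0.2)$predicted_ratio,
                  numeric(1))
  expect_true(all(diff(preds) < 0))
  expect_error(attenuation_check(0, 0.1, 0.2), "r2")
  expect_error(attenuation_check(0.1, 0, 0.2), "nonzero")
})

test_that("validation table assembles criteria and leaves unknowns NA", {
  cand <- data.frame(gene_id = c("A", "B"), log_or_std = c(0.1, -0.2),
                     pvalue = c(1e-7, 1e-8), effective_n = c(7, 9))
  prox <- data.frame(gene_id = c("A", "B"),
                     gwas_hit_within_window = c(TRUE, FALSE),
                     hit_labels = c("A", ""))
  mr <- data.frame(gene_id = c("A", "B"), theta_hat = c(0.3, 0.1),
                   pvalue = c(0.001, 0.5), eligible = c(TRUE, FALSE))
  prot <- data.frame(gene_id = "A", log_or_std = 0.35, pvalue = 1e-4)
  curated <- data.frame(gene_id = "B", mouse_model = TRUE, drug = FALSE)
  tab <- assemble_validation_table(cand, prox, mr, prot, curated)
  expect_equal(nrow(tab), 2)
  expect_true(tab$mr_pass[tab$gene_id == "A"])
  expect_true(is.na(tab$mr_pass[tab$gene_id == "B"]))  # ineligible -> not evaluated
  expect_true(tab$protein_pass[tab$gene_id == "A"])    # 0.35 >= 2 x 0.1, same sign
  expect_true(is.na(tab$protein_pass[tab$gene_id == "B"]))
  expect_true(tab$mouse_model[tab$gene_id == "B"])
  expect_true(is.na(tab$mouse_model[tab$gene_id == "A"]))  # unknown, not FALSE
  expect_true(is.na(tab$monogenic[1]))
  # empty candidate set gives an empty, well-formed table
  empty <- assemble_validation_table(cand[0, ], prox, mr, prot, curated)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("gene_id", "mr_pass", "protein_pass") %in% names(empty)))
})

test_that("score correlation matrix is reordered by clustering with unit diagonal", {
  set.seed(92)
  n <- 500
  base1 <- rnorm(n); base2 <- rnorm(n)
  m <- cbind(a = base1 + rnorm(n, sd = 0.3), b = base2 + rnorm(n, sd = 0.3),
             c = base1 + rnorm(n, sd = 0.3), d = base2 + rnorm(n, sd = 0.3))
  C <- score_correlation(m)
  expect_equal(unname(diag(C)), rep(1, 4))
  ord <- colnames(C)
  # clustering places the correlated pairs adjacently
  pos <- match(c("a", "c"), ord)
  expect_equal(abs(diff(pos)), 1)
})
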