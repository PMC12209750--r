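# Shared setup for the numbered analysis scripts. Each script can be run on
# its own from the repository root: heavy intermediates are cached under
# results/cache/ and rebuilt deterministically when absent.

suppressMessages(library(gatescores))

SEED <- 20260924L
RESULTS <- "results"
CACHE <- file.path(RESULTS, "cache")
dir.create(CACHE, showWarnings = FALSE, recursive = TRUE)

# Reference study conditions: 50 genes, 3 core, 7 trans loci per gene.
ARCH <- synthetic_architecture()
N_PANEL <- 2000L    # LD reference panel individuals
N_STUDY <- 20000L   # QTL-study sample size
N_COHORT <- 50000L  # disease-cohort sample size

cache_get <- function(name, build) {
  path <- file.path(CACHE, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  obj <- build()
  saveRDS(obj, path)
  obj
}

panel_obj <- function() cache_get("panel", function()
  simulate_ld_panel(arch_blocks(ARCH), N_PANEL, seed = SEED))
qtl_obj <- function() cache_get("qtl", function()
  simulate_qtl_study(panel_obj(), ARCH, N_STUDY, seed = SEED + 1L,
                     study = "synthetic_eqtl"))
cohort_obj <- function() cache_get("cohort", function()
  simulate_cohort(panel_obj(), ARCH, N_COHORT, seed = SEED + 2L))
pipeline_obj <- function() cache_get("pipeline", function()
  suppressWarnings(gate_pipeline(qtl_obj(), panel_obj(), cohort_obj(),
                                 gene_annotation(ARCH),
                                 study = "synthetic_eqtl")))
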