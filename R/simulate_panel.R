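# Latent-Gaussian genotype model.
#
# Each haplotype carries a standard-normal latent variable per SNP following
# an AR(1) chain within a block; the minor allele is present when the latent
# exceeds the upper-tail quantile of its frequency. Dosage = sum of two
# independent haplotypes, which yields Hardy-Weinberg genotypes. The latent
# adjacent correlation is calibrated numerically so that the *dosage*
# correlation, not the latent one, hits the block's target rho.

# P(Z1 > t1, Z2 > t2) for standard bivariate normal with correlation r.
bvn_upper <- function(t1, t2, r) {
  if (abs(r) < 1e-12) return(pnorm(t1, lower.tail = FALSE) *
                               pnorm(t2, lower.tail = FALSE))
  f <- function(z) dnorm(z) * pnorm((r * z - t2) / sqrt(1 - r^2))
  integrate(f, t1, Inf, rel.tol = 1e-10)$value
}

# Correlation of the two allele indicators (equals the dosage correlation)
# induced by latent correlation r at minor allele frequencies p1, p2.
dosage_cor_from_latent <- function(r, p1, p2) {
  t1 <- qnorm(1 - p1); t2 <- qnorm(1 - p2)
  (bvn_upper(t1, t2, r) - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Invert dosage_cor_from_latent in r for a target dosage correlation rho.
latent_r_for_dosage_cor <- function(rho, p1, p2) {
  if (rho == 0) return(0)
  upper <- 0.99995
  reach <- dosage_cor_from_latent(upper, p1, p2)
  assert_that(rho < reach,
              sprintf("adjacent dosage correlation %.3f unreachable for MAFs %.3f / %.3f (max %.3f)",
                      rho, p1, p2, reach))
  uniroot(function(r) dosage_cor_from_latent(r, p1, p2) - rho,
          lower = 0, upper = upper, tol = 1e-9)$root
}

# Draw an n x m matrix of latent AR(1) chains with per-step correlations r.
latent_chain <- function(n, mafs, r) {
  m <- length(mafs)
  z <- matrix(0, n, m)
  z[, 1] <- rnorm(n)
  for (k in seq_len(m - 1L)) {
    z[, k + 1L] <- r[k] * z[, k] + sqrt(1 - r[k]^2) * rnorm(n)
  }
  z
}

draw_block_dosages <- function(n, mafs, r) {
  thr <- qnorm(1 - mafs)
  g <- matrix(0L, n, length(mafs))
  for (h in 1:2) {
    z <- latent_chain(n, mafs, r)
    g <- g + (sweep(z, 2, thr, `>`)) * 1L
  }
  g
}

allele_pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                       ncol = 2, byrow = TRUE)

#' Simulate an LD reference panel
#'
#' Generates genotype dosages for a set of LD blocks under the latent-Gaussian
#' AR(1) model described in the package vignette. The returned panel retains
#' the calibrated generative model, so further individuals (QTL-study or
#' cohort samples) can be drawn from exactly the same population with
#' [draw_genotypes()].
#'
#' @param blocks List of [ld_block_spec()] objects; blocks on the same
#'   chromosome must not overlap.
#' @param n_individuals Number of panel individuals (>= 2).
#' @param seed Integer seed; output is a pure function of `(blocks, n, seed)`.
#' @return An object of class `reference_panel` with elements `snps` (data
#'   frame: snp_id, chrom, pos, effect_allele, other_allele, maf), `dosages`
#'   (individuals x SNPs integer matrix in 0..2) and `model` (per-block
#'   realized MAFs and latent correlations).
#' @export
simulate_ld_panel <- function(blocks, n_individuals, seed) {
  assert_that(n_individuals >= 2, "n_individuals must be >= 2")
  for (b in blocks) assert_that(inherits(b, "ld_block_spec"),
                                "blocks must be ld_block_spec objects")
  check_block_overlap(blocks)
  set.seed(sub_seed(seed, 1L))
  model <- lapply(blocks, function(b) {
    mafs <- runif(b$n_snps, b$maf_range[1], b$maf_range[2])
    r <- if (b$n_snps > 1) {
      vapply(seq_len(b$n_snps - 1L), function(k)
        latent_r_for_dosage_cor(b$rho, mafs[k], mafs[k + 1L]), numeric(1))
    } else numeric(0)
    list(chrom = b$chrom, positions = block_positions(b),
         snp_ids = block_snp_ids(b), mafs = mafs, latent_r = r)
  })
  panel <- structure(list(model = model, blocks = blocks), class = "reference_panel")
  panel$snps <- panel_snp_table(panel)
  panel$dosages <- draw_genotypes(panel, n_individuals, sub_seed(seed, 2L))
  panel
}

check_block_overlap <- function(blocks) {
  spans <- do.call(rbind, lapply(blocks, function(b) {
    pos <- block_positions(b)
    data.frame(chrom = b$chrom, start = min(pos), end = max(pos))
  }))
  for (ch in unique(spans$chrom)) {
    s <- spans[spans$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("LD blocks overlap on chromosome ", ch, call. = FALSE)
    }
  }
}

panel_snp_table <- function(panel) {
  rows <- lapply(panel$model, function(m) {
    k <- seq_along(m$snp_ids)
    pair <- allele_pairs[((seq_along(k) - 1L) %% nrow(allele_pairs)) + 1L, ,
                         drop = FALSE]
    data.frame(snp_id = m$snp_ids, chrom = m$chrom, pos = m$positions,
               effect_allele = pair[, 1], other_allele = pair[, 2],
               maf = m$mafs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Draw genotypes from a panel's generative model
#'
#' Fresh individuals from the same population as a simulated reference panel:
#' identical MAFs and calibrated latent LD structure, independent sampling.
#'
#' @param panel A `reference_panel` from [simulate_ld_panel()].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Integer dosage matrix (n x SNPs) with SNP ids as column names.
#' @export
draw_genotypes <- function(panel, n, seed) {
  assert_that(inherits(panel, "reference_panel"), "panel must be a reference_panel")
  set.seed(as.integer(seed %% 2147483629))
  g <- do.call(cbind, lapply(panel$model, function(m)
    draw_block_dosages(n, m$mafs, m$latent_r)))
  colnames(g) <- unlist(lapply(panel$model, `[[`, "snp_ids"))
  const <- apply(g, 2, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    stop("monomorphic dosage column(s) ", paste(colnames(g)[const], collapse = ", "),
         "; increase n or the minor allele frequency", call. = FALSE)
  }
  g
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("reference_panel:", nrow(x$dosages), "individuals x", nrow(x$snps),
      "SNPs in", length(x$model), "LD blocks\n")
  invisible(x)
}
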