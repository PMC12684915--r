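# Genotype-based relatedness: method-of-moments IBD (Z0/Z1/Z2, PI-HAT),
# KING-robust kinship, heterozygosity and inbreeding coefficients, and
# powers-of-two kinship-degree binning.

# indicator matrices (NA -> 0) and the non-missing mask
dosage_indicators <- function(d) {
  M <- !is.na(d)
  mk <- function(v) { x <- !is.na(d) & d == v; storage.mode(x) <- "double"; x }
  storage.mode(M) <- "double"
  list(A0 = mk(0), A1 = mk(1), A2 = mk(2), M = M)
}

# sample alternate-allele frequencies and the locus filter
locus_filter <- function(d, maf_min) {
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(p) & maf >= maf_min & p > 0 & p < 1
  list(p = p, keep = keep)
}

#' Method-of-moments IBD estimation (PI-HAT)
#'
#' Re-implementation of the classic PLINK-style moment estimator of
#' pairwise identity by descent from unlinked SNPs. Per pair, the observed
#' counts of IBS-state loci (restricted to loci genotyped in both
#' individuals) are combined with the expected IBS-given-IBD proportions
#' computed from sample allele frequencies, solving sequentially for Z0
#' (from IBS0), Z1 (from IBS1) and Z2 = 1 - Z0 - Z1. Negative components
#' are clipped to zero and the triple renormalized; PI-HAT = Z2 + Z1/2.
#' Allele frequencies are estimated once from all individuals, relatives
#' included; the resulting small bias is deliberate and is measured by the
#' gene-drop recovery tests.
#'
#' @param gm a [genotype_matrix()] with at least two individuals.
#' @param maf_min loci below this minor-allele frequency are excluded
#'   (default 0.01).
#' @param min_loci pairs with fewer pairwise-complete informative loci get
#'   `NA` estimates (default 100).
#' @return data.frame with one row per unordered pair: `id1`, `id2`,
#'   `n_loci`, `Z0`, `Z1`, `Z2`, `pi_hat`.
#' @export
mom_ibd <- function(gm, maf_min = 0.01, min_loci = 100L) {
  d <- gm$dosage
  if (nrow(d) < 2L) stop("need at least two individuals")
  flt <- locus_filter(d, maf_min)
  d <- d[, flt$keep, drop = FALSE]
  p <- flt$p[flt$keep]; q <- 1 - p
  ind <- dosage_indicators(d)
  A0 <- ind$A0; A1 <- ind$A1; A2 <- ind$A2; M <- ind$M

  IBS0 <- A0 %*% t(A2) + A2 %*% t(A0)
  IBS1 <- A1 %*% t(A0 + A2) + (A0 + A2) %*% t(A1)
  IBS2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)

  # E[count of IBS state s | IBD state z] over pairwise-complete loci
  pairsum <- function(cl) M %*% (cl * t(M))
  E00 <- pairsum(2 * p^2 * q^2)
  E10 <- pairsum(4 * p^3 * q + 4 * p * q^3)
  E11 <- pairsum(2 * p^2 * q + 2 * p * q^2)
  E20 <- pairsum(p^4 + q^4 + 4 * p^2 * q^2)
  E21 <- pairsum(p^3 + q^3 + p^2 * q + p * q^2)
  N <- M %*% t(M)

  Z0 <- IBS0 / E00
  Z1 <- (IBS1 - Z0 * E10) / E11
  Z2 <- (IBS2 - Z0 * E20 - Z1 * E21) / N
  pairs <- which(upper.tri(N), arr.ind = TRUE)
  z <- cbind(Z0[pairs], Z1[pairs], Z2[pairs])
  z[z < 0] <- 0
  z[z > 1] <- 1
  z <- z / rowSums(z)
  out <- data.frame(
    id1 = rownames(d)[pairs[, 1L]], id2 = rownames(d)[pairs[, 2L]],
    n_loci = as.integer(N[pairs]),
    Z0 = z[, 1L], Z1 = z[, 2L], Z2 = z[, 3L],
    pi_hat = z[, 3L] + 0.5 * z[, 2L], stringsAsFactors = FALSE)
  low <- out$n_loci < min_loci
  out[low, c("Z0", "Z1", "Z2", "pi_hat")] <- NA_real_
  out
}

#' KING-robust kinship estimator
#'
#' Between-family robust kinship from counts of double-heterozygous loci,
#' opposite-homozygous loci, and the two individuals' heterozygote counts,
#' all restricted to pairwise-complete loci:
#' `phi = (N_AaAa - 2 * N_AAaa) / (N_Aa(i) + N_Aa(j))`.
#' The estimate does not use allele frequencies, making it robust to
#' population structure; values near 0.5 indicate duplicates or
#' monozygotic twins, and slightly negative values are expected for
#' unrelated pairs.
#'
#' @inheritParams mom_ibd
#' @return data.frame with `id1`, `id2`, `n_loci`, `king_phi` (`NA` when
#'   neither individual is heterozygous at shared loci or too few loci).
#' @export
king_robust <- function(gm, maf_min = 0.01, min_loci = 100L) {
  d <- gm$dosage
  if (nrow(d) < 2L) stop("need at least two individuals")
  flt <- locus_filter(d, maf_min)
  d <- d[, flt$keep, drop = FALSE]
  ind <- dosage_indicators(d)
  A0 <- ind$A0; A1 <- ind$A1; A2 <- ind$A2; M <- ind$M
  Nhh <- A1 %*% t(A1)
  Nopp <- A0 %*% t(A2) + A2 %*% t(A0)
  Hi <- A1 %*% t(M)   # het count of row individual at shared loci
  Hj <- M %*% t(A1)
  N <- M %*% t(M)
  phi <- (Nhh - 2 * Nopp) / (Hi + Hj)
  pairs <- which(upper.tri(N), arr.ind = TRUE)
  out <- data.frame(
    id1 = rownames(d)[pairs[, 1L]], id2 = rownames(d)[pairs[, 2L]],
    n_loci = as.integer(N[pairs]), king_phi = phi[pairs],
    stringsAsFactors = FALSE)
  bad <- out$n_loci < min_loci | (Hi + Hj)[pairs] == 0
  out$king_phi[bad] <- NA_real_
  out
}

#' Kinship-degree classification
#'
#' Powers-of-two binning of a kinship estimate: degree d for kinship phi
#' in `(2^-(d + 3/2), 2^-(d + 1/2)]`, d = 1..4 (estimates above the
#' degree-1 lower bound are also called degree 1, covering duplicates);
#' below the degree-4 lower bound (2^-5.5, about 0.0221) the call is
#' `"unrelated"`. PI-HAT inputs are halved to the kinship scale first.
#'
#' @param x numeric estimates.
#' @param scale `"kinship"` (KING phi, pedigree f) or `"pihat"`.
#' @return character vector of calls: `"1"`, `"2"`, `"3"`, `"4"`,
#'   `"unrelated"` (`NA` in, `NA` out).
#' @export
classify_degree <- function(x, scale = c("kinship", "pihat")) {
  scale <- match.arg(scale)
  phi <- if (scale == "pihat") x / 2 else x
  cut_pts <- 2^-((1:4) + 1.5)
  out <- rep(NA_character_, length(phi))
  ok <- !is.na(phi)
  call_one <- function(v) {
    d <- which(v > cut_pts)
    if (length(d)) as.character(d[1L]) else "unrelated"
  }
  out[ok] <- vapply(phi[ok], call_one, character(1))
  out
}

#' Per-individual heterozygosity and inbreeding coefficient
#'
#' Observed heterozygosity is the fraction of heterozygous calls among an
#' individual's non-missing loci; expected heterozygosity averages
#' `2 p (1 - p)` (sample allele frequencies) over the same loci. The
#' within-individual inbreeding coefficient is `F = 1 - O_het / E_het`.
#'
#' @inheritParams mom_ibd
#' @return data.frame `id`, `n_loci`, `observed_het`, `expected_het`,
#'   `inbreeding_F` (rows all-`NA` beyond `id` for individuals with no
#'   genotyped loci).
#' @export
het_and_F <- function(gm, maf_min = 0.01) {
  d <- gm$dosage
  flt <- locus_filter(d, maf_min)
  d <- d[, flt$keep, drop = FALSE]
  p <- flt$p[flt$keep]
  M <- !is.na(d)
  n_loci <- rowSums(M)
  o_het <- rowSums(d == 1, na.rm = TRUE) / n_loci
  e_het <- as.vector(M %*% (2 * p * (1 - p))) / n_loci
  out <- data.frame(id = rownames(d), n_loci = as.integer(n_loci),
                    observed_het = o_het, expected_het = e_het,
                    inbreeding_F = 1 - o_het / e_het,
                    stringsAsFactors = FALSE)
  out[out$n_loci == 0L, c("observed_het", "expected_het", "inbreeding_F")] <-
    NA_real_
  rownames(out) <- NULL
  out
}

#' Merge IBD and KING tables into one kinship table
#'
#' Convenience join of [mom_ibd()] and [king_robust()] with a degree call
#' from PI-HAT (falling back to KING phi where PI-HAT is absent).
#'
#' @inheritParams mom_ibd
#' @export
kinship_table <- function(gm, maf_min = 0.01, min_loci = 100L) {
  ibd <- mom_ibd(gm, maf_min, min_loci)
  king <- king_robust(gm, maf_min, min_loci)
  out <- merge(ibd, king[, c("id1", "id2", "king_phi")],
               by = c("id1", "id2"), sort = FALSE)
  est <- ifelse(is.na(out$pi_hat), out$king_phi, out$pi_hat / 2)
  out$degree_call <- classify_degree(est, scale = "kinship")
  out
}
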