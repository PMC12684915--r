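# Mendelian gene dropping: simulate biallelic SNP genotypes through a
# pedigree to provide ground truth for the genotype-based kinship
# estimators, plus PED/MAP and VCF text I/O.

#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages: individuals x loci, entries in
#' {0, 1, 2, NA} counting copies of the alternate allele.
#'
#' @param dosage integer/numeric matrix with rownames = individual ids.
#' @param loci data.frame with columns `id`, `chrom`, `pos` (1-based);
#'   autogenerated when `NULL`.
#' @param founder_freqs optional per-locus alternate-allele frequency used
#'   when the matrix was simulated.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, loci = NULL, founder_freqs = NULL) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)))
  L <- ncol(dosage)
  if (is.null(loci)) {
    loci <- data.frame(id = sprintf("snp%05d", seq_len(L)),
                       chrom = ((seq_len(L) - 1L) %% 38L) + 1L,
                       pos = ((seq_len(L) - 1L) %/% 38L) * 1000L + 1L,
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(loci) == L)
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  colnames(dosage) <- loci$id
  structure(list(dosage = dosage, loci = loci,
                 founder_freqs = founder_freqs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Draw founder allele frequencies
#'
#' I.i.d. uniform alternate-allele frequencies on `[low, high]`,
#' deterministic per seed.
#'
#' @param n_loci number of loci (0 allowed, giving an empty vector).
#' @param low,high bounds with `0 < low <= high < 1`.
#' @param seed integer seed.
#' @export
draw_founder_frequencies <- function(n_loci, low = 0.1, high = 0.5,
                                     seed = 1L) {
  if (!(low > 0 && high < 1 && low <= high))
    stop("need 0 < low <= high < 1")
  if (n_loci == 0L) return(numeric(0))
  set.seed(substream_seed(seed, 0L, "freqs"))
  runif(n_loci, low, high)
}

#' Drop genotypes through a pedigree
#'
#' Founders draw two alleles per locus from Hardy-Weinberg proportions at
#' the supplied frequencies; every non-founder inherits one uniformly
#' chosen allele from each parent, independently per locus (loci are
#' unlinked). An individual with exactly one recorded parent receives the
#' missing parent's contribution as a fresh founder draw. With
#' `track_ibd = TRUE` the result carries founder-haplotype labels so that
#' realized identity-by-descent sharing can be measured directly.
#'
#' @param ped a [pedigree()] (acyclic).
#' @param freqs non-empty vector of alternate-allele frequencies in (0, 1]
#'   (frequency 1 is degenerate but permitted for tests).
#' @param seed integer seed.
#' @param track_ibd also return integer label matrices `lab1`, `lab2`
#'   identifying the founder haplotype each allele descends from.
#' @return a [genotype_matrix()]; with `track_ibd`, label matrices are
#'   attached as attribute `"ibd_labels"`.
#' @export
drop_genotypes <- function(ped, freqs, seed = 1L, track_ibd = FALSE) {
  if (!length(freqs)) stop("freqs must be non-empty")
  stopifnot(all(freqs > 0 & freqs <= 1))
  ind <- ped$individuals
  n <- nrow(ind); L <- length(freqs)
  ord <- ped_topo_order(ped)
  par <- ped_parent_idx(ped)
  set.seed(substream_seed(seed, 0L, "genedrop"))
  H1 <- matrix(0L, n, L); H2 <- matrix(0L, n, L)
  if (track_ibd) { lab1 <- matrix(0L, n, L); lab2 <- matrix(0L, n, L) }
  next_lab <- 1L
  founder_draw <- function() rbinom(L, 1L, freqs)
  for (i in ord) {
    for (side in 1:2) {
      p <- if (side == 1L) par$mother[i] else par$father[i]
      if (is.na(p)) {
        hap <- founder_draw()
        if (track_ibd) { lab <- rep(next_lab, L); next_lab <- next_lab + 1L }
      } else {
        pick <- runif(L) < 0.5
        hap <- ifelse(pick, H1[p, ], H2[p, ])
        if (track_ibd) lab <- ifelse(pick, lab1[p, ], lab2[p, ])
      }
      if (side == 1L) { H1[i, ] <- hap; if (track_ibd) lab1[i, ] <- lab }
      else            { H2[i, ] <- hap; if (track_ibd) lab2[i, ] <- lab }
    }
  }
  dosage <- H1 + H2
  rownames(dosage) <- ind$id
  gm <- genotype_matrix(dosage, founder_freqs = freqs)
  if (track_ibd) {
    rownames(lab1) <- rownames(lab2) <- ind$id
    attr(gm, "ibd_labels") <- list(lab1 = lab1, lab2 = lab2)
  }
  gm
}

#' Realized IBD-sharing fraction between two individuals
#'
#' Uses the founder-haplotype labels recorded by
#' `drop_genotypes(..., track_ibd = TRUE)` to compute, per locus, the
#' number of alleles shared identical by descent, and returns the mean
#' shared fraction (the realized analogue of PI-HAT).
#'
#' @param gm genotype matrix carrying `"ibd_labels"`.
#' @param i,j individual ids.
#' @export
realized_ibd <- function(gm, i, j) {
  lab <- attr(gm, "ibd_labels")
  if (is.null(lab)) stop("genotype matrix lacks IBD labels; ",
                         "rerun drop_genotypes(track_ibd = TRUE)")
  a1 <- lab$lab1[i, ]; a2 <- lab$lab2[i, ]
  b1 <- lab$lab1[j, ]; b2 <- lab$lab2[j, ]
  # matched sharing: count IBD allele pairings without reusing an allele
  shared <- ifelse((a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1), 2L,
                   (a1 == b1 | a1 == b2 | a2 == b1 | a2 == b2) * 1L)
  mean(shared) / 2
}

#' Apply genotype missingness
#'
#' Each dosage entry is independently set missing with probability `rate`.
#'
#' @param gm a [genotype_matrix()].
#' @param rate missing probability in [0, 1).
#' @param seed integer seed.
#' @export
apply_missingness <- function(gm, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(gm)
  set.seed(substream_seed(seed, 0L, "missing"))
  d <- gm$dosage
  d[runif(length(d)) < rate] <- NA
  gm$dosage <- d
  gm
}

# -- PED/MAP ------------------------------------------------------------

#' Write genotypes as PLINK-style PED/MAP text files
#'
#' White-space separated dialect: alleles coded 1 (reference) / 2
#' (alternate), missing genotypes `0 0`; the MAP file uses 1-based
#' positions on autosome codes 1-38 (dog). Family id equals individual
#' id; parental ids and phenotype are written as 0.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix (`<prefix>.ped`, `<prefix>.map`).
#' @return the prefix, invisibly.
#' @export
write_ped <- function(gm, prefix) {
  d <- gm$dosage
  code <- function(x) {
    out <- matrix("0 0", nrow(d), ncol(d))
    out[!is.na(x) & x == 0] <- "1 1"
    out[!is.na(x) & x == 1] <- "1 2"
    out[!is.na(x) & x == 2] <- "2 2"
    out
  }
  geno <- code(d)
  lines <- paste(rownames(d), rownames(d), 0, 0, 0, 0,
                 apply(geno, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  map <- gm$loci
  writeLines(paste(map$chrom, map$id, 0, map$pos), paste0(prefix, ".map"))
  invisible(prefix)
}

#' Read PED/MAP text files into a genotype matrix
#'
#' @param prefix path prefix written by [write_ped()] (alleles 1/2,
#'   missing 0).
#' @export
read_ped <- function(prefix) {
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    colClasses = "character")
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos"),
                    colClasses = c("integer", "character", "numeric",
                                   "integer"))
  alle <- as.matrix(ped[, -(1:6), drop = FALSE])
  if (ncol(alle) != 2L * nrow(map))
    stop("PED genotype columns do not match MAP locus count")
  a1 <- alle[, seq(1L, ncol(alle), 2L), drop = FALSE]
  a2 <- alle[, seq(2L, ncol(alle), 2L), drop = FALSE]
  d <- (a1 == "2") + (a2 == "2")
  d[a1 == "0" | a2 == "0"] <- NA
  d <- matrix(as.numeric(d), nrow(ped), nrow(map))
  rownames(d) <- ped[[2L]]
  genotype_matrix(d, loci = map[, c("id", "chrom", "pos")])
}

# -- VCF ----------------------------------------------------------------

#' Write genotypes as a minimal GT-only VCF
#'
#' REF is coded `A`, ALT `G`; dosages map to `0/0`, `0/1`, `1/1`, missing
#' to `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path (plain text `.vcf`).
#' @export
write_vcf <- function(gm, path) {
  d <- gm$dosage
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$id, "A", "G", ".",
                "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Uses vcfR when available (the standard R VCF reader); falls back to a
#' minimal tab-separated reader for the GT-only records written by
#' [write_vcf()].
#'
#' @param path VCF file path.
#' @export
read_vcf_genotypes <- function(path) {
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    hi <- grep("^#CHROM", lines)
    hdr <- strsplit(lines[hi], "\t")[[1L]]
    rec <- do.call(rbind, strsplit(lines[-seq_len(hi)], "\t"))
    fix <- data.frame(CHROM = rec[, 1L], POS = rec[, 2L], ID = rec[, 3L],
                      stringsAsFactors = FALSE)
    gt <- t(rec[, -(1:9), drop = FALSE])
    colnames(gt) <- fix$ID
    rownames(gt) <- hdr[-(1:9)]
    gt <- t(gt)
  }
  ids <- colnames(gt)
  clean <- gsub("\\|", "/", gt)
  d <- matrix(NA_real_, ncol(gt), nrow(gt))
  d[t(clean == "0/0")] <- 0
  d[t(clean == "0/1") | t(clean == "1/0")] <- 1
  d[t(clean == "1/1")] <- 2
  rownames(d) <- ids
  loci <- data.frame(id = fix$ID, chrom = as.integer(fix$CHROM),
                     pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  genotype_matrix(d, loci = loci)
}
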