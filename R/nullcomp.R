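# Simulation ensembles under null mating scenarios, empirical-quantile
# placement of observed statistics, and the permutation ECDF comparison
# of partner-count distributions between the sexes.

#' Mating-system statistics of one pedigree replicate
#'
#' The statistic set tracked across null-ensemble replicates: mean
#' full-sibling, maternal and paternal half-sibling counts per sampled
#' individual, number of repeated parental pairs, close-inbreeding case
#' counts (total and by degree), and male/female Morisita skew and Crow
#' index of offspring numbers (parents of either sex with zero recorded
#' offspring included via the parent cohort of the previous generations).
#'
#' @param ped a [pedigree()].
#' @param close_inbreeding also classify parent pairs (costs a kinship
#'   matrix; default `TRUE`).
#' @return named numeric vector.
#' @export
replicate_statistics <- function(ped, close_inbreeding = TRUE) {
  sib <- sibling_counts(ped)
  opc <- offspring_and_partner_counts(ped)
  # adults of breeding cohorts: everyone not in the final (pup) generation
  par_pool <- opc[ped$individuals$age_class != "pup", , drop = FALSE]
  skew <- function(sex) {
    x <- par_pool$n_offspring[par_pool$sex == sex]
    if (length(x) >= 2L && sum(x) >= 2) morisita_skew(x) else NA_real_
  }
  crow <- function(sex) {
    x <- par_pool$n_offspring[par_pool$sex == sex]
    if (length(x) >= 2L && mean(x) > 0) crow_index(x) else NA_real_
  }
  rp <- repeated_pairs(ped)
  out <- c(mean_full_sibs = mean(sib$n_full_sibs),
           mean_mat_half_sibs = mean(sib$n_mat_half_sibs),
           mean_pat_half_sibs = mean(sib$n_pat_half_sibs),
           n_repeated_pairs = nrow(rp),
           morisita_males = skew("M"), morisita_females = skew("F"),
           crow_males = crow("M"), crow_females = crow("F"))
  if (close_inbreeding) {
    ci <- close_inbreeding(ped)
    by_deg <- vapply(1:4, function(d)
      sum(ci$cases$n_matings[ci$cases$degree == d]), numeric(1))
    out <- c(out, n_inbreeding_cases = ci$n_case_matings,
             setNames(by_deg, paste0("n_inbreeding_deg", 1:4)),
             inbreeding_rate_percent = ci$rate_percent)
  }
  out
}

#' Run a null-simulation ensemble
#'
#' Simulates `config$n_replicates` pedigrees under the configured mating
#' scenario (optionally subsampling each to `config$subsample_n` sampled
#' individuals, emulating genotyping), computes [replicate_statistics()]
#' for each, and — when observed values are supplied — places each
#' observed statistic as an empirical quantile of its null distribution.
#'
#' @param config a [sim_config()].
#' @param observed optional named numeric vector/list of observed
#'   statistic values (names matching [replicate_statistics()] output).
#' @param close_inbreeding forwarded to [replicate_statistics()].
#' @return object of class `null_ensemble`: list with `scenario`,
#'   `n_replicates`, `stats` (replicates x statistics data.frame),
#'   `observed`, `quantiles` (per observed statistic: `q`,
#'   `outside_envelope`).
#' @export
run_ensemble <- function(config, observed = NULL, close_inbreeding = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  simfun <- if (config$scenario == "structured")
    simulate_structured_population else simulate_pedigree
  rows <- lapply(seq_len(config$n_replicates), function(r) {
    ped <- simfun(config, replicate = r)
    if (!is.null(config$subsample_n))
      ped <- subsample_pedigree(ped, config$subsample_n,
                                seed = substream_seed(config$seed, r, "sub"))
    replicate_statistics(ped, close_inbreeding = close_inbreeding)
  })
  stats <- as.data.frame(do.call(rbind, rows))
  quantiles <- NULL
  if (!is.null(observed)) {
    observed <- unlist(observed)
    quantiles <- lapply(names(observed), function(nm) {
      if (!nm %in% names(stats)) return(NULL)
      empirical_quantile(observed[[nm]], stats[[nm]])
    })
    names(quantiles) <- names(observed)
    quantiles <- quantiles[!vapply(quantiles, is.null, logical(1))]
  }
  structure(list(scenario = config$scenario,
                 n_replicates = config$n_replicates,
                 stats = stats, observed = observed, quantiles = quantiles),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> scenario=%s, %d replicates, %d statistics\n",
              x$scenario, x$n_replicates, ncol(x$stats)))
  if (length(x$quantiles)) {
    for (nm in names(x$quantiles)) {
      q <- x$quantiles[[nm]]
      cat(sprintf("  %-24s obs=%.4g q=%.4f%s\n", nm, x$observed[[nm]], q$q,
                  if (q$outside_envelope) "  [outside 95% envelope]" else ""))
    }
  }
  invisible(x)
}

#' Empirical quantile of an observed value in a null distribution
#'
#' q = (#\{sim < obs\} + 0.5 #\{sim = obs\} + 1) / (R + 1), midrank over
#' ties, clamped to [1/(R+1), R/(R+1)] so that no observation sits at an
#' exact 0 or 1. The 95% envelope flag marks q < 0.025 or q > 0.975.
#'
#' @param observed scalar observed value.
#' @param sims vector of replicate values (length >= 1; `NA`s dropped).
#' @return list `q`, `outside_envelope`.
#' @export
empirical_quantile <- function(observed, sims) {
  sims <- sims[!is.na(sims)]
  if (!length(sims)) stop("empty replicate vector")
  R <- length(sims)
  q_raw <- (sum(sims < observed) + 0.5 * sum(sims == observed) + 1) / (R + 1)
  q <- min(max(q_raw, 1 / (R + 1)), R / (R + 1))
  # flag on the unclamped midrank so extremes register even at small R
  list(q = q, outside_envelope = q_raw < 0.025 || q_raw > 0.975)
}

#' Permutation ECDF comparison of partner counts between sexes
#'
#' Computes the empirical cumulative distribution of per-individual
#' partner counts for males, females and all individuals, then permutes
#' the sex labels R times to obtain a pointwise 2.5/97.5% envelope for
#' each sex's curve. A sex is flagged when its observed curve exits the
#' envelope at any evaluation point; under label-exchangeability
#' (identical male and female distributions) flags are rare.
#'
#' @param partners per-individual non-negative integer partner counts.
#' @param sexes parallel vector of `"F"`/`"M"` labels (both must occur).
#' @param R number of permutations (default 1000).
#' @param seed integer seed.
#' @return list `grid`, `ecdf_all`, `ecdf_male`, `ecdf_female`,
#'   `envelope_male`, `envelope_female` (2 x grid matrices, rows
#'   lo/hi), `flag_male`, `flag_female`, `flag_any`.
#' @export
permutation_ecdf <- function(partners, sexes, R = 1000L, seed = 1L) {
  stopifnot(length(partners) == length(sexes), R >= 1L)
  keep <- sexes %in% c("F", "M")
  partners <- partners[keep]; sexes <- sexes[keep]
  if (length(unique(sexes)) < 2L)
    stop("both sexes must be represented")
  grid <- sort(unique(partners))
  curve <- function(x) vapply(grid, function(g) mean(x <= g), numeric(1))
  obs_m <- curve(partners[sexes == "M"])
  obs_f <- curve(partners[sexes == "F"])
  set.seed(substream_seed(seed, 0L, "permecdf"))
  perm_m <- matrix(0, R, length(grid))
  perm_f <- matrix(0, R, length(grid))
  for (r in seq_len(R)) {
    lab <- sample(sexes)
    perm_m[r, ] <- curve(partners[lab == "M"])
    perm_f[r, ] <- curve(partners[lab == "F"])
  }
  env <- function(pm) apply(pm, 2L, quantile, probs = c(0.025, 0.975),
                            type = 1, names = FALSE)
  env_m <- env(perm_m); env_f <- env(perm_f)
  rownames(env_m) <- rownames(env_f) <- c("lo", "hi")
  flag_m <- any(obs_m < env_m["lo", ] | obs_m > env_m["hi", ])
  flag_f <- any(obs_f < env_f["lo", ] | obs_f > env_f["hi", ])
  list(grid = grid, ecdf_all = curve(partners), ecdf_male = obs_m,
       ecdf_female = obs_f, envelope_male = env_m, envelope_female = env_f,
       flag_male = flag_m, flag_female = flag_f,
       flag_any = flag_m || flag_f)
}
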