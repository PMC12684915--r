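# Forward pedigree simulation under null mating scenarios, plus the
# structured synthetic-population generator used as a stand-in for the
# study populations.

#' Derive a deterministic substream seed
#'
#' One master seed governs every source of randomness; per-replicate,
#' per-stage substreams are derived with a Lehmer-style hash so that
#' replicates are reproducible individually and mutually independent.
#'
#' @param seed master seed (integer).
#' @param replicate replicate number (integer).
#' @param stage short stage label.
#' @return integer seed in [1, 2^31 - 2].
#' @export
substream_seed <- function(seed, replicate = 1L, stage = "") {
  m <- 2147483647
  val <- as.numeric(seed) %% m
  for (x in c(as.numeric(replicate), sum(utf8ToInt(stage)))) {
    val <- (val * 48271 + x + 1) %% m
  }
  as.integer(val) + 1L
}

# -- distribution specs -------------------------------------------------

#' Categorical count distribution
#'
#' @param probs named numeric vector; names are non-negative integer
#'   values, entries their probabilities (must sum to 1).
#' @return a distribution spec usable as `litter_size_dist` or
#'   `fathers_per_litter_dist` in [sim_config()].
#' @export
dist_categorical <- function(probs) {
  vals <- as.integer(names(probs))
  if (anyNA(vals)) stop("probs must be named by integer values")
  if (abs(sum(probs) - 1) > 1e-8) stop("probabilities must sum to 1")
  structure(list(values = vals, probs = unname(probs) / sum(probs)),
            class = "count_dist")
}

#' Truncated Poisson count distribution
#'
#' Poisson(`mean`) conditioned on the range `[min, max]`; the package
#' default litter-size distribution is `dist_truncpois(5, 1, 10)`.
#'
#' @param mean Poisson mean before truncation.
#' @param min,max inclusive support bounds.
#' @export
dist_truncpois <- function(mean, min = 1L, max = 10L) {
  vals <- seq.int(min, max)
  p <- stats::dpois(vals, mean)
  if (sum(p) <= 0) stop("empty truncated support")
  structure(list(values = vals, probs = p / sum(p)), class = "count_dist")
}

draw_count <- function(dist, n) {
  dist$values[sample.int(length(dist$values), n, replace = TRUE,
                         prob = dist$probs)]
}

# -- configuration ------------------------------------------------------

#' Simulation configuration
#'
#' Bundles all parameters of the forward pedigree simulator. Defaults
#' follow the null-model design used throughout the package: concurrent
#' generations (every mating round draws parents from all previously
#' created individuals); each breeding female produces at most
#' `female_max_litters_per_gen` litters per round (a physiological cap
#' applied to females only, males are unconstrained); litter sizes are
#' truncated-Poisson(5) on 1..10; under `random_litter` the number of
#' fathers per litter is drawn from `{1: 0.7, 2: 0.2, 3: 0.1}`.
#'
#' @param scenario `"random"` (each pup's father drawn independently and
#'   uniformly), `"random_litter"` (a limited father set per litter), or
#'   `"structured"` (adds reproductive skew, pair fidelity, social groups
#'   and sex-biased dispersal; see [simulate_structured_population()]).
#' @param n_founders founder population size.
#' @param sex_ratio proportion of females (default 0.5).
#' @param n_generations total generations including the founders.
#' @param female_max_litters_per_gen cap on litters per female per
#'   generation.
#' @param litter_size_dist,fathers_per_litter_dist count-distribution
#'   specs ([dist_categorical()] / [dist_truncpois()]).
#' @param target_pop_size offspring produced per generation.
#' @param subsample_n number of individuals marked sampled downstream
#'   (`NULL` = all sampled).
#' @param n_replicates ensemble size for [run_ensemble()].
#' @param seed master seed.
#' @param structured_knobs list with `male_skew` (>= 0; dispersion of male
#'   mating weights, 0 = uniform), `pair_fidelity` ([0,1]; probability a
#'   female reuses her previous partner for a further litter),
#'   `philopatry` ([0,1]; probability offspring stay in the mother's
#'   group), `n_groups`, `n_locations`, `female_dispersal_bias` ([0,1];
#'   probability a between-location migrant is female), `migration_rate`
#'   ([0,1); per-offspring between-location movement rate).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(scenario = c("random", "random_litter", "structured"),
                       n_founders = 200L,
                       sex_ratio = 0.5,
                       n_generations = 4L,
                       female_max_litters_per_gen = 1L,
                       litter_size_dist = dist_truncpois(5, 1, 10),
                       fathers_per_litter_dist =
                         dist_categorical(c("1" = 0.7, "2" = 0.2, "3" = 0.1)),
                       target_pop_size = 200L,
                       subsample_n = NULL,
                       n_replicates = 1000L,
                       seed = 1L,
                       structured_knobs = list()) {
  scenario <- match.arg(scenario)
  knobs <- utils::modifyList(
    list(male_skew = 0, pair_fidelity = 0, philopatry = 0.5,
         n_groups = 8L, n_locations = 2L, female_dispersal_bias = 0.5,
         migration_rate = 0.1),
    structured_knobs)
  cfg <- structure(list(
    scenario = scenario, n_founders = as.integer(n_founders),
    sex_ratio = sex_ratio, n_generations = as.integer(n_generations),
    female_max_litters_per_gen = as.integer(female_max_litters_per_gen),
    litter_size_dist = litter_size_dist,
    fathers_per_litter_dist = fathers_per_litter_dist,
    target_pop_size = as.integer(target_pop_size),
    subsample_n = if (is.null(subsample_n)) NULL else as.integer(subsample_n),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed), structured_knobs = knobs),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_founders >= 2L, cfg$n_generations >= 1L,
            cfg$target_pop_size >= 1L, cfg$female_max_litters_per_gen >= 1L,
            inherits(cfg$litter_size_dist, "count_dist"),
            inherits(cfg$fathers_per_litter_dist, "count_dist"))
  if (cfg$sex_ratio <= 0 || cfg$sex_ratio >= 1)
    stop("sex_ratio must lie strictly between 0 and 1 ",
         "(both sexes must be possible)")
  k <- cfg$structured_knobs
  if (k$male_skew < 0) stop("male_skew must be >= 0")
  for (nm in c("pair_fidelity", "philopatry", "female_dispersal_bias")) {
    if (k[[nm]] < 0 || k[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (k$migration_rate < 0 || k$migration_rate >= 1)
    stop("migration_rate must lie in [0, 1)")
  invisible(cfg)
}

# -- forward simulation -------------------------------------------------

#' Simulate a pedigree under a null mating scenario
#'
#' Forward simulation with concurrent generations: a founder cohort
#' (generation 0, sexes split by `sex_ratio`) is followed by
#' `n_generations - 1` rounds of mating, and each round draws its parents
#' from *all* previously created individuals, so cohorts coexist, females
#' accrue litters across rounds, and the same pair can breed repeatedly —
#' as in real multi-year genealogies. Each round, breeding females (each
#' limited to `female_max_litters_per_gen` litters per round) are drawn
#' until the round's offspring quota (`target_pop_size`) is met. Under
#' `scenario = "random"` (fully
#' promiscuous mating) both parents of every pup are drawn independently
#' and uniformly: fathers without any cap, mothers subject only to the
#' female physiological capacity (`female_max_litters_per_gen` times the
#' maximum litter size); a female's offspring within a generation form
#' her litter. Under `scenario = "random_litter"` breeding females
#' produce litters with sizes from `litter_size_dist`; each litter draws
#' its number of fathers from `fathers_per_litter_dist` and pups are
#' partitioned uniformly among that father set, so full siblings arise.
#' The result is byte-identical for identical `(seed, replicate)`.
#'
#' @param config a [sim_config()] with scenario `random` or
#'   `random_litter`.
#' @param replicate replicate index (seeds the substream).
#' @return a [pedigree()]; the final generation is age class `pup`, all
#'   earlier generations `adult`.
#' @export
simulate_pedigree <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$scenario %in% c("random", "random_litter"))
    stop("scenario must be 'random' or 'random_litter'; use ",
         "simulate_structured_population() for 'structured'")
  sim_forward(config, replicate, structured = FALSE)
}

# shared engine for the null scenarios and the structured generator.
# Generations are concurrent: each mating round draws parents from all
# previously created individuals (founders and earlier rounds), so the
# same pair can produce litters in different rounds and females accrue
# litters across rounds, as in real multi-year genealogies.
sim_forward <- function(config, replicate, structured) {
  set.seed(substream_seed(config$seed, replicate, "pedigree"))
  k <- config$structured_knobs
  n0 <- config$n_founders
  n_f <- max(1L, min(n0 - 1L, round(n0 * config$sex_ratio)))
  sex0 <- sample(c(rep("F", n_f), rep("M", n0 - n_f)))
  founders <- data.frame(
    id = sprintf("R%d_G0_I%04d", replicate, seq_len(n0)),
    sex = sex0, age_class = "adult",
    mother_id = NA_character_, father_id = NA_character_,
    litter_id = NA_character_,
    group_id = if (structured)
      sprintf("grp%02d", sample.int(k$n_groups, n0, replace = TRUE))
    else NA_character_,
    location_id = if (structured)
      sprintf("loc%d", sample.int(k$n_locations, n0, replace = TRUE))
    else NA_character_,
    sampled = TRUE, generation = 0L, stringsAsFactors = FALSE)
  # persistent male mating weights (consistent dominance across rounds)
  weights <- setNames(
    if (structured && k$male_skew > 0) rlnorm(n0, 0, k$male_skew)
    else rep(1, n0), founders$id)

  cohorts <- list(founders)
  last_partner <- character(0)  # mother id -> her last litter's 1st father
  for (g in seq_len(config$n_generations - 1L)) {
    pool <- do.call(rbind, cohorts)
    females <- pool$id[pool$sex == "F"]
    males <- pool$id[pool$sex == "M"]
    if (!length(males) || !length(females))
      stop("impossible config: breeding pool lacks one sex")
    male_w <- unname(weights[males])
    quota <- config$target_pop_size
    last_round <- g == config$n_generations - 1L

    if (config$scenario == "random" && !structured) {
      # fully promiscuous: both parents drawn independently per pup;
      # the female physiological cap (max litters x max litter size) is
      # enforced by rejection, so mother draws stay i.i.d. uniform
      # whenever the cap does not bind. A female's offspring within a
      # round form one litter.
      cap <- config$female_max_litters_per_gen *
        max(config$litter_size_dist$values)
      if (length(females) * cap < quota)
        stop("female capacity too small for target_pop_size")
      for (try in 1:100) {
        moms <- females[sample.int(length(females), quota, replace = TRUE)]
        if (max(table(moms)) <= cap) break
        if (try == 100L) {  # near-saturated cap: fall back to slot draw
          slots <- rep(females, cap)
          moms <- slots[sample.int(length(slots), quota)]
        }
      }
      dads <- males[sample.int(length(males), quota, replace = TRUE)]
      off <- data.frame(
        id = sprintf("R%d_G%d_I%04d", replicate, g, seq_len(quota)),
        sex = ifelse(runif(quota) < config$sex_ratio, "F", "M"),
        age_class = if (last_round) "pup" else "adult",
        mother_id = moms, father_id = dads,
        litter_id = sprintf("R%d_G%d_%s", replicate, g, moms),
        group_id = NA_character_, location_id = NA_character_,
        sampled = TRUE, generation = g, stringsAsFactors = FALSE)
    } else {
      # litter-structured mating: breeding females drawn until the
      # offspring quota is met, litter sizes from litter_size_dist, a
      # limited father set per litter from fathers_per_litter_dist
      slots <- sample(rep(females, config$female_max_litters_per_gen))
      made <- 0L
      rows <- list()
      litter_no <- 0L
      for (mom in slots) {
        if (made >= quota) break
        litter_no <- litter_no + 1L
        s <- min(draw_count(config$litter_size_dist, 1L), quota - made)
        lid <- sprintf("R%d_G%d_L%04d", replicate, g, litter_no)
        nf <- min(draw_count(config$fathers_per_litter_dist, 1L),
                  length(males), s)
        fset <- males[sample.int(length(males), nf, replace = FALSE,
                                 prob = male_w)]
        if (structured && k$pair_fidelity > 0 &&
            !is.na(last_partner[mom]) && runif(1) < k$pair_fidelity) {
          fset[1L] <- last_partner[[mom]]
          fset <- unique(fset)
        }
        dads <- fset[sample.int(length(fset), s, replace = TRUE)]
        last_partner[mom] <- dads[1L]
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("R%d_G%d_I%04d", replicate, g, made + seq_len(s)),
          sex = ifelse(runif(s) < config$sex_ratio, "F", "M"),
          age_class = if (last_round) "pup" else "adult",
          mother_id = mom, father_id = dads, litter_id = lid,
          group_id = NA_character_, location_id = NA_character_,
          sampled = TRUE, generation = g, stringsAsFactors = FALSE)
        made <- made + s
      }
      off <- do.call(rbind, rows)
    }
    if (structured) {
      mom_idx <- match(off$mother_id, pool$id)
      stay <- runif(nrow(off)) < k$philopatry
      off$group_id <- ifelse(
        stay, pool$group_id[mom_idx],
        sprintf("grp%02d", sample.int(k$n_groups, nrow(off), replace = TRUE)))
      off$location_id <- pool$location_id[mom_idx]
      if (k$n_locations > 1L && k$migration_rate > 0) {
        p_mig <- 2 * k$migration_rate *
          ifelse(off$sex == "F", k$female_dispersal_bias,
                 1 - k$female_dispersal_bias)
        mig <- runif(nrow(off)) < pmin(1, p_mig)
        cur <- as.integer(sub("loc", "", off$location_id))
        shift <- sample.int(k$n_locations - 1L, nrow(off), replace = TRUE)
        off$location_id[mig] <- sprintf(
          "loc%d", 1L + (cur[mig] - 1L + shift[mig]) %% k$n_locations)
      }
    }
    weights[off$id] <- if (structured && k$male_skew > 0)
      rlnorm(nrow(off), 0, k$male_skew) else rep(1, nrow(off))
    cohorts[[g + 1L]] <- off
  }
  ind <- do.call(rbind, cohorts)
  generation <- setNames(ind$generation, ind$id)
  ind$generation <- NULL
  ped <- pedigree(ind, validate = FALSE)
  ped$generation_index <- generation
  ped
}

#' Structured synthetic population
#'
#' Extends the `random_litter` scenario with the features of real
#' free-ranging dog populations that the null scenarios deliberately lack:
#' male mating weights with log-normal dispersion controlled by
#' `male_skew` (0 = uniform, i.e. identical to `random_litter`), partner
#' reuse with probability `pair_fidelity` (visible when females may have
#' several litters per generation), social groups with offspring retained
#' in the mother's group with probability `philopatry`, maternally
#' inherited locations, and between-location movement whose sex
#' composition is set by `female_dispersal_bias`
#' (1 = all migrants female).
#'
#' @param config a [sim_config()] with `scenario = "structured"`.
#' @param replicate replicate index.
#' @return a [pedigree()] with group and location attributes filled in.
#' @export
simulate_structured_population <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (config$scenario != "structured")
    stop("config$scenario must be 'structured'")
  sim_forward(config, replicate, structured = TRUE)
}

#' Mark a random subsample as sampled
#'
#' Emulates the genotyped subset of a study population: `n` uniformly
#' drawn individuals keep `sampled = TRUE`, all others are set to
#' `FALSE`. Parent links are retained for everyone, mirroring genealogy
#' reconstruction in which unsampled parents are inferred; downstream
#' statistics count relationships among sampled individuals only.
#'
#' @param ped a [pedigree()].
#' @param n subsample size (at most the population size).
#' @param seed integer seed.
#' @export
subsample_pedigree <- function(ped, n, seed = 1L) {
  n_tot <- nrow(ped$individuals)
  if (n > n_tot) stop("subsample size ", n, " exceeds population ", n_tot)
  set.seed(substream_seed(seed, 0L, "subsample"))
  keep <- sample.int(n_tot, n)
  ped$individuals$sampled <- seq_len(n_tot) %in% keep
  ped
}

#' Simulate dyadic proximity interactions
#'
#' Draws Poisson interaction counts for every dyad of group-assigned
#' individuals, with the mean inflated for same-group dyads and for
#' realized parent pairs, independently per season. Zero-count dyads are
#' omitted.
#'
#' @param ped a [pedigree()] with `group_id` set for at least two
#'   individuals.
#' @param params list: `between_rate` (mean count for a between-group
#'   dyad, default 0.2), `within_rate` (mean count for a same-group dyad,
#'   default 2), `parent_pair_mult` (mean multiplier for realized parent
#'   pairs, default 3), `seasons` (character vector, default `"s1"`).
#' @param seed integer seed.
#' @return data.frame (`id_a`, `id_b`, `season`, `count`) with
#'   `id_a < id_b`; unordered pairs are unique within a season.
#' @export
simulate_interactions <- function(ped, params = list(), seed = 1L) {
  p <- utils::modifyList(
    list(between_rate = 0.2, within_rate = 2, parent_pair_mult = 3,
         seasons = "s1"), params)
  ind <- ped$individuals[!is.na(ped$individuals$group_id), , drop = FALSE]
  if (nrow(ind) < 2L) stop("pedigree has fewer than two grouped individuals")
  set.seed(substream_seed(seed, 0L, "interactions"))
  pairs <- t(utils::combn(ind$id, 2L))
  a <- pmin(pairs[, 1L], pairs[, 2L]); b <- pmax(pairs[, 1L], pairs[, 2L])
  grp <- setNames(ind$group_id, ind$id)
  same <- grp[a] == grp[b]
  pp <- realized_parent_pairs(ped)
  key <- paste(pmin(pp$mother, pp$father), pmax(pp$mother, pp$father))
  is_pair <- paste(a, b) %in% key
  lambda <- ifelse(same, p$within_rate, p$between_rate) *
    ifelse(is_pair, p$parent_pair_mult, 1)
  out <- do.call(rbind, lapply(p$seasons, function(s) {
    counts <- rpois(length(lambda), lambda)
    data.frame(id_a = a, id_b = b, season = s, count = counts,
               stringsAsFactors = FALSE)
  }))
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# distinct (mother, father) pairs with both parents recorded
realized_parent_pairs <- function(ped) {
  ind <- ped$individuals
  ok <- !is.na(ind$mother_id) & !is.na(ind$father_id)
  unique(data.frame(mother = ind$mother_id[ok], father = ind$father_id[ok],
                    stringsAsFactors = FALSE))
}
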