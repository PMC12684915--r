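# Forward pedigree simulation under null scenarios and the structured
# synthetic-population generator.

small_cfg <- function(scenario, seed = 1L, ...) {
  sim_config(scenario = scenario, n_founders = 60L, target_pop_size = 60L,
             n_generations = 3L, n_replicates = 5L, seed = seed, ...)
}

test_that("simulation is deterministic in (seed, replicate)", {
  cfg <- small_cfg("random_litter", seed = 5L)
  expect_identical(simulate_pedigree(cfg, 2L), simulate_pedigree(cfg, 2L))
  expect_false(identical(simulate_pedigree(cfg, 1L),
                         simulate_pedigree(cfg, 2L)))
})

test_that("offspring have both parents and females respect the litter cap", {
  for (sc in c("random", "random_litter")) {
    ped <- simulate_pedigree(small_cfg(sc, seed = 3L), 1L)
    ind <- ped$individuals
    off <- ind[!is.na(ind$mother_id), , drop = FALSE]
    expect_equal(nrow(off), 120L)  # two rounds x target size
    expect_false(anyNA(off$father_id))
    sex <- setNames(ind$sex, ind$id)
    expect_true(all(sex[off$mother_id] == "F"))
    expect_true(all(sex[off$father_id] == "M"))
    if (sc == "random_litter") {
      # per round, each mother has at most female_max_litters_per_gen litters
      round <- sub("_.*$", "", sub("^R1_", "", off$id))
      per <- tapply(off$litter_id, paste(round, off$mother_id),
                    function(x) length(unique(x)))
      expect_lte(max(per), 1L)
    }
  }
})

test_that("expected distinct fathers per litter follows the occupancy law", {
  # random scenario: each pup draws its father uniformly among m males, so
  # a litter of size k has m(1 - (1 - 1/m)^k) distinct fathers on average
  cfg <- sim_config(scenario = "random", n_founders = 40L,
                    target_pop_size = 120L, n_generations = 2L, seed = 8L)
  obs <- list()
  for (r in 1:40) {
    ped <- simulate_pedigree(cfg, r)
    ind <- ped$individuals
    off <- ind[!is.na(ind$litter_id), , drop = FALSE]
    m <- sum(ind$sex == "M" & is.na(ind$mother_id))
    per <- split(off$father_id, off$litter_id)
    for (l in per)
      obs[[length(obs) + 1L]] <- c(k = length(l),
                                   d = length(unique(l)), m = m)
  }
  tab <- do.call(rbind, obs)
  for (k in 2:6) {
    sel <- tab[, "k"] == k
    if (sum(sel) < 30) next
    m <- tab[sel, "m"][1]
    expected <- m * (1 - (1 - 1 / m)^k)
    expect_equal(mean(tab[sel, "d"]), expected, tolerance = 0.08,
                 label = sprintf("litter size %d", k))
  }
})

test_that("subsampling marks exactly n individuals and scales sib counts", {
  cfg <- small_cfg("random_litter", seed = 4L)
  ped <- simulate_pedigree(cfg, 1L)
  n_tot <- nrow(ped$individuals)
  expect_error(subsample_pedigree(ped, n_tot + 1L), "exceeds")
  # identity case: n = population size leaves statistics unchanged
  full <- sibling_counts(ped)
  expect_equal(sibling_counts(subsample_pedigree(ped, n_tot, 1L)), full)
  # n = 1: no pairs left
  s1 <- sibling_counts(subsample_pedigree(ped, 1L, 1L))
  expect_equal(nrow(s1), 1L)
  expect_equal(sum(s1[, -(1:2)]), 0L)
  # 50% subsampling halves half-sib counts in expectation (each partner
  # retained with probability ~ (n-1)/(N-1))
  tot_full <- sum(full$n_mat_half_sibs + full$n_pat_half_sibs)
  ratios <- vapply(1:60, function(s) {
    sub <- sibling_counts(subsample_pedigree(ped, n_tot %/% 2L, seed = s))
    sum(sub$n_mat_half_sibs + sub$n_pat_half_sibs) / tot_full
  }, numeric(1))
  # pair retention probability ~ 0.25 at half sampling
  expect_equal(mean(ratios), 0.25, tolerance = 0.03)
})

test_that("structured generator with knobs off matches the litter null", {
  cfg_off <- sim_config(scenario = "structured", n_founders = 100L,
                        target_pop_size = 100L, n_generations = 3L,
                        seed = 31L,
                        structured_knobs = list(male_skew = 0,
                                                pair_fidelity = 0,
                                                philopatry = 0,
                                                n_locations = 1L))
  cfg_null <- sim_config(scenario = "random_litter", n_founders = 100L,
                         target_pop_size = 100L, n_generations = 3L,
                         seed = 77L)
  s_off <- vapply(1:15, function(r) replicate_statistics(
    simulate_structured_population(cfg_off, r),
    close_inbreeding = FALSE)["morisita_males"], numeric(1))
  s_null <- vapply(1:15, function(r) replicate_statistics(
    simulate_pedigree(cfg_null, r),
    close_inbreeding = FALSE)["morisita_males"], numeric(1))
  expect_equal(mean(s_off), mean(s_null), tolerance = 0.35)
})

test_that("male skew concentrates paternity", {
  base <- list(pair_fidelity = 0, philopatry = 0, n_locations = 1L)
  mk <- function(skew, seed) sim_config(
    scenario = "structured", n_founders = 100L, target_pop_size = 100L,
    n_generations = 3L, seed = seed,
    structured_knobs = c(list(male_skew = skew), base))
  m_hi <- vapply(1:10, function(r) replicate_statistics(
    simulate_structured_population(mk(1.5, 50L), r),
    close_inbreeding = FALSE)["morisita_males"], numeric(1))
  m_lo <- vapply(1:10, function(r) replicate_statistics(
    simulate_structured_population(mk(0, 51L), r),
    close_inbreeding = FALSE)["morisita_males"], numeric(1))
  expect_gt(mean(m_hi), 2 * mean(m_lo))
})

test_that("dispersal and philopatry boundary knobs are exact", {
  cfg <- sim_config(scenario = "structured", n_founders = 80L,
                    target_pop_size = 80L, n_generations = 3L, seed = 12L,
                    structured_knobs = list(philopatry = 1,
                                            female_dispersal_bias = 1,
                                            migration_rate = 0.2,
                                            n_locations = 2L))
  ped <- simulate_structured_population(cfg, 1L)
  ind <- ped$individuals
  off <- ind[!is.na(ind$mother_id), , drop = FALSE]
  mom <- match(off$mother_id, ind$id)
  # philopatry = 1: every offspring in its mother's group
  expect_true(all(off$group_id == ind$group_id[mom]))
  # female_dispersal_bias = 1: all between-location migrants are female
  migrants <- off[off$location_id != ind$location_id[mom], , drop = FALSE]
  expect_gt(nrow(migrants), 0L)
  expect_true(all(migrants$sex == "F"))
})

test_that("interaction simulation is deterministic and group-driven", {
  cfg <- sim_config(scenario = "structured", n_founders = 40L,
                    target_pop_size = 40L, n_generations = 2L, seed = 6L,
                    structured_knobs = list(philopatry = 1, n_groups = 3L,
                                            n_locations = 1L))
  ped <- simulate_structured_population(cfg, 1L)
  t1 <- simulate_interactions(ped, seed = 9L)
  t2 <- simulate_interactions(ped, seed = 9L)
  expect_identical(t1, t2)
  expect_true(all(t1$count >= 1L))
  expect_true(all(t1$id_a < t1$id_b))
  # zero between-group rate: communities exactly equal groups
  t0 <- simulate_interactions(
    ped, params = list(between_rate = 0, within_rate = 3), seed = 2L)
  grp <- setNames(ped$individuals$group_id, ped$individuals$id)
  expect_true(all(grp[t0$id_a] == grp[t0$id_b]))
  net <- build_network(t0)
  com <- detect_communities(net)$membership
  cross <- table(grp[names(com)], com)
  expect_true(all(rowSums(cross > 0) == 1L))  # each group one community
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sex_ratio = 0), "sex_ratio")
  expect_error(sim_config(structured_knobs = list(male_skew = -1)),
               "male_skew")
  expect_error(sim_config(structured_knobs = list(pair_fidelity = 2)),
               "pair_fidelity")
  expect_error(dist_categorical(c("1" = 0.5, "2" = 0.4)), "sum to 1")
  cfg <- small_cfg("structured")
  expect_error(simulate_pedigree(cfg), "structured")
  expect_error(
    simulate_structured_population(small_cfg("random")), "structured")
})
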