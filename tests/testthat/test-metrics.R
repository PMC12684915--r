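# Genealogy-derived mating-system statistics.

family_ped <- function() {
  # male "sire" with litters (dam1, L1: 3 pups) and (dam2, L2: 2 pups)
  pedigree(data.frame(
    id = c("sire", "dam1", "dam2", sprintf("p%d", 1:5)),
    sex = c("M", "F", "F", rep("U", 5)),
    age_class = c(rep("adult", 3), rep("pup", 5)),
    mother_id = c(NA, NA, NA, "dam1", "dam1", "dam1", "dam2", "dam2"),
    father_id = c(NA, NA, NA, rep("sire", 5)),
    litter_id = c(NA, NA, NA, "L1", "L1", "L1", "L2", "L2"),
    stringsAsFactors = FALSE))
}

test_that("offspring, reduced-offspring and partner counts are exact", {
  oc <- offspring_and_partner_counts(family_ped())
  sire <- oc[oc$id == "sire", ]
  expect_equal(sire$n_offspring, 5L)
  expect_equal(sire$n_offspring_reduced, 2L)  # one pup per pair per litter
  expect_equal(sire$n_partners, 2L)
  expect_equal(oc[oc$id == "dam1", "n_offspring"], 3L)
  expect_equal(oc[oc$id == "p1", c("n_offspring", "n_partners")],
               data.frame(n_offspring = 0L, n_partners = 0L,
                          row.names = 4L))
})

test_that("counts match a brute-force parent-column scan on simulations", {
  ped <- simulate_pedigree(
    sim_config(scenario = "random_litter", n_founders = 80L,
               target_pop_size = 80L, n_generations = 4L, seed = 19L), 1L)
  oc <- offspring_and_partner_counts(ped)
  sib <- sibling_counts(ped)
  ind <- ped$individuals
  for (id in sample(ind$id, 40L)) {
    is_off <- !is.na(ind$mother_id) &
      (ind$mother_id == id | (!is.na(ind$father_id) & ind$father_id == id))
    expect_equal(oc$n_offspring[oc$id == id], sum(is_off), label = id)
    partners <- unique(c(ind$father_id[!is.na(ind$mother_id) &
                                         ind$mother_id == id],
                         ind$mother_id[!is.na(ind$father_id) &
                                         ind$father_id == id]))
    expect_equal(oc$n_partners[oc$id == id],
                 length(partners[!is.na(partners)]), label = id)
    # brute-force sibling scan
    me <- ind[ind$id == id, ]
    others <- ind[ind$id != id, ]
    same_m <- !is.na(me$mother_id) & !is.na(others$mother_id) &
      others$mother_id == me$mother_id
    same_f <- !is.na(me$father_id) & !is.na(others$father_id) &
      others$father_id == me$father_id
    expect_equal(sib$n_full_sibs[sib$id == id], sum(same_m & same_f))
    expect_equal(sib$n_mat_half_sibs[sib$id == id], sum(same_m & !same_f))
    expect_equal(sib$n_pat_half_sibs[sib$id == id], sum(!same_m & same_f))
  }
  # sibling relations are symmetric, so population totals are even
  expect_equal(sum(sib$n_full_sibs) %% 2L, 0L)
  expect_equal(sum(sib$n_mat_half_sibs + sib$n_pat_half_sibs) %% 2L, 0L)
  # partner/offspring ordering invariant
  expect_true(all(oc$n_partners <= pmax(oc$n_offspring_reduced, 0L) |
                    oc$n_offspring == 0L))
  expect_true(all(oc$n_offspring_reduced <= oc$n_offspring))
})

test_that("sibling counts handle the textbook configurations", {
  ped <- pedigree(data.frame(
    id = c("M", "X", "Y", "a", "b"), sex = c("F", "M", "M", "U", "U"),
    mother_id = c(NA, NA, NA, "M", "M"),
    father_id = c(NA, NA, NA, "X", "Y"), stringsAsFactors = FALSE))
  s <- sibling_counts(ped)
  expect_equal(s[s$id == "a", "n_mat_half_sibs"], 1L)
  expect_equal(s[s$id == "a", "n_full_sibs"], 0L)
  trio <- family_ped()
  st <- sibling_counts(trio)
  expect_equal(st[st$id == "p1", "n_full_sibs"], 2L)
  expect_equal(st[st$id == "p1", "n_pat_half_sibs"], 2L)
})

test_that("multiple paternity counts litters by the two-offspring rule", {
  ped <- pedigree(data.frame(
    id = c("m1", "m2", "A", "B", "x1", "x2", "x3", "y1"),
    sex = c("F", "F", "M", "M", rep("U", 4)),
    mother_id = c(NA, NA, NA, NA, "m1", "m1", "m1", "m2"),
    father_id = c(NA, NA, NA, NA, "A", "A", "B", "A"),
    litter_id = c(NA, NA, NA, NA, "L1", "L1", "L1", "L2"),
    stringsAsFactors = FALSE))
  mp <- multiple_paternity(ped)
  # L2 has a single sampled offspring: excluded from the denominator
  expect_equal(mp$n_eligible_litters, 1L)
  expect_equal(mp$n_multifather_litters, 1L)  # fathers {A, A, B}
  expect_equal(mp$percent, 100)
})

test_that("multifather litter fraction matches the occupancy expectation", {
  cfg <- sim_config(scenario = "random", n_founders = 30L,
                    target_pop_size = 90L, n_generations = 2L, seed = 23L)
  num <- 0L; den <- 0L; expc <- 0
  for (r in 1:30) {
    ped <- simulate_pedigree(cfg, r)
    m <- sum(ped$individuals$sex == "M" & is.na(ped$individuals$mother_id))
    mp <- multiple_paternity(ped)
    el <- mp$litters[mp$litters$n_sampled_offspring >= 2L, , drop = FALSE]
    num <- num + sum(el$n_fathers >= 2L)
    den <- den + nrow(el)
    # P(single father | k pups) = (1/m)^(k-1)
    expc <- expc + sum(1 - (1 / m)^(el$n_sampled_offspring - 1))
  }
  expect_lt(abs(num / den - expc / den), 0.03)
})

test_that("repeated parental pairs are detected with partner context", {
  ped <- pedigree(data.frame(
    id = c("f", "m", "m2", "a", "b", "c"),
    sex = c("F", "M", "M", "U", "U", "U"),
    mother_id = c(NA, NA, NA, "f", "f", "f"),
    father_id = c(NA, NA, NA, "m", "m", "m2"),
    litter_id = c(NA, NA, NA, "s1", "s2", "s3"),
    stringsAsFactors = FALSE))
  rp <- repeated_pairs(ped)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$n_litters, 2L)
  expect_true(rp$other_partners)  # f also bred with m2
  # all litters by distinct pairs: empty result
  expect_equal(nrow(repeated_pairs(family_ped())), 0L)
})

test_that("close inbreeding classifies realized parent pairs", {
  fd <- pedigree(data.frame(
    id = c("gm", "sire", "dau", "x", "um", "uf", "y"),
    sex = c("F", "M", "F", "U", "F", "M", "U"),
    mother_id = c(NA, NA, "gm", "dau", NA, NA, "um"),
    father_id = c(NA, NA, "sire", "sire", NA, NA, "uf"),
    litter_id = c(NA, NA, "L0", "L1", NA, NA, "L2"),
    stringsAsFactors = FALSE))
  ci <- close_inbreeding(fd)
  expect_equal(nrow(ci$cases), 1L)
  expect_equal(ci$cases$rel_type, "parent-offspring")  # father-daughter
  expect_equal(ci$cases$degree, 1L)
  expect_equal(ci$n_matings, 3L)
  expect_equal(ci$rate_percent, 100 / 3)
  # unrelated founder couples: no cases
  ci0 <- close_inbreeding(family_ped())
  expect_equal(nrow(ci0$cases), 0L)
  expect_equal(ci0$rate_percent, 0)
})

test_that("skew indices match hand values and brute-force implementations", {
  expect_equal(crow_index(c(2, 2, 2)), 0)
  expect_equal(crow_index(c(0, 4)), 2)  # mean 2, sample variance 8
  expect_error(crow_index(c(0, 0)), "zero mean")
  expect_equal(morisita_skew(c(1, 1, 1, 1)), 0)
  expect_equal(morisita_skew(c(4, 0, 0, 0)), 4)  # full monopolization = n
  expect_equal(morisita_skew(c(2, 1, 1)), 0.5)
  expect_error(morisita_skew(c(1, 0)), "total")
  set.seed(31)
  for (i in 1:300) {
    x <- rpois(sample(2:30, 1), sample(1:8, 1))
    if (sum(x) >= 2) expect_equal(morisita_skew(x), brute_morisita(x),
                                  tolerance = 1e-12)
    if (mean(x) > 0) {
      expect_equal(crow_index(x), brute_crow(x), tolerance = 1e-12)
      # scale invariance of Crow's index
      expect_equal(crow_index(3.7 * x), crow_index(x), tolerance = 1e-12)
    }
  }
})

test_that("group kin summaries capture strangers, families and philopatry", {
  # one group of mutual strangers + one nuclear family group
  ped <- pedigree(data.frame(
    id = c("s1", "s2", "s3", "fm", "ff", "fk1", "fk2"),
    sex = c("M", "M", "F", "F", "M", "U", "U"),
    age_class = "adult",
    mother_id = c(NA, NA, NA, NA, NA, "fm", "fm"),
    father_id = c(NA, NA, NA, NA, NA, "ff", "ff"),
    group_id = c("g1", "g1", "g1", "g2", "g2", "g2", "g2"),
    stringsAsFactors = FALSE))
  gs <- group_kin_summary(ped, pedigree_kinship_table(ped))
  g1 <- gs$groups[gs$groups$group_id == "g1", ]
  expect_equal(g1$pct_unrelated_members, 100)
  expect_equal(g1$mean_pihat, 0)
  g2 <- gs$groups[gs$groups$group_id == "g2", ]
  expect_equal(g2$pct_unrelated_members, 0)
  expect_gt(g2$mean_pihat, 0.3)
  expect_warning(group_kin_summary(
    pedigree(data.frame(id = c("a", "b"), sex = "U",
                        group_id = c("g", "g"))),
    pedigree_kinship_table(ped)), "at least")
  # full philopatry: every adult offspring found in its natal group
  cfg <- sim_config(scenario = "structured", n_founders = 60L,
                    target_pop_size = 60L, n_generations = 3L, seed = 37L,
                    structured_knobs = list(philopatry = 1, n_groups = 4L,
                                            n_locations = 1L))
  sim <- simulate_structured_population(cfg, 1L)
  gsim <- group_kin_summary(sim, pedigree_kinship_table(sim))
  expect_equal(gsim$population$pct_adult_offspring_in_natal_group, 100)
})

test_that("dispersal summary flags individuals closer to the other site", {
  # two disconnected families in two locations: no defined cross distances
  ped2 <- pedigree(data.frame(
    id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    sex = c("F", "M", "U", "F", "M", "U"),
    mother_id = c(NA, NA, "a1", NA, NA, "b1"),
    father_id = c(NA, NA, "a2", NA, NA, "b2"),
    location_id = rep(c("east", "west"), each = 3),
    stringsAsFactors = FALSE))
  ds <- dispersal_summary(ped2)
  expect_true(all(is.na(ds$individuals$mean_dist_other_location)))
  expect_equal(sum(ds$flagged_sex_counts), 0L)
  # a female sampled away from all her close relatives is flagged:
  # mig (west) is daughter of m (east); her only west companion w2 is a
  # grandchild of m, three genealogical steps away
  ped3 <- pedigree(data.frame(
    id = c("m", "f", "k1", "k2", "mig", "w2"),
    sex = c("F", "M", "F", "U", "F", "U"),
    mother_id = c(NA, NA, "m", "m", "m", "k1"),
    father_id = c(NA, NA, "f", "f", NA, NA),
    location_id = c("east", "east", "east", "east", "west", "west"),
    stringsAsFactors = FALSE))
  ds3 <- dispersal_summary(ped3)
  mig <- ds3$individuals[ds3$individuals$id == "mig", ]
  expect_equal(mig$mean_dist_same_location, 3)  # mig-m-k1-w2
  expect_lt(mig$mean_dist_other_location, 3)
  expect_true(mig$closer_to_other)
  expect_equal(unname(ds3$flagged_sex_counts["F"]), 1L)
  expect_error(dispersal_summary(family_ped()), "two locations")
})
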