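# Genealogy-derived mating-system statistics: offspring/partner counts,
# sibling structure, multiple paternity, repeated parental pairs, close
# inbreeding, skew indices, group kin structure and dispersal summaries.
# All statistics count relationships among sampled individuals only, so
# they respect simulated genotyping subsampling.

sampled_individuals <- function(ped) {
  ped$individuals[ped$individuals$sampled %in% TRUE, , drop = FALSE]
}

#' Offspring and reproductive-partner counts
#'
#' For every individual: the number of (sampled) offspring of any age, the
#' reduced offspring number counting one pup per litter per parent pair (a
#' proxy for the number of successful matings, correcting for litters
#' sampled together), and the number of distinct reproductive partners
#' inferred from shared offspring. Offspring lacking a litter id
#' contribute individually to the reduced count; offspring whose
#' co-parent is unrecorded contribute no partner identity.
#'
#' @param ped a [pedigree()].
#' @return data.frame `id`, `sex`, `n_offspring`, `n_offspring_reduced`,
#'   `n_partners`.
#' @export
offspring_and_partner_counts <- function(ped) {
  ind <- ped$individuals
  off <- sampled_individuals(ped)
  litter_key <- ifelse(is.na(off$litter_id), paste0("solo:", off$id),
                       off$litter_id)
  count_for <- function(parent_col, partner_col) {
    par <- off[[parent_col]]; co <- off[[partner_col]]
    keep <- !is.na(par)
    n_off <- table(par[keep])
    red_key <- paste(par, co, litter_key)[keep]
    n_red <- table(par[keep][!duplicated(red_key)])
    pkey <- keep & !is.na(co)
    n_par <- table(par[pkey][!duplicated(paste(par, co)[pkey])])
    list(off = n_off, red = n_red, partners = n_par)
  }
  mo <- count_for("mother_id", "father_id")
  fa <- count_for("father_id", "mother_id")
  pull <- function(tab, ids) {
    v <- as.integer(tab[ids]); v[is.na(v)] <- 0L; v
  }
  data.frame(
    id = ind$id, sex = ind$sex,
    n_offspring = pull(mo$off, ind$id) + pull(fa$off, ind$id),
    n_offspring_reduced = pull(mo$red, ind$id) + pull(fa$red, ind$id),
    n_partners = pull(mo$partners, ind$id) + pull(fa$partners, ind$id),
    stringsAsFactors = FALSE)
}

#' Sibling counts
#'
#' Per (sampled) individual: full siblings (both recorded parents shared),
#' maternal and paternal half-siblings (exactly the one recorded parent
#' shared). An individual with a single recorded parent is a half-sibling
#' of that parent's other offspring, since its missing parent is treated
#' as a distinct anonymous founder.
#'
#' @param ped a [pedigree()].
#' @return data.frame `id`, `sex`, `n_full_sibs`, `n_mat_half_sibs`,
#'   `n_pat_half_sibs` (rows for sampled individuals).
#' @export
sibling_counts <- function(ped) {
  s <- sampled_individuals(ped)
  both <- !is.na(s$mother_id) & !is.na(s$father_id)
  pair_key <- ifelse(both, paste(s$mother_id, s$father_id), NA)
  n_pair <- table(pair_key[both])
  n_mom <- table(s$mother_id[!is.na(s$mother_id)])
  n_dad <- table(s$father_id[!is.na(s$father_id)])
  at <- function(tab, key) {
    v <- rep(0L, length(key))
    ok <- !is.na(key)
    x <- as.integer(tab[key[ok]]); x[is.na(x)] <- 0L
    v[ok] <- x
    v
  }
  full <- pmax(at(n_pair, pair_key) - 1L, 0L)
  mat <- ifelse(is.na(s$mother_id), 0L, at(n_mom, s$mother_id) - 1L - full)
  pat <- ifelse(is.na(s$father_id), 0L, at(n_dad, s$father_id) - 1L - full)
  data.frame(id = s$id, sex = s$sex, n_full_sibs = full,
             n_mat_half_sibs = as.integer(mat),
             n_pat_half_sibs = as.integer(pat), stringsAsFactors = FALSE)
}

#' Multiple paternity within litters
#'
#' Eligible litters contain at least two sampled offspring; a litter shows
#' multiple paternity when at least two distinct fathers are recorded
#' among its sampled offspring.
#'
#' @param ped a [pedigree()] with litter ids.
#' @return list `n_eligible_litters`, `n_multifather_litters`, `percent`,
#'   and per-litter detail data.frame `litter_id`, `n_sampled_offspring`,
#'   `n_fathers`.
#' @export
multiple_paternity <- function(ped) {
  s <- sampled_individuals(ped)
  s <- s[!is.na(s$litter_id), , drop = FALSE]
  nm <- tapply(s$mother_id, s$litter_id,
               function(x) length(unique(x[!is.na(x)])))
  if (any(!is.na(nm) & nm > 1))
    stop("litter(s) with conflicting mothers: ",
         paste(names(nm)[!is.na(nm) & nm > 1], collapse = ", "))
  n_off <- tapply(s$id, s$litter_id, length)
  n_fa <- tapply(s$father_id, s$litter_id,
                 function(x) length(unique(x[!is.na(x)])))
  detail <- data.frame(litter_id = names(n_off),
                       n_sampled_offspring = as.integer(n_off),
                       n_fathers = as.integer(n_fa[names(n_off)]),
                       stringsAsFactors = FALSE)
  eligible <- detail[detail$n_sampled_offspring >= 2L, , drop = FALSE]
  n_multi <- sum(eligible$n_fathers >= 2L)
  list(n_eligible_litters = nrow(eligible),
       n_multifather_litters = n_multi,
       percent = if (nrow(eligible)) 100 * n_multi / nrow(eligible)
                 else NA_real_,
       litters = detail)
}

#' Repeated parental pairs
#'
#' Groups litters of sampled offspring by (mother, father) and reports
#' pairs that produced two or more litters, together with whether either
#' member also produced offspring with other partners.
#'
#' @param ped a [pedigree()] with litter ids.
#' @return data.frame `mother`, `father`, `n_litters`,
#'   `other_partners` (logical); zero rows when all pairs are unique.
#' @export
repeated_pairs <- function(ped) {
  s <- sampled_individuals(ped)
  s <- s[!is.na(s$mother_id) & !is.na(s$father_id), , drop = FALSE]
  lid <- ifelse(is.na(s$litter_id), paste0("solo:", s$id), s$litter_id)
  key <- paste(s$mother_id, s$father_id)
  tab <- tapply(lid, key, function(x) length(unique(x)))
  pairs <- do.call(rbind, strsplit(names(tab), " "))
  res <- data.frame(mother = pairs[, 1L], father = pairs[, 2L],
                    n_litters = as.integer(tab), stringsAsFactors = FALSE)
  res <- res[res$n_litters >= 2L, , drop = FALSE]
  if (nrow(res)) {
    n_partners_m <- tapply(s$father_id, s$mother_id,
                           function(x) length(unique(x)))
    n_partners_f <- tapply(s$mother_id, s$father_id,
                           function(x) length(unique(x)))
    res$other_partners <- as.integer(n_partners_m[res$mother]) > 1L |
      as.integer(n_partners_f[res$father]) > 1L
  } else res$other_partners <- logical(0)
  rownames(res) <- NULL
  res
}

#' Close inbreeding among realized matings
#'
#' Classifies every realized parent pair with [classify_relationship()];
#' cases are matings between relatives of the first to fourth kinship
#' degree. When the same pair qualifies for several relationship types,
#' the closest degree is retained. The rate denominator is the number of
#' detected matings: distinct (mother, father, litter) triples when litter
#' ids are present, distinct parent pairs otherwise (configurable).
#'
#' @param ped a [pedigree()].
#' @param K optional precomputed [kinship_matrix()].
#' @param unit `"pair_litter"` (default) or `"pair"` mating denominator.
#' @return list with `cases` (data.frame `mother`, `father`, `rel_type`,
#'   `degree`, `kinship_f`, `n_matings`), `n_matings`, `n_case_matings`,
#'   `rate_percent`.
#' @export
close_inbreeding <- function(ped, K = NULL, unit = c("pair_litter", "pair")) {
  unit <- match.arg(unit)
  ind <- ped$individuals
  s <- sampled_individuals(ped)
  ok <- !is.na(s$mother_id) & !is.na(s$father_id) &
    s$mother_id %in% ind$id & s$father_id %in% ind$id
  s <- s[ok, , drop = FALSE]
  if (!nrow(s))
    return(list(cases = data.frame(), n_matings = 0L, n_case_matings = 0L,
                rate_percent = NA_real_))
  if (is.null(K)) K <- kinship_matrix(ped)
  lid <- ifelse(is.na(s$litter_id), paste0("pair:", s$mother_id, ":",
                                           s$father_id), s$litter_id)
  key <- paste(s$mother_id, s$father_id)
  n_mat_per_pair <- if (unit == "pair_litter")
    tapply(lid, key, function(x) length(unique(x)))
  else setNames(rep(1L, length(unique(key))), unique(key))
  upairs <- unique(data.frame(mother = s$mother_id, father = s$father_id,
                              stringsAsFactors = FALSE))
  calls <- lapply(seq_len(nrow(upairs)), function(r) {
    classify_relationship(ped, upairs$mother[r], upairs$father[r], K = K)
  })
  upairs$rel_type <- vapply(calls, `[[`, character(1), "rel_type")
  upairs$degree <- vapply(calls, function(x) as.integer(x$degree),
                          integer(1))
  upairs$kinship_f <- vapply(calls, `[[`, numeric(1), "kinship_f")
  upairs$n_matings <-
    as.integer(n_mat_per_pair[paste(upairs$mother, upairs$father)])
  cases <- upairs[!is.na(upairs$degree), , drop = FALSE]
  rownames(cases) <- NULL
  n_matings <- sum(upairs$n_matings)
  n_case <- sum(cases$n_matings)
  list(cases = cases, n_matings = n_matings, n_case_matings = n_case,
       rate_percent = if (n_matings) 100 * n_case / n_matings else NA_real_)
}

#' Crow's opportunity for selection
#'
#' The squared coefficient of variation in reproductive output,
#' I = var(x) / mean(x)^2, an upper bound on the intensity of selection.
#' Uses the sample-variance (n - 1) convention.
#'
#' @param values non-negative reproductive outputs (n >= 2, mean > 0).
#' @export
crow_index <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  if (m <= 0) stop("Crow's index undefined for zero mean")
  var(values) / m^2
}

#' Morisita index of reproductive skew
#'
#' I_delta = n * sum(x_i * (x_i - 1)) / (X * (X - 1)) with X = sum(x):
#' 0 for perfectly even allocation, n when one of n individuals
#' monopolizes all output.
#'
#' @param counts non-negative integer outputs (n >= 2, sum >= 2).
#' @export
morisita_skew <- function(counts) {
  n <- length(counts)
  if (n < 2L) stop("need at least two individuals")
  X <- sum(counts)
  if (X < 2) stop("Morisita index undefined for total below 2")
  n * sum(counts * (counts - 1)) / (X * (X - 1))
}

#' Pedigree-truth kinship table
#'
#' Builds a pairwise table over sampled individuals from exact pedigree
#' kinship (PI-HAT = 2 f for non-inbred pairs) with a powers-of-two
#' degree call — the pedigree analogue of [kinship_table()], useful when
#' genotypes are simulated or unavailable.
#'
#' @param ped a [pedigree()].
#' @export
pedigree_kinship_table <- function(ped) {
  s <- sampled_individuals(ped)
  K <- kinship_matrix(ped)[s$id, s$id, drop = FALSE]
  pairs <- which(upper.tri(K), arr.ind = TRUE)
  f <- K[pairs]
  data.frame(id1 = s$id[pairs[, 1L]], id2 = s$id[pairs[, 2L]],
             pi_hat = 2 * f, king_phi = f,
             degree_call = classify_degree(f, scale = "kinship"),
             stringsAsFactors = FALSE)
}

#' Kin structure of social groups
#'
#' For every social group with at least `min_members` sampled members:
#' mean pairwise PI-HAT within the group; the percentage of members
#' unrelated (kinship beyond `related_max_degree`, default third degree,
#' matching the convention that fourth-degree-and-below pairs count as
#' unrelated) to every other sampled group member; the percentage of
#' parent pairs involving the group whose two members share a group; and
#' the percentage of adult offspring natal to the group that stayed in it.
#'
#' @param ped a [pedigree()] with group assignments.
#' @param kin pairwise table with columns `id1`, `id2`, `pi_hat`,
#'   `degree_call` ([kinship_table()] or [pedigree_kinship_table()]).
#' @param min_members minimum sampled group size (default 3).
#' @param related_max_degree highest degree still counted as related.
#' @return list `groups` (per-group data.frame) and `population`
#'   (across-group averages); empty with a warning when no group
#'   qualifies.
#' @export
group_kin_summary <- function(ped, kin, min_members = 3L,
                              related_max_degree = 3L) {
  s <- sampled_individuals(ped)
  s <- s[!is.na(s$group_id), , drop = FALSE]
  sizes <- table(s$group_id)
  groups <- names(sizes)[sizes >= min_members]
  if (!length(groups)) {
    warning("no group with at least ", min_members, " sampled members")
    return(list(groups = data.frame(), population = list()))
  }
  grp <- setNames(ped$individuals$group_id, ped$individuals$id)
  kin_key <- paste(pmin(kin$id1, kin$id2), pmax(kin$id1, kin$id2))
  related_calls <- as.character(seq_len(related_max_degree))
  pp <- realized_parent_pairs(ped)
  pp$gm <- unname(grp[pp$mother]); pp$gf <- unname(grp[pp$father])
  pp <- pp[!is.na(pp$gm) & !is.na(pp$gf), , drop = FALSE]
  adults <- ped$individuals[ped$individuals$age_class == "adult" &
                              !is.na(ped$individuals$mother_id), ,
                            drop = FALSE]
  adults$natal <- unname(grp[adults$mother_id])
  adults <- adults[!is.na(adults$natal) & !is.na(adults$group_id), ,
                   drop = FALSE]

  rows <- lapply(groups, function(g) {
    mem <- s$id[s$group_id == g]
    prs <- t(utils::combn(mem, 2L))
    keys <- paste(pmin(prs[, 1L], prs[, 2L]), pmax(prs[, 1L], prs[, 2L]))
    kidx <- match(keys, kin_key)
    mean_pihat <- mean(kin$pi_hat[kidx], na.rm = TRUE)
    rel <- !is.na(kidx) & kin$degree_call[kidx] %in% related_calls
    has_rel <- vapply(mem, function(m)
      any(rel & (prs[, 1L] == m | prs[, 2L] == m)), logical(1))
    gpp <- pp[pp$gm == g | pp$gf == g, , drop = FALSE]
    nat <- adults[adults$natal == g, , drop = FALSE]
    data.frame(
      group_id = g, n_members = length(mem), mean_pihat = mean_pihat,
      pct_unrelated_members = 100 * mean(!has_rel),
      pct_parent_pairs_same_group =
        if (nrow(gpp)) 100 * mean(gpp$gm == gpp$gf) else NA_real_,
      pct_adult_offspring_in_natal_group =
        if (nrow(nat)) 100 * mean(nat$group_id == g) else NA_real_,
      stringsAsFactors = FALSE)
  })
  gdf <- do.call(rbind, rows)
  pop <- list(
    mean_pihat = mean(gdf$mean_pihat, na.rm = TRUE),
    pct_unrelated_members = mean(gdf$pct_unrelated_members, na.rm = TRUE),
    pct_parent_pairs_same_group =
      if (nrow(pp)) 100 * mean(pp$gm == pp$gf) else NA_real_,
    pct_adult_offspring_in_natal_group =
      if (nrow(adults)) 100 * mean(adults$group_id == adults$natal)
      else NA_real_)
  list(groups = gdf, population = pop)
}

#' Genealogical-distance dispersal summary
#'
#' For each sampled individual in a two-location population: the mean
#' genealogical distance ([genealogical_distance()]) to sampled
#' individuals in the same location and in the other location (over
#' connected pairs only), and whether the individual is genealogically
#' closer to the other location — the signature of a disperser. The sex
#' tabulation of flagged individuals is returned for downstream
#' chi-square testing (the test itself is delegated).
#'
#' @param ped a [pedigree()] with exactly two location labels among
#'   sampled individuals.
#' @return list `individuals` (data.frame `id`, `sex`, `location_id`,
#'   `mean_dist_same_location`, `mean_dist_other_location`,
#'   `closer_to_other`) and `flagged_sex_counts` (named counts among
#'   flagged individuals).
#' @export
dispersal_summary <- function(ped) {
  s <- sampled_individuals(ped)
  s <- s[!is.na(s$location_id), , drop = FALSE]
  locs <- unique(s$location_id)
  if (length(locs) != 2L)
    stop("dispersal summary requires exactly two locations, found ",
         length(locs))
  D <- genealogical_distance(ped)[s$id, s$id, drop = FALSE]
  diag(D) <- NA
  same <- outer(s$location_id, s$location_id, "==")
  mean_same <- vapply(seq_len(nrow(s)), function(i)
    mean(D[i, same[i, ] & seq_len(nrow(s)) != i], na.rm = TRUE), numeric(1))
  mean_other <- vapply(seq_len(nrow(s)), function(i)
    mean(D[i, !same[i, ]], na.rm = TRUE), numeric(1))
  mean_same[is.nan(mean_same)] <- NA
  mean_other[is.nan(mean_other)] <- NA
  closer <- ifelse(is.na(mean_same) | is.na(mean_other), NA,
                   mean_other < mean_same)
  out <- data.frame(id = s$id, sex = s$sex, location_id = s$location_id,
                    mean_dist_same_location = mean_same,
                    mean_dist_other_location = mean_other,
                    closer_to_other = closer, stringsAsFactors = FALSE)
  flagged <- out$sex[!is.na(out$closer_to_other) & out$closer_to_other]
  list(individuals = out,
       flagged_sex_counts = c(F = sum(flagged == "F"),
                              M = sum(flagged == "M"),
                              U = sum(flagged == "U")))
}
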