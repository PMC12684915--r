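#' @importFrom stats rbinom rgamma rlnorm rmultinom rpois runif sd setNames
#'   quantile var
#' @importFrom utils head read.table write.table
NULL

GENEALOGY_COLUMNS <- c("id", "sex", "age_class", "mother_id", "father_id",
                       "litter_id", "group_id", "location_id", "sampled")

#' Construct a pedigree
#'
#' A pedigree is the central data structure of the package: a table of
#' individuals with sex, age class, social group and sampling-location
#' attributes, linked by mother/father edges and grouped into litters.
#' Parent links must form a directed acyclic graph (no individual is its
#' own ancestor); mothers must not be recorded as male and fathers must
#' not be recorded as female; all offspring sharing a litter id must share
#' the litter's mother.
#'
#' @param individuals data.frame with columns `id`, `sex` (one of
#'   `"F"`, `"M"`, `"U"`), `age_class` (`"pup"`, `"subadult"`, `"adult"`,
#'   `"unknown"`), `mother_id`, `father_id`, `litter_id`, `group_id`,
#'   `location_id` (each `NA` when absent) and logical `sampled`.
#'   Missing attribute columns are added with `NA` / `TRUE` defaults.
#' @param validate check structural invariants (default `TRUE`).
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(individuals, validate = TRUE) {
  stopifnot(is.data.frame(individuals), "id" %in% names(individuals))
  ind <- as.data.frame(individuals, stringsAsFactors = FALSE)
  ind$id <- as.character(ind$id)
  defaults <- list(sex = "U", age_class = "unknown", mother_id = NA_character_,
                   father_id = NA_character_, litter_id = NA_character_,
                   group_id = NA_character_, location_id = NA_character_,
                   sampled = TRUE)
  for (col in names(defaults)) {
    if (!col %in% names(ind)) ind[[col]] <- defaults[[col]]
  }
  for (col in c("sex", "age_class", "mother_id", "father_id", "litter_id",
                "group_id", "location_id")) {
    ind[[col]] <- as.character(ind[[col]])
    ind[[col]][!is.na(ind[[col]]) & ind[[col]] == ""] <- NA_character_
  }
  ind$sampled <- as.logical(ind$sampled)
  ind <- ind[, GENEALOGY_COLUMNS]
  rownames(ind) <- NULL
  ped <- structure(list(individuals = ind), class = "pedigree")
  if (validate) validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  ind <- ped$individuals
  if (anyDuplicated(ind$id))
    stop("duplicate individual id(s): ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  if (!all(ind$sex %in% c("F", "M", "U")))
    stop("sex must be one of F, M, U")
  sex <- setNames(ind$sex, ind$id)
  m <- ind$mother_id[!is.na(ind$mother_id) & ind$mother_id %in% ind$id]
  if (any(sex[m] == "M")) stop("mother link points to a male individual")
  f <- ind$father_id[!is.na(ind$father_id) & ind$father_id %in% ind$id]
  if (any(sex[f] == "F")) stop("father link points to a female individual")
  lit <- ind[!is.na(ind$litter_id), , drop = FALSE]
  if (nrow(lit)) {
    nm <- tapply(lit$mother_id, lit$litter_id,
                 function(x) length(unique(x[!is.na(x)])))
    bad <- names(nm)[!is.na(nm) & nm > 1]
    if (length(bad))
      stop("litter(s) with conflicting mothers: ", paste(bad, collapse = ", "))
  }
  ped_topo_order(ped)  # errors on cycles
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  ind <- x$individuals
  cat(sprintf("<pedigree> %d individuals (%d F / %d M / %d U), %d litters\n",
              nrow(ind), sum(ind$sex == "F"), sum(ind$sex == "M"),
              sum(ind$sex == "U"),
              length(unique(ind$litter_id[!is.na(ind$litter_id)]))))
  invisible(x)
}

ped_index <- function(ped, ids) {
  idx <- match(ids, ped$individuals$id)
  if (anyNA(idx))
    stop("unknown individual id(s): ",
         paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# parent indices (NA when absent or referring to an id not in the table)
ped_parent_idx <- function(ped) {
  ind <- ped$individuals
  list(mother = match(ind$mother_id, ind$id),
       father = match(ind$father_id, ind$id))
}

# topological order (founders first); errors if parent links are cyclic
ped_topo_order <- function(ped) {
  par <- ped_parent_idx(ped)
  n <- nrow(ped$individuals)
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(par$mother[i], par$father[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != n)
    stop("pedigree parent links contain a cycle")
  order
}

#' Pedigree kinship matrix (tabular method)
#'
#' Computes Wright's kinship coefficient f for every pair of individuals by
#' the tabular (recurrence) method: processing individuals parents-first,
#' f(i, j) = (f(mother_i, j) + f(father_i, j)) / 2 for j not descended from
#' i, and f(i, i) = (1 + f(mother_i, father_i)) / 2, i.e. 0.5 * (1 + F_i)
#' where F_i is i's inbreeding coefficient. Missing parents contribute 0
#' (treated as unique unrelated founders).
#'
#' @param ped a [pedigree()].
#' @return symmetric numeric matrix with dimnames = individual ids.
#' @export
kinship_matrix <- function(ped) {
  ind <- ped$individuals
  n <- nrow(ind)
  ord <- ped_topo_order(ped)
  par <- ped_parent_idx(ped)
  K <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  pos <- integer(n)  # processing rank of each index
  pos[ord] <- seq_len(n)
  for (r in seq_len(n)) {
    i <- ord[r]
    m <- par$mother[i]; f <- par$father[i]
    if (r > 1L) {
      prev <- ord[seq_len(r - 1L)]
      km <- if (is.na(m)) 0 else K[m, prev]
      kf <- if (is.na(f)) 0 else K[f, prev]
      K[i, prev] <- 0.5 * (km + kf)
      K[prev, i] <- K[i, prev]
    }
    kmf <- if (is.na(m) || is.na(f)) 0 else K[m, f]
    K[i, i] <- 0.5 * (1 + kmf)
  }
  K
}

#' Pairwise pedigree kinship coefficient
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids.
#' @return kinship coefficient f in [0, 0.5] for non-inbred individuals;
#'   f(i, i) = 0.5 * (1 + F_i) may exceed 0.5 under inbreeding.
#' @seealso [kinship_matrix()] for all pairs at once.
#' @export
pedigree_kinship <- function(ped, i, j) {
  ped_index(ped, c(i, j))
  K <- kinship_matrix(ped)
  unname(K[i, j])
}

REL_TYPES <- data.frame(
  rel_type = c("parent-offspring", "full-sibling", "half-sibling",
               "grandparent-grandchild", "avuncular", "half-avuncular",
               "full-first-cousin", "great-grandparent", "half-first-cousin"),
  degree = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L),
  stringsAsFactors = FALSE
)

rec_parents <- function(ind, id) {
  r <- ind[match(id, ind$id), c("mother_id", "father_id")]
  p <- c(r$mother_id, r$father_id)
  p[!is.na(p) & p %in% ind$id]
}

# sibling relation on recorded parents: 2 = full, 1 = half, 0 = none
shared_parent_count <- function(ind, a, b) {
  ra <- ind[match(a, ind$id), ]; rb <- ind[match(b, ind$id), ]
  same_m <- !is.na(ra$mother_id) && !is.na(rb$mother_id) &&
    ra$mother_id == rb$mother_id
  same_f <- !is.na(ra$father_id) && !is.na(rb$father_id) &&
    ra$father_id == rb$father_id
  sum(same_m, same_f)
}

#' Classify the pedigree relationship of a pair
#'
#' Pattern-matches pedigree paths up to great-grandparent depth onto the
#' close-kin taxonomy used for inbreeding screening: parent-offspring and
#' full siblings (degree 1); half siblings, grandparent-grandchild and
#' avuncular (degree 2); half-avuncular, full first cousins and
#' great-grandparent (degree 3); half first cousins (degree 4). When a pair
#' qualifies for several types, the closest (numerically lowest degree) is
#' returned; within a degree the priority follows the order above. Pairs
#' with no qualifying path but positive pedigree kinship are `distant`;
#' pairs with zero kinship are `unrelated` (degree absent in both cases).
#'
#' @param ped a [pedigree()].
#' @param i,j distinct individual ids.
#' @param K optional precomputed [kinship_matrix()] (recomputed otherwise).
#' @return list with elements `pair`, `rel_type`, `degree` (NA for
#'   distant/unrelated) and `kinship_f`.
#' @export
classify_relationship <- function(ped, i, j, K = NULL) {
  ped_index(ped, c(i, j))
  if (i == j) stop("i and j must be distinct individuals")
  ind <- ped$individuals
  if (is.null(K)) K <- kinship_matrix(ped)
  f <- unname(K[i, j])

  pi <- rec_parents(ind, i); pj <- rec_parents(ind, j)
  gi <- unlist(lapply(pi, rec_parents, ind = ind))
  gj <- unlist(lapply(pj, rec_parents, ind = ind))
  ggi <- unlist(lapply(gi, rec_parents, ind = ind))
  ggj <- unlist(lapply(gj, rec_parents, ind = ind))

  sib <- shared_parent_count(ind, i, j)
  # sibling relation between a and each member of ids, max over members
  max_sib_with <- function(a, ids) {
    if (!length(ids)) return(0L)
    max(vapply(ids, function(b) shared_parent_count(ind, a, b), integer(1)))
  }
  # best sibship between any parent of one and the other individual
  avunc <- max(c(0L, max_sib_with(i, pj[pj != i]),
                 vapply(pi[pi != j], max_sib_with, integer(1), ids = j)))
  # sibship between parents of i and parents of j (cousin link)
  cousin <- 0L
  for (a in pi) cousin <- max(cousin, max_sib_with(a, pj[pj != a]))

  type <-
    if (j %in% pi || i %in% pj) "parent-offspring"
    else if (sib == 2L) "full-sibling"
    else if (sib == 1L) "half-sibling"
    else if (j %in% gi || i %in% gj) "grandparent-grandchild"
    else if (avunc == 2L) "avuncular"
    else if (avunc == 1L) "half-avuncular"
    else if (cousin == 2L) "full-first-cousin"
    else if (j %in% ggi || i %in% ggj) "great-grandparent"
    else if (cousin == 1L) "half-first-cousin"
    else if (f > 0) "distant"
    else "unrelated"

  degree <- REL_TYPES$degree[match(type, REL_TYPES$rel_type)]
  list(pair = c(i, j), rel_type = type,
       degree = if (length(degree) && !is.na(degree)) degree else NA_integer_,
       kinship_f = f)
}

#' Genealogical distance
#'
#' Number of steps connecting two individuals in the genealogy: the
#' shortest-path length in the undirected graph whose edges are
#' parent-offspring links. Full siblings are two steps apart (via a shared
#' parent); sibling links are not edges. `NA` when the individuals lie in
#' disconnected components.
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids (omit both to get the full matrix).
#' @return integer distance (or `NA`), or the full distance matrix when
#'   `i` and `j` are missing.
#' @export
genealogical_distance <- function(ped, i = NULL, j = NULL) {
  g <- pedigree_graph(ped)
  D <- igraph::distances(g)
  D[is.infinite(D)] <- NA_real_
  if (is.null(i) && is.null(j)) return(D)
  ped_index(ped, c(i, j))
  unname(D[i, j])
}

# undirected parent-offspring graph over all individuals
pedigree_graph <- function(ped) {
  ind <- ped$individuals
  edges <- rbind(
    cbind(ind$id, ind$mother_id)[!is.na(ind$mother_id) &
                                   ind$mother_id %in% ind$id, , drop = FALSE],
    cbind(ind$id, ind$father_id)[!is.na(ind$father_id) &
                                   ind$father_id %in% ind$id, , drop = FALSE])
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(ind), name = ind$id)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  g
}
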