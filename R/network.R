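# Weighted proximity networks: construction from dyadic interaction
# counts, the five individual network measures, greedy-modularity
# community detection, and multi-season group assignment.

#' Build a weighted proximity network
#'
#' Aggregates dyadic interaction counts (observations of two individuals
#' within close proximity) into an undirected weighted graph, optionally
#' restricted to selected seasons and to dyads of a given sex composition
#' (male-male, male-female, female-female).
#'
#' @param interactions data.frame `id_a`, `id_b`, `season`, `count`
#'   (unordered pair unique per season, `id_a != id_b`, counts >= 1).
#' @param seasons character vector of seasons to keep (`NULL` = all).
#' @param stratum `"all"`, `"MM"`, `"MF"` or `"FF"`.
#' @param sexes named character vector id -> sex, required when
#'   `stratum != "all"`; also attached as a node attribute when given.
#' @return object of class `social_network` wrapping an igraph graph with
#'   edge attribute `weight`.
#' @export
build_network <- function(interactions, seasons = NULL, stratum = "all",
                          sexes = NULL) {
  stopifnot(all(c("id_a", "id_b", "season", "count") %in%
                  names(interactions)))
  if (!stratum %in% c("all", "MM", "MF", "FF"))
    stop("unknown stratum '", stratum, "'")
  x <- interactions
  if (any(x$id_a == x$id_b)) stop("self-interaction rows are not allowed")
  if (!is.null(seasons)) x <- x[x$season %in% seasons, , drop = FALSE]
  if (stratum != "all") {
    if (is.null(sexes)) stop("stratum filtering requires a sexes vector")
    sa <- unname(sexes[x$id_a]); sb <- unname(sexes[x$id_b])
    pair <- paste0(pmin(sa, sb), pmax(sa, sb))
    want <- c(MM = "MM", MF = "FM", FF = "FF")[[stratum]]
    x <- x[!is.na(pair) & pair == want, , drop = FALSE]
  }
  a <- pmin(x$id_a, x$id_b); b <- pmax(x$id_a, x$id_b)
  w <- tapply(x$count, paste(a, b, sep = "\r"), sum)
  ids <- sort(unique(c(a, b)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (length(w)) {
    ends <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    g <- igraph::add_edges(g, t(ends), weight = as.numeric(w))
  }
  if (!is.null(sexes) && length(ids))
    igraph::V(g)$sex <- unname(sexes[ids])
  structure(list(graph = g, stratum = stratum,
                 seasons = if (is.null(seasons)) unique(interactions$season)
                           else seasons),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network> %d nodes, %d edges (stratum %s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$stratum))
  invisible(x)
}

#' Individual network measures
#'
#' The five measures used to relate sociality to reproductive success:
#' degree centrality (number of direct interaction partners), strength
#' (sum of all interaction counts), strongest link (interaction count
#' with the most frequent partner), eigenvector centrality (weighted
#' principal eigenvector, computed per connected component and scaled to
#' a maximum of 1; isolated nodes score 0), and betweenness (weighted
#' shortest-path betweenness with edge length 1/weight, endpoints
#' excluded, unnormalized). Z-scored variants are computed over all nodes
#' of the network.
#'
#' @param net a [build_network()] result.
#' @return data.frame per node: raw measures plus `*_z` columns.
#' @export
node_measures <- function(net) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty network")
  w <- igraph::E(g)$weight
  deg <- igraph::degree(g)
  strength <- igraph::strength(g, weights = w)
  strongest <- vapply(seq_len(n), function(v) {
    iw <- igraph::incident(g, v)$weight
    if (length(iw)) max(iw) else 0
  }, numeric(1))
  btw <- igraph::betweenness(g, weights = 1 / w, normalized = FALSE)
  eig <- rep(0, n)
  comp <- igraph::components(g)
  for (k in seq_len(comp$no)) {
    vs <- which(comp$membership == k)
    if (length(vs) < 2L) next
    sub <- igraph::induced_subgraph(g, vs)
    ev <- igraph::eigen_centrality(
      sub, weights = igraph::E(sub)$weight)$vector
    eig[vs] <- ev
  }
  z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else rep(0, length(x))
  data.frame(
    id = igraph::V(g)$name,
    degree_centrality = as.integer(deg), strength = strength,
    strongest_link = strongest, eigen_centrality = eig, betweenness = btw,
    degree_centrality_z = z(deg), strength_z = z(strength),
    strongest_link_z = z(strongest), eigen_centrality_z = z(eig),
    betweenness_z = z(btw),
    stratum = net$stratum, stringsAsFactors = FALSE, row.names = NULL)
}

#' Greedy-modularity community detection
#'
#' Hierarchical agglomerative modularity maximization (fast-greedy) on
#' the weighted graph; deterministic for a given graph. When several cuts
#' of the dendrogram share the maximal modularity (within 1e-12) the
#' coarsest partition (fewest communities) is returned, so e.g. a single
#' connected edge forms one community.
#'
#' @param net a [build_network()] result.
#' @return list `membership` (named integer vector) and `modularity` of
#'   the returned partition.
#' @export
detect_communities <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0L) stop("empty network")
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  mods <- cl$modularity
  n_com <- igraph::vcount(g) - (seq_along(mods) - 1L)
  pick <- which(mods >= max(mods) - 1e-12)
  mem <- igraph::cut_at(cl, no = n_com[pick[length(pick)]])
  list(membership = setNames(as.integer(mem), igraph::V(g)$name),
       modularity = igraph::modularity(g, mem,
                                       weights = igraph::E(g)$weight))
}

#' Assign individuals to social groups across seasons
#'
#' Given one community partition per season, per-season communities are
#' first matched into consensus clusters by greedy Jaccard overlap with
#' the first season's communities. Each individual is then assigned to
#' the consensus cluster into which its summed interaction weight (over
#' all seasons) is largest; exact ties leave the individual unassigned
#' (`NA`). With a single season this reduces to assigning each individual
#' to the community it interacts most with.
#'
#' @param partitions named list season -> membership vector (named by
#'   individual id), e.g. from [detect_communities()].
#' @param interactions interaction table covering those seasons.
#' @return data.frame `id`, `group` (consensus cluster label or `NA`).
#' @export
assign_groups <- function(partitions, interactions) {
  stopifnot(length(partitions) >= 1L)
  seasons <- names(partitions)
  if (is.null(seasons)) stop("partitions must be a named list (by season)")
  # consensus cluster ids, seeded by the first season's communities
  ref <- split(names(partitions[[1L]]), partitions[[1L]])
  cons_members <- ref
  names(cons_members) <- sprintf("C%02d", seq_along(cons_members))
  season_map <- list()
  season_map[[seasons[1L]]] <-
    setNames(names(cons_members), names(ref))
  for (s in seasons[-1L]) {
    cl <- split(names(partitions[[s]]), partitions[[s]])
    m <- character(length(cl)); names(m) <- names(cl)
    for (ci in names(cl)) {
      jac <- vapply(cons_members, function(mem) {
        u <- length(union(mem, cl[[ci]]))
        if (u == 0) 0 else length(intersect(mem, cl[[ci]])) / u
      }, numeric(1))
      if (length(jac) && max(jac) > 0) {
        best <- names(jac)[which.max(jac)]
      } else {
        best <- sprintf("C%02d", length(cons_members) + 1L)
        cons_members[[best]] <- character(0)
      }
      cons_members[[best]] <- union(cons_members[[best]], cl[[ci]])
      m[ci] <- best
    }
    season_map[[s]] <- m
  }
  ids <- sort(unique(c(interactions$id_a, interactions$id_b,
                       unlist(lapply(partitions, names)))))
  wt <- matrix(0, length(ids), length(cons_members),
               dimnames = list(ids, names(cons_members)))
  x <- interactions[interactions$season %in% seasons, , drop = FALSE]
  for (r in seq_len(nrow(x))) {
    s <- x$season[r]
    mem <- partitions[[s]]
    map <- season_map[[s]]
    cb <- map[as.character(mem[x$id_b[r]])]
    ca <- map[as.character(mem[x$id_a[r]])]
    if (!is.na(cb)) wt[x$id_a[r], cb] <- wt[x$id_a[r], cb] + x$count[r]
    if (!is.na(ca)) wt[x$id_b[r], ca] <- wt[x$id_b[r], ca] + x$count[r]
  }
  group <- apply(wt, 1L, function(v) {
    if (all(v == 0)) return(NA_character_)
    top <- which(v == max(v))
    if (length(top) > 1L) NA_character_ else colnames(wt)[top]
  })
  data.frame(id = ids, group = unname(group), stringsAsFactors = FALSE)
}
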