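# Independent brute-force oracles and small random-instance generators.
# These deliberately avoid the package's own code paths (and igraph where
# the package relies on it) so that agreement is informative.

# random mating pedigree built directly from data.frame plumbing
rand_pedigree <- function(n_founders = 10L, n_gen = 3L, n_per_gen = 10L,
                          seed = 1L) {
  set.seed(seed)
  ids <- sprintf("f%02d", seq_len(n_founders))
  sex <- sample(rep(c("F", "M"), length.out = n_founders))
  df <- data.frame(id = ids, sex = sex, mother_id = NA_character_,
                   father_id = NA_character_, litter_id = NA_character_,
                   stringsAsFactors = FALSE)
  for (g in seq_len(n_gen - 1L)) {
    fem <- df$id[df$sex == "F"]; mal <- df$id[df$sex == "M"]
    kid <- data.frame(
      id = sprintf("g%d_%02d", g, seq_len(n_per_gen)),
      sex = sample(c("F", "M"), n_per_gen, replace = TRUE),
      mother_id = sample(fem, n_per_gen, replace = TRUE),
      father_id = sample(mal, n_per_gen, replace = TRUE),
      litter_id = NA_character_, stringsAsFactors = FALSE)
    df <- rbind(df, kid)
  }
  pedigree(df)
}

# recursive-definition kinship oracle: f(i,j) = (f(mother_i,j)+f(father_i,j))/2
# recursing on whichever argument is deeper in the pedigree
oracle_kinship <- function(ped) {
  ind <- ped$individuals
  n <- nrow(ind)
  mo <- match(ind$mother_id, ind$id); fa <- match(ind$father_id, ind$id)
  depth <- rep(0L, n)
  repeat {
    d2 <- pmax(ifelse(is.na(mo), 0L, depth[mo] + 1L),
               ifelse(is.na(fa), 0L, depth[fa] + 1L))
    if (all(d2 == depth)) break
    depth <- d2
  }
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + f(mo[i], fa[i]))
    } else {
      if (depth[i] < depth[j]) { t <- i; i <- j; j <- t }
      if (depth[i] == 0L) 0 else 0.5 * (f(mo[i], j) + f(fa[i], j))
    }
    memo[[key]] <- val
    val
  }
  K <- matrix(0, n, n, dimnames = list(ind$id, ind$id))
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  K
}

# common-ancestor enumerator: classifies a pair from exact-depth shared
# ancestor sets, in the fixed degree/priority order
oracle_classify <- function(ped, i, j, KO = NULL) {
  ind <- ped$individuals
  anc_at <- function(id, d) {
    cur <- id
    for (k in seq_len(d)) {
      r <- ind[match(cur, ind$id), c("mother_id", "father_id")]
      cur <- unique(unlist(r, use.names = FALSE))
      cur <- cur[!is.na(cur) & cur %in% ind$id]
      if (!length(cur)) return(character(0))
    }
    cur
  }
  parents <- function(id) anc_at(id, 1L)
  shared1 <- function(a, b) length(intersect(parents(a), parents(b)))
  sib_with_parent <- function(x, y) {
    # best sibship between x and any parent of y
    ps <- setdiff(parents(y), x)
    if (!length(ps)) return(0L)
    max(vapply(ps, function(p) shared1(x, p), integer(1)))
  }
  cousin_link <- function() {
    best <- 0L
    for (a in parents(i)) for (b in setdiff(parents(j), a))
      best <- max(best, shared1(a, b))
    best
  }
  if (j %in% parents(i) || i %in% parents(j)) return("parent-offspring")
  s <- shared1(i, j)
  if (s == 2L) return("full-sibling")
  if (s == 1L) return("half-sibling")
  if (j %in% anc_at(i, 2L) || i %in% anc_at(j, 2L))
    return("grandparent-grandchild")
  av <- max(sib_with_parent(i, j), sib_with_parent(j, i))
  if (av == 2L) return("avuncular")
  if (av == 1L) return("half-avuncular")
  cz <- cousin_link()
  if (cz == 2L) return("full-first-cousin")
  if (j %in% anc_at(i, 3L) || i %in% anc_at(j, 3L))
    return("great-grandparent")
  if (cz == 1L) return("half-first-cousin")
  if (is.null(KO)) KO <- oracle_kinship(ped)
  if (KO[i, j] > 0) "distant" else "unrelated"
}

brute_crow <- function(x) sum((x - mean(x))^2) / (length(x) - 1) / mean(x)^2

brute_morisita <- function(x)
  length(x) * sum(x * (x - 1)) / (sum(x) * (sum(x) - 1))

brute_quantile <- function(obs, sims) {
  r <- sort(sims)
  lo <- sum(r < obs); ties <- sum(r == obs)
  R <- length(r)
  min(max((lo + 0.5 * ties + 1) / (R + 1), 1 / (R + 1)), R / (R + 1))
}

# -- network oracles (matrix based, no igraph) --------------------------

# edges: data.frame id_a, id_b, weight over node set `ids`
brute_adjacency <- function(edges, ids) {
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    A[edges$id_a[r], edges$id_b[r]] <- edges$weight[r]
    A[edges$id_b[r], edges$id_a[r]] <- edges$weight[r]
  }
  A
}

brute_eigen_centrality <- function(A) {
  n <- nrow(A)
  # connected components by reachability
  R <- (A > 0) | diag(TRUE, n)
  for (k in seq_len(n)) R <- R | (R %*% R > 0)
  seen <- rep(FALSE, n)
  out <- numeric(n)
  for (v in seq_len(n)) {
    if (seen[v]) next
    comp <- which(R[v, ])
    seen[comp] <- TRUE
    if (length(comp) >= 2L) {
      e <- eigen(A[comp, comp, drop = FALSE], symmetric = TRUE)
      vec <- abs(e$vectors[, which.max(e$values)])
      out[comp] <- vec / max(vec)
    }
  }
  out
}

brute_betweenness <- function(A, tol = 1e-10) {
  n <- nrow(A)
  L <- ifelse(A > 0, 1 / A, Inf)
  diag(L) <- 0
  D <- L
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  # shortest-path counts from each source by increasing distance
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || is.infinite(D[s, v])) next
      preds <- which(A[, v] > 0 &
                       abs(D[s, ] + L[, v] - D[s, v]) < tol)
      sigma[s, v] <- sum(sigma[s, preds])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
      if (s == v || t == v || is.infinite(D[s, t])) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) < tol)
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- tot
  }
  btw
}

rand_edges <- function(n_nodes, p = 0.35, max_w = 5L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2L))
  keep <- runif(nrow(pairs)) < p
  data.frame(id_a = pairs[keep, 1L], id_b = pairs[keep, 2L],
             weight = sample.int(max_w, sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}

edges_to_interactions <- function(edges, season = "s1") {
  data.frame(id_a = edges$id_a, id_b = edges$id_b, season = season,
             count = edges$weight, stringsAsFactors = FALSE)
}
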