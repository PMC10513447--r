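# Independent brute-force oracles used to check the package implementations.
# These deliberately avoid the code paths under test.

# Patristic distance by explicit path walking: distance(i,j) =
# depth(i) + depth(j) - 2 * depth(common ancestor on the root paths).
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  elen <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  root <- ntip + 1L
  path_to_root <- function(v) {
    p <- v
    while (v != root) { v <- parent[v]; p <- c(p, v) }
    p
  }
  depth <- function(v) {
    d <- 0
    while (v != root) { d <- d + elen[v]; v <- parent[v] }
    d
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i == j) next
    anc <- intersect(path_to_root(i), path_to_root(j))[1]
    d[i, j] <- depth(i) + depth(j) - 2 * depth(anc)
  }
  d
}

# MPD/MNTD by direct loops over pairs / nearest neighbors.
oracle_mpd <- function(d, abund = NULL) {
  k <- nrow(d)
  if (is.null(abund)) abund <- rep(1, k)
  num <- 0; den <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    num <- num + abund[i] * abund[j] * d[i, j]
    den <- den + abund[i] * abund[j]
  }
  num / den
}

oracle_mntd <- function(d, abund = NULL) {
  k <- nrow(d)
  if (is.null(abund)) abund <- rep(1, k)
  nn <- numeric(k)
  for (i in seq_len(k)) nn[i] <- min(d[i, -i])
  sum(abund * nn) / sum(abund)
}

# Holm step-down adjustment straight from the definition.
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, min(1, (m - i + 1) * p[ord[i]]))
    adj[ord[i]] <- running
  }
  adj
}

# Haversine written out independently (R = 6371 km).
oracle_haversine <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) *
    sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(a))
}

toy_tree <- function() read_tree_newick("((A:1,B:1):1,(C:1,D:1):1);")

# Greedy maximin (farthest-point) tip selection: a maximally dispersed set.
maximin_tips <- function(d, k, start) {
  sel <- start
  while (length(sel) < k) {
    rest <- setdiff(seq_len(nrow(d)), sel)
    mind <- vapply(rest, function(i) min(d[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])
  }
  rownames(d)[sel]
}
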