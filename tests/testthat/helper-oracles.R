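# Fixtures and independent brute-force oracles. The oracles deliberately
# take different computational routes than the package (ancestor walks and
# edge-set enumeration instead of cophenetic matrices and path caches) so
# agreement is a genuine cross-check.

t4 <- function() read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")

t4_table <- function() {
  load_taxon_table(data.frame(
    species = c("A", "B", "C", "D"),
    genus = c("G1", "G1", "G2", "G2"),
    family = c("FamX", "FamX", "FamY", "FamY"),
    element = c("TA", "TA", "NT", "NT"),
    r1 = c(1L, 1L, 0L, 0L), r2 = c(0L, 1L, 1L, 1L),
    stringsAsFactors = FALSE))
}

# chain phylogeny: one tip under k stacked single-child internal nodes,
# root labelled "r" (ape's Newick reader mangles singleton chains, so these
# are built directly)
chain_tree <- function(k) {
  n <- k + 1L
  structure(list(edge = cbind(2:(n + 1L), c(if (n > 1L) 3:(n + 1L), 1L)),
                 Nnode = n, tip.label = "t",
                 node.label = c("r", if (k) paste0("u", seq_len(k)))),
            class = "phylo")
}

# per-tip ancestor walks: (nodes on root path, cumulative distances)
.anc_walks <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(nn); elen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    nodes <- tip; dist <- 0
    v <- tip
    while (parent[v] != 0L) {
      dist <- c(dist, dist[length(dist)] + elen[v])
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    list(nodes = nodes, dist = dist)
  })
}

oracle_patristic <- function(tree) {
  walks <- .anc_walks(tree)
  n <- ape::Ntip(tree)
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    wi <- walks[[i]]; wj <- walks[[j]]
    k <- match(wi$nodes, wj$nodes)
    hit <- which(!is.na(k))[1L]  # first common ancestor on i's walk
    d[i, j] <- wi$dist[hit] + wj$dist[k[hit]]
  }
  d
}

oracle_mpd <- function(community, dm) {
  community <- unique(community)
  s <- 0; n <- 0
  for (i in seq_along(community)) for (j in seq_along(community)) {
    if (i < j) { s <- s + dm[community[i], community[j]]; n <- n + 1 }
  }
  s / n
}

oracle_mntd <- function(community, dm) {
  community <- unique(community)
  mean(vapply(community, function(a) {
    min(vapply(setdiff(community, a), function(b) dm[a, b], 0))
  }, 0))
}

oracle_dnn <- function(dm, ca, cb) {
  dir_mean <- function(x, y)
    mean(vapply(x, function(a) min(vapply(y, function(b) dm[a, b], 0)), 0))
  (dir_mean(ca, cb) + dir_mean(cb, ca)) / 2
}

# tip sets below each edge (by the edge's child node)
.edge_tipsets <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], below))
  }
  lapply(tree$edge[, 2], below)
}

# root-inclusive PD by edge enumeration: an edge belongs to the spanning
# subtree iff at least one community member descends from it
oracle_pd <- function(tree, tips) {
  sets <- .edge_tipsets(tree)
  keep <- vapply(sets, function(s) any(tips %in% s), TRUE)
  sum(tree$edge.length[keep])
}

oracle_phylosor <- function(tree, ca, cb) {
  sets <- .edge_tipsets(tree)
  ina <- vapply(sets, function(s) any(ca %in% s), TRUE)
  inb <- vapply(sets, function(s) any(cb %in% s), TRUE)
  shared <- sum(tree$edge.length[ina & inb])
  shared / (0.5 * (sum(tree$edge.length[ina]) + sum(tree$edge.length[inb])))
}

# all non-empty subsets of a vector (for exhaustive small-tree checks)
all_subsets <- function(x) {
  unlist(lapply(seq_along(x), function(k)
    utils::combn(x, k, simplify = FALSE)), recursive = FALSE)
}

random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- round(tr$edge.length, 6) + 0.01
    tr
  })
}
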