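# Between-flora phylogenetic beta diversity: PhyloSor similarity and
# nearest-neighbour distance (Dnn) with a tip-shuffle standardized effect
# size.

# Edge indices on the path from each tip to the root, computed once per tree.
.tip_edge_paths <- function(tree) {
  parent_edge <- integer(ape::Ntip(tree) + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ape::Ntip(tree) + 1L
  lapply(seq_len(ape::Ntip(tree)), function(tip) {
    path <- integer()
    v <- tip
    while (v != root) {
      e <- parent_edge[v]
      path <- c(path, e)
      v <- tree$edge[e, 1]
    }
    path
  })
}

#' Rooted phylogenetic diversity of a tip set
#'
#' Sum of branch lengths of the subtree spanning the tips *and the root*
#' (root-inclusive convention, as in the Phylomatic lineage); for a single
#' tip this is its path length to the root.
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param tips Non-empty character vector of tip labels.
#' @return Numeric scalar (Myr).
#' @export
rooted_pd <- function(tree, tips) {
  sum(tree$edge.length[.spanning_edges(tree, tips)])
}

.spanning_edges <- function(tree, tips, paths = NULL) {
  if (!length(tips)) stop("tip set must be non-empty")
  w <- match(unique(tips), tree$tip.label)
  if (anyNA(w))
    stop("tips missing from the tree: ",
         paste(setdiff(tips, tree$tip.label), collapse = ", "))
  paths <- paths %||% .tip_edge_paths(tree)
  unique(unlist(paths[w]))
}

#' PhyloSor phylogenetic similarity between two communities
#'
#' The ratio of branch length shared by the two communities' rooted
#' spanning subtrees to the mean of their total spanning branch lengths:
#' `BL_shared / (0.5 * (BL_A + BL_B))`. Ranges from 0 (no shared edges) to
#' 1 (identical branch sets).
#'
#' @param tree A `"phylo"` with branch lengths.
#' @param comm_a,comm_b Non-empty character vectors of tip labels.
#' @return Numeric scalar in `[0, 1]`.
#' @export
phylosor <- function(tree, comm_a, comm_b) {
  paths <- .tip_edge_paths(tree)
  ea <- .spanning_edges(tree, comm_a, paths)
  eb <- .spanning_edges(tree, comm_b, paths)
  shared <- sum(tree$edge.length[intersect(ea, eb)])
  shared / (0.5 * (sum(tree$edge.length[ea]) + sum(tree$edge.length[eb])))
}

#' Nearest-neighbour phylogenetic distance between two communities
#'
#' For each taxon of one community, the patristic distance to its closest
#' relative in the other; by default the two directional means are averaged
#' (`direction = "mean"`). Taxa shared by both communities contribute zero.
#'
#' @param dm Patristic distance matrix.
#' @param comm_a,comm_b Non-empty character vectors of taxon names.
#' @param direction `"mean"` (symmetrized), `"ab"` (A into B) or `"ba"`.
#' @return Numeric scalar (Myr).
#' @export
dnn <- function(dm, comm_a, comm_b, direction = c("mean", "ab", "ba")) {
  direction <- match.arg(direction)
  ia <- .comm_idx(comm_a, dm); ib <- .comm_idx(comm_b, dm)
  ab <- mean(apply(dm[ia, ib, drop = FALSE], 1L, min))
  ba <- mean(apply(dm[ib, ia, drop = FALSE], 1L, min))
  switch(direction, mean = (ab + ba) / 2, ab = ab, ba = ba)
}

#' PhyloSor and S.E.S. Dnn for every pair of regions
#'
#' For each region pair: PhyloSor (no null model), observed Dnn, and the
#' standardized effect size of Dnn against `n_perm` tip shuffles of the
#' phylogeny, `-(Dnn_obs - mean(Dnn_null)) / sd(Dnn_null)`, so positive
#' values mean the two floras are phylogenetically *closer* than expected.
#' The same shuffles are reused across all pairs within a permutation.
#'
#' @param tree A `"phylo"` covering all matrix taxa.
#' @param matrix Flora matrix from [build_flora_matrix()] (>= 2 regions).
#' @param n_perm Number of tip shuffles (999 by default).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param direction Dnn symmetrization, see [dnn()].
#' @return Data frame with one row per unordered region pair: `region_i`,
#'   `region_j`, `phylosor`, `dnn_obs`, `dnn_null_mean`, `dnn_null_sd`,
#'   `ses_dnn`, `p`, `n_perm`, `degenerate`.
#' @export
analyze_beta <- function(tree, matrix, n_perm = 999, seed = NULL,
                         direction = "mean") {
  if (nrow(matrix) < 2L) stop("beta diversity needs at least 2 regions")
  taxa <- colnames(matrix)
  if (!all(taxa %in% tree$tip.label))
    stop("matrix taxa missing from the tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  ptree <- if (length(taxa) < ape::Ntip(tree))
    ape::keep.tip(tree, taxa) else tree
  dm <- patristic_matrix(ptree)
  comms <- lapply(rownames(matrix), function(r) region_taxa(matrix, r))
  names(comms) <- rownames(matrix)

  empty <- names(comms)[lengths(comms) == 0L]
  if (length(empty))
    warning("regions with zero taxa skipped: ",
            paste(empty, collapse = ", "))
  use <- setdiff(names(comms), empty)
  if (length(use) < 2L) stop("fewer than 2 non-empty regions")
  prs <- utils::combn(use, 2L)
  idxs <- lapply(comms, function(cm) match(cm, colnames(dm)))
  npool <- ncol(dm)

  dnn_idx <- function(ia, ib) {
    ab <- mean(apply(dm[ia, ib, drop = FALSE], 1L, min))
    ba <- mean(apply(dm[ib, ia, drop = FALSE], 1L, min))
    switch(direction, mean = (ab + ba) / 2, ab = ab, ba = ba)
  }

  obs <- apply(prs, 2L, function(pr) dnn_idx(idxs[[pr[1]]], idxs[[pr[2]]]))
  ps <- apply(prs, 2L, function(pr)
    phylosor(ptree, comms[[pr[1]]], comms[[pr[2]]]))

  nulls <- matrix(NA_real_, n_perm, ncol(prs))
  with_seed_opt(seed, {
    for (i in seq_len(n_perm)) {
      map <- sample.int(npool)
      for (k in seq_len(ncol(prs)))
        nulls[i, k] <- dnn_idx(map[idxs[[prs[1, k]]]],
                               map[idxs[[prs[2, k]]]])
    }
  })

  rows <- lapply(seq_len(ncol(prs)), function(k) {
    ss <- ses_index(obs[k], nulls[, k], flip_sign = TRUE)
    data.frame(region_i = prs[1, k], region_j = prs[2, k],
               phylosor = ps[k], dnn_obs = ss$observed,
               dnn_null_mean = ss$null_mean, dnn_null_sd = ss$null_sd,
               ses_dnn = ss$ses, p = ss$p, n_perm = ss$n_perm,
               degenerate = ss$degenerate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
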