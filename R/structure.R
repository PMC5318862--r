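# Within-flora phylogenetic structure: MPD/MNTD against a tip-shuffle null,
# summarized as NRI/NTI.

#' Patristic (tip-to-tip) distance matrix
#'
#' @param tree A `"phylo"` object with branch lengths.
#' @return Symmetric numeric matrix of path-length distances between tips.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  stats::cophenetic(tree)
}

#' Mean pairwise phylogenetic distance of a community
#'
#' The mean of the patristic distance over all unordered pairs of community
#' members. Undefined for fewer than two members.
#'
#' @param community Character vector of taxon names.
#' @param dm Patristic distance matrix (see [patristic_matrix()]).
#' @return Numeric scalar (Myr).
#' @export
mpd <- function(community, dm) {
  idx <- .comm_idx(community, dm)
  s <- length(idx)
  if (s < 2L) stop("MPD is undefined for communities of fewer than 2 taxa")
  sum(dm[idx, idx]) / (s * (s - 1))
}

#' Mean nearest-taxon phylogenetic distance of a community
#'
#' For each member, the distance to its nearest other member; averaged over
#' members. Undefined for fewer than two members.
#'
#' @inheritParams mpd
#' @return Numeric scalar (Myr).
#' @export
mntd <- function(community, dm) {
  idx <- .comm_idx(community, dm)
  if (length(idx) < 2L)
    stop("MNTD is undefined for communities of fewer than 2 taxa")
  sub <- dm[idx, idx]
  diag(sub) <- Inf
  mean(apply(sub, 1L, min))
}

.comm_idx <- function(community, dm) {
  idx <- match(unique(community), colnames(dm))
  if (anyNA(idx))
    stop("community members missing from the distance matrix: ",
         paste(unique(community)[is.na(idx)], collapse = ", "))
  idx
}

#' Standardized effect size of an observed metric against null draws
#'
#' With `flip_sign = TRUE` (the NRI/NTI and S.E.S. Dnn convention) the SES
#' is `-(observed - mean(nulls)) / sd(nulls)`, so communities whose taxa are
#' *closer* than expected score positive (clustering). The permutation
#' p-value is one-sided toward clustering: `(#{null <= observed} + 1) /
#' (n + 1)` when flipped, and the upper-tail analogue otherwise. When the
#' null draws have zero spread the SES is undefined and reported as `NA`
#' with `degenerate = TRUE`, never as infinity.
#'
#' @param observed Observed metric value.
#' @param nulls Numeric vector of null metric values.
#' @param flip_sign Flip the SES sign so smaller-than-null is positive.
#' @return One-row data frame: `observed`, `null_mean`, `null_sd`, `ses`,
#'   `p`, `n_perm`, `degenerate`.
#' @export
ses_index <- function(observed, nulls, flip_sign = TRUE) {
  if (!length(nulls)) stop("null distribution is empty")
  m <- mean(nulls); s <- stats::sd(nulls)
  n <- length(nulls)
  degenerate <- is.na(s) || s == 0
  ses <- if (degenerate) NA_real_ else {
    raw <- (observed - m) / s
    if (flip_sign) -raw else raw
  }
  p <- if (flip_sign) (sum(nulls <= observed) + 1) / (n + 1)
       else (sum(nulls >= observed) + 1) / (n + 1)
  data.frame(observed = observed, null_mean = m, null_sd = s,
             ses = ses, p = p, n_perm = n, degenerate = degenerate)
}

#' NRI and NTI per region under a tip-shuffle null
#'
#' For each region of `matrix`, computes observed MPD and MNTD on the
#' pool-pruned tree, then shuffles the tip labels of that tree `n_perm`
#' times; each shuffle is shared by all regions, and both metrics are
#' recomputed from it. NRI (from MPD) and NTI (from MNTD) are the
#' sign-flipped standardized effect sizes, positive for phylogenetic
#' clustering. Regions with fewer than two taxa yield a degenerate row.
#'
#' @param tree A `"phylo"` with branch lengths covering the pool.
#' @param matrix Flora matrix from [build_flora_matrix()] (regions x taxa).
#' @param pool Taxa forming the species pool whose labels are shuffled;
#'   defaults to all columns of `matrix`. Every region must be a subset.
#' @param n_perm Number of tip shuffles (999 by default).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Data frame with one row per region x metric (`NRI`, `NTI`):
#'   `region`, `metric`, `richness`, `observed`, `null_mean`, `null_sd`,
#'   `ses`, `p`, `sig_two_sided`, `n_perm`, `degenerate`.
#' @export
analyze_structure <- function(tree, matrix, pool = colnames(matrix),
                              n_perm = 999, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!all(pool %in% tree$tip.label))
    stop("pool members missing from the tree: ",
         paste(setdiff(pool, tree$tip.label), collapse = ", "))
  comms <- lapply(rownames(matrix), function(r) region_taxa(matrix, r))
  names(comms) <- rownames(matrix)
  for (r in names(comms))
    if (!all(comms[[r]] %in% pool))
      stop("region ", r, " has taxa outside the pool")
  if (any(lengths(comms) > length(pool)))
    stop("pool smaller than a community")

  ptree <- if (length(pool) < ape::Ntip(tree))
    ape::keep.tip(tree, pool) else tree
  dm <- patristic_matrix(ptree)
  npool <- ncol(dm)
  idxs <- lapply(comms, function(cm) match(cm, colnames(dm)))

  ok <- lengths(idxs) >= 2L
  obs_mpd <- obs_mntd <- stats::setNames(rep(NA_real_, length(comms)),
                                         names(comms))
  for (r in names(comms)[ok]) {
    obs_mpd[r] <- mpd(comms[[r]], dm)
    obs_mntd[r] <- mntd(comms[[r]], dm)
  }

  null_mpd <- matrix(NA_real_, n_perm, length(comms),
                     dimnames = list(NULL, names(comms)))
  null_mntd <- null_mpd
  with_seed_opt(seed, {
    for (i in seq_len(n_perm)) {
      map <- sample.int(npool)           # one shared shuffle per permutation
      for (r in names(comms)[ok]) {
        idx <- map[idxs[[r]]]
        s <- length(idx)
        sub <- dm[idx, idx]
        null_mpd[i, r] <- sum(sub) / (s * (s - 1))
        diag(sub) <- Inf
        null_mntd[i, r] <- mean(apply(sub, 1L, min))
      }
    }
  })

  rows <- list()
  for (r in names(comms)) {
    for (metric in c("NRI", "NTI")) {
      if (!ok[[r]]) {
        row <- data.frame(observed = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, ses = NA_real_, p = NA_real_,
                          n_perm = n_perm, degenerate = TRUE)
      } else {
        nulls <- if (metric == "NRI") null_mpd[, r] else null_mntd[, r]
        o <- if (metric == "NRI") obs_mpd[r] else obs_mntd[r]
        row <- ses_index(o, nulls, flip_sign = TRUE)
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(region = r, metric = metric,
                         richness = length(comms[[r]])),
              row)
    }
  }
  out <- do.call(rbind, rows)
  out$sig_two_sided <- !is.na(out$ses) & abs(out$ses) > 1.96
  rownames(out) <- NULL
  out[c("region", "metric", "richness", "observed", "null_mean", "null_sd",
        "ses", "p", "sig_two_sided", "n_perm", "degenerate")]
}
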