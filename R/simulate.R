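# Synthetic data: seedable trees, taxonomies, regional communities and
# element labels with known statistical structure, so every pipeline stage
# is testable without external floristic data.

#' Simulate an ultrametric phylogeny
#'
#' Constant-rate Yule or birth-death tree conditioned on the number of
#' surviving tips (via [ape::rphylo()]), with tips relabelled `s0001...` so
#' synthetic taxonomies can be layered on top. Deterministic under `seed`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param model `"yule"` (pure birth) or `"birth_death"`.
#' @param birth,death Speciation and extinction rates (per lineage per unit
#'   time); `death < birth` required for the birth-death model.
#' @param seed Integer seed.
#' @return Ultrametric `"phylo"` object.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "birth_death"),
                          birth = 1, death = 0.5, seed = NULL) {
  model <- match.arg(model)
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (model == "yule") death <- 0
  if (birth <= 0 || death < 0 || death >= birth)
    stop("invalid rates: need birth > 0 and 0 <= death < birth")
  tr <- with_seed_opt(seed, ape::rphylo(n_tips, birth = birth,
                                        death = death, T0 = 50))
  tr$tip.label <- sprintf("s%04d", seq_len(n_tips))
  validate_phylogeny(tr)
}

# Split tips into `k` disjoint monophyletic blocks by repeatedly breaking
# the largest current block at its crown node. Splits whose children all
# reach `min_size` tips are preferred, so downstream stages (one genus cut
# per family) stay feasible whenever the topology allows it.
.clade_blocks <- function(tree, k, min_size = 1L) {
  ntip <- ape::Ntip(tree)
  if (k > ntip) stop("cannot form ", k, " clades from ", ntip, " tips")
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  block_tips <- function(v) {
    if (v <= ntip) return(v)
    unlist(lapply(kids[[as.character(v)]], block_tips))
  }
  blocks <- list(ntip + 1L)  # node numbers; tips are unsplittable blocks
  while (length(blocks) < k) {
    sizes <- vapply(blocks, function(v) length(block_tips(v)), integer(1))
    splittable <- which(unlist(blocks) > ntip)
    if (!length(splittable))
      stop("infeasible partition: not enough internal clades")
    child_ok <- vapply(splittable, function(i) {
      all(vapply(kids[[as.character(blocks[[i]])]],
                 function(v) length(block_tips(v)), integer(1)) >= min_size)
    }, logical(1))
    cand <- if (any(child_ok)) splittable[child_ok] else splittable
    i <- cand[which.max(sizes[cand])]
    blocks <- c(blocks[-i], as.list(kids[[as.character(blocks[[i]])]]))
  }
  lapply(blocks, function(v) tree$tip.label[block_tips(v)])
}

#' Simulate a family/genus taxonomy over a tree
#'
#' Cuts the tree into `n_families` disjoint monophyletic clades (families),
#' then each family into `genera_per_family` monophyletic genera, so every
#' tip receives a genus and family consistent with the tree. Fails when the
#' topology cannot support the requested partition.
#'
#' @param tree A `"phylo"` object.
#' @param n_families Number of family clades.
#' @param genera_per_family Number of genus clades within each family.
#' @param seed Unused placeholder for interface symmetry (the partition is
#'   deterministic given the tree); reserved.
#' @return Data frame with columns `species`, `genus`, `family`.
#' @export
simulate_taxonomy <- function(tree, n_families, genera_per_family = 2L,
                              seed = NULL) {
  fams <- .clade_blocks(tree, n_families, min_size = genera_per_family)
  if (any(lengths(fams) < genera_per_family))
    stop("infeasible partition: a family clade has fewer tips than the ",
         "requested genera per family")
  # deterministic naming by first tip, lexicographic family order
  fams <- fams[order(vapply(fams, function(x) sort(x)[1], ""))]
  out <- list()
  for (i in seq_along(fams)) {
    fam <- sprintf("F%02d", i)
    sub <- if (length(fams[[i]]) > 1L) ape::keep.tip(tree, fams[[i]]) else NULL
    gens <- if (is.null(sub)) list(fams[[i]])
            else .clade_blocks(sub, genera_per_family)
    gens <- gens[order(vapply(gens, function(x) sort(x)[1], ""))]
    for (j in seq_along(gens))
      out[[length(out) + 1L]] <-
        data.frame(species = gens[[j]],
                   genus = sprintf("%s_G%02d", fam, j),
                   family = fam)
  }
  res <- do.call(rbind, out)
  res[order(res$species), , drop = FALSE]
}

#' Specify one synthetic regional community
#'
#' @param structure `"clustered"`, `"overdispersed"` or `"random"`.
#' @param size Number of taxa (>= 2, <= pool size).
#' @param strength In `[0, 1]`: 1 = pure structure, 0 = uniform random.
#' @return A `"community_spec"` list.
#' @export
community_spec <- function(structure = c("random", "clustered",
                                         "overdispersed"),
                           size, strength = 1) {
  structure <- match.arg(structure)
  stopifnot(size >= 2, strength >= 0, strength <= 1)
  structure(list(structure = structure, size = size, strength = strength),
            class = "community_spec")
}

# Greedy maximum-dispersion selection of k tips: each step adds the tip
# with the largest summed distance to those already selected, directly
# pushing up the community's MPD (exact max-MPD subset selection is
# NP-hard; plain farthest-point max-min spreads the minimum spacing but
# leaves MPD barely above the random expectation on large trees).
.maxdisp_select <- function(dm, k) {
  sel <- which.max(rowSums(dm))  # start from the most isolated tip
  tot <- dm[, sel]
  while (length(sel) < k) {
    cand <- tot
    cand[sel] <- -Inf
    nxt <- which.max(cand)
    sel <- c(sel, nxt)
    tot <- tot + dm[, nxt]
  }
  sel
}

#' Simulate regional communities with controlled phylogenetic structure
#'
#' * clustered: members drawn from the smallest clade holding at least
#'   `size` tips;
#' * overdispersed: greedy maximum-dispersion selection on patristic
#'   distance (each step adds the taxon with the largest summed distance
#'   to those already chosen);
#' * random: uniform without replacement.
#'
#' `strength` interpolates: a fraction `strength` of the members follow the
#' structure, the rest are uniform draws from the remaining pool.
#'
#' @param tree Pool phylogeny.
#' @param specs Named list of [community_spec()]s, one per region.
#' @param seed Integer seed.
#' @return Binary flora matrix (regions x tips) with attribute
#'   `rank = "species"`.
#' @export
simulate_communities <- function(tree, specs, seed = NULL) {
  tips <- tree$tip.label
  n <- length(tips)
  if (is.null(names(specs)) || any(!nzchar(names(specs))))
    names(specs) <- sprintf("region%d", seq_along(specs))
  for (sp in specs)
    if (sp$size > n) stop("community size exceeds number of tips")
  dm <- NULL
  mat <- matrix(0L, length(specs), n,
                dimnames = list(names(specs), tips))
  with_seed_opt(seed, {
    for (r in names(specs)) {
      sp <- specs[[r]]
      k_struct <- round(sp$strength * sp$size)
      chosen <- character()
      if (k_struct > 0 && sp$structure == "clustered") {
        cl <- .smallest_clade_with(tree, sp$size)
        chosen <- sample(cl, min(k_struct, length(cl)))
      } else if (k_struct > 0 && sp$structure == "overdispersed") {
        dm <- dm %||% patristic_matrix(tree)
        chosen <- tips[.maxdisp_select(dm, k_struct)]
      }
      rest <- sample(setdiff(tips, chosen), sp$size - length(chosen))
      mat[r, c(chosen, rest)] <- 1L
    }
  })
  structure(mat, rank = "species")
}

# Tip labels of the smallest clade containing at least k tips.
.smallest_clade_with <- function(tree, k) {
  ntip <- ape::Ntip(tree)
  counts <- vapply((ntip + 1L):(ntip + tree$Nnode), function(v)
    length(phangorn::Descendants(tree, v, type = "tips")[[1]]), integer(1))
  ok <- which(counts >= k)
  best <- ok[which.min(counts[ok])]
  tree$tip.label[phangorn::Descendants(tree, ntip + best,
                                       type = "tips")[[1]]]
}

#' Assign element codes to a synthetic taxonomy
#'
#' Codes are assigned per genus (all congeners share a code, as element
#' typologies operate at genus rank): each genus draws a super-group
#' (tropical / temperate / unknown) with the stated proportions, then a
#' uniform base code within it.
#'
#' @param taxonomy Data frame from [simulate_taxonomy()].
#' @param p_tropical,p_temperate Super-group proportions; the remainder is
#'   `UNKNOWN`. Defaults 0.5 / 0.45 (0.05 unknown), emulating a flora where
#'   a small fraction of distribution patterns is unclear.
#' @param vocab Element vocabulary supplying the base codes.
#' @param seed Integer seed.
#' @return The taxonomy with an `element` column added.
#' @export
simulate_elements <- function(taxonomy, p_tropical = 0.5,
                              p_temperate = 0.45,
                              vocab = element_vocabulary("genus"),
                              seed = NULL) {
  stopifnot(p_tropical + p_temperate <= 1)
  tro <- vocab$code[vocab$supergroup == "tropical"]
  tem <- vocab$code[vocab$supergroup == "temperate"]
  genera <- sort(unique(taxonomy$genus))
  code <- with_seed_opt(seed, {
    grp <- sample(c("tropical", "temperate", "UNKNOWN"), length(genera),
                  replace = TRUE,
                  prob = c(p_tropical, p_temperate,
                           1 - p_tropical - p_temperate))
    vapply(grp, function(g) switch(g,
      tropical = sample(tro, 1L),
      temperate = sample(tem, 1L),
      "UNKNOWN"), character(1))
  })
  taxonomy$element <- unname(stats::setNames(code, genera)[taxonomy$genus])
  taxonomy
}

#' Simulate a complete synthetic flora
#'
#' Convenience bundle: tree, taxonomy, element codes and regional
#' communities, returned as the package's standard inputs (a phylogeny and
#' a `"taxon_table"`).
#'
#' @param n_tips Pool size.
#' @param n_families,genera_per_family Taxonomy shape.
#' @param specs Named list of [community_spec()]s (default: three regions —
#'   one clustered, one overdispersed, one random — of 30 taxa each).
#' @param p_tropical,p_temperate Element proportions, see
#'   [simulate_elements()].
#' @param seed Master seed; expanded into per-stage streams.
#' @return List with `tree`, `table` (a `"taxon_table"`), `matrix`
#'   (species-rank flora matrix).
#' @export
simulate_flora <- function(n_tips = 200, n_families = 8,
                           genera_per_family = 3,
                           specs = NULL,
                           p_tropical = 0.5, p_temperate = 0.45,
                           seed = 1) {
  if (is.null(specs))
    specs <- list(south = community_spec("overdispersed", 30),
                  central = community_spec("random", 30),
                  northwest = community_spec("clustered", 30))
  seeds <- seed_streams(seed, 3L)
  # a given topology may not admit the requested family/genus cut; draw
  # fresh trees (deterministically from the master seed) until one does
  tree_seeds <- seed_streams(seeds[1], 50L)
  tax <- NULL
  for (ts in tree_seeds) {
    tree <- simulate_tree(n_tips, "yule", seed = ts)
    tax <- tryCatch(simulate_taxonomy(tree, n_families, genera_per_family),
                    error = function(e) NULL)
    if (!is.null(tax)) break
  }
  if (is.null(tax))
    stop("could not realize the requested taxonomy shape on ", n_tips,
         "-tip trees")
  tax <- simulate_elements(tax, p_tropical, p_temperate, seed = seeds[2])
  mat <- simulate_communities(tree, specs, seed = seeds[3])
  tab <- tax
  for (r in rownames(mat))
    tab[[r]] <- as.integer(mat[r, tab$species])
  tab <- load_taxon_table(tab)
  list(tree = tree, table = tab, matrix = mat)
}
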