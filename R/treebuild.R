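# Tree construction: grafting checklist taxa onto a backbone megatree and
# deriving dated, rank-collapsed analysis trees.

#' Graft checklist taxa onto a backbone phylogeny
#'
#' Species in `table` that are not tips of `backbone` are bound into the
#' smallest containing clade that is resolvable on the tree (their genus if
#' any congener is a tip, otherwise their family), under one of three
#' scenarios:
#'
#' * `"S1"` — attach at the crown node of the containing clade as a
#'   polytomy, with pendant length equal to the crown age;
#' * `"S2"` — attach at a uniformly chosen point within the clade (an
#'   internal node or the midpoint of a pendant edge);
#' * `"S3"` — attach as in S1, then re-date every node created by grafting
#'   with [bladj_smooth()], holding the backbone's original node ages fixed.
#'
#' When the containing clade is a single tip, a new node is inserted at half
#' of that tip's pendant edge and the taxon attached there, preserving
#' ultrametricity (the Phylomatic convention). Taxa whose genus and family
#' are both absent are left unplaced and reported. Genus membership of
#' backbone tips missing from `table` is inferred from the first word of the
#' binomial tip label; family membership requires a table entry.
#'
#' @param backbone Ultrametric `"phylo"` backbone with branch lengths (Myr).
#' @param table A `"taxon_table"` listing the species to place.
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param seed Integer seed; mandatory for S2 and S3.
#' @return A list with elements `tree` (the grafted phylogeny) and `report`
#'   (a `"graft_report"`: character vectors `polytomy`, `random`,
#'   `scenario3`, `unplaced`, and a `details` data frame).
#' @export
graft_taxa <- function(backbone, table, scenario = c("S1", "S2", "S3"),
                       seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(backbone) || !inherits(backbone, "phylo") ||
      ape::Ntip(backbone) < 2L)
    stop("backbone must be a phylo object with at least 2 tips")
  backbone <- validate_phylogeny(backbone, require_lengths = TRUE)
  if (scenario %in% c("S1", "S3") && !attr(backbone, "ultrametric"))
    stop("scenario ", scenario, " requires an ultrametric backbone ",
         "(attachment-node ages are undefined otherwise)")
  if (scenario %in% c("S2", "S3") && is.null(seed))
    stop("scenario ", scenario, " requires a seed")

  sp2gen <- stats::setNames(table$genus, table$species)
  sp2fam <- stats::setNames(table$family, table$species)
  genus_of <- function(tips) {
    g <- unname(sp2gen[tips])
    miss <- is.na(g)
    g[miss] <- vapply(strsplit(tips[miss], "[ _]"), `[`, "", 1L)
    g
  }
  to_add <- setdiff(table$species, backbone$tip.label)

  # original backbone node ages, tracked by descendant tip set (for S3)
  orig_sets <- NULL
  if (scenario == "S3") {
    ages0 <- node_ages(backbone)
    ntip0 <- ape::Ntip(backbone)
    orig_sets <- lapply(seq_len(backbone$Nnode), function(i) {
      node <- ntip0 + i
      list(tips = ape::extract.clade(backbone, node)$tip.label,
           age = ages0[node])
    })
  }

  tree <- backbone
  placed <- character(); unplaced <- character()
  det <- list()
  method_name <- switch(scenario, S1 = "polytomy", S2 = "random",
                        S3 = "scenario3")

  with_seed_opt(seed, {
    for (sp in to_add) {
      tips <- tree$tip.label
      members <- tips[genus_of(tips) == sp2gen[[sp]]]
      clade_rank <- "genus"; clade <- sp2gen[[sp]]
      if (!length(members)) {
        # family fallback: tips whose family is known via the table
        fam_tips <- names(sp2fam)[sp2fam == sp2fam[[sp]]]
        members <- intersect(tips, fam_tips)
        clade_rank <- "family"; clade <- sp2fam[[sp]]
      }
      if (!length(members)) {
        unplaced <- c(unplaced, sp)
        next
      }
      tree <- if (scenario == "S2")
        attach_random(tree, sp, members)
      else
        attach_polytomy(tree, sp, members)
      placed <- c(placed, sp)
      det[[length(det) + 1L]] <-
        data.frame(taxon = sp, method = method_name,
                   clade_rank = clade_rank, clade = clade)
    }
  })

  if (scenario == "S3" && length(placed)) {
    ntip <- ape::Ntip(tree)
    cal_nodes <- vapply(orig_sets, function(s) {
      if (length(s$tips) == 1L) NA_integer_
      else ape::getMRCA(tree, s$tips)
    }, integer(1))
    ages <- stats::setNames(vapply(orig_sets, `[[`, 0, "age"), cal_nodes)
    ages <- ages[!is.na(cal_nodes)]
    # distinct original nodes can map to one grafted node only if equal-aged
    ages <- tapply(ages, names(ages), max)
    tree <- bladj_ages(tree,
                       stats::setNames(as.numeric(ages),
                                       names(ages)))
  }

  report <- structure(
    list(polytomy = if (scenario == "S1") placed else character(),
         random = if (scenario == "S2") placed else character(),
         scenario3 = if (scenario == "S3") placed else character(),
         unplaced = unplaced,
         details = if (length(det)) do.call(rbind, det) else
           data.frame(taxon = character(), method = character(),
                      clade_rank = character(), clade = character())),
    class = "graft_report")
  list(tree = validate_phylogeny(tree), report = report)
}

# Single-tip phylo used as the grafting unit.
.tip_tree <- function(label, length) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
                 edge.length = length, Nnode = 1L), class = "phylo")
}

# S1: bind at the crown MRCA of members (>=2) as a polytomy, or at half the
# pendant edge of a single member.
attach_polytomy <- function(tree, label, members) {
  if (length(members) >= 2L) {
    node <- ape::getMRCA(tree, members)
    age <- node_ages(tree)[node]
    ape::bind.tree(tree, .tip_tree(label, age), where = node)
  } else {
    w <- match(members, tree$tip.label)
    L <- tree$edge.length[tree$edge[, 2] == w]
    ape::bind.tree(tree, .tip_tree(label, L / 2), where = w,
                   position = L / 2)
  }
}

# S2: choose uniformly among internal nodes of the clade and pendant-edge
# midpoints of its tips; attach with pendant length equal to the point's age.
attach_random <- function(tree, label, members) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  if (length(members) >= 2L) {
    crown <- ape::getMRCA(tree, members)
    desc <- phangorn::Descendants(tree, crown, type = "all")
    inner <- c(crown, desc[desc > ntip])
    desc_tips <- desc[desc <= ntip]
  } else {
    desc_tips <- match(members, tree$tip.label)
    inner <- integer()
  }
  pick <- sample.int(length(inner) + length(desc_tips), 1L)
  if (pick <= length(inner)) {
    node <- inner[pick]
    ape::bind.tree(tree, .tip_tree(label, ages[node]), where = node)
  } else {
    w <- desc_tips[pick - length(inner)]
    L <- tree$edge.length[tree$edge[, 2] == w]
    ape::bind.tree(tree, .tip_tree(label, L / 2), where = w,
                   position = L / 2)
  }
}

#' Assign ages to undated nodes by even interpolation (BLADJ)
#'
#' Given fixed ages for some internal nodes (always including the root) and
#' age 0 for every tip, each undated node receives an age that divides the
#' interval between its nearest dated ancestor and nearest dated descendant
#' into equal steps: a chain of k undated nodes between two dated ones
#' splits that age span into k+1 equal pieces. Edge lengths are then parent
#' age minus child age.
#'
#' @param tree A `"phylo"` object (branch lengths, if any, are discarded).
#' @param calibrations Data frame with columns `clade` and `age_myr` (or
#'   `age`). `clade` is either an internal node label or a
#'   semicolon-separated set of tip labels whose MRCA is dated. `"root"`
#'   refers to the root node.
#' @return The tree with recomputed branch lengths.
#' @export
bladj_smooth <- function(tree, calibrations) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(calibrations)) {
    agecol <- intersect(c("age_myr", "age"), names(calibrations))[1]
    if (is.na(agecol) || !"clade" %in% names(calibrations))
      stop("calibrations need columns 'clade' and 'age_myr' (or 'age')")
    nodes <- vapply(calibrations$clade, resolve_clade, integer(1),
                    tree = tree)
    ages <- stats::setNames(as.numeric(calibrations[[agecol]]), nodes)
  } else {
    ages <- calibrations  # named numeric: names are node numbers
  }
  if (anyNA(ages) || any(ages < 0)) stop("calibration ages must be >= 0")
  if (anyDuplicated(names(ages)))
    stop("conflicting calibrations for a single node")
  bladj_ages(tree, ages)
}

# Resolve a calibration clade spec to an internal node number.
resolve_clade <- function(tree, spec) {
  spec <- trimws(spec)
  if (identical(spec, "root")) return(ape::Ntip(tree) + 1L)
  if (!is.null(tree$node.label) && spec %in% tree$node.label)
    return(ape::Ntip(tree) + match(spec, tree$node.label))
  tips <- trimws(strsplit(spec, ";")[[1]])
  if (length(tips) < 2L || !all(tips %in% tree$tip.label))
    stop("cannot resolve calibration clade: ", spec)
  ape::getMRCA(tree, tips)
}

# Core BLADJ interpolation on node numbers.
bladj_ages <- function(tree, cal) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  age <- rep(NA_real_, nn)
  age[seq_len(ntip)] <- 0
  dated <- rep(FALSE, nn)
  dated[seq_len(ntip)] <- TRUE
  idx <- as.integer(names(cal))
  if (any(idx <= ntip)) stop("calibrations must name internal nodes")
  age[idx] <- unname(cal)
  dated[idx] <- TRUE
  root <- ntip + 1L
  if (is.na(age[root])) stop("root age must be calibrated")

  # order edges parents-before-children by BFS from the root (robust to
  # nodes of out-degree 1, which arise in calibration chain fixtures)
  edge <- tree$edge
  kids_e <- split(seq_len(nrow(edge)), edge[, 1])
  ord <- integer(0); queue <- root
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    es <- kids_e[[as.character(v)]]
    ord <- c(ord, es)
    queue <- c(queue, edge[es, 2][edge[es, 2] > ntip])
  }
  edge <- edge[ord, , drop = FALSE]
  parent <- integer(nn); parent[edge[, 2]] <- edge[, 1]

  # ancestor >= descendant consistency among the dated nodes
  for (v in idx) {
    a <- parent[v]
    while (a != 0L) {
      if (dated[a] && !is.na(age[a]) && age[a] < age[v] - 1e-9)
        stop("calibration conflict: node ", v, " (", age[v],
             ") older than its ancestor ", a, " (", age[a], ")")
      if (a == root) break
      a <- parent[a]
    }
  }

  # nearest originally-dated node below each node: (steps, max age at that
  # distance), by post-order sweep
  steps <- rep(NA_real_, nn); bage <- rep(NA_real_, nn)
  for (i in rev(seq_len(nrow(edge)))) {
    ch <- edge[i, 2]
    if (dated[ch]) { steps[ch] <- 0; bage[ch] <- age[ch] }
    pa <- edge[i, 1]
    s <- steps[ch] + 1
    if (is.na(steps[pa]) || s < steps[pa] ||
        (s == steps[pa] && bage[ch] > bage[pa])) {
      if (is.na(steps[pa]) || s <= steps[pa]) {
        steps[pa] <- s; bage[pa] <- bage[ch]
      }
    }
  }

  # top-down even interpolation
  for (i in seq_len(nrow(edge))) {
    ch <- edge[i, 2]
    if (dated[ch]) next
    a <- age[edge[i, 1]]
    b <- bage[ch]; m <- steps[ch]
    if (a < b - 1e-9)
      stop("interpolated age below a dated descendant at node ", ch)
    age[ch] <- a - (a - b) / (m + 1)
  }

  el <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  if (any(el < -1e-9)) stop("negative edge length after dating")
  tree$edge.length <- pmax(el, 0)
  validate_phylogeny(tree)
}

#' Collapse a species-level tree to genus or family rank
#'
#' Keeps one exemplar tip per rank-level taxon (the lexicographically first
#' species), prunes the rest, and relabels the exemplar with the rank name.
#' Rank taxa with no tip on the tree are omitted with a warning.
#'
#' @param tree Species-level `"phylo"`; every tip must occur in `table`.
#' @param table A `"taxon_table"`.
#' @param rank `"species"` (identity), `"genus"` or `"family"`.
#' @return The rank-level phylogeny.
#' @export
collapse_to_rank <- function(tree, table,
                             rank = c("species", "genus", "family")) {
  rank <- match.arg(rank)
  if (rank == "species") return(tree)
  unmapped <- setdiff(tree$tip.label, table$species)
  if (length(unmapped))
    stop("tips not present in the taxon table: ",
         paste(unmapped, collapse = ", "))
  grp <- stats::setNames(table[[rank]], table$species)[tree$tip.label]
  missing_taxa <- setdiff(unique(table[[rank]]), grp)
  if (length(missing_taxa))
    warning("rank taxa with no tip on the tree omitted: ",
            paste(missing_taxa, collapse = ", "))
  exemplars <- vapply(split(tree$tip.label, grp), function(sp) sort(sp)[1L],
                      character(1))
  pruned <- ape::keep.tip(tree, unname(exemplars))
  pruned$tip.label <- names(exemplars)[match(pruned$tip.label, exemplars)]
  validate_phylogeny(pruned)
}

#' Read a node-age calibration table
#' @param file CSV with columns `clade` and `age_myr`.
#' @return Data frame.
#' @export
read_calibrations <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("clade") %in% names(df)) ||
      !any(c("age_myr", "age") %in% names(df)))
    stop("calibration CSV needs columns 'clade' and 'age_myr'")
  df
}

#' @export
print.graft_report <- function(x, ...) {
  cat("Graft report:",
      length(x$polytomy), "polytomy,",
      length(x$random), "random,",
      length(x$scenario3), "BLADJ-redated,",
      length(x$unplaced), "unplaced\n")
  invisible(x)
}
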