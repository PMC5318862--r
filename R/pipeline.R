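# Orchestration: one config in, rank-level trees and structure/beta tables
# out, deterministically under a master seed.

#' Assemble a pipeline run configuration
#'
#' Inputs may be file paths (Newick / CSV) or in-memory objects (a
#' `"phylo"`, a `"taxon_table"`, ...). Unset optional inputs are skipped.
#'
#' @param backbone Backbone phylogeny: Newick path or `"phylo"`.
#' @param taxon_table Checklist: CSV path or `"taxon_table"` / data frame.
#' @param synonyms Optional synonym map: CSV path or `"synonym_map"`.
#' @param vocabulary Optional element vocabulary: CSV path or
#'   `"element_vocabulary"`; defaults to the built-in genus vocabulary.
#' @param scenario Grafting scenario, `"S1"` (default), `"S2"` or `"S3"`.
#' @param ranks Ranks to analyse, subset of species/genus/family.
#' @param element_groups Element groups to analyse at genus/family rank, in
#'   addition to `"ALL TAXA"`; e.g. `c("ALL TRO", "ALL TEM")`.
#' @param n_perm Tip shuffles per null (999 by default).
#' @param seed Master seed; expanded into per-stage streams.
#' @param out_dir Output directory.
#' @return A `"run_config"` list.
#' @export
run_config <- function(backbone, taxon_table, synonyms = NULL,
                       vocabulary = NULL, scenario = "S1",
                       ranks = c("species", "genus", "family"),
                       element_groups = character(),
                       n_perm = 999, seed = 1, out_dir = "phyloflora-out") {
  stopifnot(scenario %in% c("S1", "S2", "S3"), n_perm >= 1,
            all(ranks %in% c("species", "genus", "family")))
  structure(list(backbone = backbone, taxon_table = taxon_table,
                 synonyms = synonyms, vocabulary = vocabulary,
                 scenario = scenario, ranks = ranks,
                 element_groups = element_groups, n_perm = n_perm,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys match the arguments of [run_config()]; path-valued keys
#' are resolved relative to the YAML file's directory.
#'
#' @param file YAML path.
#' @return A `"run_config"`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  rel <- function(p) if (is.null(p)) NULL else file.path(base, p)
  run_config(backbone = rel(y$backbone), taxon_table = rel(y$taxon_table),
             synonyms = rel(y$synonyms), vocabulary = rel(y$vocabulary),
             scenario = y$scenario %||% "S1",
             ranks = y$ranks %||% c("species", "genus", "family"),
             element_groups = y$element_groups %||% character(),
             n_perm = y$n_perm %||% 999, seed = y$seed %||% 1,
             out_dir = y$out_dir %||% file.path(base, "phyloflora-out"))
}

.load_input <- function(x, reader) {
  if (is.null(x) || !is.character(x)) x else reader(x)
}

#' Run the full phylofloristic analysis
#'
#' Reads and reconciles the checklist, grafts its species onto the backbone
#' under the chosen scenario, derives family/genus/species analysis trees,
#' and computes NRI/NTI per region and PhyloSor / S.E.S. Dnn per region
#' pair — for all taxa and for each requested geographical-element group at
#' genus and family rank. Writes, under `out_dir`: one Newick per rank,
#' `structure.csv`, `beta.csv` and `run_metadata.json`. Outputs are
#' byte-identical across reruns with the same config and seed; on failure,
#' files already written are removed.
#'
#' @param config A `"run_config"` (see [run_config()]).
#' @return Invisibly, a list with `structure`, `beta`, `trees`, `report`,
#'   `metadata`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  written <- character()
  on_fail <- function(stage, e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    on_fail(name, e))

  vocab <- stage("vocabulary",
                 .load_input(config$vocabulary, read_element_vocabulary) %||%
                   element_vocabulary("genus"))
  synonyms <- stage("synonyms", .load_input(config$synonyms,
                                            read_synonym_map))
  table <- stage("taxon_table", {
    raw <- config$taxon_table
    if (is.character(raw))
      load_taxon_table(raw, synonyms = synonyms, vocabulary = vocab)
    else if (inherits(raw, "taxon_table") && is.null(synonyms)) raw
    else load_taxon_table(as.data.frame(raw), synonyms = synonyms,
                          vocabulary = vocab)
  })
  backbone <- stage("backbone", {
    b <- config$backbone
    if (is.character(b)) read_newick(b) else validate_phylogeny(b)
  })

  groups <- unique(c("ALL TAXA", config$element_groups))
  grid <- expand.grid(rank = config$ranks, group = groups,
                      stringsAsFactors = FALSE)
  # element groups are defined at genus/family rank only
  grid <- grid[grid$group == "ALL TAXA" | grid$rank != "species", ]
  seeds <- seed_streams(config$seed, 1L + 2L * nrow(grid))
  graft_seed <- seeds[1]

  message("grafting ", sum(!table$species %in% backbone$tip.label),
          " taxa under scenario ", config$scenario)
  grafted <- stage("treebuild",
                   graft_taxa(backbone, table, scenario = config$scenario,
                              seed = if (config$scenario == "S1") NULL
                                     else graft_seed))
  sp_matrix <- stage("flora_matrix", build_flora_matrix(table, "species"))
  placeable <- intersect(colnames(sp_matrix), grafted$tree$tip.label)
  excluded <- setdiff(colnames(sp_matrix), placeable)
  if (length(excluded))
    message("excluding ", length(excluded),
            " species without a placement on the tree: ",
            paste(excluded, collapse = ", "))
  sp_tree <- stage("treebuild", ape::keep.tip(grafted$tree, placeable))
  table_placed <- table[table$species %in% placeable, , drop = FALSE]
  attr(table_placed, "regions") <- regions_of(table)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  trees <- list(); struct_out <- list(); beta_out <- list()
  for (rank in config$ranks) {
    trees[[rank]] <- stage("treebuild",
                           collapse_to_rank(sp_tree, table_placed, rank))
    f <- file.path(config$out_dir, paste0("tree_", rank, ".nwk"))
    write_newick(trees[[rank]], f)
    written <- c(written, f)
  }

  for (i in seq_len(nrow(grid))) {
    rank <- grid$rank[i]; group <- grid$group[i]
    sseed <- seeds[2L * i]; bseed <- seeds[2L * i + 1L]
    sp_in_group <- suppressMessages(
      partition_by_element(table_placed, vocab, group))
    taxa <- if (rank == "species") sp_in_group
            else unique(table_placed[[rank]][table_placed$species %in%
                                               sp_in_group])
    mat <- stage("flora_matrix", suppressWarnings(
      build_flora_matrix(table_placed, rank)))
    taxa <- intersect(intersect(taxa, colnames(mat)),
                      trees[[rank]]$tip.label)
    if (length(taxa) < 3L) {
      warning("group '", group, "' at rank ", rank,
              " has too few taxa; skipped")
      next
    }
    gmat <- mat[, taxa, drop = FALSE]
    keep_rows <- rowSums(gmat) > 0
    gmat <- gmat[keep_rows, , drop = FALSE]
    gtree <- ape::keep.tip(trees[[rank]], taxa)
    st <- stage("structure",
                analyze_structure(gtree, gmat, pool = taxa,
                                  n_perm = config$n_perm, seed = sseed))
    struct_out[[length(struct_out) + 1L]] <-
      cbind(data.frame(level = rank, group = group), st)
    if (nrow(gmat) >= 2L) {
      bt <- stage("beta", suppressWarnings(
        analyze_beta(gtree, gmat, n_perm = config$n_perm, seed = bseed)))
      beta_out[[length(beta_out) + 1L]] <-
        cbind(data.frame(level = rank, group = group), bt)
    }
  }

  structure_tab <- do.call(rbind, struct_out)
  beta_tab <- if (length(beta_out)) do.call(rbind, beta_out) else NULL
  f <- file.path(config$out_dir, "structure.csv")
  utils::write.csv(structure_tab, f, row.names = FALSE)
  written <- c(written, f)
  if (!is.null(beta_tab)) {
    f <- file.path(config$out_dir, "beta.csv")
    utils::write.csv(beta_tab, f, row.names = FALSE)
    written <- c(written, f)
  }

  metadata <- list(
    package_version = as.character(utils::packageVersion("phyloflora")),
    scenario = config$scenario,
    ranks = config$ranks,
    element_groups = groups,
    n_perm = config$n_perm,
    master_seed = config$seed,
    stage_seeds = as.list(stats::setNames(
      seeds, c("graft", paste0(rep(c("structure_", "beta_"), nrow(grid)),
                               rep(seq_len(nrow(grid)), each = 2L))))),
    dnn_symmetrization = "mean of directional means",
    n_species = nrow(table),
    n_grafted = nrow(grafted$report$details),
    unplaced = grafted$report$unplaced,
    excluded_species = excluded)
  f <- file.path(config$out_dir, "run_metadata.json")
  jsonlite::write_json(metadata, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, f)

  invisible(list(structure = structure_tab, beta = beta_tab, trees = trees,
                 report = grafted$report, metadata = metadata))
}
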