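#' Read a synonym map
#'
#' A synonym map is a two-column CSV (`verbatim,accepted`) replacing verbatim
#' checklist names with accepted names. The map must be functional (one
#' accepted name per verbatim name) and accepted names must be fixed points,
#' so applying the map twice equals applying it once.
#'
#' @param file Path to the CSV.
#' @return A named character vector (verbatim -> accepted) of class
#'   `"synonym_map"`.
#' @export
read_synonym_map <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("verbatim", "accepted") %in% names(df)))
    stop("synonym CSV needs columns 'verbatim' and 'accepted'")
  synonym_map(df$verbatim, df$accepted)
}

#' Build a synonym map from vectors
#'
#' @param verbatim,accepted Character vectors of equal length.
#' @return Named character vector of class `"synonym_map"`.
#' @export
synonym_map <- function(verbatim = character(), accepted = character()) {
  stopifnot(length(verbatim) == length(accepted))
  if (anyDuplicated(verbatim))
    stop("synonym map is not functional: duplicated verbatim names")
  bad <- accepted[accepted %in% verbatim & accepted != verbatim]
  if (length(bad))
    stop("accepted names must be fixed points of the map: ",
         paste(unique(bad), collapse = ", "))
  structure(stats::setNames(accepted, verbatim), class = "synonym_map")
}

#' Apply a synonym map to names
#'
#' Idempotent: names not in the map pass through unchanged.
#'
#' @param names Character vector of taxon names.
#' @param map A `"synonym_map"` (or NULL for the identity).
#' @return Character vector of accepted names.
#' @export
apply_synonyms <- function(names, map = NULL) {
  if (is.null(map) || !length(map)) return(names)
  hit <- names %in% names(map)
  names[hit] <- unname(map[names[hit]])
  names
}

# Markers that flag infraspecific names; such records are rejected because
# the analysis works at species rank and above.
.infraspecific_markers <- c(" var\\.", " subsp\\.", " ssp\\.", " f\\.",
                            " forma ", " cv\\.")

#' Load a floristic taxon table
#'
#' Reads a checklist CSV with columns `species,genus,family,element` plus one
#' binary presence column per region, applies the synonym map, and merges
#' rows that resolve to the same accepted species by OR-ing their presence
#' flags. Element codes outside `vocabulary` are set to `"UNKNOWN"` with a
#' warning; names carrying infraspecific markers (var., subsp., ...) are
#' rejected.
#'
#' @param file Path to the CSV, or a data frame with the same columns.
#' @param synonyms Optional `"synonym_map"`.
#' @param vocabulary Optional element vocabulary (see
#'   [element_vocabulary()]); codes outside it become `"UNKNOWN"`.
#' @return A data frame of class `"taxon_table"` with attributes `regions`
#'   (region column names) and `merged` (accepted names that absorbed
#'   synonyms).
#' @export
load_taxon_table <- function(file, synonyms = NULL, vocabulary = NULL) {
  df <- if (is.data.frame(file)) file else
    utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "genus", "family", "element")
  if (!all(need %in% names(df)))
    stop("taxon table needs columns: ", paste(need, collapse = ", "))
  regions <- setdiff(names(df), need)
  if (!length(regions)) stop("taxon table has no region columns")

  bad_rank <- grepl(paste(.infraspecific_markers, collapse = "|"), df$species)
  if (any(bad_rank))
    stop("infraspecific names are not modelled; offending rows: ",
         paste(which(bad_rank), collapse = ", "))
  if (any(!nzchar(df$genus) | is.na(df$genus)))
    stop("empty genus in row(s): ",
         paste(which(!nzchar(df$genus) | is.na(df$genus)), collapse = ", "))
  if (any(!nzchar(df$family) | is.na(df$family)))
    stop("empty family in row(s): ",
         paste(which(!nzchar(df$family) | is.na(df$family)), collapse = ", "))
  pres <- as.matrix(df[regions])
  if (!all(pres %in% c(0, 1)))
    stop("presence cells must be 0 or 1")
  storage.mode(pres) <- "integer"

  df$species <- apply_synonyms(df$species, synonyms)
  df$element[is.na(df$element) | !nzchar(df$element)] <- "UNKNOWN"
  if (!is.null(vocabulary)) {
    ok <- df$element %in% c(vocabulary$code, "UNKNOWN")
    if (any(!ok)) {
      warning(sum(!ok), " taxa with element codes outside the vocabulary ",
              "set to UNKNOWN: ",
              paste(unique(df$element[!ok]), collapse = ", "))
      df$element[!ok] <- "UNKNOWN"
    }
  }

  merged <- character()
  if (anyDuplicated(df$species)) {
    merged <- unique(df$species[duplicated(df$species)])
    keep <- !duplicated(df$species)
    for (sp in merged) {
      rows <- df$species == sp
      pres[which(rows)[1L], ] <- as.integer(colSums(pres[rows, , drop = FALSE]) > 0)
    }
    df <- df[keep, , drop = FALSE]
    pres <- pres[keep, , drop = FALSE]
    message("merged ", length(merged), " duplicate accepted name(s): ",
            paste(merged, collapse = ", "))
  }
  df[regions] <- as.data.frame(pres)
  rownames(df) <- NULL
  structure(df, regions = regions, merged = merged,
            class = c("taxon_table", "data.frame"))
}

#' Region column names of a taxon table
#' @param table A `"taxon_table"`.
#' @return Character vector.
#' @export
regions_of <- function(table) {
  attr(table, "regions") %||%
    setdiff(names(table), c("species", "genus", "family", "element"))
}

#' Build a regions x taxa presence/absence matrix at a rank
#'
#' At genus or family rank a taxon is present in a region iff at least one
#' constituent species is. Taxa absent from every region are dropped with a
#' warning (they cannot affect any metric). Columns are ordered
#' lexicographically; rows keep the input region order.
#'
#' @param table A `"taxon_table"`.
#' @param rank One of `"species"`, `"genus"`, `"family"`.
#' @return Binary integer matrix (regions x taxa) with attribute `rank`.
#' @export
build_flora_matrix <- function(table, rank = c("species", "genus", "family")) {
  rank <- match.arg(rank)
  regions <- regions_of(table)
  pres <- t(as.matrix(table[regions]))  # regions x species
  colnames(pres) <- table$species
  if (rank != "species") {
    grp <- table[[rank]]
    agg <- vapply(sort(unique(grp)), function(g) {
      as.integer(rowSums(pres[, grp == g, drop = FALSE]) > 0)
    }, integer(length(regions)))
    if (length(regions) == 1L) agg <- matrix(agg, nrow = 1L,
                                             dimnames = list(regions, sort(unique(grp))))
    pres <- agg
    rownames(pres) <- regions
  } else {
    pres <- pres[, order(colnames(pres)), drop = FALSE]
  }
  empty <- colSums(pres) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " taxa present in no region: ",
            paste(colnames(pres)[empty], collapse = ", "))
    pres <- pres[, !empty, drop = FALSE]
  }
  storage.mode(pres) <- "integer"
  structure(pres, rank = rank)
}

#' Taxa present in one region of a flora matrix
#' @param matrix A flora matrix from [build_flora_matrix()].
#' @param region Region name or row index.
#' @return Character vector of taxa.
#' @export
region_taxa <- function(matrix, region) {
  colnames(matrix)[matrix[region, ] == 1L]
}
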