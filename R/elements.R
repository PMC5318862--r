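# Geographical distribution elements: vocabulary and taxon partitioning.

# Genus-level element codes with their tropical/temperate super-group
# membership. COSM (cosmopolitan) belongs to neither super-group; ESHD is
# retained as an inert legacy code with no super-group.
.genus_elements <- data.frame(
  code = c("COSM", "PT", "TATAD", "OWT", "TATA", "TATAF", "TA",
           "NT", "EANAD", "OWTE", "TEA", "MWACA", "CA", "EA", "EC", "ESHD"),
  description = c(
    "cosmopolitan",
    "pantropic",
    "tropical Asia and tropical America disjointed",
    "old world tropic",
    "tropical Asia to tropical Australia",
    "tropical Asia to tropical Africa",
    "tropical Asia",
    "north temperate",
    "east Asia and North America disjointed",
    "old world temperate",
    "temperate Asia",
    "Mediterranean, west Asia to center Asia",
    "center Asia",
    "east Asia",
    "endemic to China",
    "unassigned legacy code"),
  supergroup = c("", rep("tropical", 6L), rep("temperate", 8L), ""),
  stringsAsFactors = FALSE)

#' Geographical-element vocabulary
#'
#' The genus-level vocabulary carries the 15 distribution types standard in
#' Chinese floristics (plus the inert legacy code ESHD), grouped into
#' tropical and temperate super-groups; cosmopolitan belongs to neither.
#' The family-level vocabulary is a synthetic placeholder built from the
#' same codes — family-level element typologies vary between floras — and is
#' meant to be overridden via [read_element_vocabulary()] for real data.
#'
#' @param rank `"genus"` or `"family"`.
#' @return Data frame of class `"element_vocabulary"` with columns `rank`,
#'   `code`, `description`, `supergroup`.
#' @export
element_vocabulary <- function(rank = c("genus", "family")) {
  rank <- match.arg(rank)
  v <- .genus_elements
  if (rank == "family") {
    # placeholder family set: the 13 broadest codes of the genus vocabulary
    v <- v[!v$code %in% c("MWACA", "EC", "ESHD"), , drop = FALSE]
  }
  structure(cbind(data.frame(rank = rank), v, row.names = NULL),
            class = c("element_vocabulary", "data.frame"))
}

#' Read an element vocabulary from CSV
#'
#' @param file CSV with columns `rank`, `code`, `description`, `supergroup`
#'   (supergroup one of `"tropical"`, `"temperate"`, `""`).
#' @return An `"element_vocabulary"` data frame.
#' @export
read_element_vocabulary <- function(file) {
  v <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("rank", "code", "description", "supergroup")
  if (!all(need %in% names(v)))
    stop("vocabulary CSV needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(v[c("rank", "code")]))
    stop("duplicated element codes within a rank")
  v$supergroup[is.na(v$supergroup)] <- ""
  structure(v, class = c("element_vocabulary", "data.frame"))
}

#' Names of the analysis groups defined by a vocabulary
#'
#' @param vocab An `"element_vocabulary"`.
#' @return Character vector: `"ALL TAXA"`, `"ALL TRO"`, `"ALL TEM"` and the
#'   base codes.
#' @export
element_groups <- function(vocab) {
  c("ALL TAXA", "ALL TRO", "ALL TEM", vocab$code)
}

#' Taxa belonging to a geographical-element group
#'
#' `group` may be a base code, `"ALL TRO"` (union of tropical codes),
#' `"ALL TEM"` (union of temperate codes), or `"ALL TAXA"` (all taxa
#' regardless of element, including uncoded ones). For any group other
#' than `"ALL TAXA"`, taxa with element `"UNKNOWN"` are never returned,
#' mirroring the exclusion of taxa with unclear distribution patterns;
#' their count is reported via a message.
#'
#' @param table A `"taxon_table"`.
#' @param vocab An `"element_vocabulary"`.
#' @param group Group name.
#' @return Character vector of species names.
#' @export
partition_by_element <- function(table, vocab, group) {
  if (identical(group, "ALL TAXA")) return(table$species)
  codes <- switch(group,
    "ALL TRO" = vocab$code[vocab$supergroup == "tropical"],
    "ALL TEM" = vocab$code[vocab$supergroup == "temperate"],
    {
      if (!group %in% vocab$code)
        stop("unknown element group '", group, "'; valid groups: ",
             paste(element_groups(vocab), collapse = ", "))
      group
    })
  n_unknown <- sum(table$element == "UNKNOWN")
  if (n_unknown)
    message(n_unknown, " taxa with unknown element excluded from group '",
            group, "'")
  table$species[table$element %in% codes]
}
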