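# Taxonomic standardisation against offline lookup sources, the majority-vote
# consensus list, record annotation, and per-cell richness deltas of each
# source against the consensus.

.rank_markers <- c("subsp.", "ssp.", "var.", "f.", "fo.", "forma", "subvar.",
                   "cf.", "aff.", "subsp", "ssp", "var")

#' Normalise a scientific name to a binomial
#'
#' Strips authorship strings, infraspecific epithets and rank markers
#' (subsp., var., f., ...), collapses whitespace, and canonicalises case
#' (Genus capitalised, epithet lower-case). Uninomials are returned
#' unchanged apart from whitespace collapsing and are flagged.
#'
#' @param x character vector of raw names.
#' @return Character vector of binomials, with a logical attribute
#'   `uninomial` marking inputs that had no usable specific epithet.
#' @export
#' @examples
#' normalise_name("Bryum argenteum var. lanatum (P.Beauv.) Hampe")
normalise_name <- function(x) {
  x0 <- gsub("\\s+", " ", trimws(x))
  out <- character(length(x0))
  uni <- logical(length(x0))
  for (i in seq_along(x0)) {
    if (is.na(x0[i]) || x0[i] == "") {
      out[i] <- NA_character_
      uni[i] <- TRUE
      next
    }
    tok <- strsplit(x0[i], " ", fixed = TRUE)[[1]]
    genus <- paste0(toupper(substr(tok[1], 1, 1)),
                    tolower(substr(tok[1], 2, nchar(tok[1]))))
    ep <- if (length(tok) >= 2) tok[2] else ""
    ok_ep <- nzchar(ep) && grepl("^[A-Za-z-]+$", ep) &&
      !(tolower(ep) %in% .rank_markers)
    if (ok_ep) {
      out[i] <- paste(genus, tolower(ep))
    } else {
      out[i] <- x0[i]
      uni[i] <- TRUE
    }
  }
  attr(out, "uninomial") <- uni
  out
}

#' Standardise raw names against one lookup source
#'
#' Exact match on the normalised binomial first; if the lookup's policy is
#' fuzzy, unmatched names are matched to the nearest entry within the
#' maximum edit distance, with distance ties left `unresolved`. Names absent
#' from the lookup get status `no_match`.
#'
#' @param raw_names character vector of raw names.
#' @param lookup a [taxon_lookup()].
#' @return Tibble with `raw_name`, `raw_norm`, `accepted_name`, `status`,
#'   one row per unique input name.
#' @export
standardise <- function(raw_names, lookup) {
  stopifnot(inherits(lookup, "taxon_lookup"))
  res <- tibble::tibble(raw_name = unique(raw_names))
  res$raw_norm <- as.character(normalise_name(res$raw_name))
  ent <- lookup$entries[c("raw_norm", "accepted_name", "status")]
  res <- dplyr::left_join(res, ent, by = "raw_norm")
  miss <- is.na(res$status)
  res$status[miss] <- "no_match"
  if (lookup$match_policy == "fuzzy" && any(miss)) {
    keys <- ent$raw_norm
    for (i in which(miss)) {
      d <- utils::adist(res$raw_norm[i], keys)[1, ]
      dmin <- min(d)
      if (is.finite(dmin) && dmin <= lookup$max_distance) {
        hits <- unique(ent$accepted_name[d == dmin])
        if (length(hits) == 1 && !is.na(hits)) {
          res$accepted_name[i] <- hits
          res$status[i] <- "synonym"
        } else {
          res$status[i] <- "unresolved"
        }
      }
    }
  }
  res
}

#' Build the majority-vote consensus species list
#'
#' Each source votes for the accepted binomials it resolves (unresolved and
#' no_match rows carry no vote; two sources reaching the same accepted name
#' through different synonym paths still count as two votes). Names with at
#' least `min_votes` votes form the consensus.
#'
#' @param per_source_maps named list of standardisation maps (outputs of
#'   [standardise()]), one per source.
#' @param min_votes minimum number of endorsing sources (default 3).
#' @return A `consensus_list`: tibble of member names with their votes, plus
#'   the full vote table as attribute `votes_all`.
#' @export
build_consensus <- function(per_source_maps, min_votes = 3) {
  if (length(per_source_maps) < min_votes) {
    stop("fewer sources (", length(per_source_maps),
         ") than min_votes (", min_votes, ")", call. = FALSE)
  }
  sets <- lapply(per_source_maps, function(m) {
    unique(m$accepted_name[!is.na(m$accepted_name)])
  })
  votes <- table(unlist(sets))
  all_votes <- tibble::tibble(accepted_name = names(votes),
                              votes = as.integer(votes)) |>
    dplyr::arrange(.data$accepted_name)
  members <- dplyr::filter(all_votes, .data$votes >= min_votes)
  structure(members,
            votes_all = all_votes,
            min_votes = min_votes,
            n_sources = length(per_source_maps),
            class = c("consensus_list", class(members)))
}

.consensus_names <- function(consensus) consensus$accepted_name

# collapse standardisation maps to one row per normalised name per source
# (several raw spellings can normalise to the same binomial)
.norm_level_maps <- function(maps) {
  dplyr::bind_rows(lapply(maps, function(m) {
    dplyr::distinct(m[c("raw_norm", "accepted_name")])
  }))
}

#' Annotate records with the consensus accepted name
#'
#' A record is retained iff at least one source maps its raw name to a
#' consensus member; the final name is the consensus member chosen by the
#' most sources for that raw name (ties broken lexicographically and
#' flagged). Produces the consensus-standardised dataset.
#'
#' @param records canonical occurrence tibble.
#' @param per_source_maps named list of [standardise()] outputs.
#' @param consensus a [build_consensus()] result.
#' @return List with `records` (retained rows plus `acceptedName` and
#'   `name_tie` columns), `removed`, and a `report` tibble.
#' @export
apply_consensus <- function(records, per_source_maps, consensus) {
  cons <- .consensus_names(consensus)
  votes <- .norm_level_maps(per_source_maps) |>
    dplyr::filter(!is.na(.data$accepted_name),
                  .data$accepted_name %in% cons) |>
    dplyr::count(.data$raw_norm, .data$accepted_name, name = "n_sources") |>
    dplyr::arrange(.data$raw_norm, dplyr::desc(.data$n_sources),
                   .data$accepted_name)
  final <- votes |>
    dplyr::group_by(.data$raw_norm) |>
    dplyr::summarise(
      acceptedName = .data$accepted_name[1],
      name_tie = sum(.data$n_sources == .data$n_sources[1]) > 1,
      .groups = "drop")
  rn <- tibble::tibble(scientificName = records$scientificName)
  rn$raw_norm <- as.character(normalise_name(rn$scientificName))
  ann <- dplyr::left_join(rn, final, by = "raw_norm")
  keep <- !is.na(ann$acceptedName)
  kept <- records[keep, , drop = FALSE]
  kept$acceptedName <- ann$acceptedName[keep]
  kept$name_tie <- ann$name_tie[keep]
  list(records = kept,
       removed = records[!keep, , drop = FALSE],
       report = tibble::tibble(rule = "consensus_taxonomy",
                               n_in = nrow(records),
                               n_removed = sum(!keep),
                               n_kept = sum(keep)))
}

#' Annotate records under a single standardisation source
#'
#' Retains records whose raw name resolves to an accepted name in that
#' source; annotates them with `acceptedName`.
#'
#' @param records canonical occurrence tibble.
#' @param map a [standardise()] output for one source.
#' @return List with `records`, `removed` and `report`, as in
#'   [apply_consensus()].
#' @export
apply_source <- function(records, map) {
  rn <- tibble::tibble(raw_norm = as.character(normalise_name(records$scientificName)))
  ann <- dplyr::left_join(rn,
                          dplyr::distinct(map[c("raw_norm", "accepted_name")]),
                          by = "raw_norm")
  keep <- !is.na(ann$accepted_name)
  kept <- records[keep, , drop = FALSE]
  kept$acceptedName <- ann$accepted_name[keep]
  list(records = kept,
       removed = records[!keep, , drop = FALSE],
       report = tibble::tibble(rule = "source_taxonomy",
                               n_in = nrow(records),
                               n_removed = sum(!keep),
                               n_kept = sum(keep)))
}

#' Per-cell richness change of a source relative to the consensus
#'
#' For every grid cell, compares observed richness (distinct accepted names)
#' under one source's standardisation with the consensus standardisation and
#' classifies the cell as Increase / Decrease / Equal. Cells present in only
#' one dataset count richness 0 in the other.
#'
#' @param records_source cell-annotated records standardised by one source
#'   (must carry `cell_id`, `region`, `acceptedName`).
#' @param records_consensus cell-annotated consensus-standardised records.
#' @return List with `deltas` (cell_id, region, richness_source,
#'   richness_consensus, klass) and `proportions` (per region share of I/D/E
#'   cells, summing to 1).
#' @export
cell_richness_delta <- function(records_source, records_consensus) {
  rich <- function(x, nm) {
    dplyr::summarise(dplyr::group_by(x, .data$cell_id, .data$region),
                     "{nm}" := dplyr::n_distinct(.data$acceptedName),
                     .groups = "drop")
  }
  d <- dplyr::full_join(rich(records_source, "richness_source"),
                        rich(records_consensus, "richness_consensus"),
                        by = c("cell_id", "region")) |>
    dplyr::mutate(
      richness_source = dplyr::coalesce(.data$richness_source, 0L),
      richness_consensus = dplyr::coalesce(.data$richness_consensus, 0L),
      klass = dplyr::case_when(
        .data$richness_source > .data$richness_consensus ~ "I",
        .data$richness_source < .data$richness_consensus ~ "D",
        TRUE ~ "E"))
  props <- d |>
    dplyr::count(.data$region, .data$klass) |>
    dplyr::group_by(.data$region) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  list(deltas = d, proportions = props)
}
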