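# Quality control: removal of cross-source duplicates and flagging of
# records that fall significantly outside their species' known
# stratigraphic range (likely misidentification, contamination or
# reworking).

#' Remove cross-source duplicate records
#'
#' Records identical on the combination of species, numeric abundance,
#' sample depth and coordinates are duplicates introduced by overlapping
#' sources; exactly one survives, taken from the highest-priority source.
#' Numeric fields are compared to a tolerance of 1e-9 (values are rounded to
#' 9 decimals before matching) for float round-trip safety.
#'
#' @param records Occurrence tibble with harmonized abundances and
#'   coordinates.
#' @param source_priority Character vector of `db.source` values, highest
#'   priority first; sources not listed rank below all listed ones. Default
#'   order prefers compilation databases, then drilling-report extractions,
#'   then literature compilations -- override to taste.
#' @return List `records` (deduplicated, original order preserved) and
#'   `removed` (tibble `rowID`, `kept.rowID`, `db.source`, `kept.db.source`).
#' @export
drop_duplicates <- function(records, source_priority = character(0)) {
  records <- as_occurrences(records)
  rank <- match(records$db.source, source_priority)
  rank[is.na(rank)] <- length(source_priority) + 1L
  key <- paste(records$species,
               round(records$abundance, 9),
               round(records$sample.depth, 9),
               round(records$latitude, 9),
               round(records$longitude, 9), sep = "\r")
  ord <- order(rank, records$rowID)   # deterministic winner per key
  first <- !duplicated(key[ord])
  keep_idx <- sort(ord[first])
  kept_of <- ord[first][match(key, key[ord[first]])]
  removed_idx <- setdiff(seq_len(nrow(records)), keep_idx)
  removed <- tibble(
    rowID = records$rowID[removed_idx],
    kept.rowID = records$rowID[kept_of[removed_idx]],
    db.source = records$db.source[removed_idx],
    kept.db.source = records$db.source[kept_of[removed_idx]]
  )
  list(records = records[keep_idx, ], removed = removed)
}

#' Load a species stratigraphic-range table
#'
#' @param path_or_table CSV path or tibble with columns `species`,
#'   `speciation`, `extinction` (Ma; speciation is the older bound).
#' @return Validated tibble.
#' @export
load_species_ranges <- function(path_or_table) {
  rng <- if (is.character(path_or_table)) {
    readr::read_csv(path_or_table, col_types = "cdd", progress = FALSE,
                    show_col_types = FALSE)
  } else {
    as_tibble(path_or_table)
  }
  stopifnot(all(c("species", "speciation", "extinction") %in% names(rng)))
  if (any(rng$speciation < rng$extinction | rng$extinction < 0)) {
    stop("ranges must satisfy speciation >= extinction >= 0", call. = FALSE)
  }
  rng
}

#' Flag records falling significantly outside their species' range
#'
#' Records more than 2 Ma outside the species' known range in the Neogene
#' (record age < 23 Ma) or more than 5 Ma outside in the Paleogene are
#' flagged `trim = "exc"` (excluded if trimming is applied); all others are
#' `"inc"`. The looser Paleogene cut-off allows for the larger age-model
#' errors of older samples. Nothing is deleted: the flag lets users trim or
#' not. Species without a known range are kept `"inc"` and reported.
#'
#' @param records Occurrence tibble with ages and resolved species names.
#' @param ranges Range table from [load_species_ranges()].
#' @param neogene_tol,paleogene_tol Ma outside the range tolerated before a
#'   record is flagged; defaults 2 and 5.
#' @param boundary Neogene/Paleogene boundary age keying the tolerance to
#'   the record's age; default 23 Ma (ages < 23 use the Neogene rule).
#' @return List `records` (with `trim` set) and `unknown_species`
#'   (character).
#' @export
flag_trim <- function(records, ranges, neogene_tol = 2, paleogene_tol = 5,
                      boundary = 23) {
  records <- as_occurrences(records)
  idx <- match(records$species, ranges$species)
  speciation <- ranges$speciation[idx]
  extinction <- ranges$extinction[idx]
  tol <- ifelse(records$age < boundary, neogene_tol, paleogene_tol)
  out <- records$age > speciation + tol | records$age < extinction - tol
  records$trim <- ifelse(!is.na(out) & out, "exc", "inc")
  records$trim[is.na(records$age)] <- NA_character_
  list(records = records,
       unknown_species = sort(unique(records$species[is.na(idx) &
                                                       !is.na(records$species)])))
}
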