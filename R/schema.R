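#' @importFrom rlang .data %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number across all_of n_distinct
#' @importFrom tibble tibble as_tibble
NULL

# Column order of the harmonized occurrence dataset. One row per species per
# sample depth per hole; metadata grouped as source / taxon / abundance /
# chronology / geography / drilling / sampling.
.occ_character_cols <- c(
  "rowID", "db.source", "db.ID", "holeID", "sampleID", "person", "date",
  "species", "orig.species", "orig.abundance", "abun.units",
  "age.calc", "zone", "mag.zone", "age.model", "AM.type",
  "leg", "site", "hole", "core", "section",
  "reason", "sample.type", "processing", "preservation", "trim"
)

.occ_numeric_cols <- c(
  "abundance", "total.IDd", "num.ind", "rel.abun",
  "sample.depth", "age", "age.err", "segment",
  "zon.age", "age.st", "age.en", "rng.age",
  "int.age", "err.int.age",
  "mag.age", "mag.age.st", "mag.age.en", "int.mag.age", "err.int.mag.age",
  "mod.age", "r2", "n.pts",
  "latitude", "longitude", "water.depth", "pal.lat", "pal.long",
  "sample.top"
)

#' Column names of the harmonized occurrence schema
#'
#' Returns the full, ordered column set of the harmonized occurrence record:
#' one row per species per sample depth per hole, with source identifiers,
#' original and numeric abundances, age-model outputs, modern and
#' paleo-coordinates, drilling metadata and the range-trim flag.
#'
#' @return Character vector of column names in serialization order.
#' @export
occurrence_columns <- function() {
  c(
    "rowID", "db.source", "db.ID", "holeID", "sampleID", "person", "date",
    "species", "orig.species", "orig.abundance", "abundance", "abun.units",
    "total.IDd", "num.ind", "rel.abun",
    "sample.depth", "age", "age.err", "segment", "age.calc",
    "zone", "zon.age", "age.st", "age.en", "rng.age",
    "int.age", "err.int.age",
    "mag.zone", "mag.age", "mag.age.st", "mag.age.en",
    "int.mag.age", "err.int.mag.age",
    "mod.age", "r2", "n.pts", "age.model", "AM.type",
    "latitude", "longitude", "water.depth", "pal.lat", "pal.long",
    "leg", "site", "hole", "core", "section", "sample.top",
    "reason", "sample.type", "processing", "preservation", "trim"
  )
}

#' An empty occurrence table
#'
#' @return A zero-row tibble with every schema column, correctly typed.
#' @export
empty_occurrences <- function() {
  cols <- occurrence_columns()
  out <- lapply(cols, function(cl) {
    if (cl %in% .occ_numeric_cols) numeric(0) else character(0)
  })
  names(out) <- cols
  as_tibble(out)
}

#' Coerce a data frame to the occurrence schema
#'
#' Adds any missing schema columns (filled with `NA`), coerces numeric
#' columns, drops nothing, and orders columns canonically. Extra columns are
#' an error so that typos in upstream mappings surface early.
#'
#' @param x A data frame holding (a subset of) the schema columns.
#' @return A tibble with the full schema column set in canonical order.
#' @export
as_occurrences <- function(x) {
  x <- as_tibble(x)
  extra <- setdiff(names(x), occurrence_columns())
  if (length(extra) > 0) {
    stop("unknown occurrence columns: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  for (cl in setdiff(occurrence_columns(), names(x))) {
    x[[cl]] <- if (cl %in% .occ_numeric_cols) NA_real_ else NA_character_
  }
  for (cl in .occ_numeric_cols) x[[cl]] <- as.numeric(x[[cl]])
  for (cl in .occ_character_cols) x[[cl]] <- as.character(x[[cl]])
  x[, occurrence_columns()]
}

#' Check schema invariants of an occurrence table
#'
#' Verifies coordinate bounds, the Cenozoic age window (0--66 Ma), relative
#' abundances in 0--100, non-negative abundances and rowID uniqueness.
#'
#' @param records Occurrence tibble.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
check_occurrences <- function(records) {
  records <- as_occurrences(records)
  bad <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) stop(msg, call. = FALSE)
  }
  for (cl in c("latitude", "pal.lat")) {
    bad(records[[cl]] < -90 | records[[cl]] > 90, paste(cl, "outside [-90, 90]"))
  }
  for (cl in c("longitude", "pal.long")) {
    bad(records[[cl]] <= -180 | records[[cl]] > 180, paste(cl, "outside (-180, 180]"))
  }
  bad(records$age < 0 | records$age > 66, "age outside the Cenozoic (0-66 Ma)")
  bad(records$rel.abun < 0 | records$rel.abun > 100, "rel.abun outside [0, 100]")
  bad(records$abundance < 0, "negative abundance")
  ids <- records$rowID[!is.na(records$rowID)]
  if (anyDuplicated(ids)) stop("duplicate rowID", call. = FALSE)
  invisible(TRUE)
}

#' Read one source table into raw occurrence records
#'
#' Sources serve their records in different layouts; a per-source mapping
#' names which columns hold species, abundance, depth and metadata, and this
#' reader reshapes everything to the long one-row-per-species-per-sample
#' form. Unmapped metadata is set to `NA`.
#'
#' @param path Delimited text file (comma- or tab-separated).
#' @param mapping A list (typically read from YAML via [read_source_config()])
#'   with elements:
#'   \describe{
#'     \item{format}{`"long"` (one row per species per sample) or `"wide"`
#'       (one row per sample, one column per species).}
#'     \item{species, abundance}{column names, `format = "long"` only.}
#'     \item{species_columns}{`format = "wide"` only: the species columns;
#'       defaults to every column not otherwise mapped.}
#'     \item{depth}{sample-depth column (mbsf), or `NULL` when the source has
#'       no depth.}
#'     \item{sample}{optional sample-label column; defaults to the depth.}
#'     \item{metadata}{optional named list mapping schema columns (e.g.
#'       `latitude`, `water.depth`, `age`) to source columns.}
#'     \item{constants}{optional named list of fixed schema values (e.g.
#'       `db.source`, `holeID`, `latitude`).}
#'   }
#' @return A tibble of raw records in the occurrence schema; `orig.species`
#'   and `orig.abundance` carry the source values verbatim. Empty abundance
#'   cells of wide tables are not emitted.
#' @export
read_occurrence_table <- function(path, mapping) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  ingest_table(raw, mapping)
}

#' @rdname read_occurrence_table
#' @param table A data frame already in the source's layout (the in-memory
#'   equivalent of the file at `path`).
#' @export
ingest_table <- function(table, mapping) {
  raw <- as_tibble(table)
  raw <- mutate(raw, across(dplyr::everything(), as.character))
  fmt <- mapping$format %||% "long"
  mapped_cols <- unlist(c(
    mapping[c("species", "abundance", "depth", "sample")],
    mapping$metadata
  ), use.names = FALSE)
  missing_cols <- setdiff(mapped_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("mapping names missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  if (fmt == "wide") {
    sp_cols <- mapping$species_columns %||% setdiff(names(raw), mapped_cols)
    missing_sp <- setdiff(sp_cols, names(raw))
    if (length(missing_sp) > 0) {
      stop("mapping names missing column(s): ", paste(missing_sp, collapse = ", "),
           call. = FALSE)
    }
    long <- tidyr::pivot_longer(raw, cols = all_of(sp_cols),
                                names_to = ".species", values_to = ".abundance")
    long <- filter(long, !is.na(.data$.abundance), .data$.abundance != "")
  } else {
    long <- raw
    long$.species <- raw[[mapping$species]]
    long$.abundance <- raw[[mapping$abundance]]
  }

  out <- tibble(
    orig.species = as.character(long$.species),
    species = as.character(long$.species),
    orig.abundance = as.character(long$.abundance)
  )
  out$sample.depth <- if (!is.null(mapping$depth)) {
    as.numeric(long[[mapping$depth]])
  } else NA_real_
  out$sampleID <- if (!is.null(mapping$sample)) {
    as.character(long[[mapping$sample]])
  } else if (!is.null(mapping$depth)) {
    as.character(long[[mapping$depth]])
  } else NA_character_
  for (schema_col in names(mapping$metadata %||% list())) {
    out[[schema_col]] <- long[[mapping$metadata[[schema_col]]]]
  }
  for (schema_col in names(mapping$constants %||% list())) {
    out[[schema_col]] <- as.character(mapping$constants[[schema_col]])
  }
  as_occurrences(out)
}

#' Read a per-source ingestion config
#'
#' @param path YAML file whose top level is `sources:`, a named list of
#'   per-source mappings (see [read_occurrence_table()]); each entry may also
#'   carry `path:` pointing at its data file.
#' @return The parsed list.
#' @export
read_source_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Drop records missing crucial columns
#'
#' Records missing any of the four crucial columns -- species name, numeric
#' abundance, age, and paleocoordinates -- cannot support spatiotemporal
#' analyses and are removed. Each rejected record carries exactly one primary
#' reason, the first failing rule in the order species, abundance, age,
#' paleocoordinates.
#'
#' @param records Occurrence tibble (after all upstream stages, so age and
#'   paleocoordinates are populated where possible).
#' @return A list with `clean` (records passing all rules), `rejected`
#'   (tibble of `rowID`, `reason`), and `report` (per-status counts).
#' @export
validate_and_filter <- function(records) {
  records <- as_occurrences(records)
  reason <- rep(NA_character_, nrow(records))
  miss <- function(x) is.na(x) | (is.character(x) & x == "")
  rules <- list(
    "missing species"          = miss(records$species),
    "missing abundance"        = miss(records$abundance),
    "missing age"              = miss(records$age),
    "missing paleocoordinates" = miss(records$pal.lat) | miss(records$pal.long)
  )
  for (nm in names(rules)) {
    reason[is.na(reason) & rules[[nm]]] <- nm
  }
  keep <- is.na(reason)
  rejected <- tibble(rowID = records$rowID[!keep], reason = reason[!keep])
  report <- dplyr::count(
    bind_rows(tibble(reason = "retained")[rep(1, sum(keep)), ], rejected["reason"]),
    .data$reason, name = "records"
  )
  list(clean = records[keep, ], rejected = rejected, report = report)
}

#' Assign deterministic hole, sample and row identifiers
#'
#' Records are sorted by (`holeID`, `sample.depth`, `species`) so that IDs
#' are stable across re-runs on identical input. Each sample receives
#' `sampleID = holeID + "_" + sample number`; each row receives
#' `rowID = db.ID + "_" + sampleID + "_" + row number`, the row number being
#' unique within its sample.
#'
#' @param records Occurrence tibble; `holeID` may be absent, in which case it
#'   is built from `db.source`, `site` and `hole`.
#' @param registry Optional tibble (`db.source`, `dataset`, `db.ID`) mapping
#'   source/dataset pairs to database IDs; when `NULL`, existing `db.ID`
#'   values are kept (missing ones default to the `db.source`).
#' @return Records with `holeID`, `sampleID`, `rowID` and `db.ID` populated,
#'   in deterministic order.
#' @export
assign_ids <- function(records, registry = NULL) {
  records <- as_occurrences(records)
  no_hole <- is.na(records$holeID)
  if (any(no_hole)) {
    built <- paste(records$db.source, records$site, records$hole, sep = "_")
    records$holeID[no_hole] <- gsub("_NA|NA_", "", built[no_hole])
  }
  if (!is.null(registry)) {
    key <- paste(records$db.source, records$db.ID, sep = "\r")
    rkey <- paste(registry$db.source, registry$dataset, sep = "\r")
    hit <- match(key, rkey)
    records$db.ID[!is.na(hit)] <- registry$db.ID[hit[!is.na(hit)]]
  }
  records$db.ID[is.na(records$db.ID)] <- records$db.source[is.na(records$db.ID)]
  records <- arrange(records, .data$holeID, .data$sample.depth, .data$species)
  sample_key <- paste(records$holeID, records$sample.depth, records$sampleID, sep = "\r")
  records <- records |>
    group_by(.data$holeID) |>
    mutate(.snum = match(sample_key[dplyr::cur_group_rows()],
                         unique(sample_key[dplyr::cur_group_rows()]))) |>
    ungroup() |>
    mutate(sampleID = paste0(.data$holeID, "_", .data$.snum)) |>
    group_by(.data$sampleID) |>
    mutate(rowID = paste0(.data$db.ID, "_", .data$sampleID, "_", row_number())) |>
    ungroup() |>
    select(-".snum")
  if (anyDuplicated(records$rowID)) {
    stop("rowID collision after assignment; ordering is not deterministic",
         call. = FALSE)
  }
  records
}

#' Write / read the harmonized occurrence dataset
#'
#' Serialization is UTF-8 CSV with the documented column order, `NA` for
#' absent values and `.` as decimal separator; `read_occurrences()` inverts
#' it losslessly.
#'
#' @param records Occurrence tibble.
#' @param path Output CSV path.
#' @return `write_occurrences()` returns `path` invisibly;
#'   `read_occurrences()` returns the occurrence tibble.
#' @export
write_occurrences <- function(records, path) {
  records <- as_occurrences(records)
  readr::write_csv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  spec <- lapply(occurrence_columns(), function(cl) {
    if (cl %in% .occ_numeric_cols) readr::col_double() else readr::col_character()
  })
  names(spec) <- occurrence_columns()
  as_occurrences(readr::read_csv(path, col_types = do.call(readr::cols, spec),
                                 na = "NA", progress = FALSE, show_col_types = FALSE))
}
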