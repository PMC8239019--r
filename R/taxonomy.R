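# Taxonomic harmonization: raw name cleaning, synonym resolution against a
# curated synonymy list, and merging of rows that resolve to one senior name.

.synonymy_statuses <- c("valid", "junior synonym", "typo", "invalid",
                        "Mesozoic-only", "not-species-level")
.accepting_statuses <- c("valid", "junior synonym", "typo")

#' Normalize raw species names
#'
#' Trims and collapses whitespace and case-normalizes to a capitalized genus
#' plus lower-case epithet. Open-nomenclature qualifiers (`cf.`, `aff.`,
#' `?`, `sp.`, `spp.`) mark a name as imprecise: such records cannot be tied
#' to a single species concept and are flagged for rejection.
#'
#' @param raw Character vector of raw names.
#' @return A tibble with columns `raw`, `clean` (normalized binomial, `NA`
#'   when nothing remains after cleaning), and `qualified` (`TRUE` when an
#'   open-nomenclature qualifier or a genus-only name was detected).
#' @export
normalize_names <- function(raw) {
  clean <- gsub("\\s+", " ", trimws(as.character(raw)))
  qual_re <- "(^|\\s)(cf\\.?|aff\\.?|ex gr\\.?|sp{1,2}\\.?)(\\s|$)|\\?"
  qualified <- grepl(qual_re, clean, ignore.case = TRUE)
  clean <- tolower(clean)
  # capitalize genus only
  substr(clean, 1, 1) <- toupper(substr(clean, 1, 1))
  one_word <- !grepl(" ", clean)
  qualified <- qualified | (one_word & nchar(clean) > 0)
  clean[clean == ""] <- NA_character_
  tibble(raw = as.character(raw), clean = clean, qualified = qualified)
}

#' Load and check a synonymy table
#'
#' The synonymy maps every raw name that may appear in a source to its
#' senior synonym and a status. Checked invariants: resolution is a function
#' (one senior per raw name); senior names of accepted statuses (`valid`,
#' `junior synonym`, `typo`) occur in the valid-species list; a senior's
#' senior is itself (no chains or cycles).
#'
#' @param synonymy Tibble or CSV path with columns `raw`, `senior`, `status`.
#' @param valid_species Character vector (or single-column CSV path) of
#'   accepted species names.
#' @return A list of class `"synonymy_table"` with elements `table` and
#'   `valid_species`.
#' @export
load_synonymy <- function(synonymy, valid_species) {
  if (is.character(synonymy) && length(synonymy) == 1) {
    synonymy <- readr::read_csv(synonymy, col_types = "ccc", progress = FALSE,
                                show_col_types = FALSE)
  }
  synonymy <- as_tibble(synonymy)
  if (is.character(valid_species) && length(valid_species) == 1 &&
      file.exists(valid_species)) {
    valid_species <- readr::read_csv(valid_species, col_types = "c",
                                     progress = FALSE, show_col_types = FALSE)[[1]]
  }
  stopifnot(all(c("raw", "senior", "status") %in% names(synonymy)))
  bad_status <- setdiff(unique(synonymy$status), .synonymy_statuses)
  if (length(bad_status) > 0) {
    stop("unknown synonymy status: ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(synonymy$raw)) {
    dup <- synonymy$raw[duplicated(synonymy$raw)]
    stop("synonymy resolution is not a function; duplicated raw name(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  acc <- synonymy[synonymy$status %in% .accepting_statuses, ]
  missing_valid <- setdiff(acc$senior, valid_species)
  if (length(missing_valid) > 0) {
    stop("senior name(s) not in the valid-species list: ",
         paste(missing_valid, collapse = ", "), call. = FALSE)
  }
  # no chains: the senior of a listed senior must be itself
  idx <- match(acc$senior, synonymy$raw)
  chained <- !is.na(idx) & synonymy$senior[idx] != acc$senior
  if (any(chained)) {
    stop("synonymy chain detected for: ",
         paste(unique(acc$senior[chained]), collapse = ", "), call. = FALSE)
  }
  structure(list(table = synonymy, valid_species = valid_species),
            class = "synonymy_table")
}

#' Resolve names to their senior synonyms
#'
#' Accepted names (`valid`, `junior synonym`, `typo`) resolve to their senior
#' synonym; exclusively Mesozoic, invalid and not-species-level entries are
#' rejected with their status; names absent from the synonymy are rejected as
#' `"unknown name"` and surfaced for curation. Qualified (open-nomenclature)
#' names are rejected as `"not-species-level"` before lookup.
#'
#' @param names Character vector of raw names.
#' @param synonymy A `"synonymy_table"` from [load_synonymy()].
#' @return A tibble `raw`, `senior` (`NA` when rejected), `status`,
#'   `accepted`.
#' @export
resolve_names <- function(names, synonymy) {
  stopifnot(inherits(synonymy, "synonymy_table"))
  norm <- normalize_names(names)
  idx <- match(norm$clean, synonymy$table$raw)
  status <- synonymy$table$status[idx]
  senior <- synonymy$table$senior[idx]
  status[is.na(idx)] <- "unknown name"
  status[norm$qualified] <- "not-species-level"
  accepted <- status %in% .accepting_statuses
  senior[!accepted] <- NA_character_
  tibble(raw = norm$raw, senior = senior, status = status, accepted = accepted)
}

#' Curation log of unresolvable names
#'
#' @param resolved Output of [resolve_names()].
#' @return Tibble of distinct rejected names with status and record counts.
#' @export
curation_log <- function(resolved) {
  resolved |>
    filter(!.data$accepted) |>
    dplyr::count(.data$raw, .data$status, name = "records") |>
    arrange(.data$status, .data$raw)
}

#' Merge rows that resolve to the same senior synonym
#'
#' Within each sample, records whose names resolve to one senior synonym
#' collapse to a single row with their numeric abundances summed; for
#' presence/absence samples the merged abundance is set to one (present).
#' The original names and abundances are retained, comma-joined, in
#' `orig.species` / `orig.abundance`.
#'
#' @param records Occurrence tibble with `species` already resolved to senior
#'   names and `abundance` numeric.
#' @return Merged occurrence tibble, one row per (sample, senior name).
#' @export
merge_synonym_rows <- function(records) {
  records <- as_occurrences(records)
  mixed <- records |>
    group_by(.data$db.source, .data$db.ID, .data$holeID, .data$sampleID) |>
    summarise(k = n_distinct(.data$abun.units), .groups = "drop") |>
    filter(.data$k > 1)
  if (nrow(mixed) > 0) {
    stop("mixed abundance units within sample(s): ",
         paste(mixed$sampleID, collapse = ", "), call. = FALSE)
  }
  first_or_na <- function(x) if (length(x) == 0) NA else x[[1]]
  records |>
    arrange(.data$sampleID, .data$species, .data$orig.species) |>
    group_by(.data$db.source, .data$db.ID, .data$holeID, .data$sampleID,
             .data$species) |>
    summarise(
      orig.species = paste(.data$orig.species, collapse = ", "),
      orig.abundance = paste(.data$orig.abundance, collapse = ", "),
      abundance = if (first_or_na(.data$abun.units) %in% "P/A") {
        as.numeric(any(.data$abundance > 0))
      } else {
        sum(.data$abundance)
      },
      across(!all_of(c("orig.species", "orig.abundance", "abundance", "rowID")),
             first_or_na),
      .groups = "drop"
    ) |>
    as_occurrences()
}
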