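# End-to-end orchestration: ingest heterogeneous sources, harmonize
# taxonomy and abundance, derive tie points, fit age models, assign ages,
# rotate to paleocoordinates, deduplicate, trim-flag, and filter.

#' Harmonize abundances of ingested records
#'
#' Per source dataset and sample: classifies the abundance encoding, maps
#' raw values to numeric abundances (with the per-dataset vocabulary), and
#' computes specimen totals and relative percent abundances. Unclassifiable
#' samples are quarantined.
#'
#' @param records Raw occurrence tibble (from [read_occurrence_table()] /
#'   [ingest_table()]).
#' @param overrides Optional vocabulary-override tibble
#'   ([read_vocabulary_overrides()]).
#' @return List `records` (with `abundance`, `abun.units`, `num.ind`,
#'   `rel.abun` filled) and `quarantined` (tibble of sample keys).
#' @export
harmonize_abundance <- function(records, overrides = NULL) {
  records <- as_occurrences(records)
  key <- paste(records$db.source, records$db.ID, records$holeID,
               records$sampleID, sep = "\r")
  quarantined <- character(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    vocab <- dataset_vocabulary(records$db.ID[idx[1]], overrides)
    cls <- classify_units(records$orig.abundance[idx], vocab)
    if (is.na(cls$units)) {
      quarantined <- c(quarantined, k)
      next
    }
    records$abun.units[idx] <- cls$units
    records$abundance[idx] <- to_numeric(records$orig.abundance[idx],
                                         cls$units, vocab, cls$inconsistent)
  }
  keep <- !(key %in% quarantined)
  out <- relative_abundance(records[keep, ])
  list(records = out,
       quarantined = tibble(sample = unique(quarantined)))
}

#' Derive tie points for one hole from its occurrence records
#'
#' Scores each marker event's taxon as present/absent down the hole's
#' sampled depths and places a tie point at the midpoint of the bracketing
#' sample pair ([tie_from_occurrences()]); adds the 0 Ma seafloor tie when
#' the surface is declared Holocene/Recent/Modern.
#'
#' Raw first/last occurrences in shipboard-style data do not always
#' represent true datums: isolated single-sample occurrences are typically
#' reworked grains or misidentifications. Presences are therefore cleaned
#' before picking transitions: only runs of at least `min_run` consecutive
#' sampled depths count as genuine occupancy (reworked grains can appear in
#' adjacent samples, so the default demands three).
#'
#' @param records Occurrence records of one hole (numeric abundances).
#' @param events An `"event_table"`.
#' @param region Calibration region of the site (from [assign_region()]).
#' @param surface_age_class Declared surface age class or `NA`.
#' @param min_run Minimum consecutive-sample presence run used for datum
#'   picking; default 3.
#' @return Tie-point tibble (possibly zero rows).
#' @export
derive_tiepoints <- function(records, events, region = "global",
                             surface_age_class = NA_character_,
                             min_run = 3) {
  depths <- sort(unique(records$sample.depth))
  clean_presence <- function(present) {
    if (min_run <= 1) return(present)
    r <- rle(present)
    r$values[r$values & r$lengths < min_run] <- FALSE
    inverse.rle(r)
  }
  ties <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- calibrate_event(paste(switch(events$event.type[i],
                                       "first occurrence" = "B",
                                       "last occurrence" = "T",
                                       "B"),
                                events$taxon[i]),
                          scheme = events$scheme[i], region = region,
                          events = events)
    if (is.null(ev)) return(NULL)
    present <- clean_presence(depths %in% records$sample.depth[
      records$species == events$taxon[i] & records$abundance > 0])
    if (!any(present)) return(NULL)
    tie_from_occurrences(ev, depths, present)
  })
  sf <- add_seafloor_tie(surface_age_class)
  if (!is.null(sf)) ties <- bind_rows(sf, ties)
  ties
}

#' Run the full harmonization pipeline on a synthetic corpus
#'
#' Ingests every source in its own dialect, resolves taxonomy (the corpus
#' uses an identity synonymy over its species pool), harmonizes abundances,
#' assigns identifiers, derives tie points and fits a segmented age-depth
#' model per hole, assigns sample ages, reconstructs paleocoordinates,
#' removes cross-source duplicates, flags out-of-range records, and applies
#' the crucial-column filter.
#'
#' @param corpus A `"synthetic_corpus"` from [simulate_corpus()].
#' @param source_priority Source order for deduplication; the mirror source
#'   ranks last by default so originals are kept.
#' @param hiatus_frac Hiatus threshold for [segment_tiepoints()].
#' @return List: `records` (the clean, flagged dataset), `full` (including
#'   zero-abundance records, before filtering), `models` (per-hole
#'   `"age_depth_model"`), `dedup` (removed duplicates), `dropped_age`,
#'   `skipped_paleo`, `validation` (the filter report), `trim_unknown`.
#' @export
process_corpus <- function(corpus,
                           source_priority = c("src_wide-count",
                                               "src_long-binned",
                                               "src_long-PA", "mirror"),
                           hiatus_frac = 0.10) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  raw <- purrr::map_dfr(corpus$sources, function(src) {
    ingest_table(src$table, src$mapping)
  })
  # identity synonymy over the pool: every pool name is its own senior
  syn <- load_synonymy(
    tibble(raw = corpus$species_ranges$species,
           senior = corpus$species_ranges$species,
           status = "valid"),
    corpus$species_ranges$species
  )
  res <- resolve_names(raw$species, syn)
  raw$species <- res$senior
  raw <- raw[res$accepted, ]
  ab <- harmonize_abundance(raw)
  recs <- merge_synonym_rows(ab$records)
  recs <- relative_abundance(recs)
  recs <- assign_ids(recs)

  models <- list()
  dated <- list()
  dropped <- list()
  for (hid in unique(recs$holeID)) {
    hrecs <- recs[recs$holeID == hid, ]
    region <- assign_region(hrecs$latitude[1], hrecs$longitude[1])
    sac <- corpus$surface$surface.age.class[match(hid, corpus$surface$holeID)]
    ties <- derive_tiepoints(hrecs, corpus$events, region, sac)
    if (nrow(ties) < 1) {
      dropped[[hid]] <- tibble(rowID = hrecs$rowID, reason = "no tie points")
      next
    }
    model <- fit_age_depth_model(ties, holeID = hid, hiatus_frac = hiatus_frac)
    models[[hid]] <- model
    aa <- assign_ages(hrecs, model)
    dated[[hid]] <- aa$samples
    dropped[[hid]] <- aa$dropped
  }
  recs <- bind_rows(dated)
  dropped <- bind_rows(dropped)

  pc <- paleocoordinates(recs, corpus$rotation_table, corpus$plates)
  recs <- pc$records

  dd <- drop_duplicates(recs, source_priority)
  recs <- dd$records

  tr <- flag_trim(recs, corpus$species_ranges)
  recs <- tr$records

  split <- split_zero_abundance(recs)
  vf <- validate_and_filter(split$main)

  list(records = vf$clean, full = split$full, models = models,
       dedup = dd$removed, dropped_age = dropped,
       skipped_paleo = pc$skipped, validation = vf$report,
       trim_unknown = tr$unknown_species)
}
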