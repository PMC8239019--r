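# Chronology: marker events (biostratigraphic datums, magnetochron
# boundaries) calibrated to GTS 2020 ages, resolved per zonal scheme and
# region, and turned into depth-age tie points from occurrence data.

.event_types <- c("first occurrence", "last occurrence", "acme base",
                  "acme top", "magnetochron base", "magnetochron top")
.regions <- c("Atlantic-tropical", "Atlantic-temperate",
              "IndoPacific-tropical", "IndoPacific-temperate", "global")

#' Assign a site to a calibration region
#'
#' Marker-event ages can differ between ocean basins and between tropical
#' and temperate waters. Sites are classed Atlantic vs Indo-Pacific from
#' configurable longitude boundaries and tropical vs temperate with the
#' division at 23.5° latitude (inclusive: |lat| = 23.5 is tropical).
#'
#' @param latitude,longitude Decimal degrees.
#' @param atlantic_lon Two-element numeric, the longitudes bounding the
#'   Atlantic sector; default 70°W to 20°E.
#' @return Character vector of regions, e.g. `"Atlantic-tropical"`.
#' @export
assign_region <- function(latitude, longitude, atlantic_lon = c(-70, 20)) {
  stopifnot(all(abs(latitude) <= 90), all(longitude > -180 & longitude <= 180))
  basin <- ifelse(longitude >= atlantic_lon[1] & longitude < atlantic_lon[2],
                  "Atlantic", "IndoPacific")
  belt <- ifelse(abs(latitude) <= 23.5, "tropical", "temperate")
  paste(basin, belt, sep = "-")
}

#' Load a marker-event calibration table
#'
#' @param path_or_table CSV path or tibble with columns `taxon`, `event.type`,
#'   `scheme`, `region`, `age.st`, `age.en`, `AM.type` (ages in Ma on
#'   GTS 2020; `age.st` is the older bound). `scheme` may be `NA` for
#'   scheme-independent events; `region` `"global"` for basin-independent
#'   ages.
#' @return Validated tibble of class `"event_table"`. Contradictory duplicate
#'   keys (same taxon/type/scheme/region, different ages) are fatal.
#' @export
load_event_table <- function(path_or_table) {
  ev <- if (is.character(path_or_table)) {
    readr::read_csv(path_or_table, col_types = readr::cols(
      taxon = "c", event.type = "c", scheme = "c", region = "c",
      age.st = "d", age.en = "d", AM.type = "c"
    ), progress = FALSE, show_col_types = FALSE)
  } else {
    as_tibble(path_or_table)
  }
  stopifnot(all(c("taxon", "event.type", "region", "age.st", "age.en") %in% names(ev)))
  if (!"scheme" %in% names(ev)) ev$scheme <- NA_character_
  if (!"AM.type" %in% names(ev)) ev$AM.type <- NA_character_
  bad_type <- setdiff(unique(ev$event.type), .event_types)
  if (length(bad_type) > 0) {
    stop("unknown event type(s): ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (any(ev$age.st < ev$age.en | ev$age.en < 0)) {
    stop("event ages must satisfy age.st >= age.en >= 0", call. = FALSE)
  }
  key <- paste(ev$taxon, ev$event.type, ev$scheme, ev$region, sep = "\r")
  dups <- ev[key %in% key[duplicated(key)], ]
  if (nrow(dups) > 0) {
    contradictory <- dups |>
      group_by(.data$taxon, .data$event.type, .data$scheme, .data$region) |>
      summarise(k = n_distinct(paste(.data$age.st, .data$age.en)), .groups = "drop") |>
      filter(.data$k > 1)
    if (nrow(contradictory) > 0) {
      stop("contradictory duplicate event entries for: ",
           paste(contradictory$taxon, contradictory$event.type, sep = "/",
                 collapse = "; "), call. = FALSE)
    }
  }
  structure(ev, class = c("event_table", class(ev)))
}

# Event-label abbreviations. B/FO/FAD = base (first occurrence); T/LAD =
# top (last occurrence). LO and HO are ambiguous and resolved per study:
# a study listing both LO and HO reads LO = lowest occurrence (a base) and
# HO = highest; a study mixing FO with LO reads LO = last occurrence.
.parse_event_label <- function(label, study_labels = character(0)) {
  label <- trimws(label)
  m <- regmatches(label, regexec("^(B|T|FO|LO|HO|FAD|LAD|Base|Top)\\s+(.*)$", label,
                                 ignore.case = TRUE))[[1]]
  if (length(m) == 0) return(list(taxon = label, type = NA_character_))
  abbr <- toupper(m[2])
  taxon <- m[3]
  prefixes <- toupper(sub("\\s.*$", "", trimws(study_labels)))
  type <- switch(abbr,
    B = , FO = , FAD = , BASE = "first occurrence",
    T = , LAD = , TOP = "last occurrence",
    HO = "last occurrence",
    LO = if ("HO" %in% prefixes) "first occurrence" else "last occurrence",
    NA_character_
  )
  list(taxon = taxon, type = type)
}

#' Calibrate a raw event label to GTS 2020 ages
#'
#' Resolves an event label as used in a study (e.g. `"B M8"`, `"LO
#' Morozovella aragonensis"`) to its calibrated age interval, honouring the
#' zonal scheme the study used and the site's region. Region-specific
#' entries are preferred over global ones. Abbreviation ambiguity (LO =
#' lowest vs last occurrence) is settled from the study's full event list.
#' Unresolvable events return `NULL` so callers can drop them from the age
#' model.
#'
#' @param label Raw event label.
#' @param scheme Zonal scheme the study used (may be `NA`).
#' @param region Site region from [assign_region()].
#' @param events An `"event_table"`.
#' @param study_labels All event labels of the study, for LO/HO
#'   disambiguation.
#' @return A one-row tibble (`taxon`, `event.type`, `age.st`, `age.en`,
#'   `age`, `AM.type`) or `NULL` when unresolvable.
#' @export
calibrate_event <- function(label, scheme = NA, region = "global", events,
                            study_labels = character(0)) {
  stopifnot(inherits(events, "event_table"))
  parsed <- .parse_event_label(label, study_labels)
  hit <- events[events$taxon == parsed$taxon, , drop = FALSE]
  if (!is.na(parsed$type)) hit <- hit[hit$event.type == parsed$type, , drop = FALSE]
  if (!is.na(scheme)) {
    hit <- hit[is.na(hit$scheme) | hit$scheme == scheme, , drop = FALSE]
    # a scheme-specific entry beats a scheme-free one
    if (any(!is.na(hit$scheme))) hit <- hit[!is.na(hit$scheme), , drop = FALSE]
  } else {
    hit <- hit[is.na(hit$scheme), , drop = FALSE]
  }
  regional <- hit[hit$region == region, , drop = FALSE]
  if (nrow(regional) == 0) regional <- hit[hit$region == "global", , drop = FALSE]
  regional <- dplyr::distinct(regional, .data$taxon, .data$event.type,
                              .data$age.st, .data$age.en, .keep_all = TRUE)
  if (nrow(regional) != 1) return(NULL)
  tibble(
    taxon = regional$taxon, event.type = regional$event.type,
    age.st = regional$age.st, age.en = regional$age.en,
    age = (regional$age.st + regional$age.en) / 2,
    AM.type = regional$AM.type
  )
}

#' Build a tie point from presence/absence down a hole
#'
#' The true depth of a datum lies between the samples bracketing the
#' species' appearance or disappearance, so the tie depth is the midpoint of
#' that bracketing pair: for an extinction-type event (last occurrence,
#' acme top, magnetochron top), halfway between the shallowest sample with a
#' presence and the next sample upcore from which the species is absent; for
#' an origination-type event, the mirror image downcore. The tie age is the
#' event's age midpoint and the age range its calibrated width.
#'
#' @param event One-row tibble from [calibrate_event()].
#' @param depths Strictly increasing sample depths (mbsf).
#' @param present Logical vector, presence of the event taxon per depth.
#' @return One-row tibble (`depth`, `age`, `age.range`, `kind`, `taxon`,
#'   `event.type`) or `NULL` when the taxon has no bracket (present in every
#'   sample) -- such events carry no depth information.
#' @export
tie_from_occurrences <- function(event, depths, present) {
  stopifnot(!is.unsorted(depths, strictly = TRUE), length(depths) == length(present))
  if (!any(present)) return(NULL)
  if (all(present)) return(NULL)
  base_like <- event$event.type %in% c("first occurrence", "acme base",
                                       "magnetochron base")
  if (base_like) {
    # deepest presence vs its downcore absent neighbour; presence reaching
    # the hole bottom means the datum lies below the cored interval
    i <- max(which(present))
    if (i == length(depths)) return(NULL)
    pair <- depths[c(i, i + 1)]
  } else {
    # shallowest presence vs its upcore absent neighbour; presence reaching
    # the hole top means the datum lies above the cored interval
    i <- min(which(present))
    if (i == 1) return(NULL)
    pair <- depths[c(i - 1, i)]
  }
  kind <- if (grepl("magnetochron", event$event.type)) {
    "magnetostratigraphic"
  } else {
    "biostratigraphic"
  }
  tibble(
    depth = mean(pair),
    age = (event$age.st + event$age.en) / 2,
    age.range = event$age.st - event$age.en,
    kind = kind, taxon = event$taxon, event.type = event$event.type
  )
}

#' Seafloor tie point for holes with a declared modern surface
#'
#' When a report strictly states the sediment surface (0 mbsf) is Holocene,
#' Recent or Modern, a 0 Ma tie point at 0 mbsf is added; otherwise no
#' surface age is assumed.
#'
#' @param surface_age_class Character, the report's surface age statement
#'   (`NA` when none was made).
#' @return One-row tie-point tibble or `NULL`.
#' @export
add_seafloor_tie <- function(surface_age_class) {
  if (length(surface_age_class) == 0 || is.na(surface_age_class)) return(NULL)
  if (!tolower(surface_age_class) %in% c("holocene", "recent", "modern")) {
    return(NULL)
  }
  tibble(depth = 0, age = 0, age.range = 0, kind = "seafloor",
         taxon = NA_character_, event.type = NA_character_)
}
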