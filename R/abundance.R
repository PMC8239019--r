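# Abundance harmonization. Sources score abundance in five ways --
# presence/absence, binned (ordinal letter codes), relative abundance,
# raw counts, and specimens per gram -- which are all carried to a numeric
# `abundance` plus, where meaningful, a relative percent `rel.abun`.

.abun_unit_levels <- c("relative abundance", "count", "number per gram",
                       "binned", "P/A")

#' Default binned-abundance vocabulary
#'
#' The common ordinal scale none < present < rare < few < common < abundant
#' < dominant, coded 0..6. Datasets using other alphabets (or reusing a
#' letter with a different meaning, e.g. `A` for absent) supply an override.
#'
#' @return Tibble with `label` and integer `code`.
#' @export
default_vocabulary <- function() {
  tibble(label = c("N", "P", "R", "F", "C", "A", "D"), code = 0:6)
}

#' Load per-dataset vocabulary overrides
#'
#' @param path CSV with columns `db.ID`, `label`, `code`.
#' @return Tibble of overrides; codes must be unique and start at 0 within a
#'   dataset.
#' @export
read_vocabulary_overrides <- function(path) {
  v <- readr::read_csv(path, col_types = "ccd", progress = FALSE,
                       show_col_types = FALSE)
  chk <- v |>
    group_by(.data$db.ID) |>
    summarise(ok = min(.data$code) == 0 && !anyDuplicated(.data$code) &&
                !anyDuplicated(.data$label), .groups = "drop")
  if (!all(chk$ok)) {
    stop("invalid vocabulary override for dataset(s): ",
         paste(chk$db.ID[!chk$ok], collapse = ", "), call. = FALSE)
  }
  v
}

#' Vocabulary for one dataset
#'
#' @param db_id Dataset ID.
#' @param overrides Tibble from [read_vocabulary_overrides()], or `NULL`.
#' @return The dataset's vocabulary tibble (`label`, `code`).
#' @export
dataset_vocabulary <- function(db_id = NULL, overrides = NULL) {
  if (!is.null(overrides) && !is.null(db_id) && db_id %in% overrides$db.ID) {
    ov <- overrides[overrides$db.ID == db_id, c("label", "code")]
    return(arrange(ov, .data$code))
  }
  default_vocabulary()
}

.is_numeric_like <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}

#' Classify the abundance encoding of one sample
#'
#' Decides which of the five encodings a sample's raw values use. All-letter
#' samples whose labels sit in the vocabulary are `binned`; numeric samples
#' restricted to \{0, 1\} are presence/absence; non-negative integers summing
#' above one are counts; other non-negative numerics are relative abundances
#' when they fit a percent scale (each value at most 100), otherwise
#' specimens per gram. Mixed numeric/letter samples are classified by the
#' majority with the minority flagged inconsistent.
#'
#' @param values Character vector of one sample's raw abundance values.
#' @param vocabulary Vocabulary tibble, default [default_vocabulary()].
#' @return List with `units` (one of the five encodings, or `NA` if
#'   unclassifiable -- the sample should then be quarantined) and
#'   `inconsistent`, a logical vector marking minority values.
#' @export
classify_units <- function(values, vocabulary = default_vocabulary()) {
  values <- trimws(as.character(values))
  numeric_like <- .is_numeric_like(values)
  letter_like <- !numeric_like & values %in% vocabulary$label
  inconsistent <- rep(FALSE, length(values))

  if (!any(numeric_like) && !all(letter_like)) {
    return(list(units = NA_character_, inconsistent = inconsistent))
  }
  if (all(letter_like)) {
    return(list(units = "binned", inconsistent = inconsistent))
  }
  if (any(numeric_like) && any(letter_like)) {
    if (sum(numeric_like) >= sum(letter_like)) {
      inconsistent <- letter_like
    } else {
      return(list(units = "binned", inconsistent = numeric_like))
    }
  } else if (!all(numeric_like)) {
    return(list(units = NA_character_, inconsistent = inconsistent))
  }

  num <- suppressWarnings(as.numeric(values[numeric_like]))
  if (any(num < 0)) return(list(units = NA_character_, inconsistent = inconsistent))
  units <- if (all(num %in% c(0, 1)) && !any(inconsistent)) {
    "P/A"
  } else if (all(num == round(num)) && sum(num) > 1) {
    "count"
  } else if (all(num <= 100)) {
    "relative abundance"
  } else {
    "number per gram"
  }
  list(units = units, inconsistent = inconsistent)
}

#' Convert raw abundance values to numeric
#'
#' Binned letters map through the (per-dataset) vocabulary to their ordinal
#' code; presence/absence becomes 1/0; counts, relative abundances and
#' per-gram densities pass through as numbers. Values flagged inconsistent
#' with the sample's majority encoding (e.g. a stray `P` in a counted
#' sample) are assigned 0.01, recording presence without inventing a count.
#'
#' @param values Character vector of one sample's raw values.
#' @param units The sample's encoding from [classify_units()].
#' @param vocabulary Vocabulary tibble.
#' @param inconsistent Logical vector from [classify_units()].
#' @return Numeric abundances.
#' @export
to_numeric <- function(values, units, vocabulary = default_vocabulary(),
                       inconsistent = rep(FALSE, length(values))) {
  values <- trimws(as.character(values))
  out <- rep(NA_real_, length(values))
  out[inconsistent] <- 0.01
  todo <- !inconsistent
  if (identical(units, "binned")) {
    idx <- match(values[todo], vocabulary$label)
    if (anyNA(idx)) {
      stop("label(s) not in vocabulary: ",
           paste(unique(values[todo][is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    out[todo] <- vocabulary$code[idx]
  } else if (identical(units, "P/A")) {
    pa <- values[todo]
    num <- suppressWarnings(as.numeric(pa))
    num[is.na(num)] <- as.numeric(toupper(pa[is.na(num)]) %in% c("P", "X", "PRESENT"))
    out[todo] <- as.numeric(num > 0)
  } else {
    num <- suppressWarnings(as.numeric(values[todo]))
    if (anyNA(num)) {
      stop("non-numeric value(s) in ", units, " sample: ",
           paste(unique(values[todo][is.na(num)]), collapse = ", "),
           call. = FALSE)
    }
    out[todo] <- num
  }
  out
}

#' Per-sample totals and relative percent abundances
#'
#' For counted (and per-gram) samples, `num.ind` is the recorded specimen
#' total (`total.IDd`) when available, otherwise the sum of numeric
#' abundances, and `rel.abun = 100 * abundance / num.ind`. Relative-abundance
#' samples pass through with `rel.abun = abundance`. Binned and
#' presence/absence samples keep `rel.abun` absent: ordinal codes are not
#' proportions.
#'
#' @param records Occurrence tibble with numeric `abundance` and `abun.units`
#'   set; `total.IDd` populated where the source recorded it.
#' @return Records with `num.ind` and `rel.abun` filled in.
#' @export
relative_abundance <- function(records) {
  records <- as_occurrences(records)
  records |>
    group_by(.data$db.source, .data$db.ID, .data$holeID, .data$sampleID) |>
    mutate(
      num.ind = dplyr::case_when(
        !is.na(.data$total.IDd) ~ .data$total.IDd,
        .data$abun.units %in% c("count", "number per gram", "relative abundance") ~
          sum(.data$abundance),
        TRUE ~ NA_real_
      ),
      rel.abun = dplyr::case_when(
        .data$abun.units == "relative abundance" ~ .data$abundance,
        .data$abun.units %in% c("count", "number per gram") & .data$num.ind > 0 ~
          100 * .data$abundance / .data$num.ind,
        TRUE ~ NA_real_
      )
    ) |>
    ungroup() |>
    (\(x) {
      bad <- x$abun.units %in% c("count", "number per gram") &
        !is.na(x$num.ind) & x$num.ind == 0 & x$abundance > 0
      if (any(bad, na.rm = TRUE)) {
        stop("zero specimen total with nonzero abundances in sample(s): ",
             paste(unique(x$sampleID[bad]), collapse = ", "), call. = FALSE)
      }
      x
    })()
}

#' Split zero-abundance records out of the main dataset
#'
#' Zero-abundance (absence) records are retained in the full dataset as an
#' indication of sampling, but excluded from the main (presence-only)
#' dataset.
#'
#' @param records Occurrence tibble with numeric abundances.
#' @return List with `main` (positive abundances only) and `full` (all
#'   records).
#' @export
split_zero_abundance <- function(records) {
  records <- as_occurrences(records)
  list(main = filter(records, .data$abundance > 0), full = records)
}
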