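# Synthetic drill cores with known truth. A core is a piecewise-linear
# age-depth curve (segment sedimentation rates in m/Ma, optional hiatus),
# sampled at regular depths; species occurrences are drawn from known
# stratigraphic ranges, marker events are observable as presence
# transitions, abundances are rendered in any of the supported encodings,
# and reworked contaminants and cross-source duplicates are injected at
# known positions. Every stage of the harmonization pipeline can therefore
# be scored against recoverable ground truth.

.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic species pool
#'
#' 51 species with 8 Ma stratigraphic ranges whose origination/extinction
#' boundaries tile the 0--58 Ma interval every 1 Ma -- about eight species
#' extant at any age, and a biostratigraphic marker event every million
#' years, the event density a well-zoned pelagic section provides.
#'
#' @return Tibble `species`, `speciation`, `extinction` (Ma).
#' @export
synthetic_species_pool <- function() {
  i <- 1:51
  tibble(
    species = sprintf("Synthetica forma%02d", i),
    speciation = i + 7,
    extinction = i - 1
  )
}

#' Marker-event table for a species pool
#'
#' One first-occurrence and one last-occurrence event per species, globally
#' calibrated, with a symmetric age window of `width` Ma about the true age
#' (zero width = perfectly calibrated events).
#'
#' @param pool Species-range tibble.
#' @param width Calibration window width in Ma; default 0.
#' @return An `"event_table"`.
#' @export
synthetic_event_table <- function(pool = synthetic_species_pool(), width = 0) {
  ev <- bind_rows(
    tibble(taxon = pool$species, event.type = "first occurrence",
           age.st = pool$speciation + width / 2,
           age.en = pmax(0, pool$speciation - width / 2)),
    tibble(taxon = pool$species, event.type = "last occurrence",
           age.st = pool$extinction + width / 2,
           age.en = pmax(0, pool$extinction - width / 2))
  )
  ev$scheme <- NA_character_
  ev$region <- "global"
  ev$AM.type <- "biostratigraphy"
  load_event_table(ev)
}

# piecewise-linear age-depth truth: cumulative travel time through the rate
# segments, plus the hiatus jump below its depth
.true_age_fun <- function(depth_span, rates, rate_breaks, surface_age, hiatus) {
  nodes <- c(depth_span[1], rate_breaks, depth_span[2])
  function(d) {
    a <- vapply(d, function(di) {
      acc <- surface_age
      for (j in seq_along(rates)) {
        lo <- nodes[j]; hi <- nodes[j + 1]
        acc <- acc + (max(0, min(di, hi) - lo)) / rates[j]
      }
      acc
    }, numeric(1))
    if (!is.null(hiatus)) a <- a + ifelse(d > hiatus$depth, hiatus$span, 0)
    a
  }
}

# inverse of the truth curve; NA for ages inside the hiatus gap or outside
# the core's age span
.true_depth_fun <- function(depth_span, rates, rate_breaks, surface_age, hiatus) {
  age_of <- .true_age_fun(depth_span, rates, rate_breaks, surface_age, hiatus)
  a_top <- age_of(depth_span[1])
  a_bot <- age_of(depth_span[2])
  nodes <- c(depth_span[1], rate_breaks, depth_span[2])
  function(a) {
    vapply(a, function(ai) {
      if (ai < a_top - 1e-12 || ai > a_bot + 1e-12) return(NA_real_)
      if (!is.null(hiatus)) {
        # ages in (young-side age, young-side age + span) fell in the gap
        gap_lo <- age_of(hiatus$depth)
        if (ai > gap_lo && ai < gap_lo + hiatus$span) return(NA_real_)
        if (ai >= gap_lo + hiatus$span) ai <- ai - hiatus$span
      }
      acc <- surface_age
      for (j in seq_along(rates)) {
        seg_time <- (nodes[j + 1] - nodes[j]) / rates[j]
        if (ai <= acc + seg_time + 1e-12) {
          return(nodes[j] + (ai - acc) * rates[j])
        }
        acc <- acc + seg_time
      }
      depth_span[2]
    }, numeric(1))
  }
}

#' Simulate one drill core with known truth
#'
#' Samples at regular depths down the core; the true age of each depth
#' follows a piecewise-linear age-depth curve (one sedimentation rate per
#' depth segment) with an optional hiatus. Each species of the pool is
#' present wherever the sample's true age falls inside its stratigraphic
#' range (with the stated detection probability); abundances are rendered in
#' the requested encoding; reworked contaminants (records far outside their
#' species' true range) are injected at the stated rate and recorded in the
#' truth.
#'
#' @param holeID Hole identifier.
#' @param seed Integer seed; the seed fully determines the core.
#' @param depth_span Numeric length-2, core top and bottom (mbsf).
#' @param sample_spacing Sample spacing (m).
#' @param rates Sedimentation rates (m/Ma), one per depth segment.
#' @param rate_breaks Depths separating rate segments (length
#'   `length(rates) - 1`); default splits the span evenly.
#' @param surface_age Age at the core top (Ma); a 0 surface is declared
#'   Holocene.
#' @param hiatus `NULL` or `list(depth =, span =)`: depth (mbsf) of a
#'   hiatus and the missing time (Ma).
#' @param pool Species-range tibble; default [synthetic_species_pool()].
#' @param detection_prob Probability an in-range species is recorded in a
#'   sample; default 1.
#' @param encoding One of `"count"`, `"binned"`, `"P/A"`,
#'   `"relative abundance"`.
#' @param contamination_rate Per-record probability of injecting one
#'   contaminant record into the same sample; default 0.
#' @param contaminant_margin Contaminants are placed more than
#'   `trim tolerance + margin` Ma outside their species' range; default 0.5.
#' @param latitude,longitude Modern site coordinates.
#' @param plate Plate id for paleorotation.
#' @return List with `occurrences` (tibble `sample.depth`, `species`,
#'   `value` (raw encoded), `count`, `contaminant`), `events` (an
#'   `"event_table"` for the pool), and `truth` (class
#'   `"synthetic_core_truth"`): the age-depth functions (`age_of`,
#'   `depth_of`), sample depths and true ages, hiatus, species ranges,
#'   contaminant keys, and the seed.
#' @export
simulate_core <- function(holeID = "SYN01", seed = 1,
                          depth_span = c(0, 100), sample_spacing = 1,
                          rates = c(8, 12.5), rate_breaks = NULL,
                          surface_age = 0, hiatus = NULL,
                          pool = synthetic_species_pool(),
                          detection_prob = 1,
                          encoding = c("count", "binned", "P/A",
                                       "relative abundance"),
                          contamination_rate = 0, contaminant_margin = 0.5,
                          latitude = 0, longitude = -30, plate = 101L) {
  encoding <- match.arg(encoding)
  if (is.null(rate_breaks)) {
    rate_breaks <- if (length(rates) > 1) {
      seq(depth_span[1], depth_span[2],
          length.out = length(rates) + 1)[2:length(rates)]
    } else numeric(0)
  }
  stopifnot(length(rate_breaks) == length(rates) - 1, all(rates > 0))
  if (!is.null(hiatus)) {
    if (hiatus$depth <= depth_span[1] || hiatus$depth >= depth_span[2]) {
      stop("hiatus depth outside the core's depth span", call. = FALSE)
    }
    stopifnot(hiatus$span > 0)
  }
  age_of <- .true_age_fun(depth_span, rates, rate_breaks, surface_age, hiatus)
  depth_of <- .true_depth_fun(depth_span, rates, rate_breaks, surface_age, hiatus)
  depths <- seq(depth_span[1], depth_span[2], by = sample_spacing)
  true_age <- age_of(depths)

  occ <- .with_seed(seed, {
    lambda <- stats::setNames(stats::runif(nrow(pool), 5, 40), pool$species)
    rows <- purrr::map_dfr(seq_along(depths), function(i) {
      a <- true_age[i]
      in_range <- pool$extinction <= a & a <= pool$speciation
      sp <- pool$species[in_range]
      if (detection_prob < 1 && length(sp) > 0) {
        sp <- sp[stats::runif(length(sp)) <= detection_prob]
      }
      if (length(sp) == 0) return(NULL)
      cnt <- pmax(1, stats::rpois(length(sp), lambda[sp]))
      tibble(sample.depth = depths[i], species = sp, count = cnt,
             contaminant = FALSE)
    })
    # contaminants: per base record, with probability `contamination_rate`,
    # one record of a species whose range is farther than the trim
    # tolerance + margin from the sample's age
    if (contamination_rate > 0 && nrow(rows) > 0) {
      inject <- which(stats::runif(nrow(rows)) <= contamination_rate)
      extra <- purrr::map_dfr(inject, function(r) {
        a <- age_of(rows$sample.depth[r])
        tol <- if (a < 22.8) 2 else 5
        ok <- pool$extinction > a + tol + contaminant_margin |
          pool$speciation < a - tol - contaminant_margin
        # near the era boundary the assigned age may land on either side;
        # demand the larger tolerance there
        if (abs(a - 23) < 0.2) {
          ok <- pool$extinction > a + 5 + contaminant_margin |
            pool$speciation < a - 5 - contaminant_margin
        }
        cand <- pool$species[ok]
        cand <- setdiff(cand, rows$species[rows$sample.depth == rows$sample.depth[r]])
        if (length(cand) == 0) return(NULL)
        tibble(sample.depth = rows$sample.depth[r],
               species = cand[sample.int(length(cand), 1)],
               count = 1, contaminant = TRUE)
      })
      # two contaminants may collide on the same (sample, species) cell;
      # keep one record per cell
      rows <- dplyr::distinct(bind_rows(rows, extra),
                              .data$sample.depth, .data$species,
                              .keep_all = TRUE)
    }
    # barren samples stay in the record as a scored-but-absent row: real
    # datasets retain zero abundances as evidence of sampling, and datum
    # bracketing needs the barren sample below a species' deepest presence
    barren <- setdiff(depths, rows$sample.depth)
    if (length(barren) > 0) {
      rows <- bind_rows(rows, tibble(sample.depth = barren,
                                     species = pool$species[1],
                                     count = 0, contaminant = FALSE))
    }
    arrange(rows, .data$sample.depth, .data$species)
  })

  occ$value <- switch(encoding,
    "count" = as.character(occ$count),
    "P/A" = ifelse(occ$count > 0, "1", "0"),
    "binned" = as.character(cut(occ$count, c(-Inf, 0, 1, 4, 9, 19, 49, Inf),
                                labels = c("N", "P", "R", "F", "C", "A", "D"))),
    "relative abundance" = {
      tot <- stats::ave(occ$count, occ$sample.depth, FUN = sum)
      ifelse(tot > 0, as.character(round(100 * occ$count / tot, 4)), "0")
    }
  )

  truth <- structure(list(
    holeID = holeID, plate = plate,
    latitude = latitude, longitude = longitude,
    depth_span = depth_span, sample_spacing = sample_spacing,
    rates = rates, rate_breaks = rate_breaks, surface_age = surface_age,
    hiatus = hiatus,
    age_of = age_of, depth_of = depth_of,
    sample_depths = depths, true_ages = true_age,
    species_ranges = pool,
    contaminants = occ[occ$contaminant, c("sample.depth", "species")],
    encoding = encoding, seed = seed
  ), class = "synthetic_core_truth")
  truth$contaminants$holeID <- rep(holeID, nrow(truth$contaminants))

  list(occurrences = occ, events = synthetic_event_table(pool), truth = truth)
}

#' True ages of depths under a synthetic truth
#'
#' @param truth A `"synthetic_core_truth"`.
#' @param depths Depths (mbsf).
#' @return True ages (Ma).
#' @export
true_ages <- function(truth, depths) truth$age_of(depths)

#' Noiseless tie points from a synthetic truth
#'
#' Places tie points directly on the true age-depth curve at a regular age
#' spacing (skipping ages lost to the hiatus), with zero calibrated age
#' range -- the idealized input for scoring the age-depth estimators
#' themselves, free of event-calibration and sampling error.
#'
#' @param truth A `"synthetic_core_truth"`.
#' @param ties_per_ma Tie density (points per Ma); default 1.
#' @return Tie-point tibble (`depth`, `age`, `age.range`, `kind`, `taxon`,
#'   `event.type`).
#' @export
true_tiepoints <- function(truth, ties_per_ma = 1) {
  a0 <- truth$age_of(truth$depth_span[1])
  a1 <- truth$age_of(truth$depth_span[2])
  ages <- seq(a0, a1, by = 1 / ties_per_ma)
  depth <- truth$depth_of(ages)
  keep <- !is.na(depth)
  tibble(depth = depth[keep], age = ages[keep], age.range = 0,
         kind = "biostratigraphic", taxon = NA_character_,
         event.type = NA_character_)
}

#' Built-in synthetic plate-rotation table
#'
#' A small deterministic rotation model: plates 101 and 102 cover the whole
#' Cenozoic (102 moving relative to 101, which moves relative to the
#' anchor), and plate 201 is covered only to 5 Ma so that the
#' uncovered-plate path is exercised.
#'
#' @return A `"rotation_table"`.
#' @export
synthetic_rotation_table <- function() {
  txt <- c(
    "101   0.0  90.0    0.0    0.0  001 ! identity at present",
    "101  40.0  35.0   45.0  -12.0  001",
    "101  70.0  35.0   45.0  -22.0  001",
    "102   0.0  90.0    0.0    0.0  101",
    "102  30.0 -50.0  120.0    9.0  101",
    "102  70.0 -50.0  120.0   21.0  101",
    "201   0.0  90.0    0.0    0.0  001",
    "201   5.0  10.0  -60.0    1.5  001",
    "999   0.0   0.0    0.0    0.0  001 ! terminator"
  )
  f <- tempfile(fileext = ".rot")
  writeLines(txt, f)
  on.exit(unlink(f))
  parse_rotation_file(f)
}

# render one hole's occurrence rows in a source dialect, returning the
# table plus the column mapping that reads it back
.render_dialect <- function(occ, dialect, holeID, latitude, longitude,
                            source_name) {
  constants <- list(db.source = source_name, db.ID = source_name,
                    holeID = holeID, latitude = latitude,
                    longitude = longitude)
  if (dialect == "wide-count") {
    wide <- occ |>
      select(depth = "sample.depth", "species", "value") |>
      tidyr::pivot_wider(names_from = "species", values_from = "value")
    list(table = wide,
         mapping = list(format = "wide", depth = "depth",
                        species_columns = setdiff(names(wide), "depth"),
                        constants = constants))
  } else {
    long <- occ |>
      select(depth = "sample.depth", taxon = "species", abun = "value")
    list(table = long,
         mapping = list(format = "long", depth = "depth", species = "taxon",
                        abundance = "abun", constants = constants))
  }
}

#' Simulate a multi-source corpus of drill holes
#'
#' Generates `n_holes` synthetic cores whose surfaces are staggered in age
#' so their records jointly tile the sampled part of the Cenozoic, renders
#' each hole's table in a rotating source dialect (wide counts, long binned
#' codes, long presence/absence), and duplicates a fraction of the records
#' into a parallel "mirror" source with identical key fields, recording the
#' duplicate ledger. Contaminants are injected per core and recorded.
#'
#' @param n_holes Number of holes; default 12.
#' @param overlap_fraction Fraction of records duplicated into the mirror
#'   source; default 0.1.
#' @param contamination_rate Per-record contaminant injection probability;
#'   default 0.02.
#' @param seed Integer seed; fully determines the corpus.
#' @param pool Species pool; default [synthetic_species_pool()].
#' @param detection_prob Passed to [simulate_core()]; default 1.
#' @param surface_step Age offset between consecutive hole surfaces (Ma);
#'   default 4, so that the deepest hole still bottoms out inside the
#'   species pool's marker-covered window.
#' @param sample_spacing Sample spacing (m); default 2.
#' @return List of class `"synthetic_corpus"`: `sources` (named list of
#'   `list(table, mapping)`), `plates`, `surface` (holeID and declared
#'   surface age class), `events`, `species_ranges`, `duplicate_ledger`
#'   (`holeID`, `sample.depth`, `species`), `contaminants`, `truths` (per
#'   hole), `rotation_table`, and `seed`.
#' @export
simulate_corpus <- function(n_holes = 12, overlap_fraction = 0.1,
                            contamination_rate = 0.02, seed = 1,
                            pool = synthetic_species_pool(),
                            detection_prob = 1, surface_step = 4,
                            sample_spacing = 2) {
  dialects <- c("wide-count", "long-binned", "long-PA")
  encodings <- c("count", "binned", "P/A")
  hole_seed <- function(h) (abs(seed) %% 1000000L * 2011L + h * 7L) %% 2147483647L
  sources <- list()
  truths <- list()
  ledger <- list()
  plates <- list()
  surface <- list()
  for (h in seq_len(n_holes)) {
    holeID <- sprintf("SYN%02d", h)
    dial <- dialects[(h - 1) %% 3 + 1]
    core <- .with_seed(hole_seed(h) + 1L, {
      simulate_core(
        holeID = holeID, seed = hole_seed(h),
        surface_age = surface_step * (h - 1),
        rates = c(4, 6.25), sample_spacing = sample_spacing,
        pool = pool, detection_prob = detection_prob,
        encoding = encodings[(h - 1) %% 3 + 1],
        contamination_rate = contamination_rate,
        latitude = stats::runif(1, -60, 60),
        longitude = stats::runif(1, -179, 180),
        plate = c(101L, 102L)[h %% 2 + 1]
      )
    })
    truths[[holeID]] <- core$truth
    plates[[h]] <- tibble(holeID = holeID, plate = core$truth$plate)
    surface[[h]] <- tibble(
      holeID = holeID,
      surface.age.class = if (core$truth$surface_age == 0) "Holocene" else NA_character_
    )
    # one source dataset per hole, in the hole's dialect
    src_name <- sprintf("%s_%s", sub("-.*", "", dial), holeID)
    rend <- .render_dialect(core$occurrences, dial, holeID,
                            core$truth$latitude, core$truth$longitude,
                            paste0("src_", dial))
    rend$mapping$constants$db.ID <- src_name
    sources[[src_name]] <- rend
    # duplicate a fraction of the records into the mirror source with
    # identical key fields (species, raw abundance, depth, coordinates)
    n_occ <- nrow(core$occurrences)
    n_dup <- round(overlap_fraction * n_occ)
    if (n_dup > 0) {
      dup_idx <- .with_seed(hole_seed(h) + 2L, sample.int(n_occ, n_dup))
      dup <- core$occurrences[sort(dup_idx), ]
      ledger[[holeID]] <- tibble(holeID = holeID,
                                 sample.depth = dup$sample.depth,
                                 species = dup$species)
      mir <- .render_dialect(dup, "long", holeID,
                             core$truth$latitude, core$truth$longitude,
                             "mirror")
      mir$mapping$constants$db.ID <- paste0("mirror_", holeID)
      sources[[paste0("mirror_", holeID)]] <- mir
    }
  }
  structure(list(
    sources = sources, plates = bind_rows(plates),
    surface = bind_rows(surface), events = synthetic_event_table(pool),
    species_ranges = pool,
    duplicate_ledger = bind_rows(ledger),
    contaminants = bind_rows(lapply(truths, function(t) t$contaminants)),
    truths = truths,
    rotation_table = synthetic_rotation_table(), seed = seed
  ), class = "synthetic_corpus")
}

#' Write a synthetic corpus to disk
#'
#' Serializes each source table as CSV plus a `sources.yaml` ingestion
#' config, the marker-event table, species ranges, plate assignments and
#' surface declarations -- the on-disk form the command-line pipeline
#' consumes.
#'
#' @param corpus A `"synthetic_corpus"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(sources = list())
  for (nm in names(corpus$sources)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(corpus$sources[[nm]]$table, f, na = "", progress = FALSE)
    cfg$sources[[nm]] <- c(list(path = basename(f)),
                           corpus$sources[[nm]]$mapping)
  }
  yaml::write_yaml(cfg, file.path(dir, "sources.yaml"))
  readr::write_csv(as_tibble(corpus$events), file.path(dir, "events.csv"),
                   progress = FALSE)
  readr::write_csv(corpus$species_ranges, file.path(dir, "species_ranges.csv"),
                   progress = FALSE)
  readr::write_csv(corpus$plates, file.path(dir, "plates.csv"),
                   progress = FALSE)
  readr::write_csv(corpus$surface, file.path(dir, "surface.csv"),
                   progress = FALSE)
  invisible(dir)
}
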