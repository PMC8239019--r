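# Validation metrics: species richness per time bin, stratigraphic-range
# completeness, and the latitude x time coverage grid.

#' Species richness per time bin
#'
#' Counts distinct species in half-open age bins `[k*w, (k+1)*w)` spanning
#' the Cenozoic (0--66 Ma). Records flagged `trim = "exc"` are excluded: the
#' richness curve is computed on the trimmed dataset so that reworked or
#' misidentified out-of-range records do not inflate diversity.
#'
#' @param records Occurrence tibble with `age`, `species` and `trim`.
#' @param bin_width Bin width in Ma; default 1.
#' @param max_age Upper limit in Ma; default 66 (Cenozoic).
#' @return Tibble `bin.st` (young edge), `bin.en` (old edge), `richness`,
#'   covering every bin (zeros included).
#' @export
richness <- function(records, bin_width = 1, max_age = 66) {
  records <- as_occurrences(records)
  recs <- filter(records, !is.na(.data$age), !is.na(.data$species),
                 is.na(.data$trim) | .data$trim != "exc")
  edges <- seq(0, max_age, by = bin_width)
  bin <- floor(recs$age / bin_width)
  counts <- tibble(bin = bin, species = recs$species) |>
    filter(.data$bin >= 0, .data$bin < length(edges) - 1) |>
    group_by(.data$bin) |>
    summarise(richness = n_distinct(.data$species), .groups = "drop")
  out <- tibble(bin.st = edges[-length(edges)],
                bin.en = edges[-1])
  out$richness <- counts$richness[match(out$bin.st / bin_width, counts$bin)]
  out$richness[is.na(out$richness)] <- 0L
  out
}

# expected bins of a closed range [extinction, speciation] against half-open
# bins [k*w, (k+1)*w): bins with an overlap of positive length; a range
# endpoint sitting exactly on an edge does not pull in the bin beyond it.
.expected_bins <- function(extinction, speciation, w) {
  k <- seq(floor(extinction / w), ceiling(speciation / w))
  k <- k[k * w < speciation & (k + 1) * w > extinction]
  if (length(k) == 0) k <- floor((extinction + speciation) / 2 / w)
  k
}

#' Stratigraphic-range completeness per species
#'
#' For each species with at least one record and a known range, the
#' completeness is the fraction of age bins overlapping its stratigraphic
#' range (speciation to extinction) in which the species actually occurs;
#' 100% means the species is found in every time bin of its expected range.
#'
#' @param records Occurrence tibble with `age` and `species`.
#' @param ranges Range table ([load_species_ranges()]).
#' @param bin_width Bin width in Ma; default 1.
#' @return List with `per_species` (tibble `species`, `expected.bins`,
#'   `occupied.bins`, `completeness` in \[0, 1\]), `summary` (tibble
#'   `median`, `mean`, `n.complete`, `pct.complete`, `n.species`), and
#'   `no_records` (species in `ranges` with no dated records).
#' @export
completeness <- function(records, ranges, bin_width = 1) {
  records <- as_occurrences(records)
  recs <- filter(records, !is.na(.data$age), !is.na(.data$species))
  per <- ranges |>
    filter(.data$species %in% recs$species) |>
    purrr::pmap_dfr(function(species, speciation, extinction, ...) {
      exp_bins <- .expected_bins(extinction, speciation, bin_width)
      ages <- recs$age[recs$species == species]
      occ_bins <- intersect(unique(floor(ages / bin_width)), exp_bins)
      tibble(species = species,
             expected.bins = length(exp_bins),
             occupied.bins = length(occ_bins),
             completeness = length(occ_bins) / length(exp_bins))
    })
  summary <- tibble(
    median = stats::median(per$completeness),
    mean = mean(per$completeness),
    n.complete = sum(per$completeness == 1),
    pct.complete = 100 * mean(per$completeness == 1),
    n.species = nrow(per)
  )
  list(per_species = per, summary = summary,
       no_records = setdiff(ranges$species, recs$species))
}

#' Latitude x time coverage grid
#'
#' Counts records per (absolute paleolatitude band, age bin) cell --
#' hemispheres folded, so a record at -45° falls in the 30-60° band. Band
#' marginals give the classic 0-30 / 30-60 / 60-90 summary rows.
#'
#' @param records Occurrence tibble with `age` and `pal.lat`.
#' @param lat_band_width Band width in degrees; default 30.
#' @param bin_width Age bin width in Ma; default 1.
#' @param max_age Upper age limit; default 66.
#' @return List `grid` (tibble `lat.band`, `bin.st`, `records`) and
#'   `band_totals` (tibble `lat.band`, `records`).
#' @export
coverage_grid <- function(records, lat_band_width = 30, bin_width = 1,
                          max_age = 66) {
  records <- as_occurrences(records)
  recs <- filter(records, !is.na(.data$age), !is.na(.data$pal.lat),
                 .data$age < max_age)
  band_lo <- pmin(floor(abs(recs$pal.lat) / lat_band_width),
                  ceiling(90 / lat_band_width) - 1) * lat_band_width
  grid <- tibble(
    lat.band = sprintf("%g-%g", band_lo, band_lo + lat_band_width),
    bin.st = floor(recs$age / bin_width) * bin_width
  ) |>
    dplyr::count(.data$lat.band, .data$bin.st, name = "records")
  band_totals <- grid |>
    group_by(.data$lat.band) |>
    summarise(records = sum(.data$records), .groups = "drop")
  list(grid = grid, band_totals = band_totals)
}

#' Plot the richness curve
#'
#' @param rich Output of [richness()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_richness <- function(rich) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(rich, ggplot2::aes(x = (.data$bin.st + .data$bin.en) / 2,
                                     y = .data$richness)) +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "Species richness") +
    ggplot2::theme_minimal()
}
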