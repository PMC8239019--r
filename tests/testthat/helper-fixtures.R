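# Shared fixture builders. Everything is generated in code; no files.

# minimal occurrence tibble with the crucial columns populated
toy_records <- function(n = 3, species = paste("Genus", letters[seq_len(n)]),
                        abundance = rep(1, n), age = rep(1, n),
                        pal.lat = rep(10, n), pal.long = rep(20, n), ...) {
  as_occurrences(tibble::tibble(
    rowID = paste0("r", seq_len(n)),
    species = species, abundance = abundance, age = age,
    pal.lat = pal.lat, pal.long = pal.long, ...
  ))
}

# a small synonymy: one valid, one junior synonym, one typo, one Mesozoic,
# one invalid
toy_synonymy <- function() {
  load_synonymy(
    tibble::tibble(
      raw = c("Globorotalia flexuosa", "Globorotalia tumida",
              "Globorotalia merotumida", "Globototalia flexuosa",
              "Hedbergella cretacea", "Nonexistens dubius"),
      senior = c("Globorotalia flexuosa", "Globorotalia tumida",
                 "Globorotalia tumida", "Globorotalia flexuosa",
                 "Hedbergella cretacea", "Nonexistens dubius"),
      status = c("valid", "valid", "junior synonym", "typo",
                 "Mesozoic-only", "invalid")
    ),
    valid_species = c("Globorotalia flexuosa", "Globorotalia tumida")
  )
}

# event table with scheme-dependent zone bases and regional variants
toy_events <- function() {
  load_event_table(tibble::tibble(
    taxon = c("M8", "M9", "Fohsella fohsi", "Morozovella aragonensis",
              "Morozovella aragonensis", "C5n", "C5n"),
    event.type = c("first occurrence", "first occurrence", "first occurrence",
                   "last occurrence", "last occurrence",
                   "magnetochron base", "magnetochron top"),
    scheme = c("Berggren95", "Wade11", NA, NA, NA, NA, NA),
    region = c("global", "global", "global", "Atlantic-tropical", "global",
               "global", "global"),
    age.st = c(13.77, 13.77, 13.77, 42.6, 43.2, 11.06, 9.79),
    age.en = c(13.77, 13.77, 13.77, 42.6, 43.2, 11.06, 9.79),
    AM.type = c(rep("biostratigraphy", 5), "magnetostratigraphy",
                "magnetostratigraphy")
  ))
}

# quick tie-point tibble
ties_tbl <- function(depth, age, age.range = 0, kind = "biostratigraphic") {
  tibble::tibble(depth = depth, age = age,
                 age.range = rep_len(age.range, length(depth)),
                 kind = rep_len(kind, length(depth)),
                 taxon = NA_character_, event.type = NA_character_)
}

# independent rotation oracle: rotation matrix built from explicit
# axis-frame composition Rz(lon) Ry(90-lat) Rz(angle) Ry/Rz inverses
oracle_rotation_matrix <- function(pole_lat, pole_lon, angle) {
  d <- pi / 180
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  # bring pole to +z, rotate about z, return
  to_pole <- Ry(-(90 - pole_lat) * d) %*% Rz(-pole_lon * d)
  solve(to_pole) %*% Rz(angle * d) %*% to_pole
}

# in-memory counterpart of read_vocabulary_overrides for the override test
read_vocabulary_overrides_tbl <- function(tbl) {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tbl, f)
  on.exit(unlink(f))
  read_vocabulary_overrides(f)
}
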