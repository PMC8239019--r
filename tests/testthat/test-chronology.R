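test_that("sites fall into basins and climate belts with an inclusive tropic", {
  expect_equal(assign_region(10, -30), "Atlantic-tropical")
  expect_equal(assign_region(-40, 160), "IndoPacific-temperate")
  expect_equal(assign_region(23.5, -30), "Atlantic-tropical")   # inclusive
  expect_equal(assign_region(23.6, -30), "Atlantic-temperate")
  expect_equal(assign_region(0, -100), "IndoPacific-tropical")
})

test_that("zone-base events resolve through the study's zonal scheme", {
  ev <- toy_events()
  a <- calibrate_event("B M8", scheme = "Berggren95", events = ev)
  b <- calibrate_event("B M9", scheme = "Wade11", events = ev)
  d <- calibrate_event("FO Fohsella fohsi", scheme = NA, events = ev)
  # the same datum defines the base of M8 (older scheme) and M9 (newer)
  expect_equal(a$age, d$age)
  expect_equal(b$age, d$age)
  expect_equal(a$age, 13.77)
})

test_that("regional calibrations are preferred and global is the fallback", {
  ev <- toy_events()
  atl <- calibrate_event("T Morozovella aragonensis", events = ev,
                         region = "Atlantic-tropical")
  other <- calibrate_event("T Morozovella aragonensis", events = ev,
                           region = "IndoPacific-temperate")
  expect_equal(atl$age, 42.6)
  expect_equal(other$age, 43.2)    # only a global entry for this region
  # unresolvable labels drop out as NULL
  expect_null(calibrate_event("B Unknown taxon", events = ev))
})

test_that("LO reads as lowest occurrence only when HO is also in use", {
  ev <- load_event_table(tibble::tibble(
    taxon = "Taxon alpha",
    event.type = c("first occurrence", "last occurrence"),
    scheme = NA, region = "global",
    age.st = c(20, 10), age.en = c(20, 10), AM.type = "biostratigraphy"
  ))
  with_ho <- calibrate_event("LO Taxon alpha", events = ev,
                             study_labels = c("LO Taxon alpha", "HO Taxon alpha"))
  with_fo <- calibrate_event("LO Taxon alpha", events = ev,
                             study_labels = c("FO Taxon alpha", "LO Taxon alpha"))
  expect_equal(with_ho$event.type, "first occurrence")
  expect_equal(with_ho$age, 20)
  expect_equal(with_fo$event.type, "last occurrence")
  expect_equal(with_fo$age, 10)
})

test_that("contradictory duplicate event entries are fatal at load", {
  tbl <- tibble::tibble(
    taxon = c("X", "X"), event.type = "first occurrence",
    scheme = NA, region = "global",
    age.st = c(10, 11), age.en = c(10, 11), AM.type = NA
  )
  expect_error(load_event_table(tbl), "contradictory")
})

test_that("tie depths are the midpoint of the bracketing sample pair", {
  lo <- tibble::tibble(taxon = "X", event.type = "last occurrence",
                       age.st = 5.2, age.en = 4.8)
  depths <- c(118.0, 120.0, 122.4, 125.0)
  # species present from 120.0 downward; first absence upcore at 118.0
  tie <- tie_from_occurrences(lo, depths, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(tie$depth, (118 + 120) / 2)
  expect_equal(tie$age, 5.0)
  expect_equal(tie$age.range, 0.4)
  # present only in the deepest sample: bracket with its upcore neighbour
  tie2 <- tie_from_occurrences(lo, depths, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(tie2$depth, (122.4 + 125.0) / 2)
  # no bracket at all (present everywhere) yields nothing
  expect_null(tie_from_occurrences(lo, depths, rep(TRUE, 4)))
  # an extinction datum above the cored interval yields nothing
  expect_null(tie_from_occurrences(lo, depths, c(TRUE, TRUE, FALSE, FALSE)))
})

test_that("tie depth error is bounded by half the sample spacing", {
  core <- simulate_core(seed = 5, sample_spacing = 2)
  recs <- tibble::tibble(sample.depth = core$occurrences$sample.depth,
                         species = core$occurrences$species,
                         abundance = core$occurrences$count)
  ties <- derive_tiepoints(recs, core$events, "global", "Holocene")
  ties <- ties[ties$kind == "biostratigraphic", ]
  true_depth <- core$truth$depth_of(ties$age)
  ok <- !is.na(true_depth)
  expect_gt(sum(ok), 5)
  expect_true(all(abs(ties$depth[ok] - true_depth[ok]) <= 2 / 2 + 1e-9))
  # resulting tie age error bound: half the local age spacing of samples
  age_err <- abs(core$truth$age_of(ties$depth[ok]) - ties$age[ok])
  expect_true(all(age_err <= 2 / min(core$truth$rates) / 2 + 1e-9))
})

test_that("a seafloor tie appears only for declared modern surfaces", {
  expect_equal(add_seafloor_tie("Holocene")$depth, 0)
  expect_equal(add_seafloor_tie("recent")$age, 0)
  expect_null(add_seafloor_tie(NA))
  expect_null(add_seafloor_tie("Pleistocene"))
})

test_that("calibration is deterministic", {
  ev <- toy_events()
  a <- replicate(3, calibrate_event("B M8", scheme = "Berggren95",
                                    events = ev)$age)
  expect_equal(a, rep(13.77, 3))
})
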