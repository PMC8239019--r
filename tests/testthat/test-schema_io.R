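test_that("wide tables reshape to one record per non-empty cell", {
  wide <- tibble::tibble(
    depth = c(1.5, 3.5),
    `Genus alpha` = c("10", "5"),
    `Genus beta` = c("2", NA),
    `Genus gamma` = c("1", "7")
  )
  mapping <- list(format = "wide", depth = "depth",
                  species_columns = setdiff(names(wide), "depth"),
                  constants = list(db.source = "srcA", holeID = "H1"))
  recs <- ingest_table(wide, mapping)
  expect_equal(nrow(recs), 5)   # one NA cell not emitted
  expect_setequal(unique(recs$species),
                  c("Genus alpha", "Genus beta", "Genus gamma"))
  expect_equal(recs$orig.abundance[recs$species == "Genus alpha" &
                                     recs$sample.depth == 1.5], "10")
  expect_true(all(recs$db.source == "srcA"))
})

test_that("long tables ingest with unmapped metadata set to absent", {
  long <- tibble::tibble(sp = c("A a", "B b", "C c", "A a", "B b", "C c"),
                         ab = as.character(1:6),
                         d = rep(c(10, 20), each = 3))
  recs <- ingest_table(long, list(format = "long", species = "sp",
                                  abundance = "ab", depth = "d"))
  expect_equal(nrow(recs), 6)     # 3 species x 2 samples
  expect_true(all(is.na(recs$latitude)))
  expect_true(all(is.na(recs$water.depth)))
  # no depth mapped -> depth absent
  recs2 <- ingest_table(long, list(format = "long", species = "sp",
                                   abundance = "ab"))
  expect_true(all(is.na(recs2$sample.depth)))
})

test_that("a mapping naming a missing column is fatal with the column name", {
  long <- tibble::tibble(sp = "A a", ab = "1")
  expect_error(
    ingest_table(long, list(format = "long", species = "sp",
                            abundance = "ab", depth = "mbsf")),
    "mbsf"
  )
  expect_error(read_occurrence_table(tempfile(), list()), "cannot read")
})

test_that("crucial-column filtering keeps counts conserved with one primary reason", {
  recs <- toy_records(10)
  recs$species[1:3] <- NA
  recs$age[3:5] <- NA
  recs$pal.lat[6] <- NA
  out <- validate_and_filter(recs)
  expect_equal(nrow(out$clean), 4)
  expect_equal(nrow(out$rejected), 6)
  expect_equal(nrow(out$clean) + nrow(out$rejected), nrow(recs))
  # record 3 misses both species and age; primary reason is species
  expect_equal(out$rejected$reason[out$rejected$rowID == "r3"],
               "missing species")
  expect_equal(sum(out$rejected$reason == "missing age"), 2)
  expect_equal(sum(out$rejected$reason == "missing paleocoordinates"), 1)
  # idempotence
  again <- validate_and_filter(out$clean)
  expect_equal(again$clean, out$clean)
  expect_equal(nrow(again$rejected), 0)
})

test_that("identifier assignment is deterministic and collision-free", {
  recs <- toy_records(4, species = c("B b", "A a", "B b", "A a"))
  recs$db.source <- "srcA"
  recs$site <- "846"
  recs$hole <- "B"
  recs$holeID <- NA_character_
  recs$sample.depth <- c(5, 5, 1, 1)
  recs$rowID <- NA_character_
  a <- assign_ids(recs)
  b <- assign_ids(recs[sample.int(4), ])   # permuted input
  expect_equal(a, b)
  # two rows of one sample share sampleID but not rowID
  expect_equal(a$sampleID[1], a$sampleID[2])
  expect_false(a$rowID[1] == a$rowID[2])
  # same site name in two sources gives distinct holeIDs
  recs2 <- recs
  recs2$db.source <- "srcB"
  both <- assign_ids(dplyr::bind_rows(recs, recs2))
  expect_equal(dplyr::n_distinct(both$holeID), 2)
  expect_false(anyDuplicated(both$rowID) > 0)
})

test_that("the dataset round-trips losslessly through CSV", {
  recs <- toy_records(3)
  recs$latitude <- c(10.25, NA, -3.5)
  recs$abun.units <- c("count", NA, "P/A")
  recs <- as_occurrences(recs)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(recs, f)
  back <- read_occurrences(f)
  expect_equal(back, recs)
  # absent values serialize as the literal NA token
  expect_true(any(grepl(",NA,", readLines(f)[3])))
  # empty set gives a header-only file
  write_occurrences(empty_occurrences(), f)
  expect_equal(length(readLines(f)), 1)
  expect_equal(nrow(read_occurrences(f)), 0)
})

test_that("schema invariants are enforced", {
  expect_error(check_occurrences(toy_records(1, age = 70)), "Cenozoic")
  expect_error(check_occurrences(toy_records(1, pal.lat = 91)), "pal.lat")
  bad <- toy_records(2)
  bad$rowID <- c("x", "x")
  expect_error(check_occurrences(bad), "rowID")
  expect_silent(check_occurrences(toy_records(2)))
})
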