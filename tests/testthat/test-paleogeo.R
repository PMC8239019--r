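rot_file <- function(lines) {
  f <- tempfile(fileext = ".rot")
  writeLines(lines, f)
  f
}

test_that("rotation files parse with comments, terminators and circuits", {
  f <- rot_file(c(
    "701  0.0 90.0 0.0 0.0 001 ! identity",
    "701 10.0 30.0 40.0 5.0 001",
    "702  0.0 90.0 0.0 0.0 701 ! chained through 701",
    "702 10.0 10.0 20.0 2.0 701",
    "999  0.0  0.0  0.0 0.0 001 ! terminator"
  ))
  tab <- parse_rotation_file(f)
  expect_s3_class(tab, "rotation_table")
  expect_setequal(unique(tab$rotations$moving), c(701L, 702L))
  # zero-angle line is the identity
  r0 <- total_rotation(701L, 0, tab)
  expect_equal(r0$angle, 0)
  # two-plate chain composes through the circuit
  r <- total_rotation(702L, 10, tab)
  expect_s3_class(r, "finite_rotation")
  oracle <- oracle_rotation_matrix(30, 40, 5) %*% oracle_rotation_matrix(10, 20, 2)
  expect_equal(rotation_matrix(r), oracle, tolerance = 1e-12)
})

test_that("non-monotone ages and broken circuits are fatal", {
  f <- rot_file(c("701 10.0 30.0 40.0 5.0 001",
                  "701  5.0 30.0 40.0 2.0 001"))
  expect_error(parse_rotation_file(f), "non-monotone")
  f2 <- rot_file(c("702 0.0 90.0 0.0 0.0 705"))
  expect_error(parse_rotation_file(f2), "705")
})

test_that("total rotations interpolate at and between table nodes", {
  f <- rot_file(c(
    "701  0.0 90.0 0.0  0.0 001",
    "701 10.0 25.0 60.0 8.0 001",
    "701 20.0 25.0 60.0 20.0 001"
  ))
  tab <- parse_rotation_file(f)
  # exactly at a node: that entry
  r10 <- total_rotation(701L, 10, tab)
  expect_equal(r10$angle, 8, tolerance = 1e-9)
  expect_equal(r10$pole_lat, 25, tolerance = 1e-9)
  # midway between nodes sharing one axis: same axis, mean angle
  r15 <- total_rotation(701L, 15, tab)
  expect_equal(r15$pole_lat, 25, tolerance = 1e-9)
  expect_equal(r15$pole_lon, 60, tolerance = 1e-9)
  expect_equal(r15$angle, 14, tolerance = 1e-9)
  # continuity: small age steps move points by small amounts
  p <- c(10, 50)
  steps <- seq(9.5, 10.5, by = 0.1)
  pos <- vapply(steps, function(a) {
    unlist(rotate_point(p[1], p[2], total_rotation(701L, a, tab)))
  }, numeric(2))
  expect_true(all(abs(diff(t(pos))) < 0.5))
  # outside the covered span: no rotation
  expect_null(total_rotation(701L, 25, tab))
})

test_that("points rotate with the right-hand convention and invert exactly", {
  # identity leaves coordinates unchanged
  id <- finite_rotation(90, 0, 0)
  expect_equal(unlist(rotate_point(12, 34, id)),
               c(pal.lat = 12, pal.long = 34))
  # +30 degrees about the north pole moves (0,0) east to (0,30)
  r <- finite_rotation(90, 0, 30)
  out <- rotate_point(0, 0, r)
  expect_equal(out$pal.lat, 0, tolerance = 1e-12)
  expect_equal(out$pal.long, 30, tolerance = 1e-12)
  # rotation followed by its inverse restores the point
  set.seed(4)
  for (i in 1:20) {
    rr <- finite_rotation(runif(1, -90, 90), runif(1, -180, 180),
                          runif(1, -180, 180))
    pt <- c(runif(1, -89, 89), runif(1, -179, 179))
    fwd <- rotate_point(pt[1], pt[2], rr)
    back <- rotate_point(fwd$pal.lat, fwd$pal.long, invert_rotation(rr))
    expect_equal(c(back$pal.lat, back$pal.long), pt, tolerance = 1e-9)
  }
})

test_that("composition is associative and matches the matrix oracle", {
  set.seed(8)
  rnd <- function() finite_rotation(runif(1, -90, 90), runif(1, -180, 180),
                                    runif(1, -179, 179))
  for (i in 1:10) {
    a <- rnd(); b <- rnd(); c <- rnd()
    left <- compose_rotations(compose_rotations(a, b), c)
    right <- compose_rotations(a, compose_rotations(b, c))
    expect_equal(rotation_matrix(left), rotation_matrix(right),
                 tolerance = 1e-9)
    expect_equal(rotation_matrix(compose_rotations(a, b)),
                 rotation_matrix(a) %*% rotation_matrix(b),
                 tolerance = 1e-9)
  }
})

test_that("paleocoordinates rotate per record, sparing modern samples", {
  tab <- synthetic_rotation_table()
  recs <- toy_records(4)
  recs$holeID <- c("H1", "H1", "H2", "H3")
  recs$latitude <- c(5, 5, -20, 40)
  recs$longitude <- c(-30, -30, 100, 10)
  recs$age <- c(0, 20, 20, 20)
  recs$pal.lat <- NA_real_
  recs$pal.long <- NA_real_
  plates <- tibble::tibble(holeID = c("H1", "H2"), plate = c(101L, 102L))
  out <- paleocoordinates(recs, tab, plates)
  # modern sample keeps its modern coordinates
  expect_equal(out$records$pal.lat[1], 5)
  expect_equal(out$records$pal.long[1], -30)
  # aged sample on the same hole moves
  expect_false(isTRUE(all.equal(out$records$pal.long[2], -30)))
  # different plates give different reconstructions
  expect_false(isTRUE(all.equal(out$records$pal.lat[2],
                                out$records$pal.lat[3])))
  # hole without a plate assignment is skipped and flagged
  expect_true(is.na(out$records$pal.lat[4]))
  expect_equal(out$skipped$reason[out$skipped$rowID == "r4"],
               "no plate assignment")
})

test_that("coverage fraction matches construction with an uncovered plate", {
  tab <- synthetic_rotation_table()   # plate 201 covered only to 5 Ma
  n_old <- 6; n_young <- 4
  recs <- toy_records(n_old + n_young)
  recs$holeID <- "H9"
  recs$latitude <- 10; recs$longitude <- 10
  recs$age <- c(rep(20, n_old), rep(3, n_young))
  recs$pal.lat <- NA_real_; recs$pal.long <- NA_real_
  plates <- tibble::tibble(holeID = "H9", plate = 201L)
  out <- paleocoordinates(recs, tab, plates)
  expect_equal(sum(!is.na(out$records$pal.lat)), n_young)
  expect_equal(sum(out$skipped$reason == "age outside rotation model span"),
               n_old)
})

test_that("rotations preserve great-circle distances", {
  haversine_deg <- function(p, q) {
    d <- pi / 180
    2 * asin(sqrt(sin((q[1] - p[1]) * d / 2)^2 +
                    cos(p[1] * d) * cos(q[1] * d) *
                      sin((q[2] - p[2]) * d / 2)^2)) / d
  }
  set.seed(10)
  for (i in 1:25) {
    r <- finite_rotation(runif(1, -90, 90), runif(1, -180, 180),
                         runif(1, -179, 179))
    p <- c(runif(1, -80, 80), runif(1, -170, 170))
    q <- c(runif(1, -80, 80), runif(1, -170, 170))
    pr <- unlist(rotate_point(p[1], p[2], r))
    qr <- unlist(rotate_point(q[1], q[2], r))
    expect_equal(unname(haversine_deg(pr, qr)), haversine_deg(p, q),
                 tolerance = 1e-9)
  }
})
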