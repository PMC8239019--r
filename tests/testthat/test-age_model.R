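test_that("hiatus splitting follows the 10 percent of core age range rule", {
  # hole age range 50 Ma: a 7 Ma gap (14%) splits, 4 Ma gaps (8%) do not
  ages <- c(0, 4, 8, 12, 16, 20, 27, 31, 35, 39, 43, 46, 50)
  ties <- ties_tbl(depth = seq(10, 130, 10), age = ages)
  seg <- segment_tiepoints(ties)
  expect_equal(seg$segment, rep(c(1, 2), c(6, 7)))
  # all gaps at 8 percent of the range: one intact segment
  ties2 <- ties_tbl(depth = seq(10, 130, 10), age = seq(0, 48, 4))
  expect_equal(unique(segment_tiepoints(ties2)$segment), 1)
})

test_that("declared structural breaks force splits regardless of age gaps", {
  # age gaps of 10% of the range never split on their own
  ties <- ties_tbl(depth = seq(10, 110, 10), age = seq(1, 2, 0.1))
  expect_equal(unique(segment_tiepoints(ties)$segment), 1)
  seg <- segment_tiepoints(ties, declared_breaks = 55)
  expect_equal(seg$segment, rep(c(1, 2), c(5, 6)))
})

test_that("splitting is invariant to adding ties inside non-gap intervals", {
  ties <- ties_tbl(depth = seq(0, 70, 10),
                   age = c(0, 1, 2, 3, 20, 21, 22, 23))
  base <- segment_tiepoints(ties)
  expect_equal(base$segment, rep(c(1, 2), c(4, 4)))
  # a tie strictly inside the continuous 0-3 Ma stretch must not change
  # where the split happens
  denser <- segment_tiepoints(ties_tbl(depth = c(5, seq(0, 70, 10)),
                                       age = c(0.5, 0, 1, 2, 3, 20, 21, 22, 23)))
  expect_equal(denser$segment, rep(c(1, 2), c(5, 4)))
})

test_that("zonal ages are the mean of the bounding ties with width as error", {
  ties <- ties_tbl(depth = c(10, 20), age = c(5, 6), age.range = c(0.4, 0.2))
  z <- zone_ages(ties, 15)
  expect_equal(z$age, 5.5)
  expect_equal(z$age.err, 1.0)
  # one-sided: a depth below the deepest tie takes that event's age + width
  z2 <- zone_ages(ties, 25)
  expect_equal(z2$age, 6)
  expect_equal(z2$age.err, 0.2)
})

test_that("magnetostratigraphic ties take precedence where they bracket", {
  ties <- ties_tbl(depth = c(10, 20, 30, 40), age = c(1, 2, 3, 4),
                   kind = c("biostratigraphic", "magnetostratigraphic",
                            "magnetostratigraphic", "biostratigraphic"))
  z <- zone_ages(ties, 25)           # bracketed by the two magneto ties
  expect_equal(z$age, 2.5)
  z2 <- zone_ages(ties, 12)          # magneto does not bracket here
  expect_equal(z2$age, 1.5)
  # magneto-only variant is absent without magneto ties
  bio <- ties_tbl(depth = c(10, 20), age = c(1, 2))
  expect_true(all(is.na(zone_ages(bio, 15, magneto_only = TRUE)$age)))
})

test_that("interpolation is linear between ties and exact at tie depths", {
  ties <- ties_tbl(depth = c(10, 20), age = c(1, 2), age.range = c(0.3, 0.5))
  out <- interp_ages(ties, c(10, 15, 20))
  expect_equal(out$age, c(1, 1.5, 2))
  expect_equal(out$age.err[2], 0.5)   # larger of the bracketing ranges
  # outside the span there is no estimate
  expect_true(is.na(interp_ages(ties, 25)$age))
  # fewer than two ties: estimator unavailable
  expect_true(all(is.na(interp_ages(ties[1, ], c(10, 15))$age)))
})

test_that("interpolation reproduces a noiseless piecewise-linear truth", {
  core <- simulate_core(seed = 2, rates = c(10, 40), surface_age = 3)
  ties <- true_tiepoints(core$truth, ties_per_ma = 2)
  depths <- core$truth$sample_depths
  inside <- depths >= min(ties$depth) & depths <= max(ties$depth)
  est <- interp_ages(ties, depths[inside])$age
  truth <- core$truth$age_of(depths[inside])
  # ties are dense enough that each gap lies within one linear piece,
  # except the one gap straddling the rate break
  brk <- core$truth$rate_breaks
  clear <- depths[inside] < max(ties$depth[ties$depth <= brk]) |
    depths[inside] > min(ties$depth[ties$depth >= brk])
  expect_equal(est[clear], truth[clear], tolerance = 1e-12)
})

test_that("trend fits switch from linear to spline at five tie points", {
  lin3 <- fit_trend(ties_tbl(depth = c(0, 10, 20), age = c(0, 1, 2)))
  expect_equal(lin3$type, "linear")
  expect_equal(lin3$n.pts, 3)
  expect_equal(lin3$r2, 1, tolerance = 1e-12)
  # five collinear ties: the smooth reproduces the line
  col5 <- fit_trend(ties_tbl(depth = seq(0, 40, 10), age = seq(0, 4, 1)))
  expect_equal(col5$type, "smooth")
  expect_equal(col5$r2, 1, tolerance = 1e-6)
  expect_equal(col5$predict(c(5, 35)), c(0.5, 3.5), tolerance = 1e-6)
  # singular: all ties at one depth
  expect_null(fit_trend(ties_tbl(depth = rep(5, 3), age = 1:3)))
})

test_that("the spline trend tracks a two-rate core within 0.25 Ma at ties", {
  core <- simulate_core(seed = 9, rates = c(10, 40), depth_span = c(0, 120))
  ties <- true_tiepoints(core$truth, ties_per_ma = 1)
  ties <- ties[unique(round(seq(1, nrow(ties), length.out = 12))), ]   # 12 marker events
  fit <- fit_trend(ties)
  expect_equal(fit$type, "smooth")
  expect_true(all(abs(fit$predict(ties$depth) - ties$age) < 0.25))
})

test_that("model selection minimizes RMSD at ties, with overrides honoured", {
  ties <- ties_tbl(depth = seq(0, 50, 10), age = seq(0, 5, 1))
  sel <- select_model(ties)
  # noiseless linear core: interp and trend tie at zero RMSD; the
  # preference order picks interp
  expect_equal(sel$selected, "interp")
  expect_equal(unname(sel$rmsd["interp"]), 0, tolerance = 1e-12)
  ovr <- select_model(ties, override = "model")
  expect_equal(ovr$selected, "model")
})

test_that("a short shallow segment uses the linear model, a long one the smooth", {
  # hiatus-style core: 3 ties above the gap, many below
  shallow <- ties_tbl(depth = c(5, 25, 45), age = c(0.5, 1.0, 1.5))
  deep <- ties_tbl(depth = seq(100, 200, 10), age = seq(8, 13, 0.5))
  model <- fit_age_depth_model(dplyr::bind_rows(shallow, deep), "H1")
  expect_equal(length(model$segments), 2)
  expect_equal(model$segments[[1]]$trend$type, "linear")
  expect_equal(model$segments[[2]]$trend$type, "smooth")
})

test_that("samples get ages from the selected estimator inside the tie span", {
  ties <- ties_tbl(depth = c(10, 20, 30), age = c(1, 2, 3),
                   age.range = c(0.2, 0.4, 0.2))
  # 3 ties only: disable the hiatus heuristic for this toy hole
  model <- fit_age_depth_model(ties, "H1", hiatus_frac = 0.6)
  samples <- toy_records(4)
  samples$holeID <- "H1"
  samples$sample.depth <- c(5, 10, 25, 35)
  samples$age <- NA_real_
  out <- assign_ages(samples, model)
  # outside the tie span on both ends: dropped
  expect_setequal(out$dropped$rowID, c("r1", "r4"))
  kept <- out$samples
  expect_equal(kept$age[kept$sample.depth == 10], 1)       # exact at tie
  expect_equal(kept$age.err[kept$sample.depth == 10], 0.2)  # that tie's range
  expect_equal(kept$age[kept$sample.depth == 25], 2.5)
  expect_equal(unique(kept$age.calc), "interp")
  expect_equal(unique(kept$segment), 1)
  # records that already carry an age keep it as original
  samples$age <- 7
  orig <- assign_ages(samples, model)
  expect_equal(unique(orig$samples$age.calc), "orig")
  expect_equal(unique(orig$samples$age), 7)
})

test_that("interpolated ages are monotone in depth and bounded by tie ages", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    ties <- ties_tbl(depth = sort(runif(n, 0, 100)),
                     age = sort(runif(n, 0, 40)))
    d <- seq(min(ties$depth), max(ties$depth), length.out = 50)
    est <- interp_ages(ties, d)$age
    expect_true(all(diff(est) >= -1e-12))
    expect_true(all(est >= min(ties$age) - 1e-12 &
                      est <= max(ties$age) + 1e-12))
    zn <- zone_ages(ties, d)$age
    expect_true(all(zn >= min(ties$age) - 1e-12 &
                      zn <= max(ties$age) + 1e-12))
  }
})
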