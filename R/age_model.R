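# Segmented age-depth modelling. Tie points are split into intact stratal
# segments at hiatuses and declared structural breaks; within each segment
# up to five estimators are fitted (zonal means, magneto-only zonal means,
# piecewise interpolation, magneto-only interpolation, and a linear/GAM
# trend) and the best fit to the tie points is selected.

#' Split tie points into intact stratal segments
#'
#' Age gaps between depth-consecutive tie points greater than 10% of the age
#' range of the core are classified as hiatuses, each starting a new
#' segment. Declared structural breaks (faults, slumps, unconformities from
#' drilling reports) also force splits.
#'
#' @param ties Tibble with at least `depth` and `age` (one hole).
#' @param declared_breaks Numeric depths (mbsf) at which to split regardless
#'   of age gaps.
#' @param hiatus_frac Gap threshold as a fraction of the hole's tie-point age
#'   range; default 0.10.
#' @return `ties` sorted by depth with an integer `segment` column (1-based,
#'   shallowest first).
#' @export
segment_tiepoints <- function(ties, declared_breaks = numeric(0),
                              hiatus_frac = 0.10) {
  ties <- arrange(as_tibble(ties), .data$depth)
  if (nrow(ties) == 0) {
    ties$segment <- integer(0)
    return(ties)
  }
  age_range <- max(ties$age) - min(ties$age)
  gap <- c(0, diff(ties$age))
  # strict "greater than" with a relative tolerance so gaps sitting exactly
  # on the threshold (up to float noise) do not split
  new_seg <- gap > hiatus_frac * age_range * (1 + 1e-9) & age_range > 0
  if (length(declared_breaks) > 0) {
    mid <- c(-Inf, ties$depth[-1] - diff(ties$depth) / 2)
    crossed <- vapply(seq_len(nrow(ties)), function(i) {
      i > 1 && any(declared_breaks > ties$depth[i - 1] &
                     declared_breaks <= ties$depth[i])
    }, logical(1))
    new_seg <- new_seg | crossed
  }
  ties$segment <- cumsum(c(TRUE, new_seg[-1]))
  ties
}

# Bracketing tie indices for each depth: the deepest tie at or above, and
# the shallowest tie at or below. NA outside the tie span on that side.
.bracket <- function(depths, tie_depths) {
  lower <- findInterval(depths, tie_depths)            # ties above (shallower or equal)
  upper <- length(tie_depths) + 1 -
    findInterval(-depths, rev(-tie_depths))            # ties below (deeper or equal)
  lower[lower == 0] <- NA
  upper[upper > length(tie_depths)] <- NA
  list(above = lower, below = upper)
}

#' Zonal-mean ages for sample depths
#'
#' Each depth interval between tie points is a zone; its samples take the
#' mean of the bounding tie ages with the bounding width as the error.
#' Depths bounded on one side only take that tie's age with its own
#' calibrated width as error. When magnetostratigraphic ties bracket a
#' depth they are given preference over biostratigraphic ones.
#'
#' @param ties Segment tie points (`depth`, `age`, `age.range`, `kind`).
#' @param depths Sample depths.
#' @param magneto_only Use magnetostratigraphic ties exclusively (the
#'   magneto-variant estimator); returns all-`NA` when the segment has none.
#' @return Tibble `age`, `age.err`, `zone` (label of the bounding ties).
#' @export
zone_ages <- function(ties, depths, magneto_only = FALSE) {
  ties <- arrange(as_tibble(ties), .data$depth)
  use <- if (magneto_only) ties[ties$kind == "magnetostratigraphic", ] else ties
  if (nrow(use) == 0) {
    return(tibble(age = rep(NA_real_, length(depths)),
                  age.err = NA_real_, zone = NA_character_))
  }
  mag <- ties[ties$kind == "magnetostratigraphic", ]
  one <- function(d, tt) {
    br <- .bracket(d, tt$depth)
    a <- br$above; b <- br$below
    if (is.na(a) && is.na(b)) {
      return(list(age = NA_real_, err = NA_real_, zone = NA_character_))
    }
    if (is.na(a)) a <- b
    if (is.na(b)) b <- a
    list(age = mean(c(tt$age[a], tt$age[b])),
         err = if (a == b) tt$age.range[a] else abs(tt$age[b] - tt$age[a]),
         zone = paste(unique(stats::na.omit(c(tt$taxon[a], tt$taxon[b]))),
                      collapse = " / "))
  }
  res <- lapply(depths, function(d) {
    if (!magneto_only && nrow(mag) >= 1) {
      br <- .bracket(d, mag$depth)
      if (!is.na(br$above) && !is.na(br$below)) return(one(d, mag))
    }
    one(d, use)
  })
  tibble(age = vapply(res, `[[`, numeric(1), "age"),
         age.err = vapply(res, `[[`, numeric(1), "err"),
         zone = vapply(res, `[[`, character(1), "zone"))
}

#' Piecewise-linear interpolation of tie-point ages
#'
#' Assumes a continuous sedimentation rate between depth-consecutive tie
#' points and interpolates sample ages linearly between them. The error is
#' propagated as the larger of the two bracketing tie age ranges. Depths
#' outside the tie span get `NA`.
#'
#' @inheritParams zone_ages
#' @return Tibble `age`, `age.err`.
#' @export
interp_ages <- function(ties, depths, magneto_only = FALSE) {
  ties <- arrange(as_tibble(ties), .data$depth)
  if (magneto_only) ties <- ties[ties$kind == "magnetostratigraphic", ]
  if (nrow(ties) < 2) {
    return(tibble(age = rep(NA_real_, length(depths)), age.err = NA_real_))
  }
  # collapse ties at identical depth to their mean age
  agg <- ties |>
    group_by(.data$depth) |>
    summarise(age = mean(.data$age), age.range = max(.data$age.range),
              .groups = "drop")
  if (nrow(agg) < 2) {
    return(tibble(age = rep(NA_real_, length(depths)), age.err = NA_real_))
  }
  age <- stats::approx(agg$depth, agg$age, xout = depths, rule = 1,
                       ties = "ordered")$y
  br <- .bracket(depths, agg$depth)
  err <- pmax(agg$age.range[br$above], agg$age.range[br$below])
  err[is.na(age)] <- NA
  tibble(age = age, age.err = err)
}

#' Fit the trend (linear or GAM) age-depth model of a segment
#'
#' With fewer than 5 tie points an ordinary least-squares line of age on
#' depth is fitted for the segment; with 5 or more, a penalized cubic
#' regression spline smooth (basis dimension `min(10, n - 1)`), with
#' smoothness chosen by generalized cross-validation whose effective-degrees
#' -of-freedom cost is inflated by a gamma of 1.1 to damp overfitting of
#' sedimentation-rate wiggles.
#'
#' @param ties Segment tie points (`depth`, `age`).
#' @param gamma GCV penalty inflation; default 1.1.
#' @return List of class `"trend_fit"`: `fit`, `type` (`"linear"` or
#'   `"smooth"`), `r2` (unadjusted), `n.pts`, and `predict(depths)`. `NULL`
#'   when the fit is singular (fewer than 2 distinct depths).
#' @export
fit_trend <- function(ties, gamma = 1.1) {
  ties <- as_tibble(ties)
  n <- nrow(ties)
  if (n < 2 || length(unique(ties$depth)) < 2) return(NULL)
  dat <- data.frame(depth = ties$depth, age = ties$age)
  if (n < 5) {
    fit <- stats::lm(age ~ depth, data = dat)
    type <- "linear"
  } else {
    k <- min(10, n - 1)
    fit <- mgcv::gam(age ~ s(depth, k = k, bs = "cr"), data = dat,
                     gamma = gamma, method = "GCV.Cp")
    type <- "smooth"
  }
  pred <- stats::fitted(fit)
  ss_res <- sum((dat$age - pred)^2)
  ss_tot <- sum((dat$age - mean(dat$age))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(
    fit = fit, type = type, r2 = r2, n.pts = n,
    predict = function(depths) {
      as.numeric(stats::predict(fit, newdata = data.frame(depth = depths)))
    }
  ), class = "trend_fit")
}

#' Fit all age-depth estimators for one hole
#'
#' Segments the tie points ([segment_tiepoints()]) and fits, per segment,
#' the zonal, magneto-zonal, interpolation, magneto-interpolation and trend
#' estimators, then selects the best ([select_model()]).
#'
#' @param ties Tie-point tibble for one hole (`depth`, `age`, `age.range`,
#'   `kind`).
#' @param holeID Hole identifier carried into outputs.
#' @param declared_breaks,hiatus_frac Passed to [segment_tiepoints()].
#' @param override Optional estimator name (`"zone"`, `"magneto"`,
#'   `"interp"`, `"model"`) forcing the choice for this hole, standing in
#'   for a manual confirmation of the age model.
#' @return Object of class `"age_depth_model"`: list with `holeID`, `ties`
#'   (with segments) and `segments`, each holding its ties, trend fit,
#'   selected estimator and diagnostics.
#' @export
fit_age_depth_model <- function(ties, holeID = NA_character_,
                                declared_breaks = numeric(0),
                                hiatus_frac = 0.10, override = NULL) {
  ties <- segment_tiepoints(ties, declared_breaks, hiatus_frac)
  segments <- lapply(split(ties, ties$segment), function(seg) {
    trend <- fit_trend(seg)
    sel <- select_model(seg, trend, override = override)
    list(ties = seg,
         depth_range = range(seg$depth),
         trend = trend,
         selected = sel$selected,
         rmsd = sel$rmsd,
         r2 = if (!is.null(trend)) trend$r2 else NA_real_,
         n.pts = nrow(seg))
  })
  structure(list(holeID = holeID, ties = ties, segments = segments),
            class = "age_depth_model")
}

#' Select the best-fitting estimator for a segment
#'
#' Candidates are scored by the root-mean-square deviation between the ages
#' they predict at the tie depths and the tie ages themselves; the lowest
#' RMSD wins. RMSD ties break in the order interp > model > zone > magneto,
#' preferring estimators that honour the tie points exactly. A per-hole
#' override (standing in for manual confirmation of the age model) bypasses
#' the criterion.
#'
#' @param seg Segment tie points.
#' @param trend A `"trend_fit"` for the segment (or `NULL`).
#' @param override Optional estimator name.
#' @return List `selected` (one of `"zone"`, `"magneto"`, `"interp"`,
#'   `"model"`, or `NA` if nothing is available) and `rmsd` (named vector of
#'   candidate scores).
#' @export
select_model <- function(seg, trend = fit_trend(seg), override = NULL) {
  seg <- as_tibble(seg)
  preds <- list(
    interp = interp_ages(seg, seg$depth)$age,
    model = if (!is.null(trend)) trend$predict(seg$depth) else rep(NA_real_, nrow(seg)),
    zone = zone_ages(seg, seg$depth)$age,
    magneto = interp_ages(seg, seg$depth, magneto_only = TRUE)$age
  )
  if (all(is.na(preds$magneto))) {
    preds$magneto <- zone_ages(seg, seg$depth, magneto_only = TRUE)$age
  }
  rmsd <- vapply(preds, function(p) {
    if (all(is.na(p))) return(NA_real_)
    sqrt(mean((p - seg$age)^2, na.rm = TRUE))
  }, numeric(1))
  if (!is.null(override)) {
    stopifnot(override %in% names(preds))
    return(list(selected = override, rmsd = rmsd))
  }
  if (all(is.na(rmsd))) return(list(selected = NA_character_, rmsd = rmsd))
  # which.min on the preference-ordered vector breaks RMSD ties as documented
  list(selected = names(preds)[which.min(rmsd)], rmsd = rmsd)
}

#' Assign modelled ages to samples
#'
#' Each sample falling inside a segment's tie-point depth span receives the
#' selected estimator's age and error, plus the parallel estimates of every
#' other estimator for the record. Samples outside the depth span of all
#' segments cannot be confidently dated and are dropped (reason logged in
#' the returned `dropped` tibble). Samples that already carry a numeric age
#' keep it, with `age.calc = "orig"`.
#'
#' @param samples Occurrence tibble for one hole (needs `sample.depth`; an
#'   existing non-`NA` `age` is preserved as original).
#' @param model An `"age_depth_model"`.
#' @return List `samples` (dated records, with `age`, `age.err`, `segment`,
#'   `age.calc` and the per-estimator columns filled) and `dropped` (rowID +
#'   reason).
#' @export
assign_ages <- function(samples, model) {
  stopifnot(inherits(model, "age_depth_model"))
  samples <- as_occurrences(samples)
  orig <- !is.na(samples$age)
  samples$age.calc[orig] <- "orig"
  todo <- which(!orig)
  seg_of <- rep(NA_integer_, nrow(samples))
  for (k in seq_along(model$segments)) {
    seg <- model$segments[[k]]
    inside <- samples$sample.depth >= seg$depth_range[1] &
      samples$sample.depth <= seg$depth_range[2]
    seg_of[which(inside)[which(inside) %in% todo & is.na(seg_of[which(inside)])]] <- k
  }
  drop_idx <- todo[is.na(seg_of[todo])]
  dropped <- tibble(rowID = samples$rowID[drop_idx],
                    reason = "outside tie-point depth span")
  for (k in seq_along(model$segments)) {
    seg <- model$segments[[k]]
    idx <- which(seg_of == k)
    if (length(idx) == 0) next
    d <- samples$sample.depth[idx]
    zn <- zone_ages(seg$ties, d)
    zn_mag <- zone_ages(seg$ties, d, magneto_only = TRUE)
    ip <- interp_ages(seg$ties, d)
    ip_mag <- interp_ages(seg$ties, d, magneto_only = TRUE)
    md <- if (!is.null(seg$trend)) seg$trend$predict(d) else rep(NA_real_, length(d))
    samples$zone[idx] <- zn$zone
    samples$zon.age[idx] <- zn$age
    samples$rng.age[idx] <- zn$age.err
    samples$int.age[idx] <- ip$age
    samples$err.int.age[idx] <- ip$age.err
    samples$mag.zone[idx] <- zn_mag$zone
    samples$mag.age[idx] <- zn_mag$age
    samples$int.mag.age[idx] <- ip_mag$age
    samples$err.int.mag.age[idx] <- ip_mag$age.err
    samples$mod.age[idx] <- md
    samples$r2[idx] <- seg$r2
    samples$n.pts[idx] <- seg$n.pts
    samples$segment[idx] <- k
    sel <- seg$selected
    samples$age.calc[idx] <- sel
    est <- switch(sel,
      interp = list(age = ip$age, err = ip$age.err),
      model = list(age = md, err = seg$rmsd[["model"]]),
      zone = list(age = zn$age, err = zn$age.err),
      magneto = if (!all(is.na(ip_mag$age))) {
        list(age = ip_mag$age, err = ip_mag$age.err)
      } else {
        list(age = zn_mag$age, err = zn_mag$age.err)
      },
      list(age = rep(NA_real_, length(d)), err = NA_real_)
    )
    samples$age[idx] <- est$age
    samples$age.err[idx] <- est$err
  }
  undated <- which(!orig & is.na(samples$age))
  undated <- setdiff(undated, drop_idx)
  if (length(undated) > 0) {
    dropped <- bind_rows(dropped, tibble(rowID = samples$rowID[undated],
                                         reason = "no estimator available"))
  }
  keep <- setdiff(seq_len(nrow(samples)), c(drop_idx, undated))
  list(samples = samples[keep, ], dropped = dropped)
}

#' @export
print.age_depth_model <- function(x, ...) {
  cat("Age-depth model for hole", x$holeID, "-", length(x$segments),
      "segment(s),", nrow(x$ties), "tie point(s)\n")
  for (k in seq_along(x$segments)) {
    s <- x$segments[[k]]
    cat(sprintf("  segment %d: %.1f-%.1f mbsf, n.pts %d, selected %s (r2 %.3f)\n",
                k, s$depth_range[1], s$depth_range[2], s$n.pts,
                s$selected, s$r2))
  }
  invisible(x)
}

#' Plot an age-depth model with all estimators overlaid
#'
#' Diagnostic panel: tie points plus the zonal, interpolation, magneto and
#' trend estimates across the modelled depth span, one panel per hole.
#'
#' @param x An `"age_depth_model"`.
#' @param n_depth Number of evaluation depths.
#' @param ... Unused.
#' @return A ggplot object (requires ggplot2).
#' @export
plot.age_depth_model <- function(x, n_depth = 200, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  curves <- purrr::map_dfr(seq_along(x$segments), function(k) {
    seg <- x$segments[[k]]
    d <- seq(seg$depth_range[1], seg$depth_range[2], length.out = n_depth)
    bind_rows(
      tibble(depth = d, age = zone_ages(seg$ties, d)$age, estimator = "zone"),
      tibble(depth = d, age = interp_ages(seg$ties, d)$age, estimator = "interp"),
      tibble(depth = d, age = interp_ages(seg$ties, d, TRUE)$age, estimator = "int mag"),
      tibble(depth = d,
             age = if (!is.null(seg$trend)) seg$trend$predict(d) else NA_real_,
             estimator = "model")
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, y = .data$depth)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$estimator), na.rm = TRUE) +
    ggplot2::geom_point(data = x$ties, ggplot2::aes(shape = .data$kind),
                        size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "Depth (mbsf)",
                  title = paste("Age-depth model:", x$holeID)) +
    ggplot2::theme_minimal()
}
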