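# Paleocoordinates. A plate-motion model is a table of total finite
# rotations (Euler pole + angle at an age) per moving plate relative to a
# fixed plate, chained in a circuit to the anchor plate. Sample coordinates
# are rotated back to their deposition-age positions. Angle sign convention:
# positive = counter-clockwise looking down the pole axis from outside the
# sphere (the convention of GPlates ".rot" files).

.deg <- pi / 180

.ll_to_xyz <- function(lat, lon) {
  la <- lat * .deg; lo <- lon * .deg
  rbind(cos(la) * cos(lo), cos(la) * sin(lo), sin(la))
}

.xyz_to_ll <- function(v) {
  lat <- asin(pmin(1, pmax(-1, v[3, ]))) / .deg
  lon <- atan2(v[2, ], v[1, ]) / .deg
  lon[lon <= -180] <- lon[lon <= -180] + 360
  lon[lon > 180] <- lon[lon > 180] - 360
  list(lat = lat, lon = lon)
}

#' Construct a finite rotation
#'
#' @param pole_lat,pole_lon Euler pole position, decimal degrees.
#' @param angle Rotation angle in degrees, positive counter-clockwise about
#'   the pole seen from outside the sphere.
#' @param age Age (Ma) the total rotation refers to, `NA` for a bare
#'   rotation.
#' @return Object of class `"finite_rotation"`.
#' @export
finite_rotation <- function(pole_lat, pole_lon, angle, age = NA_real_) {
  stopifnot(abs(pole_lat) <= 90)
  structure(list(pole_lat = pole_lat, pole_lon = pole_lon,
                 angle = angle, age = age),
            class = "finite_rotation")
}

#' @export
print.finite_rotation <- function(x, ...) {
  cat(sprintf("Finite rotation: pole (%.3f, %.3f), angle %.3f deg%s\n",
              x$pole_lat, x$pole_lon, x$angle,
              if (is.na(x$age)) "" else sprintf(" at %.2f Ma", x$age)))
  invisible(x)
}

#' Rotation matrix of a finite rotation
#'
#' Rodrigues' formula about the unit pole axis.
#'
#' @param r A `"finite_rotation"`.
#' @return 3x3 orthogonal matrix.
#' @export
rotation_matrix <- function(r) {
  u <- as.numeric(.ll_to_xyz(r$pole_lat, r$pole_lon))
  th <- r$angle * .deg
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# matrix -> axis-angle; returns angle in [0, 180] with pole on the
# corresponding axis; identity gets a conventional north pole, zero angle.
.matrix_to_rotation <- function(m, age = NA_real_) {
  tr <- sum(diag(m))
  v <- c(m[3, 2] - m[2, 3], m[1, 3] - m[3, 1], m[2, 1] - m[1, 2])
  s <- sqrt(sum(v^2))                  # 2 sin(theta)
  th <- atan2(s, tr - 1)               # stable for small angles
  if (s < 1e-12 && tr - 1 > 0) return(finite_rotation(90, 0, 0, age))
  if (th > pi - 1e-6) {
    # near a half-turn the skew part vanishes; axis from the symmetric part
    B <- (m + diag(3)) / 2
    u <- sqrt(pmax(0, diag(B)))
    i <- which.max(u)
    u <- B[, i] / u[i]
  } else {
    u <- v / s
  }
  ll <- .xyz_to_ll(matrix(u, 3, 1))
  finite_rotation(ll$lat, ll$lon, th / .deg, age)
}

#' Compose and invert finite rotations
#'
#' `compose_rotations(r2, r1)` is the rotation "apply `r1`, then `r2`";
#' composition is associative but not commutative. The inverse negates the
#' angle about the same pole.
#'
#' @param r2,r1,r `"finite_rotation"` objects.
#' @return A `"finite_rotation"`.
#' @export
compose_rotations <- function(r2, r1) {
  .matrix_to_rotation(rotation_matrix(r2) %*% rotation_matrix(r1))
}

#' @rdname compose_rotations
#' @export
invert_rotation <- function(r) {
  finite_rotation(r$pole_lat, r$pole_lon, -r$angle, r$age)
}

#' Parse a GPlates-style plate-rotation file
#'
#' Whitespace-delimited lines: moving plate, age, pole latitude, pole
#' longitude, angle, fixed plate, then an optional `!` comment. Lines whose
#' moving plate is 999 are comment/terminator lines and skipped. Per moving
#' plate, ages must be strictly increasing; every fixed plate must itself
#' chain (acyclically) to the anchor plate.
#'
#' @param path Rotation file.
#' @param anchor Anchor plate id; default `0` (`"000"`), with `"001"` also
#'   treated as anchored to it.
#' @return List of class `"rotation_table"`: `rotations` tibble
#'   (`moving`, `age`, `pole_lat`, `pole_lon`, `angle`, `fixed`), `anchor`.
#' @export
parse_rotation_file <- function(path, anchor = 0L) {
  if (!file.exists(path)) stop("cannot read rotation file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\\s+")
  ok <- vapply(fields, length, integer(1)) >= 6
  if (!all(ok)) stop("malformed rotation line(s)", call. = FALSE)
  tab <- tibble(
    moving = as.integer(vapply(fields, `[[`, character(1), 1)),
    age = as.numeric(vapply(fields, `[[`, character(1), 2)),
    pole_lat = as.numeric(vapply(fields, `[[`, character(1), 3)),
    pole_lon = as.numeric(vapply(fields, `[[`, character(1), 4)),
    angle = as.numeric(vapply(fields, `[[`, character(1), 5)),
    fixed = as.integer(vapply(fields, `[[`, character(1), 6))
  )
  tab <- tab[tab$moving != 999L, ]
  mono <- tab |>
    group_by(.data$moving) |>
    summarise(ok = !is.unsorted(.data$age, strictly = TRUE), .groups = "drop")
  if (!all(mono$ok)) {
    stop("non-monotone ages for plate(s): ",
         paste(mono$moving[!mono$ok], collapse = ", "), call. = FALSE)
  }
  # circuit closure: walk each plate's fixed chain to the anchor
  fixed_of <- tab |>
    group_by(.data$moving) |>
    summarise(fixed = .data$fixed[1], .groups = "drop")
  anchors <- c(anchor, 1L)
  for (p in fixed_of$moving) {
    seen <- integer(0)
    q <- p
    while (!(q %in% anchors)) {
      if (q %in% seen) stop("rotation circuit cycle at plate ", q, call. = FALSE)
      seen <- c(seen, q)
      nxt <- fixed_of$fixed[match(q, fixed_of$moving)]
      if (is.na(nxt)) {
        stop("unknown fixed plate ", q, " in circuit of plate ", p, call. = FALSE)
      }
      q <- nxt
    }
  }
  structure(list(rotations = tab, anchor = anchor), class = "rotation_table")
}

# total rotation of `plate` relative to its immediate fixed plate at `age`,
# by stage interpolation between the bracketing table entries. NULL when the
# age is outside the plate's covered span.
.plate_rotation <- function(plate, age, table) {
  rows <- table$rotations[table$rotations$moving == plate, ]
  if (nrow(rows) == 0) return(NULL)
  if (age > max(rows$age) + 1e-9) return(NULL)
  # implicit identity at age 0 when the table starts later
  if (min(rows$age) > 0) {
    rows <- bind_rows(tibble(moving = plate, age = 0, pole_lat = 90,
                             pole_lon = 0, angle = 0, fixed = rows$fixed[1]),
                      rows)
  }
  if (age < min(rows$age) - 1e-9) return(NULL)
  i <- findInterval(age, rows$age)
  i <- max(1, min(i, nrow(rows)))
  r1 <- finite_rotation(rows$pole_lat[i], rows$pole_lon[i], rows$angle[i],
                        rows$age[i])
  if (abs(age - rows$age[i]) < 1e-12 || i == nrow(rows)) {
    return(list(rotation = r1, fixed = rows$fixed[i]))
  }
  r2 <- finite_rotation(rows$pole_lat[i + 1], rows$pole_lon[i + 1],
                        rows$angle[i + 1], rows$age[i + 1])
  f <- (age - rows$age[i]) / (rows$age[i + 1] - rows$age[i])
  # stage rotation r2 o r1^-1, scaled linearly in its angle about its axis
  stage <- compose_rotations(r2, invert_rotation(r1))
  stage_f <- finite_rotation(stage$pole_lat, stage$pole_lon, stage$angle * f)
  list(rotation = compose_rotations(stage_f, r1), fixed = rows$fixed[i])
}

#' Total rotation of a plate relative to the anchor at an age
#'
#' Interpolates between the bracketing total rotations of the plate in
#' stage-rotation space (the stage rotation's angle is scaled linearly about
#' its fixed axis, equivalent to spherical linear interpolation), then
#' composes through the plate circuit to the anchor.
#'
#' @param plate Moving plate id.
#' @param age Age in Ma.
#' @param table A `"rotation_table"`.
#' @return A `"finite_rotation"`, or `NULL` when the age lies outside the
#'   plate's (or its circuit's) covered span -- such sites cannot be
#'   reconstructed and are skipped.
#' @export
total_rotation <- function(plate, age, table) {
  stopifnot(inherits(table, "rotation_table"))
  total <- finite_rotation(90, 0, 0, age)
  q <- plate
  anchors <- c(table$anchor, 1L)
  while (!(q %in% anchors)) {
    step <- .plate_rotation(q, age, table)
    if (is.null(step)) return(NULL)
    total <- compose_rotations(step$rotation, total)
    q <- step$fixed
  }
  total$age <- age
  total
}

#' Rotate a point on the sphere
#'
#' @param latitude,longitude Point coordinates, decimal degrees (vectors
#'   allowed).
#' @param rotation A `"finite_rotation"`.
#' @return Tibble `pal.lat`, `pal.long`, with latitude in \[-90, 90\] and
#'   longitude in (-180, 180\].
#' @export
rotate_point <- function(latitude, longitude, rotation) {
  m <- rotation_matrix(rotation)
  v <- m %*% .ll_to_xyz(latitude, longitude)
  ll <- .xyz_to_ll(v)
  tibble(pal.lat = ll$lat, pal.long = ll$lon)
}

#' Reconstruct paleocoordinates for occurrence records
#'
#' Rotates each record's site coordinates by the total rotation of its plate
#' at the record's age. Modern records (age 0) keep their modern
#' coordinates. Records without a plate assignment, or whose age is outside
#' the rotation model's span for that plate, are left with `NA`
#' paleocoordinates and reported -- downstream they fail the crucial-column
#' filter.
#'
#' @param records Occurrence tibble with `age`, `latitude`, `longitude`.
#' @param table A `"rotation_table"`.
#' @param plate_assignments Tibble (`holeID`, `plate`).
#' @return List `records` (with `pal.lat`/`pal.long` filled where possible)
#'   and `skipped` (tibble of `rowID`, `reason`).
#' @export
paleocoordinates <- function(records, table, plate_assignments) {
  records <- as_occurrences(records)
  plate <- plate_assignments$plate[match(records$holeID, plate_assignments$holeID)]
  skipped <- tibble(rowID = character(0), reason = character(0))
  no_plate <- is.na(plate) & !is.na(records$age)
  if (any(no_plate)) {
    skipped <- bind_rows(skipped, tibble(rowID = records$rowID[no_plate],
                                         reason = "no plate assignment"))
  }
  modern <- !is.na(records$age) & records$age == 0
  records$pal.lat[modern] <- records$latitude[modern]
  records$pal.long[modern] <- records$longitude[modern]
  todo <- which(!modern & !no_plate & !is.na(records$age) &
                  !is.na(records$latitude) & !is.na(records$longitude))
  if (length(todo) > 0) {
    key <- paste(plate[todo], records$age[todo], sep = "\r")
    for (k in unique(key)) {
      idx <- todo[key == k]
      rot <- total_rotation(plate[idx[1]], records$age[idx[1]], table)
      if (is.null(rot)) {
        skipped <- bind_rows(skipped, tibble(
          rowID = records$rowID[idx], reason = "age outside rotation model span"))
        next
      }
      ll <- rotate_point(records$latitude[idx], records$longitude[idx], rot)
      records$pal.lat[idx] <- ll$pal.lat
      records$pal.long[idx] <- ll$pal.long
    }
  }
  list(records = records, skipped = skipped)
}
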