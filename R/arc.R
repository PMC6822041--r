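# Traditional morphometric protocol: inscribed-circle dorsal arc angles and
# the core-to-sheath length ratio, from seven named claw points.
#
# All geometry is resolved with an explicit "through" point, so no clockwise
# orientation convention is assumed, and every output is invariant under
# rigid motion; arcs and the ratio are additionally invariant under uniform
# scaling.

#' Circumcircle through three points
#'
#' @param p1,p2,p3 Numeric length-2 points.
#' @return A list with `center` (length-2) and `radius`.
#' @details Errors with a degenerate-geometry message when the points are
#'   collinear within tolerance (twice the triangle area below `1e-9` times
#'   the squared largest pairwise distance).
#' @export
fit_circle <- function(p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 2L, length(p2) == 2L, length(p3) == 2L)
  if (any(!is.finite(c(p1, p2, p3))))
    stop("fit_circle: non-finite input point", call. = FALSE)
  cross2 <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                (p3[1] - p1[1]) * (p2[2] - p1[2]))  # twice the triangle area
  maxd2 <- max(sum((p1 - p2)^2), sum((p1 - p3)^2), sum((p2 - p3)^2))
  if (maxd2 == 0 || cross2 < 1e-9 * maxd2)
    stop("degenerate geometry: the three points are collinear (or coincident)",
         call. = FALSE)
  # Perpendicular-bisector linear system, solved relative to p1 for stability.
  a <- p2 - p1; b <- p3 - p1
  A <- rbind(a, b)
  rhs <- c(sum(a^2), sum(b^2)) / 2
  center <- p1 + drop(solve(A, rhs))
  list(center = center, radius = sqrt(sum((p1 - center)^2)))
}

#' Central angle of the arc from a to b that contains a third point
#'
#' @param center Circle center.
#' @param a,b Arc endpoints on the circle.
#' @param through A point on the circle lying on the intended arc, used to
#'   disambiguate the two candidate arcs.
#' @return The arc's central angle in degrees, in (0, 360).
#' @export
subtended_arc_deg <- function(center, a, b, through) {
  center <- as.numeric(center); a <- as.numeric(a); b <- as.numeric(b)
  through <- as.numeric(through)
  radii <- c(sqrt(sum((a - center)^2)), sqrt(sum((b - center)^2)),
             sqrt(sum((through - center)^2)))
  rbar <- mean(radii)
  if (rbar <= 0 || any(abs(radii - rbar) > 0.01 * rbar))
    stop("subtended_arc_deg: points are not equidistant from the center (within 1%)",
         call. = FALSE)
  ang <- function(p) atan2(p[2] - center[2], p[1] - center[1])
  two_pi <- 2 * pi
  d_ab <- (ang(b) - ang(a)) %% two_pi
  d_at <- (ang(through) - ang(a)) %% two_pi
  eps <- 1e-12
  if (d_at < eps || abs(d_at - d_ab) < eps * max(1, d_ab) ||
      (two_pi - d_at) < eps)
    stop("subtended_arc_deg: `through` coincides with an arc endpoint", call. = FALSE)
  res <- if (d_at <= d_ab) d_ab else two_pi - d_ab
  rad2deg(res)
}

#' Extract the seven points of the traditional protocol
#'
#' Maps the canonical landmark scheme to the seven named points:
#' keratinous-sheath tip (LM6), bony-core tip (LM4), the midpoint of the
#' crescent-shaped articulation surface (midpoint of LM1-LM2), the dorsal
#' lips of the core (LM1) and sheath (first SL3 semilandmark, adjacent to
#' LM1), and the index midpoints of the two dorsal curves.
#'
#' @param config A [claw_config()].
#' @return A named list of seven length-2 points (class `seven_points`).
#' @export
extract_seven_points <- function(config) {
  stopifnot(is_claw_config(config))
  X <- config$coords
  rng <- curve_ranges()
  sl1 <- seq(rng$start[rng$curve == "SL1"], rng$stop[rng$curve == "SL1"])
  sl3 <- seq(rng$start[rng$curve == "SL3"], rng$stop[rng$curve == "SL3"])
  mid1 <- sl1[floor((length(sl1) + 1) / 2)]   # 7th of 13
  mid3 <- sl3[floor((length(sl3) + 2) / 2)]   # 14th of 28
  structure(list(
    sheath_tip       = X[6L, ],
    core_tip         = X[4L, ],
    articulation_mid = (X[1L, ] + X[2L, ]) / 2,
    core_dorsal_lip  = X[1L, ],
    sheath_dorsal_lip = X[sl3[1L], ],
    core_arc_mid     = X[mid1, ],
    sheath_arc_mid   = X[mid3, ]),
    class = "seven_points")
}

fit_circle_named <- function(p1, p2, p3, what) {
  tryCatch(fit_circle(p1, p2, p3), error = function(e)
    stop(sprintf("%s circle: %s", what, conditionMessage(e)), call. = FALSE))
}

#' Traditional arc measurements from the seven-point protocol
#'
#' The dorsal arc of each structure is the central angle of the circle fitted
#' through its dorsal lip, dorsal-arc midpoint, and tip (arc taken through
#' the midpoint). Lengths are arc lengths on the circle fitted through the
#' articulation midpoint, the dorsal-arc midpoint, and the structure's tip;
#' a straight-line (`"chord"`) alternative is available.
#'
#' @param points A `seven_points` object (see [extract_seven_points()]).
#' @param length_method `"arc"` (default) or `"chord"`.
#' @return A list of class `arc_measurement` with `core_arc_deg`,
#'   `sheath_arc_deg`, `core_length`, `sheath_length`, `length_ratio`.
#' @export
measure_claw <- function(points, length_method = c("arc", "chord")) {
  length_method <- match.arg(length_method)
  stopifnot(inherits(points, "seven_points"))
  p <- points

  core_circ <- fit_circle_named(p$core_dorsal_lip, p$core_arc_mid, p$core_tip,
                                "core arc")
  core_arc <- subtended_arc_deg(core_circ$center, p$core_dorsal_lip, p$core_tip,
                                p$core_arc_mid)
  sheath_circ <- fit_circle_named(p$sheath_dorsal_lip, p$sheath_arc_mid,
                                  p$sheath_tip, "sheath arc")
  sheath_arc <- subtended_arc_deg(sheath_circ$center, p$sheath_dorsal_lip,
                                  p$sheath_tip, p$sheath_arc_mid)

  if (length_method == "arc") {
    core_len_circ <- fit_circle_named(p$articulation_mid, p$core_arc_mid,
                                      p$core_tip, "core length")
    core_len <- core_len_circ$radius *
      deg2rad(subtended_arc_deg(core_len_circ$center, p$articulation_mid,
                                p$core_tip, p$core_arc_mid))
    sheath_len_circ <- fit_circle_named(p$articulation_mid, p$sheath_arc_mid,
                                        p$sheath_tip, "sheath length")
    sheath_len <- sheath_len_circ$radius *
      deg2rad(subtended_arc_deg(sheath_len_circ$center, p$articulation_mid,
                                p$sheath_tip, p$sheath_arc_mid))
  } else {
    core_len <- sqrt(sum((p$core_tip - p$articulation_mid)^2))
    sheath_len <- sqrt(sum((p$sheath_tip - p$articulation_mid)^2))
  }
  if (core_len <= 0 || sheath_len <= 0)
    stop("degenerate geometry: non-positive structure length", call. = FALSE)
  ratio <- core_len / sheath_len
  if (ratio > 1.2)
    warning(sprintf("core/sheath length ratio %.3f exceeds 1.2 (biologically implausible)",
                    ratio))
  structure(list(core_arc_deg = core_arc, sheath_arc_deg = sheath_arc,
                 core_length = core_len, sheath_length = sheath_len,
                 length_ratio = ratio, length_method = length_method),
            class = "arc_measurement")
}

#' @export
print.arc_measurement <- function(x, ...) {
  cat(sprintf("arc_measurement: core %.2f deg, sheath %.2f deg, length ratio %.4f\n",
              x$core_arc_deg, x$sheath_arc_deg, x$length_ratio))
  invisible(x)
}

#' Measure a batch of configurations
#'
#' Runs the seven-point protocol on each configuration. Specimens with
#' degenerate geometry (near-flat claws) are excluded with a warning rather
#' than aborting the batch; their ids are recorded in the `excluded`
#' attribute.
#'
#' @param configs List of [claw_config()] objects.
#' @param length_method Passed to [measure_claw()].
#' @return A data frame with one row per measured specimen.
#' @export
measure_claws <- function(configs, length_method = c("arc", "chord")) {
  length_method <- match.arg(length_method)
  rows <- vector("list", length(configs))
  excluded <- character(0)
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    m <- tryCatch(measure_claw(extract_seven_points(cfg), length_method),
                  error = function(e) e)
    if (inherits(m, "error")) {
      warning(sprintf("specimen '%s' excluded: %s", cfg$specimen_id,
                      conditionMessage(m)), call. = FALSE)
      excluded <- c(excluded, cfg$specimen_id)
      next
    }
    rows[[i]] <- data.frame(specimen_id = cfg$specimen_id, species = cfg$species,
                            ecology = cfg$ecology,
                            core_arc_deg = m$core_arc_deg,
                            sheath_arc_deg = m$sheath_arc_deg,
                            core_length = m$core_length,
                            sheath_length = m$sheath_length,
                            length_ratio = m$length_ratio,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "excluded") <- excluded
  out
}
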