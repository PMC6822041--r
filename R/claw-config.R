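# Core domain types: the 83-point claw landmark configuration and the
# bony-core / keratinous-sheath landmark partition.
#
# Canonical landmark ordering (1-based, used in all user-facing I/O):
#   LM1-LM6   fixed landmarks
#   7-19      SL1, dorsal bony core      (13 semilandmarks, LM1 -> LM4)
#   20-37     SL2, ventral bony core     (18 semilandmarks, LM3 -> LM4)
#   38-65     SL3, dorsal keratinous sheath (28 semilandmarks, LM1 -> LM6)
#   66-83     SL4, ventral keratinous sheath (18 semilandmarks, LM5 -> LM6)
# Core curves precede sheath curves so the conventional subset indexing
# (core = {1,2,3,4} + 7..37, sheath = {5,6} + 38..83) is literally true.

N_LANDMARKS <- 83L
N_FIXED <- 6L
CURVE_SIZES <- c(SL1 = 13L, SL2 = 18L, SL3 = 28L, SL4 = 18L)
ECOLOGY_LEVELS <- c("predatory", "ground", "flying", "unknown")

# Index ranges for each curve in canonical order.
curve_ranges <- function() {
  start <- N_FIXED + c(0L, cumsum(CURVE_SIZES)[-length(CURVE_SIZES)]) + 1L
  stop <- N_FIXED + cumsum(CURVE_SIZES)
  data.frame(curve = names(CURVE_SIZES), start = start, stop = stop,
             stringsAsFactors = FALSE)
}

canonical_curve_id <- function() {
  rep(c("none", names(CURVE_SIZES)), times = c(N_FIXED, CURVE_SIZES))
}

canonical_roles <- function() {
  rep(c("fixed", "semilandmark"), times = c(N_FIXED, N_LANDMARKS - N_FIXED))
}

# Fixed landmarks bounding each sliding curve (terminal neighbours for
# tangent estimation): SL1 LM1->LM4, SL2 LM3->LM4, SL3 LM1->LM6, SL4 LM5->LM6.
CURVE_ENDPOINTS <- list(SL1 = c(1L, 4L), SL2 = c(3L, 4L),
                        SL3 = c(1L, 6L), SL4 = c(5L, 6L))

#' Create a claw landmark configuration
#'
#' Builds and validates one specimen's 83-point landmark configuration:
#' 6 fixed landmarks followed by 77 semilandmarks in four curves
#' (dorsal bony core, ventral bony core, dorsal keratinous sheath,
#' ventral keratinous sheath).
#'
#' @param coords Numeric 83 x 2 matrix of planar landmark coordinates in
#'   canonical order.
#' @param specimen_id Specimen identifier.
#' @param species Species name.
#' @param ecology One of `"predatory"`, `"ground"`, `"flying"`, `"unknown"`.
#' @param scale Positive length-per-unit factor already applied to `coords`
#'   (kept for provenance and TPS round-tripping).
#' @return An object of class `claw_config`.
#' @export
claw_config <- function(coords, specimen_id = "specimen", species = "unknown",
                        ecology = "unknown", scale = 1) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stop("`coords` must be a numeric matrix with 2 columns", call. = FALSE)
  if (nrow(coords) != N_LANDMARKS)
    stop(sprintf("configuration '%s' must have exactly %d landmarks, got %d",
                 specimen_id, N_LANDMARKS, nrow(coords)), call. = FALSE)
  if (any(!is.finite(coords)))
    stop(sprintf("configuration '%s' contains non-finite coordinates",
                 specimen_id), call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop(sprintf("configuration '%s': `scale` must be a positive number",
                 specimen_id), call. = FALSE)
  ecology <- match.arg(ecology, ECOLOGY_LEVELS)
  dimnames(coords) <- list(NULL, c("x", "y"))
  structure(list(specimen_id = as.character(specimen_id),
                 species = as.character(species),
                 ecology = ecology,
                 coords = coords,
                 scale = scale,
                 roles = canonical_roles(),
                 curve_id = canonical_curve_id()),
            class = "claw_config")
}

#' @export
print.claw_config <- function(x, ...) {
  cat(sprintf("claw_config '%s' (%s, %s): %d landmarks (%d fixed + %d semilandmarks)\n",
              x$specimen_id, x$species, x$ecology, nrow(x$coords), N_FIXED,
              N_LANDMARKS - N_FIXED))
  invisible(x)
}

is_claw_config <- function(x) inherits(x, "claw_config")

# Coerce a list of claw_config (or an array) to an n x 83 x 2 array plus
# metadata columns.
configs_to_array <- function(configs) {
  stopifnot(length(configs) >= 1L, all(vapply(configs, is_claw_config, TRUE)))
  n <- length(configs)
  arr <- array(NA_real_, c(n, N_LANDMARKS, 2L))
  for (i in seq_len(n)) arr[i, , ] <- configs[[i]]$coords
  dimnames(arr) <- list(vapply(configs, function(cc) cc$specimen_id, ""), NULL,
                        c("x", "y"))
  list(coords = arr,
       specimen_id = vapply(configs, function(cc) cc$specimen_id, ""),
       species = vapply(configs, function(cc) cc$species, ""),
       ecology = vapply(configs, function(cc) cc$ecology, ""))
}

#' Bony-core / keratinous-sheath landmark partition
#'
#' The default split assigns fixed landmarks 1-4 plus both bony-core curves
#' (landmarks 7-37) to the core module, and fixed landmarks 5-6 plus both
#' sheath curves (landmarks 38-83) to the sheath module.
#'
#' @param core Integer landmark indices of the first module.
#' @param sheath Integer landmark indices of the second module.
#' @param n_landmarks Total number of landmarks the partition covers.
#' @return An object of class `landmark_partition`.
#' @export
landmark_partition <- function(core = c(1:4, 7:37), sheath = c(5:6, 38:83),
                               n_landmarks = N_LANDMARKS) {
  core <- sort(unique(as.integer(core)))
  sheath <- sort(unique(as.integer(sheath)))
  if (length(intersect(core, sheath)) > 0L)
    stop("partition subsets must be disjoint", call. = FALSE)
  if (!setequal(c(core, sheath), seq_len(n_landmarks)))
    stop(sprintf("partition must cover all %d landmarks exactly once", n_landmarks),
         call. = FALSE)
  structure(list(core = core, sheath = sheath, n_landmarks = as.integer(n_landmarks)),
            class = "landmark_partition")
}

#' @export
print.landmark_partition <- function(x, ...) {
  cat(sprintf("landmark_partition: core %d landmarks, sheath %d landmarks (of %d)\n",
              length(x$core), length(x$sheath), x$n_landmarks))
  invisible(x)
}
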