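# TPS landmark file reader/writer (tpsDig-style dialects).
#
# Dialect (a): flat records
#   LM=83
#   <83 "x y" lines>
#   ID=...  IMAGE=...  SCALE=...
# Dialect (b): fixed landmarks plus curves
#   LM=6
#   <6 "x y" lines>
#   CURVES=4
#   POINTS=13 <13 lines> POINTS=18 ... (SL1..SL4 order)
#   ID=... etc.
# SCALE= is applied multiplicatively to all coordinates on read.

#' Read claw configurations from a TPS file
#'
#' Supports flat `LM=83` records and `LM=6` + `CURVES=4` records whose curve
#' blocks are flattened into the canonical 83-point ordering. `SCALE=` lines
#' are applied multiplicatively; `ID=` (or, failing that, `IMAGE=`) becomes
#' the specimen id.
#'
#' @param path Path to a TPS file.
#' @return A list of [claw_config()] objects.
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) stop(sprintf("TPS file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\s*LM\\s*=", lines, ignore.case = TRUE)
  if (length(starts) == 0L) {
    if (all(!nzchar(trimws(lines)))) return(list())
    stop("no LM= records found in TPS file", call. = FALSE)
  }
  ends <- c(starts[-1L] - 1L, length(lines))

  parse_num <- function(line, lineno, key) {
    v <- suppressWarnings(as.numeric(sub("^[^=]*=", "", line)))
    if (is.na(v))
      stop(sprintf("line %d: cannot parse %s value '%s'", lineno, key, line),
           call. = FALSE)
    v
  }
  parse_coord <- function(line, lineno) {
    parts <- strsplit(trimws(line), "\\s+")[[1L]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) != 2L || anyNA(v))
      stop(sprintf("line %d: cannot parse coordinate line '%s'", lineno, line),
           call. = FALSE)
    v
  }

  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    i <- starts[r]
    rec_name <- sprintf("record %d (starting line %d)", r, i)
    n_lm <- parse_num(lines[i], i, "LM")
    i <- i + 1L
    read_block <- function(k) {
      block <- matrix(NA_real_, k, 2L)
      for (j in seq_len(k)) {
        if (i > ends[r]) stop(sprintf("%s: expected %d coordinate lines", rec_name, k),
                              call. = FALSE)
        block[j, ] <- parse_coord(lines[i], i)
        i <<- i + 1L
      }
      block
    }
    coords <- read_block(n_lm)
    curves <- NULL
    id <- NA_character_; image <- NA_character_; scale <- 1
    while (i <= ends[r]) {
      line <- trimws(lines[i])
      if (!nzchar(line)) { i <- i + 1L; next }
      if (grepl("^CURVES\\s*=", line, ignore.case = TRUE)) {
        n_curves <- parse_num(line, i, "CURVES")
        i <- i + 1L
        curves <- vector("list", n_curves)
        for (cc in seq_len(n_curves)) {
          if (i > ends[r] || !grepl("^POINTS\\s*=", trimws(lines[i]), ignore.case = TRUE))
            stop(sprintf("%s: expected POINTS= header for curve %d", rec_name, cc),
                 call. = FALSE)
          n_pts <- parse_num(lines[i], i, "POINTS")
          i <- i + 1L
          curves[[cc]] <- read_block(n_pts)
        }
      } else if (grepl("^ID\\s*=", line, ignore.case = TRUE)) {
        id <- sub("^[^=]*=", "", line); i <- i + 1L
      } else if (grepl("^IMAGE\\s*=", line, ignore.case = TRUE)) {
        image <- sub("^[^=]*=", "", line); i <- i + 1L
      } else if (grepl("^SCALE\\s*=", line, ignore.case = TRUE)) {
        scale <- parse_num(line, i, "SCALE"); i <- i + 1L
      } else if (grepl("^[A-Za-z]+\\s*=", line)) {
        i <- i + 1L  # unrecognized keyword: tolerated
      } else {
        stop(sprintf("line %d: unexpected content '%s' in %s", i, line, rec_name),
             call. = FALSE)
      }
    }

    if (is.null(curves)) {
      if (n_lm != N_LANDMARKS)
        stop(sprintf("%s is malformed: flat record has LM=%d, expected %d",
                     rec_name, n_lm, N_LANDMARKS), call. = FALSE)
      all_coords <- coords
    } else {
      sizes <- vapply(curves, nrow, 1L)
      if (n_lm != N_FIXED || length(sizes) != length(CURVE_SIZES) ||
          any(sizes != unname(CURVE_SIZES)))
        stop(sprintf(
          "%s is malformed: expected LM=%d with curves (%s), got LM=%d with curves (%s)",
          rec_name, N_FIXED, paste(CURVE_SIZES, collapse = ","), n_lm,
          paste(sizes, collapse = ",")), call. = FALSE)
      all_coords <- rbind(coords, do.call(rbind, curves))
    }
    spec_id <- if (!is.na(id) && nzchar(id)) id
               else if (!is.na(image) && nzchar(image)) image
               else sprintf("record_%d", r)
    out[[r]] <- claw_config(all_coords * scale, specimen_id = spec_id,
                            scale = scale)
  }
  out
}

#' Write claw configurations to a TPS file
#'
#' Emits the flat `LM=83` dialect with 17 significant digits so that a
#' write/read round trip reproduces coordinates to better than 1e-12.
#' Coordinates are stored divided by `scale` with a matching `SCALE=` line,
#' mirroring how tpsDig stores calibrated digitizations.
#'
#' @param configs A list of [claw_config()] objects (may be empty).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tps <- function(configs, path) {
  stopifnot(is.list(configs))
  lines <- character(0)
  for (cfg in configs) {
    if (!is_claw_config(cfg)) stop("all elements must be claw_config objects",
                                   call. = FALSE)
    raw <- cfg$coords / cfg$scale
    lines <- c(lines,
               sprintf("LM=%d", nrow(cfg$coords)),
               sprintf("%.17g %.17g", raw[, 1], raw[, 2]),
               sprintf("ID=%s", cfg$specimen_id),
               sprintf("SCALE=%.17g", cfg$scale))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e)),
         call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' @param path CSV file with columns `specimen_id`, `species`, `ecology`.
#' @return A data frame with validated columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "ecology")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols) > 0L)
    stop(sprintf("metadata is missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(md$specimen_id))
    stop("metadata has duplicated specimen_id values", call. = FALSE)
  bad <- setdiff(unique(md$ecology), ECOLOGY_LEVELS)
  if (length(bad) > 0L)
    stop(sprintf("unknown ecology labels: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  md
}

# Attach species/ecology labels from a metadata table to configurations.
apply_metadata <- function(configs, metadata) {
  idx <- match(vapply(configs, function(x) x$specimen_id, ""), metadata$specimen_id)
  if (anyNA(idx))
    stop("some specimens are missing from the metadata table", call. = FALSE)
  for (i in seq_along(configs)) {
    configs[[i]]$species <- metadata$species[idx[i]]
    configs[[i]]$ecology <- metadata$ecology[idx[i]]
  }
  configs
}
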