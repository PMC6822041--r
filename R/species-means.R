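# Species-mean aggregation for shape samples and traditional-metric tables.

#' Species means of aligned shapes or traditional metrics
#'
#' For a `shape_sample`, averages the GPA-aligned coordinates per species
#' (without re-superimposing the means) and averages centroid size on the
#' raw scale (log-transform afterwards, downstream). For a data frame of
#' traditional metrics, averages each numeric column per species. Species
#' ecology is the unique ecology of its specimens; conflicting labels are an
#' error.
#'
#' @param x A `shape_sample` from [gpa()] or a data frame with a `species`
#'   column and numeric metric columns.
#' @param metadata Optional metadata data frame (`specimen_id`, `species`,
#'   `ecology`) overriding labels carried by `x`.
#' @return An object of the same flavour as `x`, with one row/configuration
#'   per species.
#' @export
species_means <- function(x, metadata = NULL) UseMethod("species_means")

resolve_labels <- function(specimen_id, species, ecology, metadata) {
  if (!is.null(metadata)) {
    idx <- match(specimen_id, metadata$specimen_id)
    if (anyNA(idx))
      stop("metadata is missing some specimens", call. = FALSE)
    species <- metadata$species[idx]
    ecology <- metadata$ecology[idx]
  }
  if (any(is.na(species)))
    stop("every specimen needs a species label", call. = FALSE)
  eco_by_sp <- tapply(ecology, species, function(e) unique(e))
  bad <- names(eco_by_sp)[lengths(eco_by_sp) > 1L]
  if (length(bad) > 0L)
    stop(sprintf("species with conflicting ecology labels: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  list(species = species, ecology = ecology)
}

#' @export
species_means.shape_sample <- function(x, metadata = NULL) {
  lab <- resolve_labels(x$specimen_id, x$species, x$ecology, metadata)
  sp <- sort(unique(lab$species))
  k <- dim(x$aligned)[2L]
  means <- array(NA_real_, c(length(sp), k, 2L),
                 dimnames = list(sp, NULL, c("x", "y")))
  cs <- numeric(length(sp))
  eco <- character(length(sp))
  for (j in seq_along(sp)) {
    i <- which(lab$species == sp[j])
    means[j, , ] <- if (length(i) == 1L) x$aligned[i, , ]
                    else apply(x$aligned[i, , , drop = FALSE], c(2L, 3L), mean)
    cs[j] <- mean(x$centroid_sizes[i])
    eco[j] <- lab$ecology[i[1L]]
  }
  structure(list(aligned = means, centroid_sizes = stats::setNames(cs, sp),
                 mean_shape = x$mean_shape, specimen_id = sp, species = sp,
                 ecology = eco, iterations = x$iterations,
                 converged = x$converged, slid = x$slid),
            class = "shape_sample")
}

#' @export
species_means.data.frame <- function(x, metadata = NULL) {
  if (!"species" %in% names(x) && is.null(metadata))
    stop("need a species column or a metadata table", call. = FALSE)
  species <- if ("species" %in% names(x)) x$species else NULL
  ecology <- if ("ecology" %in% names(x)) x$ecology else rep(NA_character_, nrow(x))
  spec_id <- if ("specimen_id" %in% names(x)) x$specimen_id else rownames(x)
  lab <- resolve_labels(spec_id, species, ecology, metadata)
  num_cols <- names(x)[vapply(x, is.numeric, TRUE)]
  sp <- sort(unique(lab$species))
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (cn in num_cols)
    out[[cn]] <- as.numeric(tapply(x[[cn]], lab$species, mean)[sp])
  eco <- tapply(lab$ecology, lab$species, function(e) e[1L])[sp]
  out$ecology <- as.character(eco)
  out$n_specimens <- as.integer(table(factor(lab$species, levels = sp)))
  out
}
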