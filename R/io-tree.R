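# Phylogeny I/O and phylogenetic covariance construction (backed by ape).

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' @param path Newick file containing a single tree.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("tree file not found: %s", path), call. = FALSE)
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in the Newick file", call. = FALSE)
    tr <- tr[[1L]]
  }
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a valid phylogeny", call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0L)
    stop(sprintf("duplicate tip names in tree: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  bad <- which(!is.finite(tr$edge.length) | tr$edge.length < 0)
  if (length(bad) > 0L) {
    child <- tr$edge[bad[1L], 2L]
    lab <- if (child <= length(tr$tip.label)) tr$tip.label[child]
           else sprintf("internal node %d", child)
    stop(sprintf("missing or invalid branch length on the edge leading to %s", lab),
         call. = FALSE)
  }
  invisible(tr)
}

#' Prune a phylogeny to a set of species
#'
#' Retains only `keep`, collapsing resulting degree-2 internal nodes and
#' summing branch lengths, so root-to-tip path lengths and all shared-path
#' (covariance) structure among retained tips are unchanged.
#'
#' @param tree An `ape::phylo` tree.
#' @param keep Character vector of tip labels to retain.
#' @return The pruned tree.
#' @export
prune_tree <- function(tree, keep) {
  validate_tree(tree)
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("`keep` must contain at least one species", call. = FALSE)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L)
    stop(sprintf("species not present in tree: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  if (length(keep) == length(tree$tip.label)) return(tree)
  # keep the basal path above the retained clade as a root edge so the
  # shared-path (covariance) structure among retained tips is preserved
  # exactly; phylo_covariance() adds it back onto the matrix.
  pruned <- ape::keep.tip(tree, keep)
  ref <- keep[1L]
  d_orig <- ape::node.depth.edgelength(tree)[match(ref, tree$tip.label)]
  d_new <- ape::node.depth.edgelength(pruned)[match(ref, pruned$tip.label)]
  stem <- (d_orig - d_new) + if (is.null(tree$root.edge)) 0 else tree$root.edge
  if (stem > 1e-12) pruned$root.edge <- stem
  pruned
}

#' Phylogenetic covariance matrix
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' diagonal entries are root-to-tip depths.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param species Optional ordered species names (subset of tips) giving the
#'   row/column order; defaults to the tree's tip order.
#' @return A symmetric PSD matrix with species dimnames.
#' @export
phylo_covariance <- function(tree, species = NULL) {
  validate_tree(tree)
  C <- ape::vcv(tree)
  if (!is.null(tree$root.edge)) C <- C + tree$root.edge
  if (is.null(species)) return(C)
  species <- as.character(species)
  unknown <- setdiff(species, rownames(C))
  if (length(unknown) > 0L)
    stop(sprintf("species not present in tree: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  C[species, species, drop = FALSE]
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies off-diagonal entries by `lam`, leaving tip variances unchanged.
#' `lam = 1` is Brownian motion; `lam = 0` is a star phylogeny.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lam Lambda in \[0, 1\].
#' @return The transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam < 0 || lam > 1)
    stop("`lam` must be a single value in [0, 1]", call. = FALSE)
  Cl <- C * lam
  diag(Cl) <- diag(C)
  Cl
}
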