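#' Read and validate a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces what downstream
#' eigenvector extraction needs: branch lengths on every edge, finite and
#' non-negative (zero allowed), unique leaf labels, and at least two
#' leaves. Ultrametricity is expected of the inputs (trees are assumed to
#' have been dated upstream) but only warned about, with a relative
#' tolerance of 1e-3 on root-to-tip depths.
#'
#' @param path Path to a Newick file.
#' @return An [ape] `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stopf("unparseable Newick in '%s': %s",
                                             path, conditionMessage(e)))
  if (is.null(tree)) stopf("unparseable Newick in '%s'", path)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  if (length(tree$tip.label) < 2L) stopf("tree needs >= 2 leaves")
  if (anyDuplicated(tree$tip.label))
    stopf("duplicate leaf label: %s",
          tree$tip.label[duplicated(tree$tip.label)][1L])
  if (is.null(tree$edge.length)) stopf("tree lacks branch lengths")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stopf("tree has missing or non-finite branch lengths")
  if (any(tree$edge.length < 0)) stopf("tree has negative branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (max(depths) > 0 && diff(range(depths)) / max(depths) > 1e-3)
    warnf("tree is not ultrametric (root-to-tip depths differ by %.2g%%)",
          100 * diff(range(depths)) / max(depths))
  tree
}

#' Patristic distances between leaves
#'
#' Sum of branch lengths along the path between each pair of leaves,
#' via [ape::cophenetic.phylo()].
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param species Optional subset (and ordering) of leaf labels.
#' @return Symmetric matrix of path-length distances with zero diagonal.
#' @export
patristic_distances <- function(tree, species = NULL) {
  d <- ape::cophenetic.phylo(tree)
  if (is.null(species)) return(d)
  unknown <- setdiff(species, rownames(d))
  if (length(unknown)) stopf("species not in tree: %s", unknown[1L])
  d[species, species, drop = FALSE]
}

#' Extract phylogenetic eigenvectors
#'
#' Principal coordinates analysis of the patristic distance matrix: Gower
#' double-centering of -0.5 * D^2 followed by an eigendecomposition.
#' Negative eigenvalues (possible for non-ultrametric inputs) are dropped
#' from both the variance numerator and denominator. The smallest number
#' of leading axes whose cumulative fraction of the positive-eigenvalue
#' sum reaches `threshold` is retained, so dropping the last retained axis
#' would fall below the threshold.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param species Optional subset/order of leaf labels (default all).
#' @param threshold Cumulative variance fraction to reach (default 0.65).
#' @param source_label Label naming the tree (e.g. the gene it was built
#'   from), carried through to eigenvector column provenance.
#' @return An object of class `eigenvector_set`: list with `species`,
#'   `coordinates` (n x k matrix, columns `EV1..EVk`, scaled so squared
#'   column norms equal the eigenvalues), `eigenvalues` (all positive ones,
#'   decreasing), `variance_fractions`, `cumulative_fraction`, `threshold`,
#'   `source_label`.
#' @export
extract_eigenvectors <- function(tree, species = NULL, threshold = 0.65,
                                 source_label = "tree") {
  d <- patristic_distances(tree, species)
  n <- nrow(d)
  if (n < 3L) stopf("eigenvector extraction needs >= 3 species")
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  cmat <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * cmat %*% (d * d) %*% cmat
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  if (all(eig$values <= tol)) stopf("degenerate tree: no positive eigenvalues")
  pos <- which(eig$values > tol)
  values <- eig$values[pos]
  fractions <- values / sum(values)
  k <- which(cumsum(fractions) >= threshold - 1e-12)[1L]
  coords <- eig$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(values[seq_len(k)]), k)
  dimnames(coords) <- list(rownames(d), paste0("EV", seq_len(k)))
  structure(list(species = rownames(d), coordinates = coords,
                 eigenvalues = values,
                 variance_fractions = fractions,
                 cumulative_fraction = sum(fractions[seq_len(k)]),
                 threshold = threshold, source_label = source_label),
            class = "eigenvector_set")
}

#' @export
print.eigenvector_set <- function(x, ...) {
  cat(sprintf(
    "eigenvector_set '%s': %d species, %d axes retained (%.1f%% of variance, threshold %.0f%%)\n",
    x$source_label, length(x$species), ncol(x$coordinates),
    100 * x$cumulative_fraction, 100 * x$threshold))
  invisible(x)
}

#' Export an eigenvector set as CSV
#'
#' @param evs An `eigenvector_set`.
#' @param csv_path Output path; columns are the species identifier followed
#'   by `EV1..EVk`.
#' @param id_column Name for the species column.
#' @export
write_eigenvectors <- function(evs, csv_path, id_column = "species") {
  out <- data.frame(evs$species, evs$coordinates, check.names = FALSE)
  names(out)[1L] <- id_column
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}
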