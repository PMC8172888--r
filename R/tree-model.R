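#' Read and validate phylogenies from Newick text
#'
#' Thin validating wrapper around [ape::read.tree()]. Trees must be rooted,
#' carry a branch length on every edge, and have unique tip labels; anything
#' else is an error, because downstream covariance matrices are meaningless
#' without complete branch lengths.
#'
#' @param file Path to a Newick file. Multi-tree files (one Newick record per
#'   line) are supported.
#' @param text Newick string; used instead of `file` when supplied.
#' @return An [ape::phylo] object, or a `multiPhylo` list when the input
#'   contains more than one tree.
#' @examples
#' tr <- read_trees(text = "((A:1,B:1):1,C:2);")
#' @export
read_trees <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text)) {
    stop_pf("supply either `file` or `text`")
  }
  if (!is.null(text) && !nzchar(trimws(paste(text, collapse = "")))) {
    stop_pf("`text` is empty")
  }
  tr <- if (!is.null(text)) {
    ape::read.tree(text = text)
  } else {
    ape::read.tree(file = file)
  }
  if (is.null(tr)) stop_pf("malformed Newick input")
  if (inherits(tr, "multiPhylo")) {
    out <- lapply(tr, validate_phylo)
    class(out) <- "multiPhylo"
    out
  } else {
    validate_phylo(tr)
  }
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants every function in this package relies on: unique tip
#' labels, rooted topology, and nonnegative branch lengths on all edges.
#'
#' @param tree An [ape::phylo] object.
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop_pf("not a `phylo` object")
  if (anyDuplicated(tree$tip.label)) {
    stop_pf("duplicate tip labels: ",
            paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                  collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    stop_pf("tree has no branch lengths; the analysis requires them")
  }
  if (anyNA(tree$edge.length)) stop_pf("missing branch length on some edge")
  if (any(tree$edge.length < 0)) stop_pf("negative branch length")
  # require a unique basal node; basal polytomies (including star trees) are
  # accepted as hard polytomies rooted there
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) stop_pf("tree is not rooted (no unique basal node)")
  tree
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips outside `keep`, collapsing the resulting unifurcations and
#' summing their branch lengths so that root-to-tip distances of the kept taxa
#' are unchanged.
#'
#' @param tree An [ape::phylo] object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned [ape::phylo] object.
#' @export
prune_to_taxa <- function(tree, keep) {
  validate_phylo(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop_pf("taxa not in tree: ", paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) sprintf(" (and %d more)", length(unknown) - 5))
  }
  if (length(keep) < 2) stop_pf("`keep` must contain at least 2 taxa")
  if (length(keep) == length(tree$tip.label)) return(tree)
  pr <- ape::drop.tip(tree, setdiff(tree$tip.label, keep))
  # basal edges above the new MRCA are shared history of all kept taxa; carry
  # them as a stem (root.edge) so root-to-tip distances are conserved
  d0 <- ape::node.depth.edgelength(tree)[match(keep[1], tree$tip.label)] +
    (tree$root.edge %||% 0)
  d1 <- ape::node.depth.edgelength(pr)[match(keep[1], pr$tip.label)] +
    (pr$root.edge %||% 0)
  if (d0 - d1 > 1e-12) pr$root.edge <- (pr$root.edge %||% 0) + (d0 - d1)
  pr
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' The among-species covariance implied by Brownian trait evolution: diagonal
#' entries are root-to-tip path lengths, off-diagonals the root-to-MRCA shared
#' path length of each pair. Rows and columns are returned in alphabetical
#' taxon order so matrices from different trees over the same taxa align.
#'
#' @param tree An [ape::phylo] object (rooted, with branch lengths).
#' @return A symmetric positive semi-definite matrix with taxon dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_phylo(tree)
  C <- ape::vcv.phylo(tree)
  # a stem (root) edge is shared history of all taxa: a constant on every entry
  if (!is.null(tree$root.edge)) C <- C + tree$root.edge
  ord <- order(rownames(C))
  C[ord, ord, drop = FALSE]
}

#' Pagel's lambda rescaling of a phylogenetic covariance
#'
#' Multiplies every off-diagonal entry by `lambda`, leaving the diagonal
#' untouched. `lambda = 1` returns the Brownian covariance; `lambda = 0` the
#' star phylogeny (independent species). The upper bound is fixed at 1:
#' beyond it the matrix can lose positive-definiteness, so 1 is also the
#' search boundary used when lambda is estimated.
#'
#' @param C Square covariance matrix (e.g. from [phylo_vcv()]).
#' @param lambda Scalar in \[0, 1\].
#' @return The rescaled matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop_pf("`C` must be square")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop_pf("`lambda` must be a single value in [0, 1]")
  }
  d <- diag(C)
  out <- lambda * C
  diag(out) <- d
  out
}

#' Check whether a tree is ultrametric within an absolute tolerance
#'
#' @param tree An [ape::phylo] object.
#' @param tol Positive absolute tolerance on the spread of root-to-tip
#'   distances.
#' @return `TRUE` if all root-to-tip distances agree within `tol`.
#' @export
check_ultrametric <- function(tree, tol = 1e-8) {
  validate_phylo(tree)
  if (!is.numeric(tol) || tol <= 0) stop_pf("`tol` must be > 0")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(depths) - min(depths)) <= tol
}
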