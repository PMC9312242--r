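#' UPGMA dendrogram from a labelled distance matrix
#'
#' Classic (size-weighted) unweighted pair-group method with arithmetic mean:
#' the closest pair of clusters is merged iteratively and distances to the
#' new cluster are arithmetic means weighted by cluster sizes. Node height is
#' half the merge distance, so the tree is ultrametric and the cophenetic
#' distance between two tips reproduces the merge distance of their most
#' recent common ancestor. Built on `stats::hclust(method = "average")` and
#' returned as an `ape` `phylo` tree.
#'
#' @param d Symmetric nonnegative matrix with zero diagonal and labelled
#'   rows/columns (e.g. from [nei_distance_matrix()]), or a `dist` object.
#' @return An ultrametric `phylo` tree with tip labels from `d`.
#' @examples
#' d <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' to_newick(upgma(d))
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d)) stop("distance matrix must be square")
    if (any(d < 0)) stop("distances must be nonnegative")
    if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
    if (any(diag(d) != 0)) stop("diagonal must be zero")
    if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
        paste0("t", seq_len(nrow(d)))
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < 2L) stop("need at least 2 labels")
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)   # halves heights: tip-to-MRCA = merge dist / 2
  phy
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` tree, or a single character label for the degenerate
#'   one-leaf tree.
#' @return Newick string (with trailing `;`).
#' @export
to_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L) return(paste0(tree, ";"))
  ape::write.tree(tree)
}

#' Read a square distance matrix from TSV
#'
#' Expects a header of labels and one labelled row per line, as written by
#' [write_distance_matrix()].
#'
#' @param path Input TSV path.
#' @return Labelled symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  x <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                         comment.char = "#")
  as.matrix(x)
}

#' Write a square distance matrix to TSV
#'
#' @param d Labelled square matrix.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(cbind(label = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
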