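#' Manhattan dissimilarity between the rows of a binary matrix
#'
#' d(i, j) = sum_k |M[i,k] - M[j,k]|, i.e. the unnormalized count of traits
#' on which two families differ. Applied directly to the 0/1 matrix, so the
#' result is integer-valued.
#'
#' @param M binary matrix with row names, at least 2 rows.
#' @return Labeled square distance matrix.
#' @export
manhattan_dist <- function(M) {
  if (inherits(M, "trait_matrix")) M <- M$matrix
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("need at least 2 rows")
  if (!all(M %in% c(0, 1))) stop("input must be strictly binary (0/1)")
  if (is.null(rownames(M))) stop("rows must be labeled")
  as_distmatrix(as.matrix(stats::dist(M, method = "manhattan")))
}

#' Assemblage dissimilarity between plant families
#'
#' Builds the binary plant-family x herbivore incidence matrix of the
#' network and returns the Manhattan distance between family rows: the
#' number of herbivore species found on exactly one of the two families
#' (symmetric difference of the two assemblages).
#'
#' @param net an `interaction_network` with at least 2 plant families.
#' @return Labeled square distance matrix over the plant families.
#' @export
assemblage_dissimilarity <- function(net) {
  manhattan_dist(incidence_matrix(net, rows = "plant_family"))
}

#' Patristic (cophenetic) distances on a tree
#'
#' Sum of branch lengths along the path between every pair of leaves. For
#' ultrametric trees this coincides with the cophenetic distance.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return Labeled square distance matrix, labels sorted.
#' @export
patristic <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$tip.label) < 2) stop("need at least 2 leaves")
  D <- ape::cophenetic.phylo(tree)
  lab <- sort(rownames(D))
  as_distmatrix(D[lab, lab])
}

#' Aggregate presence-absence traits to class-level diversity counts
#'
#' Condenses the binary trait matrix to a family x metabolite-class count
#' matrix: each entry is the number of traits of that class present in the
#' family (the "number of subclasses" shown in heatmap figures). Row sums
#' equal the number of present traits per family.
#'
#' @param traits a `trait_matrix` whose hierarchy assigns every trait a
#'   class.
#' @return Integer matrix, families x classes.
#' @export
aggregate_traits <- function(traits) {
  h <- traits$hierarchy
  if (any(is.na(h$class)) || any(!nzchar(h$class))) {
    stop("trait(s) with missing class: ",
         paste(h$trait[is.na(h$class) | !nzchar(h$class)], collapse = ", "))
  }
  cls <- factor(h$class, levels = unique(h$class))
  out <- t(rowsum(t(traits$matrix), cls))
  storage.mode(out) <- "integer"
  out
}
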