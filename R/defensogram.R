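## Agglomerative methods in the fixed order used for reports and for
## breaking selection ties (ascending typical performance on binary
## chemical data; bionj appended by select_algorithm).
AGGLOMERATIVE_METHODS <- c("ward_d2", "ward_d", "complete", "wpgmc",
                           "single", "wpgma", "upgmc", "upgma")

.hclust_method <- c(
  single = "single", complete = "complete", upgma = "average",
  wpgma = "mcquitty", upgmc = "centroid", wpgmc = "median",
  ward_d = "ward.D", ward_d2 = "ward.D2"
)

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Lance-Williams agglomeration under one of the eight classical update
#' rules, delegated to [stats::hclust()]. `ward_d` operates on the given
#' dissimilarities; `ward_d2` on their squares with square-rooted merge
#' heights.
#'
#' @param D labeled square dissimilarity matrix.
#' @param method one of `"single"`, `"complete"`, `"upgma"`, `"wpgma"`,
#'   `"upgmc"`, `"wpgmc"`, `"ward_d"`, `"ward_d2"`.
#' @return An `hclust` object.
#' @export
agglomerate <- function(D, method) {
  D <- as_distmatrix(D)
  if (nrow(D) < 2) stop("need at least 2 objects")
  if (!method %in% names(.hclust_method)) {
    stop("unknown method '", method, "'; choose one of: ",
         paste(names(.hclust_method), collapse = ", "))
  }
  stats::hclust(stats::as.dist(D), method = .hclust_method[[method]])
}

#' Distance-based tree by variance-weighted neighbor joining (BIONJ)
#'
#' Builds an unrooted tree from a dissimilarity matrix by neighbor joining
#' with BIONJ's variance-weighted matrix reduction: pairs are selected by
#' the standard Q criterion, branch lengths come from the two-point
#' formulas, and after each agglomeration the distances to the new node
#' are combined with a weight that minimizes the variance of the reduced
#' matrix (variances tracked alongside the distances, initialized to the
#' distances themselves). Computed in double precision; on an exactly
#' additive matrix the generating topology is recovered and the tree's
#' patristic distances equal the input to numerical precision. Negative
#' estimated branch lengths (possible on non-additive input) are clamped
#' to zero with a message.
#'
#' @param D labeled square dissimilarity matrix, n >= 3.
#' @return Unrooted `phylo` tree.
#' @export
bionj_tree <- function(D) {
  D <- as_distmatrix(D)
  n <- nrow(D)
  if (n < 3) stop("BIONJ needs at least 3 objects")
  labels <- rownames(D)

  ids <- seq_len(n)             # current node id per active row
  Dc <- D
  Vc <- D                       # variance estimates, initialized to D
  next_internal <- n + 1L
  parent <- child <- integer(0)
  elen <- numeric(0)

  while (nrow(Dc) > 3) {
    r <- nrow(Dc)
    S <- rowSums(Dc)
    Q <- (r - 2) * Dc - outer(S, S, "+")
    diag(Q) <- Inf
    k <- which.min(Q)           # column-major first minimum: deterministic
    i <- (k - 1) %% r + 1
    j <- (k - 1) %/% r + 1
    if (i > j) { tmp <- i; i <- j; j <- tmp }

    li <- Dc[i, j] / 2 + (S[i] - S[j]) / (2 * (r - 2))
    lj <- Dc[i, j] - li
    lam <- if (Vc[i, j] > 0) {
      0.5 + sum(Vc[j, -c(i, j)] - Vc[i, -c(i, j)]) / (2 * (r - 2) * Vc[i, j])
    } else 0.5
    lam <- min(1, max(0, lam))

    u <- next_internal
    next_internal <- next_internal + 1L
    parent <- c(parent, u, u)
    child <- c(child, ids[i], ids[j])
    elen <- c(elen, li, lj)

    keep <- setdiff(seq_len(r), c(i, j))
    du <- lam * (Dc[i, keep] - li) + (1 - lam) * (Dc[j, keep] - lj)
    vu <- lam * Vc[i, keep] + (1 - lam) * Vc[j, keep] -
      lam * (1 - lam) * Vc[i, j]
    Dc <- rbind(cbind(Dc[keep, keep, drop = FALSE], u = du),
                u = c(du, 0))
    Vc <- rbind(cbind(Vc[keep, keep, drop = FALSE], u = vu),
                u = c(vu, 0))
    ids <- c(ids[keep], u)
  }

  # final three nodes join at the central node (two-point formulas)
  d <- Dc
  z <- next_internal
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  parent <- c(parent, z, z, z)
  child <- c(child, ids[1], ids[2], ids[3])
  elen <- c(elen, la, lb, lc)

  # renumber internals so the central (basal) node is n + 1, per phylo
  # convention; internals were created in order n+1 .. z
  remap <- function(v) as.integer(ifelse(v <= n, v, n + (z - v) + 1L))
  tr <- structure(list(
    edge = cbind(remap(parent), remap(child)),
    edge.length = elen,
    tip.label = labels,
    Nnode = n - 2L
  ), class = "phylo")
  tr <- stats::reorder(tr, "cladewise")
  if (any(tr$edge.length < 0)) {
    message(sprintf("bionj_tree: clamped %d negative branch length(s) to 0",
                    sum(tr$edge.length < 0)))
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Cophenetic distance matrix of a dendrogram or tree
#'
#' For an `hclust` dendrogram, d(i, j) is the merge height at which leaves i
#' and j first join (ultrametric by construction for monotone methods). For
#' a `phylo` tree, the patristic path length.
#'
#' @param x an `hclust` or `phylo` object.
#' @return Labeled square distance matrix, labels sorted.
#' @export
cophenetic_of <- function(x) {
  if (inherits(x, "hclust")) {
    D <- as.matrix(stats::cophenetic(x))
    lab <- sort(rownames(D))
    as_distmatrix(D[lab, lab])
  } else if (inherits(x, "phylo")) {
    patristic(x)
  } else {
    stop("need an hclust dendrogram or a phylo tree")
  }
}

#' Choose the clustering algorithm that best preserves a dissimilarity matrix
#'
#' Runs the eight agglomerative methods plus BIONJ on `D`, computes for each
#' the Pearson correlation between the condensed (lower-triangle) entries of
#' `D` and of the method's cophenetic/patristic matrix, and selects the
#' method with the highest correlation. This is the standard criterion for
#' picking the dendrogram that retains most of the variation in the original
#' chemical dissimilarities.
#'
#' @param D labeled square dissimilarity matrix, n >= 4.
#' @return A `clustering_report`: data.frame of (method, cophenetic_r)
#'   sorted by increasing correlation, with attributes `selected` (method
#'   name) and `tree` (the selected `hclust`/`phylo` object). Methods whose
#'   correlation is undefined (constant cophenetic matrix) get `NA` and are
#'   excluded from selection.
#' @export
select_algorithm <- function(D) {
  D <- as_distmatrix(D)
  if (nrow(D) < 4) stop("need at least 4 objects for a meaningful correlation")
  dvec <- condensed(D)
  if (stats::sd(dvec) == 0) stop("constant dissimilarity matrix")
  methods <- c(AGGLOMERATIVE_METHODS, "bionj")
  fits <- lapply(methods, function(m) {
    if (m == "bionj") bionj_tree(D) else agglomerate(D, m)
  })
  names(fits) <- methods
  r <- vapply(fits, function(f) {
    cvec <- condensed(align_dist(cophenetic_of(f), rownames(D)))
    if (stats::sd(cvec) == 0) NA_real_ else stats::cor(dvec, cvec)
  }, numeric(1))
  sel <- methods[which.max(replace(r, is.na(r), -Inf))]
  report <- data.frame(method = methods, cophenetic_r = unname(r),
                       stringsAsFactors = FALSE)
  report <- report[order(report$cophenetic_r, na.last = FALSE), , drop = FALSE]
  rownames(report) <- NULL
  structure(report, selected = sel, tree = fits[[sel]],
            class = c("clustering_report", "data.frame"))
}

#' Export a defensogram as Newick
#'
#' Converts the selected dendrogram/tree to Newick with branch lengths in
#' dissimilarity units. BIONJ trees are unrooted; for display they are
#' midpoint-rooted first (statistics elsewhere always use the unrooted
#' patristic distances).
#'
#' @param x an `hclust` or `phylo` defensogram.
#' @param file optional output path.
#' @param midpoint_root root unrooted trees at their midpoint (default TRUE).
#' @return Newick string (invisibly the path when `file` is given).
#' @export
export_defensogram <- function(x, file = NULL, midpoint_root = TRUE) {
  tr <- if (inherits(x, "hclust")) ape::as.phylo(x) else x
  if (midpoint_root && !ape::is.rooted(tr) && length(tr$tip.label) > 2) {
    tr <- phangorn::midpoint(tr)
  }
  write_newick(tr, file)
}
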