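#' Construct a bipartite herbivore-host interaction network
#'
#' The network is a set of herbivore -> plant-family links plus a taxonomy
#' table for the herbivores (family, subfamily). Duplicate links are removed
#' with a warning; every herbivore appearing in `links` must have a taxonomy
#' entry.
#'
#' @param links data.frame with columns `herbivore`, `plant_family` and
#'   optionally `is_main_host` (logical).
#' @param herbivore_meta data.frame with columns `herbivore`, `family`,
#'   `subfamily`. If omitted, a single placeholder family is assigned.
#' @return An object of class `interaction_network` with elements `links`
#'   and `herbivore_meta`.
#' @export
interaction_network <- function(links, herbivore_meta = NULL) {
  stopifnot(is.data.frame(links))
  if (!all(c("herbivore", "plant_family") %in% names(links))) {
    stop("`links` needs columns 'herbivore' and 'plant_family'")
  }
  links$herbivore <- trimws(as.character(links$herbivore))
  links$plant_family <- trimws(as.character(links$plant_family))
  if (any(!nzchar(links$herbivore)) || any(!nzchar(links$plant_family))) {
    stop("empty herbivore or plant_family id in links")
  }
  if (is.null(links$is_main_host)) links$is_main_host <- FALSE
  key <- paste(links$herbivore, links$plant_family, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("removed %d duplicate link(s)", sum(duplicated(key))))
    links <- links[!duplicated(key), , drop = FALSE]
  }
  herbs <- sort(unique(links$herbivore))
  if (is.null(herbivore_meta)) {
    herbivore_meta <- data.frame(
      herbivore = herbs, family = "Unassigned", subfamily = "Unassigned",
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(herbivore_meta))
  if (!all(c("herbivore", "family") %in% names(herbivore_meta))) {
    stop("`herbivore_meta` needs columns 'herbivore' and 'family'")
  }
  herbivore_meta$herbivore <- trimws(as.character(herbivore_meta$herbivore))
  herbivore_meta$family <- trimws(as.character(herbivore_meta$family))
  if (is.null(herbivore_meta$subfamily)) herbivore_meta$subfamily <- NA_character_
  herbivore_meta <- herbivore_meta[!duplicated(herbivore_meta$herbivore), , drop = FALSE]
  missing <- setdiff(herbs, herbivore_meta$herbivore)
  if (length(missing)) {
    stop("herbivores without taxonomy entry: ", paste(missing, collapse = ", "))
  }
  herbivore_meta <- herbivore_meta[herbivore_meta$herbivore %in% herbs, , drop = FALSE]
  rownames(links) <- NULL
  rownames(herbivore_meta) <- NULL
  structure(list(links = links, herbivore_meta = herbivore_meta),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "interaction_network: %d herbivores x %d plant families, %d links\n",
    length(herbivores(x)), length(plant_families(x)), nrow(x$links)
  ))
  invisible(x)
}

#' Herbivore and plant-family label accessors
#'
#' @param net an `interaction_network`.
#' @return Sorted character vector of labels.
#' @export
herbivores <- function(net) sort(unique(net$links$herbivore))

#' @rdname herbivores
#' @export
plant_families <- function(net) sort(unique(net$links$plant_family))

#' Binary incidence matrix of a network
#'
#' @param net an `interaction_network`.
#' @param rows `"plant_family"` (default) or `"herbivore"`: which mode forms
#'   the rows.
#' @return 0/1 matrix with dimnames.
#' @export
incidence_matrix <- function(net, rows = c("plant_family", "herbivore")) {
  rows <- match.arg(rows)
  fams <- plant_families(net)
  herbs <- herbivores(net)
  m <- matrix(0L, length(fams), length(herbs), dimnames = list(fams, herbs))
  m[cbind(net$links$plant_family, net$links$herbivore)] <- 1L
  if (rows == "herbivore") t(m) else m
}

#' Construct a binary trait matrix with a trait hierarchy
#'
#' Rows are plant families, columns are secondary-metabolite traits scored as
#' present (1) or absent (0). Each trait carries a chemotaxonomic hierarchy
#' entry: group (e.g. phenolic), type (e.g. flavonoid), class (e.g.
#' flavonol) and optionally subclass.
#'
#' @param m numeric 0/1 matrix with unique row (family) and column (trait)
#'   names.
#' @param hierarchy data.frame with columns `trait`, `group`, `type`,
#'   `class`, optionally `subclass`; one row per trait column of `m`. If
#'   omitted, each trait becomes its own class in group "unknown".
#' @return Object of class `trait_matrix` with elements `matrix` and
#'   `hierarchy`.
#' @export
trait_matrix <- function(m, hierarchy = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("trait matrix needs row (family) and column (trait) names")
  }
  rownames(m) <- trimws(rownames(m))
  colnames(m) <- trimws(colnames(m))
  if (anyDuplicated(rownames(m))) stop("duplicate family labels in trait matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate trait labels in trait matrix")
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-binary trait value %s at family '%s', trait '%s'",
                 format(m[bad[1]]), rownames(m)[i[1]], colnames(m)[i[2]]))
  }
  storage.mode(m) <- "integer"
  if (is.null(hierarchy)) {
    hierarchy <- data.frame(
      trait = colnames(m), group = "unknown", type = colnames(m),
      class = colnames(m), subclass = NA_character_, stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(hierarchy))
  if (!all(c("trait", "group", "class") %in% names(hierarchy))) {
    stop("`hierarchy` needs columns 'trait', 'group', 'class'")
  }
  if (is.null(hierarchy$type)) hierarchy$type <- hierarchy$class
  if (is.null(hierarchy$subclass)) hierarchy$subclass <- NA_character_
  hierarchy$trait <- trimws(as.character(hierarchy$trait))
  missing <- setdiff(colnames(m), hierarchy$trait)
  if (length(missing)) {
    stop("traits without hierarchy entry: ", paste(missing, collapse = ", "))
  }
  hierarchy <- hierarchy[match(colnames(m), hierarchy$trait), , drop = FALSE]
  if (any(!nzchar(hierarchy$group)) || any(is.na(hierarchy$group)) ||
      any(!nzchar(hierarchy$class)) || any(is.na(hierarchy$class))) {
    stop("every trait needs a nonempty group and class")
  }
  rownames(hierarchy) <- NULL
  structure(list(matrix = m, hierarchy = hierarchy), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d families x %d binary traits (%d classes)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$hierarchy$class))))
  invisible(x)
}

#' Validate a labeled square dissimilarity matrix
#'
#' Checks symmetry (within 1e-12 relative), a zero diagonal, nonnegativity
#' and unique labels, then returns the matrix with the diagonal forced to
#' exactly zero and symmetrized.
#'
#' @param D numeric square matrix with identical row and column names.
#' @return The validated matrix.
#' @export
as_distmatrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must be labeled")
  if (is.null(colnames(D))) colnames(D) <- rownames(D)
  if (!identical(rownames(D), colnames(D))) {
    stop("row and column labels of a distance matrix must agree")
  }
  if (anyDuplicated(rownames(D))) stop("duplicate labels in distance matrix")
  tol <- 1e-12 * max(1, max(abs(D)))
  if (max(abs(D - t(D))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > tol) stop("distance matrix diagonal must be zero")
  if (min(D) < -tol) stop("distances must be nonnegative")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Lower-triangle (condensed) form of a distance matrix
#'
#' @param D square symmetric matrix.
#' @return Numeric vector of the strictly-lower-triangle entries.
#' @export
condensed <- function(D) {
  D <- as.matrix(D)
  D[lower.tri(D)]
}

#' Align a distance matrix to a reference label order
#'
#' @param D labeled square matrix.
#' @param labels character vector; must be exactly the labels of `D`.
#' @return `D` reordered to `labels`.
#' @keywords internal
align_dist <- function(D, labels) {
  extra <- setdiff(rownames(D), labels)
  miss <- setdiff(labels, rownames(D))
  if (length(extra) || length(miss)) {
    stop("label mismatch; missing: [", paste(miss, collapse = ", "),
         "], extra: [", paste(extra, collapse = ", "), "]")
  }
  D[labels, labels, drop = FALSE]
}
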