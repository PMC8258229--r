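#' Read a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the pipeline relies on: unique, nonempty leaf labels and
#' nonnegative branch lengths (zero-length branches are allowed).
#'
#' @param file path to a Newick file, or `NULL` when `text` is given.
#' @param text a Newick string.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file)) stop("give exactly one of `file` or `text`")
  tr <- if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  validate_tree(tr)
}

#' @rdname read_newick
#' @param tree a `phylo` tree to serialize.
#' @export
write_newick <- function(tree, file = NULL) {
  out <- ape::write.tree(tree, file = if (is.null(file)) "" else file)
  if (is.null(file)) out else invisible(file)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo tree")
  lab <- tr$tip.label
  if (any(is.na(lab)) || any(!nzchar(lab))) stop("empty leaf label in tree")
  dup <- unique(lab[duplicated(lab)])
  if (length(dup)) stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  if (!is.null(tr$edge.length)) {
    if (anyNA(tr$edge.length)) stop("missing branch length in tree")
    if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  }
  tr
}

#' Prune a tree to a set of leaves
#'
#' Drops all leaves outside `keep` and collapses the resulting unary nodes,
#' summing branch lengths, so that patristic distances among the kept leaves
#' are unchanged.
#'
#' @param tree a `phylo` tree.
#' @param keep character vector of leaf labels to retain (at least 2).
#' @return The pruned `phylo` tree.
#' @export
prune_to <- function(tree, keep) {
  keep <- unique(trimws(keep))
  if (length(keep) < 2) stop("need at least 2 leaves to keep")
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("labels not in tree: ", paste(missing, collapse = ", "))
  }
  validate_tree(ape::keep.tip(tree, keep))
}

#' Read an interaction table
#'
#' Long format, one link per row, tab-separated with a header. Required
#' columns: `herbivore`, `plant_family`. Optional: `family` and `subfamily`
#' (herbivore taxonomy) and logical `is_main_host`. Repeated links are
#' deduplicated with a warning.
#'
#' @param path TSV file path.
#' @return An [interaction_network].
#' @export
read_interactions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("herbivore", "plant_family") %in% names(d))) {
    stop("interaction table needs columns 'herbivore' and 'plant_family'")
  }
  links <- d[, intersect(c("herbivore", "plant_family", "is_main_host"), names(d)),
             drop = FALSE]
  if (!is.null(links$is_main_host)) links$is_main_host <- as.logical(links$is_main_host)
  meta <- NULL
  if ("family" %in% names(d)) {
    meta <- data.frame(
      herbivore = d$herbivore, family = d$family,
      subfamily = if (is.null(d$subfamily)) NA_character_ else d$subfamily,
      stringsAsFactors = FALSE
    )
    meta <- meta[!duplicated(meta$herbivore), , drop = FALSE]
  }
  interaction_network(links, meta)
}

#' @rdname read_interactions
#' @param net an `interaction_network` to write.
#' @export
write_interactions <- function(net, path) {
  d <- merge(net$links, net$herbivore_meta, by = "herbivore", sort = TRUE)
  d <- d[, c("herbivore", "family", "subfamily", "plant_family", "is_main_host")]
  d <- d[order(d$herbivore, d$plant_family), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binary trait matrix with optional hierarchy rows
#'
#' Tab-separated; the header row holds `family` followed by trait ids. Up to
#' four optional hierarchy rows directly after the header carry the
#' chemotaxonomic levels; their first cell is `#group`, `#type`, `#class` or
#' `#subclass`. Remaining rows are families with strictly 0/1 cells.
#'
#' @param path TSV file path.
#' @return A [trait_matrix].
#' @export
read_trait_matrix <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  traits <- names(raw)[-1]
  hrows <- grepl("^#", raw[[1]])
  hier <- NULL
  if (any(hrows)) {
    h <- raw[hrows, , drop = FALSE]
    lev <- sub("^#", "", h[[1]])
    bad <- setdiff(lev, c("group", "type", "class", "subclass"))
    if (length(bad)) stop("unknown hierarchy row(s): ", paste(bad, collapse = ", "))
    hier <- data.frame(trait = traits, stringsAsFactors = FALSE)
    for (i in seq_along(lev)) hier[[lev[i]]] <- as.character(h[i, -1])
    if (is.null(hier$group)) hier$group <- "unknown"
    if (is.null(hier$class)) hier$class <- hier$trait
  }
  vals <- raw[!hrows, , drop = FALSE]
  m <- as.matrix(vals[, -1, drop = FALSE])
  bad <- which(!(m %in% c("0", "1")))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-binary trait cell '%s' at family '%s', trait '%s'",
                 m[bad[1]], vals[[1]][i[1]], traits[i[2]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- vals[[1]]
  colnames(m) <- traits
  trait_matrix(m, hier)
}

#' @rdname read_trait_matrix
#' @param traits a `trait_matrix` to write.
#' @export
write_trait_matrix <- function(traits, path) {
  m <- traits$matrix
  h <- traits$hierarchy
  lines <- paste(c("family", colnames(m)), collapse = "\t")
  for (lev in c("group", "type", "class", "subclass")) {
    v <- h[[lev]]
    if (!all(is.na(v))) {
      lines <- c(lines, paste(c(paste0("#", lev), ifelse(is.na(v), "", v)),
                              collapse = "\t"))
    }
  }
  body <- apply(cbind(rownames(m), m), 1, paste, collapse = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Restrict a network to families with trait data
#'
#' Applies the filtering used before all downstream statistics: plant
#' families missing from the trait matrix are dropped, then herbivores left
#' with zero links are dropped. Idempotent.
#'
#' @param net an `interaction_network`.
#' @param traits a `trait_matrix` whose rows define the families with
#'   chemical data.
#' @return List with elements `network` (filtered) and `report` (dropped
#'   families/herbivores and the resulting counts).
#' @export
filter_network <- function(net, traits) {
  fams_with_data <- rownames(traits$matrix)
  drop_fam <- setdiff(plant_families(net), fams_with_data)
  links <- net$links[!(net$links$plant_family %in% drop_fam), , drop = FALSE]
  drop_herb <- setdiff(herbivores(net), unique(links$herbivore))
  if (length(unique(links$plant_family)) < 2 || length(unique(links$herbivore)) < 2) {
    stop("filtered network has fewer than 2 plant families or 2 herbivores")
  }
  out <- interaction_network(
    links, net$herbivore_meta[net$herbivore_meta$herbivore %in% links$herbivore, ,
                              drop = FALSE]
  )
  report <- list(
    dropped_families = sort(drop_fam),
    dropped_herbivores = sort(drop_herb),
    n_herbivores = length(herbivores(out)),
    n_families = length(plant_families(out)),
    n_links = nrow(out$links)
  )
  list(network = out, report = report)
}

#' Subset a network by herbivore family or by excluding plant families
#'
#' With `by`, keeps only the links of herbivores belonging to that taxonomic
#' family, together with the plant families they touch. With
#' `exclude_families`, removes those plant families and then any herbivore
#' left without links (e.g. obligate monocot feeders when the monocot
#' families are excluded).
#'
#' @param net an `interaction_network`.
#' @param by herbivore family name (character scalar), or `NULL`.
#' @param exclude_families character vector of plant families to remove, or
#'   `NULL`. Exactly one of `by`/`exclude_families` must be given.
#' @return The subsetted `interaction_network`.
#' @export
subset_network <- function(net, by = NULL, exclude_families = NULL) {
  if (is.null(by) == is.null(exclude_families)) {
    stop("give exactly one of `by` or `exclude_families`")
  }
  if (!is.null(by)) {
    if (!by %in% net$herbivore_meta$family) {
      stop("unknown herbivore family: ", by)
    }
    herbs <- net$herbivore_meta$herbivore[net$herbivore_meta$family == by]
    links <- net$links[net$links$herbivore %in% herbs, , drop = FALSE]
  } else {
    if (!length(exclude_families)) stop("`exclude_families` is empty")
    links <- net$links[!(net$links$plant_family %in% exclude_families), , drop = FALSE]
  }
  if (!nrow(links)) stop("subset leaves no links")
  interaction_network(
    links,
    net$herbivore_meta[net$herbivore_meta$herbivore %in% links$herbivore, ,
                       drop = FALSE]
  )
}

#' Write a labeled square distance matrix as TSV
#'
#' @param D labeled square matrix.
#' @param path output file.
#' @export
write_distance_matrix <- function(D, path) {
  D <- as_distmatrix(D)
  utils::write.table(cbind(label = rownames(D), as.data.frame(D)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
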