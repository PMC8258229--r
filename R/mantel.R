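#' Mantel matrix-correlation permutation test
#'
#' Pearson correlation between the condensed lower triangles of two labeled
#' distance matrices over the same objects, with significance from a
#' one-tailed (greater) permutation null: rows and columns of `D2` are
#' jointly permuted `n_perm` times and p = (#\{r_perm >= r_obs\} + 1) /
#' (n_perm + 1).
#'
#' @param D1,D2 labeled square distance matrices sharing one label set
#'   (`D2` is reordered to match `D1`); at least 4 objects.
#' @param n_perm number of permutations (default 9999). `n_perm = 0` skips
#'   the null and returns `p = NA` (useful when only r is needed).
#' @param seed optional integer seed for reproducibility.
#' @return A `mantel_result` list: `r`, `p`, `n_perm`, `n_objects`, `seed`.
#' @export
mantel_test <- function(D1, D2, n_perm = 9999, seed = NULL) {
  D1 <- as_distmatrix(D1)
  D2 <- align_dist(as_distmatrix(D2), rownames(D1))
  n <- nrow(D1)
  if (n < 4) stop("Mantel test needs at least 4 objects")
  x <- condensed(D1)
  if (stats::sd(x) == 0 || stats::sd(condensed(D2)) == 0) {
    stop("zero-variance distance triangle; Mantel r undefined")
  }
  r_obs <- stats::cor(x, condensed(D2))
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      r_i <- stats::cor(x, condensed(D2[perm, perm]))
      if (r_i >= r_obs) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, n_objects = n, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %s (%d objects, %d permutations)\n",
              x$r, ifelse(is.na(x$p), "NA", format(x$p)), x$n_objects, x$n_perm))
  invisible(x)
}

#' Mantel test suite over assemblage subsets
#'
#' For the total herbivore assemblage, each requested herbivore family, and
#' optionally the network with a set of plant families (typically the
#' monocots) excluded, computes the assemblage dissimilarity between plant
#' families and tests it against (a) patristic distances on the pruned host
#' tree and (b) Manhattan distances on the subsetted trait matrix.
#'
#' @param net filtered `interaction_network`.
#' @param traits `trait_matrix` covering all families of `net`.
#' @param host_tree `phylo` host phylogeny containing all families of `net`.
#' @param families herbivore family names to test as subsets; default: all
#'   families present in the network's taxonomy with >= 4 host families.
#' @param exclude_families plant families for the exclusion subset; default
#'   `c("Poaceae", "Cyperaceae", "Juncaceae")` intersected with the network
#'   (skipped when the intersection is empty). Use `character(0)` to skip.
#' @param n_perm permutations per test (default 9999).
#' @param seed integer seed; per-test seeds are derived from it.
#' @return data.frame with one row per (subset, comparison): columns
#'   `subset`, `comparison` ("phylogenetic"/"chemical"), `mantel_r`, `p`,
#'   `n_herbivores`, `n_families`, `note`. Subsets with fewer than 4 plant
#'   families are flagged "skipped: < 4 families" with NA statistics.
#' @export
run_mantel_suite <- function(net, traits, host_tree, families = NULL,
                             exclude_families = c("Poaceae", "Cyperaceae",
                                                  "Juncaceae"),
                             n_perm = 9999, seed = 1L) {
  subsets <- list(total = net)
  if (is.null(families)) {
    families <- sort(unique(net$herbivore_meta$family))
    families <- families[vapply(families, function(f) {
      length(unique(net$links$plant_family[
        net$links$herbivore %in%
          net$herbivore_meta$herbivore[net$herbivore_meta$family == f]
      ])) >= 4
    }, logical(1))]
  }
  for (f in families) subsets[[f]] <- subset_network(net, by = f)
  excl <- intersect(exclude_families, plant_families(net))
  if (length(excl)) {
    subsets[["dicot_only"]] <- subset_network(net, exclude_families = excl)
  }

  rows <- list()
  for (k in seq_along(subsets)) {
    nm <- names(subsets)[k]
    sub <- subsets[[k]]
    fams <- plant_families(sub)
    nh <- length(herbivores(sub))
    if (length(fams) < 4) {
      rows[[length(rows) + 1L]] <- data.frame(
        subset = nm, comparison = c("phylogenetic", "chemical"),
        mantel_r = NA_real_, p = NA_real_, n_herbivores = nh,
        n_families = length(fams), note = "skipped: < 4 families",
        stringsAsFactors = FALSE
      )
      next
    }
    Da <- assemblage_dissimilarity(sub)
    Dp <- patristic(prune_to(host_tree, fams))
    Dc <- manhattan_dist(traits$matrix[fams, , drop = FALSE])
    mp <- mantel_test(Da, Dp, n_perm = n_perm, seed = seed + 1000L * k)
    mc <- mantel_test(Da, Dc, n_perm = n_perm, seed = seed + 1000L * k + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      subset = nm, comparison = c("phylogenetic", "chemical"),
      mantel_r = c(mp$r, mc$r), p = c(mp$p, mc$p),
      n_herbivores = nh, n_families = length(fams), note = "",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
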