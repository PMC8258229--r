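#' Class-count table ordered by a tree's leaf order
#'
#' Source table for a defense-trait heatmap: the class-level diversity
#' counts of [aggregate_traits()], with rows arranged in the plotting order
#' of the supplied tree or dendrogram.
#'
#' @param traits a [trait_matrix].
#' @param ordering an `hclust` dendrogram or `phylo` tree whose leaves are
#'   exactly the trait-matrix families.
#' @param file optional TSV output path.
#' @return The reordered class-count matrix (invisibly when `file` given).
#' @export
export_heatmap_table <- function(traits, ordering, file = NULL) {
  counts <- aggregate_traits(traits)
  ord <- leaf_order(ordering)
  if (!setequal(ord, rownames(counts)) || length(ord) != nrow(counts)) {
    stop("ordering leaves do not match the trait-matrix families")
  }
  counts <- counts[ord, , drop = FALSE]
  if (!is.null(file)) {
    utils::write.table(cbind(family = rownames(counts), as.data.frame(counts)),
                       file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(counts))
  }
  counts
}

leaf_order <- function(x) {
  if (inherits(x, "hclust")) {
    x$labels[x$order]
  } else if (inherits(x, "phylo")) {
    tr <- stats::reorder(x, "cladewise")
    tr$tip.label[tr$edge[tr$edge[, 2] <= length(tr$tip.label), 2]]
  } else {
    stop("need an hclust dendrogram or a phylo tree")
  }
}

#' Run the full congruence analysis
#'
#' Orchestrates every stage on one set of inputs: trait-based filtering of
#' the network, defensogram construction with clustering-algorithm
#' selection, the Mantel suite over assemblage subsets, PACo and Random
#' TaPas per subset against both the host phylogeny and the defensogram.
#' All outputs are written under `outdir` as TSV/JSON/Newick; a manifest
#' records parameters and seed. Reruns with the same config are
#' reproducible.
#'
#' @param host_tree `phylo` host-family phylogeny (or Newick path).
#' @param symb_tree `phylo` herbivore phylogeny (or Newick path).
#' @param traits [trait_matrix] (or TSV path).
#' @param net [interaction_network] (or TSV path).
#' @param outdir output directory (created if needed).
#' @param subsets herbivore family names analyzed separately in PACo /
#'   Random TaPas; default: families with >= 10 links after filtering.
#' @param exclude_families plant-family exclusion list for the Mantel
#'   "dicot_only" subset.
#' @param n_perm Mantel/PACo permutations.
#' @param N,tapas_n,percentile Random TaPas replicates, subsample size
#'   (`"auto"` = 20% of links capped by the maximum matching) and kept
#'   fraction.
#' @param seed integer seed; all stage seeds derive from it.
#' @return (Invisibly) a list with every stage result and the output paths.
#' @export
run_full_analysis <- function(host_tree, symb_tree, traits, net,
                              outdir, subsets = NULL,
                              exclude_families = c("Poaceae", "Cyperaceae",
                                                   "Juncaceae"),
                              n_perm = 999, N = 2000, tapas_n = "auto",
                              percentile = 0.01, seed = 1L) {
  if (is.character(host_tree)) host_tree <- read_newick(host_tree)
  if (is.character(symb_tree)) symb_tree <- read_newick(symb_tree)
  if (is.character(traits)) traits <- read_trait_matrix(traits)
  if (is.character(net)) net <- read_interactions(net)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(msg) message("[chemcophy] ", msg)

  stage("filtering network against trait data")
  flt <- filter_network(net, traits)
  net <- flt$network
  fams <- plant_families(net)
  herbs <- herbivores(net)
  miss <- setdiff(fams, host_tree$tip.label)
  if (length(miss)) stop("families absent from host tree: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(herbs, symb_tree$tip.label)
  if (length(miss)) stop("herbivores absent from herbivore tree: ",
                         paste(miss, collapse = ", "))
  host_tree <- prune_to(host_tree, fams)
  symb_tree <- prune_to(symb_tree, herbs)
  jsonlite::write_json(flt$report, file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  stage("building defensogram (clustering-algorithm selection)")
  chem_D <- manhattan_dist(traits$matrix[fams, , drop = FALSE])
  sel <- select_algorithm(chem_D)
  utils::write.table(as.data.frame(sel), file.path(outdir, "clustering_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  defenso <- attr(sel, "tree")
  export_defensogram(defenso, file.path(outdir, "defensogram.nwk"))
  export_heatmap_table(
    trait_matrix(traits$matrix[fams, , drop = FALSE], traits$hierarchy),
    defenso, file.path(outdir, "heatmap_table.tsv")
  )

  stage("Mantel suite")
  mantel_tab <- run_mantel_suite(net, traits, host_tree,
                                 exclude_families = exclude_families,
                                 n_perm = n_perm, seed = seed)
  utils::write.table(mantel_tab, file.path(outdir, "mantel_suite.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (is.null(subsets)) {
    tab <- table(net$herbivore_meta$family[
      match(net$links$herbivore, net$herbivore_meta$herbivore)])
    subsets <- names(tab)[tab >= 10]
    subsets <- setdiff(subsets, "Unassigned")
  }
  nets <- c(list(total = net),
            stats::setNames(lapply(subsets, function(f) subset_network(net, by = f)),
                            subsets))

  host_D <- patristic(host_tree)
  symb_D <- patristic(symb_tree)
  defenso_D <- align_dist(cophenetic_of(defenso), fams)

  paco_out <- list()
  tapas_out <- list()
  k <- 0L
  for (nm in names(nets)) {
    sub <- nets[[nm]]
    for (cmp in c("phylogeny", "defensogram")) {
      k <- k + 1L
      hd <- if (cmp == "phylogeny") host_D else defenso_D
      stage(sprintf("PACo: %s vs host %s", nm, cmp))
      pf <- paco_fit(hd, symb_D, sub, n_perm = n_perm,
                     seed = seed + 100L * k)
      paco_out[[paste(nm, cmp, sep = ".")]] <- list(
        subset = nm, comparison = cmp, m2_xy = pf$m2_xy, p = pf$p,
        n_perm = pf$n_perm, n_links = length(pf$link_residuals),
        link_residuals = as.list(pf$link_residuals)
      )
      stage(sprintf("Random TaPas: %s vs host %s", nm, cmp))
      tp <- random_tapas(hd, symb_D, sub, n = tapas_n, N = N,
                         percentile = percentile, seed = seed + 100L * k + 50L)
      tapas_out[[paste(nm, cmp, sep = ".")]] <- list(
        subset = nm, comparison = cmp, G_star = tp$G_star, n = tp$n, N = tp$N,
        percentile = tp$percentile, link_freqs = as.list(tp$link_freqs),
        residuals = as.list(tp$residuals)
      )
    }
  }
  jsonlite::write_json(paco_out, file.path(outdir, "paco_results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(tapas_out, file.path(outdir, "tapas_results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest <- list(
    package = "chemcophy",
    version = as.character(utils::packageVersion("chemcophy")),
    seed = seed, n_perm = n_perm, N = N, percentile = percentile,
    tapas_n = tapas_n, subsets = subsets,
    exclude_families = exclude_families,
    selected_algorithm = attr(sel, "selected"),
    n_families = length(fams), n_herbivores = length(herbs),
    n_links = nrow(net$links)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage("done")
  invisible(list(filter_report = flt$report, clustering = sel,
                 mantel = mantel_tab, paco = paco_out, tapas = tapas_out,
                 manifest = manifest, outdir = outdir))
}
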