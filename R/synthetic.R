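#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree rescaled to unit root-to-leaf depth.
#'
#' @param n_leaves number of leaves (>= 2).
#' @param seed optional integer seed.
#' @param prefix leaf-label prefix (labels are `prefix` + zero-padded
#'   index).
#' @return Ultrametric `phylo` tree with unit depth.
#' @export
simulate_tree <- function(n_leaves, seed = NULL, prefix = "t") {
  if (n_leaves < 2) stop("need at least 2 leaves")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("%s%0*d", prefix, nchar(as.character(n_leaves)),
                          seq_len(n_leaves))
  validate_tree(tr)
}

#' Simulate a tanglegram with tunable cospeciation
#'
#' The symbiont (herbivore) tree is a copy of the host tree whose leaf
#' labels undergo `floor((1 - c) * n)` random pairwise swaps: `c = 1` gives
#' a perfectly congruent mirror, `c = 0` a heavily shuffled one. Label
#' swaps (rather than subtree moves) keep the branch-length distribution
#' identical while destroying congruence monotonically in expectation. Base
#' links are the one-to-one leaf map; each herbivore then gains
#' Poisson(`lambda`) extra links to uniformly chosen additional families,
#' mimicking multi-host herbivores.
#'
#' @param host_tree host `phylo` tree.
#' @param c cospeciation parameter in \[0, 1\].
#' @param lambda extra-link rate (>= 0).
#' @param seed optional integer seed.
#' @return List: `symb_tree` (`phylo`), `network` (`interaction_network`).
#' @export
simulate_tanglegram <- function(host_tree, c = 1, lambda = 0, seed = NULL) {
  if (c < 0 || c > 1) stop("cospeciation c must be in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  fams <- host_tree$tip.label
  n <- length(fams)
  herb_of <- stats::setNames(paste0("H_", fams), fams)

  ## links are drawn before the label swaps so that, for a fixed seed,
  ## tanglegrams at different c share the same link set and the smaller
  ## swap count is a prefix of the larger one (seed-paired comparisons
  ## across c are then nested, differing only in the extra swaps)
  links <- data.frame(herbivore = unname(herb_of), plant_family = fams,
                      stringsAsFactors = FALSE)
  extra <- stats::rpois(n, lambda)
  for (i in seq_len(n)) {
    if (extra[i] > 0) {
      pool <- setdiff(fams, fams[i])
      add <- sample(pool, min(extra[i], length(pool)))
      links <- rbind(links, data.frame(herbivore = unname(herb_of[fams[i]]),
                                       plant_family = add,
                                       stringsAsFactors = FALSE))
    }
  }
  net <- interaction_network(links)

  symb <- host_tree
  symb$tip.label <- unname(herb_of[fams])
  n_swap <- floor((1 - c) * n)
  for (k in seq_len(n_swap)) {
    ij <- sample.int(n, 2)
    symb$tip.label[ij] <- symb$tip.label[rev(ij)]
  }
  list(symb_tree = validate_tree(symb), network = net)
}

#' Simulate binary defense traits on a tree
#'
#' A fraction `1 - rho` of the traits evolves along the tree by a symmetric
#' two-state Markov process (flip probability (1 - exp(-2 mu t)) / 2 per
#' branch of length t) from a random root state, giving phylogenetically
#' conserved traits. The remaining `rho` fraction is convergent: families
#' are partitioned into `n_syndromes` tree-independent "defense syndromes"
#' and each convergent trait is present in a random half of the syndromes
#' (plus a small per-cell flip noise `eps`). Syndromes emulate convergent
#' chemistry as it occurs in plants — suites of defense traits shared by
#' unrelated families — and give the trait distances cluster structure
#' that is decoupled from the phylogeny. Traits carry a toy hierarchy
#' (classes of 4 consecutive traits, cycling through the phenolic /
#' terpenoid / nitrogen-containing / other groups).
#'
#' @param tree `phylo` tree whose leaves are the plant families.
#' @param n_traits number of binary traits.
#' @param mu flip rate of the Markov process (> 0).
#' @param rho convergent (phylogeny-independent) fraction in \[0, 1\].
#' @param n_syndromes number of convergent defense syndromes (default 6).
#' @param eps per-cell flip noise on convergent traits (default 0.05).
#' @param seed optional integer seed.
#' @return A [trait_matrix].
#' @export
simulate_traits <- function(tree, n_traits, mu = 1, rho = 0,
                            n_syndromes = 6, eps = 0.05, seed = NULL) {
  if (mu <= 0) stop("mu must be > 0")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  n_conv <- round(rho * n_traits)
  n_phy <- n_traits - n_conv

  m <- matrix(0L, n, n_traits, dimnames = list(tree$tip.label, NULL))
  if (n_phy > 0) {
    tr <- stats::reorder(tree, "cladewise")  # parents before children
    nnode <- n + tr$Nnode
    states <- matrix(0L, nnode, n_phy)
    root <- n + 1L
    states[root, ] <- stats::rbinom(n_phy, 1, 0.5)
    for (e in seq_len(nrow(tr$edge))) {
      pflip <- (1 - exp(-2 * mu * tr$edge.length[e])) / 2
      flips <- stats::rbinom(n_phy, 1, pflip)
      states[tr$edge[e, 2], ] <- bitwXor(states[tr$edge[e, 1], ], flips)
    }
    m[, seq_len(n_phy)] <- states[seq_len(n), , drop = FALSE][
      match(tree$tip.label, tr$tip.label), , drop = FALSE]
  }
  if (n_conv > 0) {
    syndrome <- sample(rep(seq_len(n_syndromes), length.out = n))
    for (j in seq_len(n_conv)) {
      present <- stats::rbinom(n_syndromes, 1, 0.5)
      v <- present[syndrome]
      flips <- stats::rbinom(n, 1, eps)
      m[, n_phy + j] <- bitwXor(v, flips)
    }
  }

  traits <- sprintf("T%03d", seq_len(n_traits))
  colnames(m) <- traits
  cls_idx <- ceiling(seq_len(n_traits) / 4)
  groups <- c("phenolic", "terpenoid", "nitrogen", "other")
  hier <- data.frame(
    trait = traits,
    group = groups[(cls_idx - 1) %% 4 + 1],
    type = sprintf("type%02d", cls_idx),
    class = sprintf("class%02d", cls_idx),
    subclass = NA_character_,
    stringsAsFactors = FALSE
  )
  trait_matrix(m, hier)
}

#' Simulate herbivore assemblages driven by chemistry or phylogeny
#'
#' Each herbivore receives a focal family (balanced random assignment:
#' focal counts differ by at most one across families, which keeps family
#' degree variation informative about the driver instead of being focal
#' sampling noise) and links to every
#' family independently with probability exp(-(d - d_min) / beta), where d
#' is the driver's distance (Manhattan trait distance or patristic
#' distance) from the focal family and d_min the smallest off-diagonal
#' distance in the matrix. Subtracting d_min makes the kernel act on the
#' distance *contrast*: binary-trait Manhattan distances carry a large
#' constant offset (any two families differ in many traits), and without
#' the shift no bandwidth separates "chemically similar" from "chemically
#' distant" hosts. The focal family itself links with probability 1, so
#' every herbivore keeps at least one link. Small `beta` makes herbivores
#' monophagous; large `beta` makes them generalists.
#'
#' @param traits a [trait_matrix] (required when `driver = "chemical"`).
#' @param host_tree a `phylo` tree (required when
#'   `driver = "phylogenetic"`).
#' @param driver `"chemical"` or `"phylogenetic"`.
#' @param n_herbivores number of herbivores to simulate.
#' @param beta kernel bandwidth in the driver's distance units; default
#'   the standard deviation of the off-diagonal driver distances.
#' @param seed optional integer seed.
#' @param herb_family taxonomy family label for the simulated herbivores.
#' @return An [interaction_network].
#' @export
simulate_assemblage <- function(traits = NULL, host_tree = NULL,
                                driver = c("chemical", "phylogenetic"),
                                n_herbivores, beta = NULL, seed = NULL,
                                herb_family = "SimHerbidae") {
  driver <- match.arg(driver)
  if (!is.null(seed)) set.seed(seed)
  D <- if (driver == "chemical") {
    if (is.null(traits)) stop("driver = 'chemical' needs `traits`")
    manhattan_dist(traits)
  } else {
    if (is.null(host_tree)) stop("driver = 'phylogenetic' needs `host_tree`")
    patristic(host_tree)
  }
  fams <- rownames(D)
  if (is.null(beta)) beta <- stats::sd(condensed(D))
  if (beta <= 0) stop("beta must be > 0")
  d_min <- min(condensed(D))
  focals <- sample(rep(sample(fams), length.out = n_herbivores))
  rows <- vector("list", n_herbivores)
  for (i in seq_len(n_herbivores)) {
    focal <- focals[i]
    p <- pmin(1, exp(-(D[focal, ] - d_min) / beta))
    hit <- stats::runif(length(fams)) < p
    hit[fams == focal] <- TRUE
    hosts <- fams[hit]
    rows[[i]] <- data.frame(
      herbivore = sprintf("H%03d", i), plant_family = hosts,
      stringsAsFactors = FALSE
    )
  }
  links <- do.call(rbind, rows)
  meta <- data.frame(herbivore = unique(links$herbivore),
                     family = herb_family, subfamily = herb_family,
                     stringsAsFactors = FALSE)
  interaction_network(links, meta)
}

#' Simulate a complete synthetic study
#'
#' Bundles the generators into one reproducible draw of the inputs the
#' pipeline expects: a host-family tree, a herbivore tree, a binary trait
#' matrix and an interaction network. With `driver = "cospeciation"` the
#' herbivore tree and the links come from [simulate_tanglegram()]
#' (congruence controlled by `cospeciation`); with `"chemical"` or
#' `"phylogenetic"` the herbivore tree is an independent Yule tree and the
#' links come from [simulate_assemblage()].
#'
#' @param n_families,n_herbivores,n_traits dimensions of the draw.
#' @param cospeciation c in \[0, 1\] (tanglegram mode).
#' @param convergence rho in \[0, 1\] passed to [simulate_traits()].
#' @param mu trait flip rate.
#' @param lambda extra-link rate (tanglegram mode).
#' @param driver `"cospeciation"`, `"chemical"` or `"phylogenetic"`.
#' @param beta assemblage kernel bandwidth (assemblage modes).
#' @param seed integer seed (mandatory: the draw is the reproducible unit).
#' @return List: `host_tree`, `symb_tree`, `traits`, `network`, `config`.
#' @export
simulate_study <- function(n_families = 30, n_herbivores = 80, n_traits = 100,
                           cospeciation = 1, convergence = 0, mu = 1,
                           lambda = 1, driver = c("cospeciation", "chemical",
                                                  "phylogenetic"),
                           beta = NULL, seed) {
  driver <- match.arg(driver)
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(seed)
  host <- simulate_tree(n_families, prefix = "Fam")
  traits <- simulate_traits(host, n_traits, mu = mu, rho = convergence)
  if (driver == "cospeciation") {
    tg <- simulate_tanglegram(host, c = cospeciation, lambda = lambda)
    symb <- tg$symb_tree
    net <- tg$network  # tanglegram mode: one herbivore per family
  } else {
    net <- simulate_assemblage(
      traits = traits, host_tree = host, driver = driver,
      n_herbivores = n_herbivores, beta = beta
    )
    symb <- simulate_tree(n_herbivores, prefix = "H")
    symb$tip.label <- herbivores(net)[seq_len(n_herbivores)]
  }
  list(host_tree = host, symb_tree = symb, traits = traits, network = net,
       config = list(n_families = n_families, n_herbivores = n_herbivores,
                     n_traits = n_traits, cospeciation = cospeciation,
                     convergence = convergence, mu = mu, lambda = lambda,
                     driver = driver, beta = beta, seed = seed))
}
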