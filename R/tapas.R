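#' Size of the largest one-to-one link subset of a network
#'
#' Maximum bipartite matching of the herbivore-host link set: the largest
#' number of links that can be chosen with all-distinct herbivores and
#' all-distinct plant families. Computed exactly via
#' [igraph::max_bipartite_match()].
#'
#' @param net a nonempty `interaction_network`.
#' @return Integer matching size.
#' @export
max_one2one <- function(net) {
  links <- net$links
  if (!nrow(links)) stop("empty network")
  herbs <- herbivores(net)
  fams <- plant_families(net)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(herbs)), rep(TRUE, length(fams))),
    edges = rbind(match(links$herbivore, herbs),
                  length(herbs) + match(links$plant_family, fams))
  )
  igraph::max_bipartite_match(g)$matching_size
}

#' Sample a one-to-one subset of links
#'
#' Uniformly shuffles the link list and greedily accepts links whose two
#' endpoints are both still unused; if fewer than `n` links are accepted the
#' draw is retried (up to `max_retry` times).
#'
#' @param net an `interaction_network`.
#' @param n subset size; must not exceed [max_one2one()].
#' @param seed optional integer seed.
#' @param max_retry bound on rejection retries (default 1000).
#' @return data.frame of `n` links (`herbivore`, `plant_family`), each
#'   endpoint distinct.
#' @export
sample_one2one <- function(net, n, seed = NULL, max_retry = 1000) {
  if (!is.null(seed)) set.seed(seed)
  links <- net$links
  maxn <- max_one2one(net)
  if (n > maxn) {
    stop(sprintf("n = %d exceeds the maximum one-to-one subset size %d", n, maxn))
  }
  for (try in seq_len(max_retry)) {
    s <- greedy_one2one(links, n)
    if (!is.null(s)) return(s)
  }
  stop("failed to draw a one-to-one subset of size ", n,
       " in ", max_retry, " attempts")
}

greedy_one2one <- function(links, n) {
  ord <- sample.int(nrow(links))
  used_h <- character(0)
  used_f <- character(0)
  keep <- integer(0)
  for (i in ord) {
    h <- links$herbivore[i]
    f <- links$plant_family[i]
    if (!(h %in% used_h) && !(f %in% used_f)) {
      keep <- c(keep, i)
      used_h <- c(used_h, h)
      used_f <- c(used_f, f)
      if (length(keep) == n) {
        return(links[keep, c("herbivore", "plant_family"), drop = FALSE])
      }
    }
  }
  NULL
}

#' Normalized Gini coefficient G*
#'
#' G = sum_ij |x_i - x_j| / (2 k^2 mean(x)), rescaled by k/(k-1) so that a
#' single nonzero value among k gives exactly 1. Used to summarize the
#' inequality of Random TaPas link frequencies: ~2/3 under random
#' association in multi-link networks, toward 0 with pervasive
#' cospeciation, toward 1 without it.
#'
#' @param x nonnegative numeric vector, length >= 2, not all zero.
#' @return G* in \[0, 1\].
#' @export
gini_star <- function(x) {
  k <- length(x)
  if (k < 2) stop("need at least 2 values")
  if (any(x < 0)) stop("values must be nonnegative")
  s <- sum(x)
  if (s == 0) stop("all-zero vector: G* undefined")
  xs <- sort(x)
  g <- sum((2 * seq_len(k) - k - 1) * xs) / (k * s)
  g * k / (k - 1)
}

## Normalized Gini for zero-sum residual vectors (Raffinetti-Siletti-
## Vernizzi form, valid with negative values): mean |x_i - x_j| over
## 2 * mean |x|, rescaled by k/(k-1). Equals 0 when all residuals vanish,
## 2/3 for symmetric uniform residuals (the random-association reference),
## and reaches 1 when a single +/- pair stands out of an otherwise flat
## vector.
gini_residual <- function(r) {
  k <- length(r)
  if (k < 2) stop("need at least 2 values")
  denom <- 2 * mean(abs(r))
  if (denom == 0) return(0)
  rs <- sort(r)
  delta <- 2 * sum((2 * seq_len(k) - k - 1) * rs) / k^2
  min(1, (delta / denom) * k / (k - 1))
}

#' Random Tanglegram Partitions
#'
#' Draws `N` one-to-one subsets of `n` links, scores each partial tanglegram
#' by the PACo global fit m2 restricted to the sampled taxa (distance
#' matrices trimmed, re-embedded and superimposed; no permutation null
#' inside), keeps the best `percentile` fraction, and counts how often each
#' network link occurs among the kept subsets.
#'
#' Because taxa with many partners are sampled less often per link, raw
#' counts are corrected by each link's expected count — `percentile` times
#' its occurrence over all `N` subsamples. The global congruence statistic
#' G* is the normalized Gini coefficient of these corrected frequencies
#' (a Gini form valid for the signed residuals): about 2/3 when the best
#' subsets are a random draw (no cophylogenetic signal), falling toward 0
#' as congruent links come to dominate the best subsets uniformly, rising
#' toward 1 when only a few links ever fit. Z-scored corrected frequencies
#' ("frequency residuals", diverging around 0) localize the signal per
#' link.
#'
#' @param host_D distance matrix covering the plant families of `net`.
#' @param symb_D distance matrix covering the herbivores of `net`.
#' @param net an `interaction_network`.
#' @param n links per subsample, or `"auto"`: min(max_one2one, 20% of
#'   links), targeting the conventional 10-20% of total links.
#' @param N number of replicates (default 10000).
#' @param percentile fraction of best-fitting replicates kept (default
#'   0.01).
#' @param seed optional integer seed.
#' @param symmetric Procrustes mode for the inner fit (default `TRUE`).
#' @param correction PCoA correction (default `"cailliez"`).
#' @return A `tapas_result` list: `G_star`, `link_freqs` (named counts over
#'   all network links among the kept subsets, summing to
#'   n * ceiling(percentile * N)), `expected_freqs` (percentile * total
#'   occurrences), `residuals` (z-scored corrected frequencies, named
#'   alike, summing to 0), `n`, `N`, `percentile`, `seed`.
#' @export
random_tapas <- function(host_D, symb_D, net, n = "auto", N = 10000,
                         percentile = 0.01, seed = NULL, symmetric = TRUE,
                         correction = "cailliez") {
  if (!is.null(seed)) set.seed(seed)
  links <- net$links
  L <- nrow(links)
  maxn <- max_one2one(net)
  if (identical(n, "auto")) {
    n <- min(maxn, ceiling(0.2 * L))
    if (n < ceiling(0.1 * L)) {
      warning(sprintf(
        "auto n = %d is below 10%% of the %d links (matching-limited)", n, L))
    }
  }
  if (n > maxn) stop(sprintf("n = %d exceeds max_one2one = %d", n, maxn))
  if (n < 2) stop("need n >= 2 links per subsample")
  if (percentile <= 0 || percentile > 1) stop("percentile must be in (0, 1]")

  host_D <- as_distmatrix(host_D)
  symb_D <- as_distmatrix(symb_D)
  link_key <- paste(links$herbivore, links$plant_family, sep = "|")

  m2 <- numeric(N)
  drawn <- vector("list", N)
  for (r in seq_len(N)) {
    s <- sample_one2one_prepared(links, n)
    fams <- s$plant_family
    herbs <- s$herbivore
    H <- pcoa_coords(host_D[fams, fams], correction = correction)
    P <- pcoa_coords(symb_D[herbs, herbs], correction = correction)
    m2[r] <- procrustes_m2(H$coords, P$coords, symmetric = symmetric)$m2
    drawn[[r]] <- paste(herbs, fams, sep = "|")
  }
  n_keep <- ceiling(percentile * N)
  kept <- order(m2)[seq_len(n_keep)]
  freq <- table(factor(unlist(drawn[kept]), levels = link_key))
  freq <- stats::setNames(as.integer(freq), link_key)
  total <- table(factor(unlist(drawn), levels = link_key))
  expected <- stats::setNames(as.numeric(total) * percentile, link_key)
  corrected <- freq - expected
  s <- stats::sd(corrected)
  resid <- if (s > 0) corrected / s else corrected
  structure(list(G_star = gini_residual(corrected), link_freqs = freq,
                 expected_freqs = expected, residuals = resid,
                 n = n, N = N, percentile = percentile, seed = seed),
            class = "tapas_result")
}

## sample_one2one without re-validating the matching bound on every draw
sample_one2one_prepared <- function(links, n, max_retry = 1000) {
  for (try in seq_len(max_retry)) {
    s <- greedy_one2one(links, n)
    if (!is.null(s)) return(s)
  }
  stop("failed to draw a one-to-one subset of size ", n)
}

#' @export
print.tapas_result <- function(x, ...) {
  cat(sprintf(
    "Random TaPas: G* = %.3f (n = %d links/subsample, N = %d, top %.1f%%)\n",
    x$G_star, x$n, x$N, 100 * x$percentile))
  invisible(x)
}
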