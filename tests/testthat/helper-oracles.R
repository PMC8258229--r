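# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force / enumeration, not through the package's own
# code paths.

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# naive Lance-Williams agglomeration; returns sorted merge heights
lw_heights <- function(D, method = c("single", "complete", "average")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  n <- nrow(D)
  size <- rep(1, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in which(active)) for (j in which(active)) {
      if (i < j && D[i, j] < best) { best <- D[i, j]; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    for (l in which(active)) {
      if (l == bi || l == bj) next
      D[bi, l] <- D[l, bi] <- switch(method,
        single   = min(D[bi, l], D[bj, l]),
        complete = max(D[bi, l], D[bj, l]),
        average  = (size[bi] * D[bi, l] + size[bj] * D[bj, l]) /
                   (size[bi] + size[bj])
      )
    }
    size[bi] <- size[bi] + size[bj]
    active[bj] <- FALSE
  }
  sort(heights)
}

# all binary matrices with the given row and column sums
enumerate_margin_class <- function(rs, cs) {
  n <- length(rs); m <- length(cs)
  cells <- expand.grid(rep(list(0:1), n * m))
  keep <- apply(cells, 1, function(v) {
    M <- matrix(v, n, m)
    all(rowSums(M) == rs) && all(colSums(M) == cs)
  })
  lapply(which(keep), function(i) matrix(as.integer(cells[i, ]), n, m))
}

# brute-force maximum one-to-one link subset (<= ~15 links)
brute_max_matching <- function(links) {
  L <- nrow(links)
  best <- 0L
  for (mask in seq_len(2^L) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(L) - 1L)) > 0)
    if (length(idx) <= best) next
    if (!anyDuplicated(links$herbivore[idx]) &&
        !anyDuplicated(links$plant_family[idx])) {
      best <- length(idx)
    }
  }
  best
}

# double-sum Gini, normalized
gini_bruteforce <- function(x) {
  k <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * k^2 * mean(x)) * k / (k - 1)
}

# random Euclidean distance matrix on n labeled points
random_euclidean_D <- function(n, dim = 3, labels = sprintf("o%02d", seq_len(n))) {
  pts <- matrix(stats::rnorm(n * dim), n)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(labels, labels)
  D
}

# small random multi-link network on the leaves of two trees
random_network <- function(host_tips, symb_tips, lambda = 1) {
  links <- do.call(rbind, lapply(symb_tips, function(h) {
    k <- min(length(host_tips), 1 + stats::rpois(1, lambda))
    data.frame(herbivore = h, plant_family = sample(host_tips, k),
               stringsAsFactors = FALSE)
  }))
  interaction_network(links)
}

# tiny deterministic trait fixture: 4 families x 6 traits, 2 classes
toy_traits <- function() {
  m <- rbind(
    FamA = c(1, 1, 1, 0, 0, 0),
    FamB = c(1, 0, 1, 0, 1, 0),
    FamC = c(0, 0, 0, 1, 1, 1),
    FamD = c(0, 1, 0, 1, 0, 1)
  )
  colnames(m) <- sprintf("T%d", 1:6)
  hier <- data.frame(
    trait = colnames(m),
    group = rep(c("phenolic", "terpenoid"), each = 3),
    type = rep(c("flavonoid", "monoterpenoid"), each = 3),
    class = rep(c("flavonol", "iridoid"), each = 3),
    stringsAsFactors = FALSE
  )
  trait_matrix(m, hier)
}

toy_network <- function() {
  interaction_network(
    data.frame(
      herbivore = c("h1", "h1", "h2", "h3", "h3", "h4", "h5"),
      plant_family = c("FamA", "FamB", "FamB", "FamC", "FamD", "FamD", "FamA"),
      stringsAsFactors = FALSE
    ),
    data.frame(
      herbivore = paste0("h", 1:5),
      family = c("Lycaenidae", "Lycaenidae", "Pieridae", "Pieridae", "Hesperiidae"),
      subfamily = NA_character_,
      stringsAsFactors = FALSE
    )
  )
}
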