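#' Principal coordinates of a dissimilarity matrix
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' -D^2/2 matrix, coordinates scaled by the square roots of the positive
#' eigenvalues. With `correction = "cailliez"` and a non-Euclidean input,
#' the smallest constant making the off-diagonal distances Euclidean is
#' added before embedding, so all taxa get full-rank real coordinates.
#'
#' @param D labeled square dissimilarity matrix.
#' @param correction `"cailliez"` (default) or `"none"`. With `"none"`,
#'   axes with negative eigenvalues are dropped with a warning.
#' @return List: `coords` (taxa x axes, rownames = labels), `eigenvalues`
#'   (of the final embedding), `correction`, `constant` (Cailliez constant
#'   applied, 0 when none was needed).
#' @export
pcoa_coords <- function(D, correction = c("cailliez", "none")) {
  correction <- match.arg(correction)
  D <- as_distmatrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 objects")
  tolf <- function(v) max(abs(v)) * 1e-8

  embed <- function(Dm) {
    B <- dbl_center(-0.5 * Dm^2)
    e <- eigen(B, symmetric = TRUE)
    list(values = e$values, vectors = e$vectors)
  }

  e <- embed(D)
  constant <- 0
  if (min(e$values) < -tolf(e$values)) {
    if (correction == "cailliez") {
      constant <- cailliez_constant(D)
      D2 <- D + constant
      diag(D2) <- 0
      D <- D2
      e <- embed(D)
    } else {
      warning(sprintf(
        "non-Euclidean distances: dropping %d axes with negative eigenvalues",
        sum(e$values < -tolf(e$values))
      ))
    }
  }
  pos <- which(e$values > tolf(e$values))
  if (!length(pos)) pos <- 1L
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[pos], 0)), length(pos))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  list(coords = coords, eigenvalues = e$values, correction = correction,
       constant = constant)
}

dbl_center <- function(A) {
  rm <- rowMeans(A)
  cm <- colMeans(A)
  A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), cm) + mean(A)
}

## Cailliez (1983): the smallest additive constant is the largest real
## eigenvalue of the 2n x 2n block matrix [[0, 2*D1], [-I, -4*D2]] with
## D1 = centered(-D^2/2), D2 = centered(-D/2).
cailliez_constant <- function(D) {
  n <- nrow(D)
  D1 <- dbl_center(-0.5 * D^2)
  D2 <- dbl_center(-0.5 * D)
  M <- rbind(cbind(matrix(0, n, n), 2 * D1),
             cbind(-diag(n), -4 * D2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' Margin-preserving randomization of a binary matrix (quasiswap)
#'
#' Generates binary matrices with exactly the row and column sums of `B` by
#' a checkerboard trial-swap chain ([vegan::nullmodel()] method `"tswap"`):
#' random 2x2 submatrices are swapped whenever the swap preserves the
#' margins, with a long burn-in from the observed matrix and draws thinned
#' proportionally to the number of presences. The trial-swap chain is
#' symmetric, so its stationary distribution is uniform over the margin
#' class — the plain fill-and-repair construction is measurably biased on
#' small matrices, which the burn-in removes.
#'
#' @param B binary matrix.
#' @param nsim number of matrices to draw.
#' @param seed optional integer seed.
#' @param burnin,thin chain control; defaults scale with `sum(B)`.
#' @return If `nsim == 1` a single matrix, else a 3-d array (dim 3 indexes
#'   draws), both with the dimnames of `B`.
#' @export
quasiswap_matrix <- function(B, nsim = 1, seed = NULL,
                             burnin = NULL, thin = NULL) {
  B <- as.matrix(B)
  if (!all(B %in% c(0, 1))) stop("input must be binary")
  fill <- sum(B)
  if (is.null(burnin)) burnin <- max(2000, 100 * fill)
  if (is.null(thin)) thin <- max(20, 2 * fill)
  if (!is.null(seed)) set.seed(seed)
  nm <- vegan::nullmodel(B, "tswap")
  sims <- stats::simulate(nm, nsim = nsim, burnin = burnin, thin = thin)
  if (nsim == 1) {
    out <- sims[, , 1]
    dimnames(out) <- dimnames(B)
    out
  } else {
    dimnames(sims) <- c(dimnames(B), list(NULL))
    sims
  }
}

## Procrustes superimposition of two row-matched configurations.
## symmetric: both configurations are column-centered and scaled to unit
## trace before the optimal rotation, so m2 = 1 - (sum of singular values)^2
## and neither side is treated as the reference.
procrustes_m2 <- function(X, Y, symmetric = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  p <- max(ncol(X), ncol(Y))
  if (ncol(X) < p) X <- cbind(X, matrix(0, nrow(X), p - ncol(X)))
  if (ncol(Y) < p) Y <- cbind(Y, matrix(0, nrow(Y), p - ncol(Y)))
  if (symmetric) {
    X <- X / sqrt(sum(X^2))
    Y <- Y / sqrt(sum(Y^2))
  }
  s <- svd(crossprod(X, Y))
  A <- s$v %*% t(s$u)
  cc <- if (symmetric) sum(s$d) else sum(s$d) / sum(Y^2)
  R <- X - cc * Y %*% A
  list(m2 = sum(R^2), residuals = rowSums(R^2))
}

#' Procrustean approach to cophylogeny (PACo)
#'
#' Measures the congruence of a bipartite herbivore-host network with the
#' two distance matrices of its parties. Both matrices are embedded by
#' principal coordinates (Cailliez-corrected by default), each taxon's
#' coordinate row is repeated once per interaction link, and the global fit
#' m2_xy is the residual sum of squares after Procrustes superimposition of
#' the two link-expanded configurations (symmetric mode by default: neither
#' party is the a-priori driver). Significance comes from re-fitting
#' `n_perm` quasiswap randomizations of the link matrix, which conserve
#' every species' interaction count: p = (#\{m2_perm <= m2_obs\} + 1) /
#' (n_perm + 1).
#'
#' @param host_D distance matrix covering all plant families of `net`.
#' @param symb_D distance matrix covering all herbivores of `net`.
#' @param net an `interaction_network`.
#' @param n_perm permutations (default 10000); 0 skips the null (`p = NA`).
#' @param symmetric logical, default `TRUE`.
#' @param seed optional integer seed.
#' @param correction PCoA correction, `"cailliez"` (default) or `"none"`.
#' @return A `paco_result` list: `m2_xy`, `p`, `n_perm`, `link_residuals`
#'   (named "herbivore|plant_family", summing to `m2_xy`), `symmetric`,
#'   `seed`.
#' @export
paco_fit <- function(host_D, symb_D, net, n_perm = 10000, symmetric = TRUE,
                     seed = NULL, correction = "cailliez") {
  fams <- plant_families(net)
  herbs <- herbivores(net)
  miss_h <- setdiff(fams, rownames(as.matrix(host_D)))
  miss_s <- setdiff(herbs, rownames(as.matrix(symb_D)))
  if (length(miss_h)) stop("families absent from host_D: ",
                           paste(miss_h, collapse = ", "))
  if (length(miss_s)) stop("herbivores absent from symb_D: ",
                           paste(miss_s, collapse = ", "))
  H <- pcoa_coords(as_distmatrix(host_D)[fams, fams], correction = correction)
  P <- pcoa_coords(as_distmatrix(symb_D)[herbs, herbs], correction = correction)

  links <- net$links
  fit <- procrustes_m2(H$coords[links$plant_family, , drop = FALSE],
                       P$coords[links$herbivore, , drop = FALSE],
                       symmetric = symmetric)
  res <- fit$residuals
  names(res) <- paste(links$herbivore, links$plant_family, sep = "|")

  p <- NA_real_
  if (n_perm > 0) {
    B <- incidence_matrix(net, rows = "plant_family")
    sims <- quasiswap_matrix(B, nsim = n_perm, seed = seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- which(sims[, , i] == 1, arr.ind = TRUE)
      m2i <- procrustes_m2(H$coords[idx[, 1], , drop = FALSE],
                           P$coords[idx[, 2], , drop = FALSE],
                           symmetric = symmetric)$m2
      if (m2i <= fit$m2) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(m2_xy = fit$m2, p = p, n_perm = n_perm, link_residuals = res,
                 symmetric = symmetric, seed = seed),
            class = "paco_result")
}

#' @export
print.paco_result <- function(x, ...) {
  cat(sprintf("PACo %s fit: m2_xy = %.4f, p = %s (%d links, %d permutations)\n",
              if (x$symmetric) "symmetric" else "asymmetric",
              x$m2_xy, ifelse(is.na(x$p), "NA", format(x$p)),
              length(x$link_residuals), x$n_perm))
  invisible(x)
}
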