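test_that("pcoa coordinates reproduce Euclidean distances", {
  # 3 collinear points: one informative axis
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  emb <- pcoa_coords(D, correction = "none")
  expect_equal(sum(emb$eigenvalues > 1e-8), 1)
  expect_equal(as.matrix(dist(emb$coords)), D, ignore_attr = TRUE,
               tolerance = 1e-8)

  # 2 objects: a single pair at +/- d/2
  D2 <- matrix(c(0, 5, 5, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  emb2 <- pcoa_coords(D2)
  expect_equal(sort(as.numeric(emb2$coords)), c(-2.5, 2.5))

  set.seed(71)
  De <- random_euclidean_D(10)
  embe <- pcoa_coords(De, correction = "none")
  expect_equal(as.matrix(dist(embe$coords)), De, ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("cailliez correction makes non-Euclidean distances embeddable", {
  # L1 distances on the unit square are non-Euclidean: both diagonals
  # equal the sum of the sides, forcing two incompatible collinearities
  m <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1))
  D <- manhattan_dist(m)
  emb0 <- suppressWarnings(pcoa_coords(D, correction = "none"))
  emb <- pcoa_coords(D, correction = "cailliez")
  expect_gt(emb$constant, 0)
  rec <- as.matrix(dist(emb$coords))
  target <- D + emb$constant
  diag(target) <- 0
  expect_equal(rec, target, ignore_attr = TRUE, tolerance = 1e-6)

  # agreement with the reference implementation's corrected embedding
  ref <- ape::pcoa(stats::as.dist(D), correction = "cailliez")
  ref_vec <- if (!is.null(ref$vectors.cor)) ref$vectors.cor else ref$vectors
  ref_rec <- as.matrix(dist(ref_vec))
  expect_equal(rec, ref_rec, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("quasiswap preserves all margins", {
  B <- rbind(c(1, 0), c(0, 1))
  out <- quasiswap_matrix(B, seed = 5)
  expect_equal(rowSums(out), rowSums(B), ignore_attr = TRUE)
  expect_equal(colSums(out), colSums(B), ignore_attr = TRUE)

  set.seed(73)
  B2 <- matrix(rbinom(60, 1, 0.4), 6, 10)
  sims <- quasiswap_matrix(B2, nsim = 25, seed = 7)
  for (i in 1:25) {
    expect_equal(rowSums(sims[, , i]), rowSums(B2), ignore_attr = TRUE)
    expect_equal(colSums(sims[, , i]), colSums(B2), ignore_attr = TRUE)
  }
})

test_that("perfectly congruent 1:1 networks give m2 = 0 and minimal p", {
  host <- simulate_tree(20, seed = 79, prefix = "F")
  tg <- simulate_tanglegram(host, c = 1, lambda = 0, seed = 2)
  fit <- paco_fit(patristic(host), patristic(tg$symb_tree), tg$network,
                  n_perm = 199, seed = 11)
  expect_lt(fit$m2_xy, 1e-9)
  expect_equal(fit$p, 1 / 200)

  # rigid rotation of one configuration changes nothing
  fit2 <- paco_fit(2 * patristic(host), patristic(tg$symb_tree), tg$network,
                   n_perm = 0)
  expect_lt(fit2$m2_xy, 1e-9)
})

test_that("per-link residuals sum to m2 and m2 is relabeling-invariant", {
  s <- simulate_study(n_families = 12, n_herbivores = 20, seed = 83,
                      driver = "phylogenetic")
  hd <- patristic(s$host_tree)
  sd2 <- patristic(s$symb_tree)
  fit <- paco_fit(hd, sd2, s$network, n_perm = 0)
  expect_equal(sum(fit$link_residuals), fit$m2_xy, tolerance = 1e-9)
  expect_gt(fit$m2_xy, 0)
  expect_lte(fit$m2_xy, 2)

  # joint relabeling of the families
  fams <- plant_families(s$network)
  new <- setNames(sprintf("Z%02d", seq_along(fams)), fams)
  links2 <- s$network$links
  links2$plant_family <- unname(new[links2$plant_family])
  hd2 <- hd
  rownames(hd2) <- colnames(hd2) <- unname(new[rownames(hd)])
  fit2 <- paco_fit(hd2, sd2, interaction_network(links2), n_perm = 0)
  expect_equal(fit2$m2_xy, fit$m2_xy, tolerance = 1e-9)

  expect_error(paco_fit(hd[-1, -1], sd2, s$network, n_perm = 0),
               "absent from host_D")
})

test_that("permuted networks conserve every species' link count", {
  s <- simulate_study(n_families = 10, n_herbivores = 15, seed = 89,
                      driver = "chemical")
  B <- incidence_matrix(s$network)
  sims <- quasiswap_matrix(B, nsim = 20, seed = 13)
  for (i in 1:20) {
    expect_equal(rowSums(sims[, , i]), rowSums(B))
    expect_equal(colSums(sims[, , i]), colSums(B))
  }
})

test_that("mean m2 rises as cospeciation falls", {
  set.seed(97)
  m2 <- sapply(c(1, 0), function(cc) {
    mean(sapply(1:8, function(i) {
      host <- simulate_tree(15, seed = 600 + i, prefix = "F")
      tg <- simulate_tanglegram(host, c = cc, lambda = 0, seed = 700 + i)
      paco_fit(patristic(host), patristic(tg$symb_tree), tg$network,
               n_perm = 0)$m2_xy
    }))
  })
  expect_lt(m2[1], m2[2])
})
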