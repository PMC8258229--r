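test_that("yule trees are binary, ultrametric, unit-depth and reproducible", {
  tr <- simulate_tree(5, seed = 131)
  expect_equal(length(tr$tip.label), 5)
  expect_equal(tr$Nnode, 4)
  depths <- ape::node.depth.edgelength(tr)[1:5]
  expect_equal(depths, rep(1, 5), tolerance = 1e-9)

  tr2 <- simulate_tree(5, seed = 131)
  expect_identical(write_newick(tr), write_newick(tr2))

  # stored branch lengths reproduce the patristic matrix (self-consistency)
  set.seed(1)
  for (i in 1:20) {
    t <- simulate_tree(8)
    D <- patristic(t)
    ref <- ape::dist.nodes(t)[1:8, 1:8]
    dimnames(ref) <- list(t$tip.label, t$tip.label)
    lab <- sort(t$tip.label)
    expect_equal(D, ref[lab, lab], tolerance = 1e-9)
  }
})

test_that("tanglegrams interpolate between congruence and shuffling", {
  host <- simulate_tree(15, seed = 137, prefix = "F")
  tg1 <- simulate_tanglegram(host, c = 1, lambda = 0, seed = 3)
  expect_identical(sub("^H_", "", tg1$symb_tree$tip.label), host$tip.label)
  expect_equal(nrow(tg1$network$links), 15)
  expect_lt(paco_fit(patristic(host), patristic(tg1$symb_tree), tg1$network,
                     n_perm = 0)$m2_xy, 1e-9)

  tg0 <- simulate_tanglegram(host, c = 0, lambda = 2, seed = 3)
  # every herbivore keeps at least one link
  expect_setequal(unique(tg0$network$links$herbivore),
                  paste0("H_", host$tip.label))
  # same seed, same links regardless of c (swaps drawn after links)
  expect_equal(tg0$network$links[order(tg0$network$links$herbivore,
                                       tg0$network$links$plant_family), ],
               simulate_tanglegram(host, c = 0.5, lambda = 2,
                                   seed = 3)$network$links[
    order(tg0$network$links$herbivore, tg0$network$links$plant_family), ],
    ignore_attr = TRUE)
})

test_that("trait evolution has signal without convergence, none with it", {
  host <- simulate_tree(30, seed = 139, prefix = "F")

  # mu -> 0: traits effectively constant
  frozen <- simulate_traits(host, 20, mu = 1e-8, rho = 0, seed = 5)
  expect_true(all(apply(frozen$matrix, 2, function(x) length(unique(x))) == 1))

  # rho = 0: Manhattan trait distance correlates with patristic distance
  set.seed(149)
  hits <- 0
  rs_conv <- numeric(25)
  for (i in 1:25) {
    tr <- simulate_traits(host, 100, mu = 1, rho = 0)
    m <- mantel_test(manhattan_dist(tr), patristic(host), n_perm = 99)
    if (m$r > 0 && m$p < 0.05) hits <- hits + 1
    trc <- simulate_traits(host, 100, mu = 1, rho = 1)
    rs_conv[i] <- mantel_test(manhattan_dist(trc), patristic(host),
                              n_perm = 0)$r
  }
  expect_gte(hits / 25, 0.9)
  # rho = 1: correlation centered on zero
  expect_lt(mean(abs(rs_conv)), 0.1)

  # invariants: binary values, full hierarchy
  tr <- simulate_traits(host, 37, mu = 1, rho = 0.5, seed = 7)
  expect_true(all(tr$matrix %in% 0:1))
  expect_equal(nrow(tr$hierarchy), 37)
  expect_true(all(nzchar(tr$hierarchy$class)))
})

test_that("assemblage driver controls which distance herbivores follow", {
  host <- simulate_tree(20, seed = 151, prefix = "F")
  traits <- simulate_traits(host, 80, mu = 1, rho = 0.8, seed = 9)

  # beta -> 0: herbivores keep only the focal family, except focals that
  # sit exactly at the global minimum distance of the (discrete) metric
  mono <- simulate_assemblage(traits = traits, driver = "chemical",
                              n_herbivores = 15, beta = 1e-6, seed = 11)
  deg <- table(mono$links$herbivore)
  expect_gte(mean(deg == 1), 0.8)
  expect_true(all(deg <= 2))

  net <- simulate_assemblage(traits = traits, driver = "chemical",
                             n_herbivores = 40, seed = 13)
  expect_equal(length(herbivores(net)), 40)

  # determinism
  net2 <- simulate_assemblage(traits = traits, driver = "chemical",
                              n_herbivores = 40, seed = 13)
  expect_identical(net$links, net2$links)
})

test_that("simulate_study bundles are reproducible end to end", {
  s1 <- simulate_study(n_families = 10, n_herbivores = 15, seed = 157,
                       driver = "chemical", convergence = 0.5)
  s2 <- simulate_study(n_families = 10, n_herbivores = 15, seed = 157,
                       driver = "chemical", convergence = 0.5)
  expect_identical(write_newick(s1$host_tree), write_newick(s2$host_tree))
  expect_identical(s1$traits$matrix, s2$traits$matrix)
  expect_identical(s1$network$links, s2$network$links)
  expect_setequal(s1$symb_tree$tip.label, herbivores(s1$network))
})
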