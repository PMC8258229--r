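three_obj_D <- function() {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D
}

test_that("agglomeration follows the Lance-Williams update rules", {
  # two objects: a single merge at their distance, for every method
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  for (m in c("single", "complete", "upgma", "wpgma", "upgmc", "wpgmc",
              "ward_d", "ward_d2")) {
    h <- agglomerate(D2, m)
    expect_equal(h$height, 3, info = m)
  }

  # hand-computed UPGMA on 3 objects: {A,B} at 2, then C at 4
  h <- agglomerate(three_obj_D(), "upgma")
  expect_equal(sort(h$height), c(2, 4))
  cc <- cophenetic_of(h)
  expect_equal(cc["A", "B"], 2)
  expect_equal(cc["A", "C"], 4)
  expect_equal(cc["B", "C"], 4)

  expect_error(agglomerate(three_obj_D(), "median_linkage"), "unknown")
})

test_that("single linkage merge heights equal MST edge weights", {
  set.seed(23)
  for (rep in 1:5) {
    D <- random_euclidean_D(8)
    h <- agglomerate(D, "single")
    g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                             mode = "undirected")
    mst <- igraph::mst(g)
    expect_equal(sort(h$height), sort(igraph::E(mst)$weight), tolerance = 1e-9)
  }
})

test_that("agglomerative cophenetic matrices are ultrametric", {
  set.seed(29)
  D <- random_euclidean_D(9)
  for (m in c("single", "complete", "upgma", "wpgma", "ward_d", "ward_d2")) {
    cc <- cophenetic_of(agglomerate(D, m))
    for (i in 1:9) for (j in 1:9) for (k in 1:9) {
      expect_lte(cc[i, j], max(cc[i, k], cc[k, j]) + 1e-9)
    }
  }
})

test_that("bionj recovers additive distance matrices exactly", {
  # 3 taxa: closed-form branch lengths
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- bionj_tree(D)
  # branch to A = (d_AB + d_AC - d_BC)/2 = 1, B = 2, C = 4
  lens <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
  expect_equal(sort(lens), c(1, 2, 4), tolerance = 1e-9)

  # constructed additive 4-taxon matrix
  gen <- read_newick(text = "((A:1,B:2):1,(C:3,D:1):1);")
  D4 <- patristic(gen)
  tr4 <- bionj_tree(D4)
  expect_equal(patristic(tr4), D4, tolerance = 1e-9)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr4)), 0)

  expect_error(bionj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), NULL))),
               "at least 3")
})

test_that("bionj agrees topologically with the reference implementation", {
  set.seed(271)
  for (i in 1:5) {
    gen <- ape::rtree(sample(6:12, 1))
    D <- patristic(gen)
    expect_equal(as.numeric(ape::dist.topo(bionj_tree(D), ape::bionj(D))), 0)
  }
})

test_that("tied distances still give deterministic bionj output", {
  D <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  t1 <- bionj_tree(D)
  t2 <- bionj_tree(D)
  expect_equal(write_newick(t1), write_newick(t2))
})

test_that("select_algorithm picks the method preserving the most structure", {
  # ultrametric input: UPGMA reproduces it exactly, r = 1
  set.seed(31)
  Dsrc <- random_euclidean_D(8)
  Dult <- cophenetic_of(agglomerate(Dsrc, "upgma"))
  rep_ult <- select_algorithm(Dult)
  expect_equal(rep_ult$cophenetic_r[rep_ult$method == "upgma"], 1,
               tolerance = 1e-9)
  expect_equal(cophenetic_of(agglomerate(Dult, "upgma")), Dult,
               tolerance = 1e-9)

  # additive non-ultrametric input: bionj is exact, r = 1, and selected
  gen <- read_newick(text = "(((A:1,B:4):2,(C:2,D:1):3):1,(E:5,F:1):2);")
  Dadd <- patristic(gen)
  rep_add <- select_algorithm(Dadd)
  expect_equal(rep_add$cophenetic_r[rep_add$method == "bionj"], 1,
               tolerance = 1e-9)
  expect_equal(attr(rep_add, "selected"), "bionj")

  # report is sorted ascending and correlations are bounded
  expect_true(all(diff(rep_add$cophenetic_r) >= 0))
  expect_true(all(abs(rep_add$cophenetic_r) <= 1 + 1e-12))
})

test_that("select_algorithm is invariant to label permutation", {
  set.seed(37)
  D <- random_euclidean_D(10)
  perm <- sample(10)
  Dp <- D[perm, perm]
  r1 <- select_algorithm(D)
  r2 <- select_algorithm(Dp)
  expect_equal(r1$cophenetic_r[order(r1$method)],
               r2$cophenetic_r[order(r2$method)], tolerance = 1e-9)
  expect_equal(attr(r1, "selected"), attr(r2, "selected"))
})

test_that("defensogram exports round-trip through newick", {
  set.seed(41)
  D <- random_euclidean_D(7)
  h <- agglomerate(D, "upgma")
  nwk <- export_defensogram(h)
  back <- read_newick(text = nwk)
  expect_setequal(back$tip.label, rownames(D))
  # dendrogram cophenetic equals patristic of its exported tree
  expect_equal(patristic(back), cophenetic_of(h), tolerance = 1e-9)
})
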