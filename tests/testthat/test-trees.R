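test_that("two-taxon NJ returns a single edge of the right length", {
  d <- its2_dist(matrix(c(0, 0.6, 0.6, 0), 2), c("a", "b"))
  t <- neighbor_joining(d)
  expect_equal(sum(t$edge.length), 0.6)
  expect_setequal(t$tip.label, c("a", "b"))
})

test_that("NJ recovers additive matrices exactly", {
  set.seed(50)
  for (r in 1:100) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(its2_dist(dm))
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0,
                 ignore_attr = TRUE)
    rec <- ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
    expect_equal(rec, dm, tolerance = 1e-8)
  }
})

test_that("NJ topology is invariant under input label permutation", {
  set.seed(51)
  tr <- ape::rtree(8)
  dm <- ape::cophenetic.phylo(tr)
  t1 <- neighbor_joining(its2_dist(dm))
  perm <- sample(8)
  t2 <- neighbor_joining(its2_dist(dm[perm, perm]))
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("single linkage uses Minkowski feature distances", {
  f <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE,
              dimnames = list(c("x", "y"), NULL))
  t <- single_linkage_tree(f, minkowski_p = 2)
  expect_equal(max(ape::branching.times(t)), 5)  # 3-4-5 triangle
  expect_error(single_linkage_tree(f, minkowski_p = 0.5), ">= 1")
})

test_that("single linkage merges the close pair first", {
  d <- its2_dist(matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3),
                 c("A", "B", "C"))
  t <- single_linkage_tree(d)
  # on these feature rows A and B merge first
  hts <- sort(ape::branching.times(t))
  ab_node <- ape::getMRCA(t, c("A", "B"))
  expect_equal(unname(ape::branching.times(t)[as.character(ab_node)]),
               min(hts))
  # cophenetic ultrametric inequality
  coph <- ape::cophenetic.phylo(t)
  for (x in 1:3) for (y in 1:3) for (z in 1:3) {
    expect_lte(coph[x, z], max(coph[x, y], coph[y, z]) + 1e-12)
  }
})

test_that("dendrogram node heights equal the merge heights", {
  set.seed(60)
  feats <- matrix(rnorm(40), 8)
  rownames(feats) <- paste0("t", 1:8)
  hc <- stats::hclust(stats::dist(feats, "minkowski", p = 2), "single")
  t <- single_linkage_tree(feats)
  expect_equal(sort(unname(ape::branching.times(t))), sort(hc$height),
               tolerance = 1e-9)
})

test_that("bootstrap supports are deterministic and bounded", {
  set.seed(61)
  feats <- matrix(rnorm(60), 6)
  rownames(feats) <- paste0("t", 1:6)
  b1 <- bootstrap_support(feats, n_boot = 50, seed = 9)
  b2 <- bootstrap_support(feats, n_boot = 50, seed = 9)
  expect_identical(attr(b1, "boot_support"), attr(b2, "boot_support"))
  s <- attr(b1, "boot_support")
  expect_true(is.na(s[1]))               # root carries no support
  expect_true(all(s[-1] >= 0 & s[-1] <= 100))
})

test_that("duplicated identical feature blocks give full support", {
  base <- matrix(c(0, 0, 0, 10, 10, 10, 20, 20, 19), 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  feats <- cbind(base, base, base, base)
  b <- bootstrap_support(feats, n_boot = 40, seed = 2)
  expect_true(all(attr(b, "boot_support")[-1] == 100))
})

test_that("a planted unstable taxon gets the lowest support", {
  set.seed(63)
  # two tight clusters and one taxon whose features conflict column-wise
  f <- rbind(a1 = c(0, 0, 0, 0), a2 = c(0.1, 0.1, 0, 0.1),
             b1 = c(5, 5, 5, 5), b2 = c(5.1, 5, 5.1, 5),
             w = c(0.2, 5.2, 0.2, 5.2))
  b <- bootstrap_support(f, n_boot = 200, seed = 4)
  s <- attr(b, "boot_support")
  keys <- its2delimit:::clade_keys(b)
  w_nodes <- grepl("\\bw\\b|w\\|", keys) & !is.na(s)
  expect_equal(min(s[-1]), min(s[w_nodes & !is.na(s)]))
})

test_that("Newick round trips preserve topology, lengths and supports", {
  t <- from_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(t), 3L)
  expect_equal(to_newick(t), "((A:1,B:1):1,C:2);")
  expect_error(from_newick("((A:1,B:1):1,C:2;"), "unclosed")
  expect_error(from_newick("(A:1,B:1)):1;"), "position")
  t$node.label <- c("", "87")
  back <- from_newick(to_newick(t))
  expect_equal(back$node.label, c("", "87"))
})

test_that("ultrametric conversion rescales dendrogram heights linearly", {
  feats <- matrix(c(0, 0, 1, 1, 4, 5), 3, byrow = TRUE,
                  dimnames = list(c("a", "b", "c"), NULL))
  t <- single_linkage_tree(feats)
  h0 <- sort(ape::branching.times(t))
  u <- make_ultrametric(t, interval = c(0, 10))
  h1 <- sort(ape::branching.times(u))
  expect_equal(max(h1), 10)
  expect_equal(h1 / max(h1), h0 / max(h0), tolerance = 1e-9)
  # two-leaf tree: single branching time at the top of the interval
  d2 <- its2_dist(matrix(c(0, 1, 1, 0), 2), c("x", "y"))
  u2 <- make_ultrametric(single_linkage_tree(d2), interval = c(0, 10))
  expect_equal(unname(ape::branching.times(u2)), 10)
})

test_that("non-ultrametric trees need an outgroup and keep height ranks", {
  set.seed(64)
  tr <- ape::rtree(8)
  expect_error(make_ultrametric(ape::unroot(tr)), "outgroup")
  u <- make_ultrametric(ape::unroot(tr), outgroup = tr$tip.label[1])
  expect_true(ape::is.ultrametric(u, tol = 1e-8))
  expect_equal(max(ape::branching.times(u)), 10)
  expect_error(make_ultrametric(ape::unroot(tr), outgroup = "nope"),
               "not in tree")
})
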