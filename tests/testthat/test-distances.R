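test_that("structure edit distance matches the worked example and an oracle", {
  expect_equal(structure_edit_distance("(((...)))", "(((...)))"), 0)
  expect_equal(structure_edit_distance("(((...)))", "((.....))"), 2)
  set.seed(21)
  for (r in 1:30) {
    a <- random_dotbracket(sample(8:30, 1))
    b <- random_dotbracket(sample(8:30, 1))
    expect_equal(structure_edit_distance(a, b), nw_edit(a, b))
  }
})

test_that("edit distance is a metric on random triples", {
  set.seed(31)
  for (r in 1:20) {
    a <- random_dotbracket(12)
    b <- random_dotbracket(15)
    c <- random_dotbracket(18)
    dab <- structure_edit_distance(a, b)
    expect_equal(dab, structure_edit_distance(b, a))
    expect_lte(dab,
               structure_edit_distance(a, c) + structure_edit_distance(c, b))
  }
})

test_that("base-pair distance is the symmetric set difference", {
  a <- its2_structure("a", "(((...)))")
  b <- its2_structure("b", "((.....))")
  c <- its2_structure("c", ".........")
  expect_equal(base_pair_distance(a, a), 0)
  expect_equal(base_pair_distance(a, b), 1)
  expect_equal(base_pair_distance(c, a), 3)
  d <- its2_structure("d", "((....))")
  expect_error(base_pair_distance(a, d), "different lengths")
})

test_that("af_matrix assembles pairwise calls and is deterministic", {
  st <- list(its2_structure("a", "(((...)))"),
             its2_structure("b", "((.....))"),
             its2_structure("c", "........."))
  m <- af_matrix(st)
  expect_equal(m$values["a", "b"], 2)
  expect_equal(m$values["a", "c"],
               structure_edit_distance("(((...)))", "........."))
  expect_equal(diag(m$values), c(a = 0, b = 0, c = 0))
  expect_identical(m, af_matrix(st))
  expect_error(af_matrix(list(st[[1]], st[[1]])), "duplicate")
  m2 <- af_matrix(st, metric = "bp")
  expect_equal(m2$values["a", "b"], 1)
})

test_that("JC69 follows the closed form and rejects saturation", {
  row1 <- strrep("A", 10)
  row2 <- paste0(strrep("A", 7), "CCC")
  expect_equal(pairwise_seq_distance(row1, row1, model = "JC69"), 0)
  expect_equal(pairwise_seq_distance(row1, row2, model = "JC69"),
               -0.75 * log(1 - 4 / 3 * 0.3), tolerance = 1e-12)
  expect_equal(round(pairwise_seq_distance(row1, row2, model = "JC69"), 6),
               0.383119)
  row3 <- paste0(strrep("C", 8), "AA")
  expect_error(pairwise_seq_distance(row1, row3, model = "JC69"),
               "saturation")
})

test_that("JC69 is monotone increasing in the mismatch proportion", {
  n <- 40L
  prev <- -1
  for (k in 1:25) {
    row2 <- paste0(strrep("C", k), strrep("A", n - k))
    d <- pairwise_seq_distance(strrep("A", n), row2, model = "JC69")
    expect_gt(d, prev)
    prev <- d
  }
})

test_that("gapped and ambiguous sites are excluded pairwise", {
  d <- pairwise_seq_distance("ACGU-N", "ACGUAA", model = "JC69")
  expect_equal(d, 0)  # the last two sites are not comparable
  expect_error(pairwise_seq_distance("----", "ACGU", model = "JC69"),
               "zero comparable")
})

test_that("K80 and F84 agree with independent references", {
  # constructed pair: 40 sites, 8 transitions (A<->G), 2 transversions
  a <- paste(c(rep("A", 20), rep("C", 20)), collapse = "")
  b <- paste(c(rep("G", 8), rep("A", 12), "A", "A", rep("C", 18)),
             collapse = "")
  P <- 8 / 40
  Q <- 2 / 40
  k80 <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  expect_equal(pairwise_seq_distance(a, b, model = "K80"), k80,
               tolerance = 1e-12)
  jc <- pairwise_seq_distance(a, b, model = "JC69")
  expect_lt(jc, k80)  # transition-rich pairs are underestimated by JC69
  # cross-check K80 and F84 against ape::dist.dna on DNA-coded data
  set.seed(8)
  for (r in 1:5) {
    s1 <- sample(c("a", "c", "g", "t"), 120, TRUE)
    s2 <- s1
    flip <- sample(120, 18)
    s2[flip] <- sample(c("a", "c", "g", "t"), 18, TRUE)
    bin <- ape::as.DNAbin(rbind(x = s1, y = s2))
    u1 <- toupper(paste(gsub("t", "u", s1), collapse = ""))
    u2 <- toupper(paste(gsub("t", "u", s2), collapse = ""))
    for (mod in c("K80", "F84")) {
      ref <- as.numeric(ape::dist.dna(bin, model = mod))
      expect_equal(pairwise_seq_distance(u1, u2, model = mod), ref,
                   tolerance = 1e-9, label = mod)
    }
  }
})

test_that("ab_matrix builds model distances and honours the cap", {
  msa <- its2_msa(its2_seqs(c("a", "b", "c"),
                            c("ACGUACGU", "ACGUACGU", "ACGUUCGA"),
                            gapped = TRUE))
  m <- ab_matrix(msa, model = "JC69")
  expect_equal(m$values["a", "b"], 0)
  expect_equal(m$values["a", "c"],
               pairwise_seq_distance("ACGUACGU", "ACGUUCGA", model = "JC69"))
  sat <- its2_msa(its2_seqs(c("a", "b"), c("AAAAAAAAAA", "CCCCCCCCAA"),
                            gapped = TRUE))
  expect_error(ab_matrix(sat, model = "JC69"), "saturated pair.*a/b")
  capped <- ab_matrix(sat, model = "JC69", cap = 5)
  expect_equal(capped$values["a", "b"], 5)
})

test_that("produced matrices satisfy the distance-matrix invariants", {
  set.seed(77)
  fam <- generate_family(3, 3, scaffold_spec(150, 3), seed = 9)
  for (m in list(ab_matrix(fam$msa), af_matrix(fam$true_structures))) {
    expect_true(isSymmetric(m$values))
    expect_true(all(diag(m$values) == 0))
    expect_true(all(is.finite(m$values)))
    expect_true(all(m$values >= 0))
  }
  # identical sequences give an identically zero AF matrix
  st <- lapply(1:3, function(i) its2_structure(paste0("s", i), "(((...)))"))
  expect_true(all(af_matrix(st)$values == 0))
})
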