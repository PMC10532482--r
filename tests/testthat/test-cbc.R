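make_salign <- function(rows, dbs) {
  ids <- names(rows)
  msa <- its2_msa(its2_seqs(ids, unname(rows), gapped = TRUE))
  st <- lapply(ids, function(i) {
    its2_structure(i, dbs[[i]])
  })
  project_structures(msa, st)
}

test_that("projection maps sequence pairs through gaps", {
  # gapless: identity
  sa <- make_salign(c(a = "GGGAAACCC", b = "GGGAAACCC"),
                    list(a = "(((...)))", b = "(((...)))"))
  expect_equal(unname(sa$projected_pairs$a), cbind(1:3, 9:7))
  # a gap shifts downstream columns
  msa <- its2_msa(its2_seqs("r", "A-CGU", gapped = TRUE))
  st <- list(its2_structure("r", "(..)"))
  p <- project_structures(msa, st)
  expect_equal(unname(p$projected_pairs$r), cbind(1L, 5L))
  # projection then de-projection is the identity
  cols <- which(strsplit("A-CGU", "")[[1]] != "-")
  back <- cbind(match(p$projected_pairs$r[, 1], cols),
                match(p$projected_pairs$r[, 2], cols))
  expect_equal(back, unname(st[[1]]$pairs))
  # length mismatch errors name the row
  st_bad <- list(its2_structure("r", "(...)"))
  expect_error(project_structures(msa, st_bad), "r")
})

test_that("column-pair classification matches the canonical examples", {
  expect_equal(classify_column_pair(c("C", "G"), c("U", "A")), "CBC")
  expect_equal(classify_column_pair(c("A", "U"), c("G", "U")), "hemi")
  expect_equal(classify_column_pair(c("G", "C"), c("G", "C")), "none")
  expect_equal(classify_column_pair(c("A", "A"), c("G", "C")),
               "not_comparable")
  expect_equal(classify_column_pair(c("-", "U"), c("A", "U")),
               "not_comparable")
  expect_equal(classify_column_pair(c("N", "U"), c("A", "U")),
               "not_comparable")
})

test_that("identical rows have zero CBC and hemi-CBC counts", {
  sa <- make_salign(c(a = "GGGAAACCC", b = "GGGAAACCC"),
                    list(a = "(((...)))", b = "(((...)))"))
  tab <- cbc_matrix(sa)
  expect_true(all(tab$cbc_counts == 0))
  expect_true(all(tab$hcbc_counts == 0))
  expect_length(tab$partition, 1L)
})

test_that("a planted compensatory substitution is counted once", {
  # rows differ by one full pair swap (G-C -> A-U at pair 2/8) and one
  # hemi change (G-C -> G-U at pair 3/7)
  sa <- make_salign(c(a = "GGGAAACCC", b = "GAGAAAUUC"),
                    list(a = "(((...)))", b = "(((...)))"))
  tab <- cbc_matrix(sa)
  expect_equal(tab$cbc_counts["a", "b"], 1L)
  expect_equal(tab$hcbc_counts["a", "b"], 1L)
  expect_true(isSymmetric(tab$cbc_counts))
  expect_equal(diag(tab$cbc_counts), c(a = 0L, b = 0L))
})

test_that("counting scope restricts to shared pairs", {
  # row b pairs only the outer helix: intersection excludes inner pairs
  sa <- make_salign(c(a = "GGGAAACCC", b = "GAGAAAUUC"),
                    list(a = "(((...)))", b = "(.......)"))
  tab <- cbc_matrix(sa, pair_scope = "intersection")
  expect_equal(tab$cbc_counts["a", "b"], 0L)  # only pair 1/9 shared, G-C = G-C
})

test_that("CBC-zero partition is the connected components", {
  fam <- generate_family(3, 4, scaffold_spec(150, 3), seed = 31)
  sa <- project_structures(fam$msa, fam$true_structures)
  tab <- cbc_matrix(sa)
  res <- delimit_by_cbc(tab)
  expect_equal(length(res$partition), 3L)
  expect_setequal(unname(lapply(res$partition, sort)),
                  unname(lapply(fam$true_partition, sort)))
  expect_true(isSymmetric(res$verdicts))
  expect_equal(unname(res$probabilities), c(0.93, 0.76))
  # partition invariant under row order
  ord <- rev(seq_along(fam$sequences$id))
  msa2 <- its2_msa(its2delimit:::subset_seqs(fam$sequences, ord))
  sa2 <- project_structures(msa2, fam$true_structures[ord])
  tab2 <- cbc_matrix(sa2)
  expect_setequal(unname(lapply(tab2$partition, sort)),
                  unname(lapply(tab$partition, sort)))
})

test_that("consensus structure honours support and non-crossing rules", {
  sa <- make_salign(c(a = "GGGAAACCC", b = "GGGAAACCC", c = "GGGAAACCC"),
                    list(a = "(((...)))", b = "(((...)))", c = "(((...)))"))
  cons <- consensus_structure(sa)
  expect_equal(cons$dotbracket, "(((...)))")
  expect_true(all(cons$pair_support == 1))
  # a pair present in 2 of 3 rows is kept at threshold 0.5 with support 2/3
  sa2 <- make_salign(c(a = "GGGAAACCC", b = "GGGAAACCC", c = "GGGAAACCC"),
                     list(a = "(((...)))", b = "(((...)))",
                          c = ".((...))."))
  cons2 <- consensus_structure(sa2, threshold = 0.5)
  expect_true(any(cons2$pairs[, 1] == 1 & cons2$pairs[, 2] == 9))
  expect_equal(cons2$pair_support[cons2$pairs[, 1] == 1], 2 / 3)
  # output is always nested
  set.seed(91)
  fam <- generate_family(2, 5, scaffold_spec(150, 3), seed = 8)
  cons3 <- consensus_structure(project_structures(fam$msa,
                                                  fam$true_structures))
  expect_silent(pair_table(cons3$dotbracket))
  expect_error(consensus_structure(sa, threshold = 0), "threshold")
})

test_that("domain counting distinguishes exterior and multiloop helices", {
  expect_equal(count_domains("(((...)))...(((...)))")$n_domains, 2L)
  d1 <- count_domains("(((...)))")
  expect_equal(d1$n_domains, 1L)
  expect_equal(d1$n_subdomains, 0L)
  expect_equal(d1$type_label, "1-domain")
  d2 <- count_domains("((..((...))..((...))..))")
  expect_equal(d2$n_domains, 1L)
  expect_equal(d2$n_subdomains, 2L)
  # bulged continuation of one arm is not a subdomain
  d3 <- count_domains("((..((...))..))")
  expect_equal(d3$n_subdomains, 0L)
  expect_equal(count_domains(".....")$n_domains, 0L)
})

test_that("the two clades of the preset family get 4 and 6 domains", {
  fam <- generate_family(2, 3, scaffold_spec(260, c(4, 6)), seed = 3,
                         clades = c(1, 2))
  sp <- fam$sequences$species
  msa_a <- its2_msa(its2delimit:::subset_seqs(fam$sequences, sp == "sp1"))
  msa_b <- its2_msa(its2delimit:::subset_seqs(fam$sequences, sp == "sp2"))
  cons_a <- consensus_structure(project_structures(
    msa_a, fam$true_structures[sp == "sp1"]))
  cons_b <- consensus_structure(project_structures(
    msa_b, fam$true_structures[sp == "sp2"]))
  expect_equal(cons_a$type_label, "4-domain")
  expect_equal(cons_b$type_label, "6-domain")
})
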