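#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}). Negative branch
#' lengths, which NJ can produce on non-additive input, are clamped to zero
#' with a warning. The result is unrooted.
#'
#' @param d an [its2_dist].
#' @return an \pkg{ape} `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(inherits(d, "its2_dist"))
  n <- length(d$labels)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                        d$labels[1L], d$values[1L, 2L] / 2,
                                        d$labels[2L], d$values[1L, 2L] / 2))
    return(tr)
  }
  tr <- ape::nj(d$values)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

hclust_to_phylo <- function(hc) {
  # dendrogram -> phylo keeping merge heights as node heights
  # (leaf-to-node height equals the hclust merge height exactly)
  labs <- hc$labels
  h <- hc$height
  rec <- function(k) {
    if (k < 0L) return(list(str = labs[-k], height = 0))
    c1 <- rec(hc$merge[k, 1L])
    c2 <- rec(hc$merge[k, 2L])
    list(str = sprintf("(%s:%.10g,%s:%.10g)",
                       c1$str, h[k] - c1$height,
                       c2$str, h[k] - c2$height),
         height = h[k])
  }
  top <- rec(nrow(hc$merge))
  ape::read.tree(text = paste0(top$str, ";"))
}

#' Single-linkage dendrogram over Minkowski distances between matrix rows
#'
#' Treats each row of the distance matrix as that taxon's distance profile
#' (a feature vector), computes pairwise Minkowski-p distances between
#' profiles, and agglomerates by single linkage. Merge heights become node
#' heights of the returned ultrametric tree.
#'
#' @param d an [its2_dist] (rows used as feature vectors) or a plain
#'   numeric matrix of features with row names.
#' @param minkowski_p Minkowski exponent, at least 1 (default 2).
#' @return rooted ultrametric `phylo` tree.
#' @export
single_linkage_tree <- function(d, minkowski_p = 2) {
  if (minkowski_p < 1) stop("minkowski_p must be >= 1")
  feats <- if (inherits(d, "its2_dist")) d$values else as.matrix(d)
  if (is.null(rownames(feats))) stop("feature matrix needs row names")
  dd <- stats::dist(feats, method = "minkowski", p = minkowski_p)
  hc <- stats::hclust(dd, method = "single")
  hclust_to_phylo(hc)
}

clade_keys <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"), "")
}

#' Bootstrap support for single-linkage dendrogram nodes
#'
#' Resamples feature columns with replacement, rebuilds the dendrogram per
#' replicate, and scores each internal node of the reference tree by the
#' percentage of replicates containing the same tip set (plain bootstrap
#' proportion; multiscale/AU p-values are deliberately not implemented).
#' The root is given no support value.
#'
#' @param features numeric matrix, rows = taxa (row names required),
#'   columns = resampled features.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param minkowski_p Minkowski exponent (default 2).
#' @return the reference `phylo` tree with `node.label` set to supports in
#'   \[0, 100\] (root label empty) and a `boot_support` attribute vector.
#' @export
bootstrap_support <- function(features, n_boot = 1000L, seed = 1L,
                              minkowski_p = 2) {
  features <- as.matrix(features)
  if (n_boot < 1L) stop("n_boot must be >= 1")
  ref <- single_linkage_tree(features, minkowski_p)
  keys <- clade_keys(ref)
  counts <- numeric(length(keys))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(features), replace = TRUE)
    rep_tree <- single_linkage_tree(features[, cols, drop = FALSE],
                                    minkowski_p)
    counts <- counts + (keys %in% clade_keys(rep_tree))
  }
  supp <- 100 * counts / n_boot
  root <- ape::Ntip(ref) + 1L
  lab <- formatC(supp, format = "fg")
  lab[1L] <- ""                      # prop.part lists the root clade first
  supp[1L] <- NA_real_
  ref$node.label <- lab
  attr(ref, "boot_support") <- supp
  ref
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Serialize a tree to Newick
#'
#' @param t a `phylo` tree.
#' @param digits significant digits for branch lengths (default 6).
#' @return a Newick string.
#' @export
to_newick <- function(t, digits = 6) {
  stopifnot(inherits(t, "phylo"))
  ape::write.tree(t, digits = digits)
}

#' Parse a Newick string
#'
#' @param s a Newick string (or a path via [ape::read.tree] semantics).
#' @return a `phylo` tree; malformed input is an error reporting the
#'   position of the first unbalanced parenthesis when detectable.
#' @export
from_newick <- function(s) {
  v <- strsplit(s, "")[[1L]]
  depth <- 0L
  for (i in seq_along(v)) {
    if (v[i] == "(") depth <- depth + 1L
    if (v[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed Newick: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("malformed Newick: ", depth, " unclosed '('")
  tr <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string")
  tr
}

node_heights <- function(t) {
  # height above the leaves for every node (tips 0), assuming ultrametric
  ages <- ape::branching.times(t)
  ages
}

#' Make a tree ultrametric on a fixed depth interval
#'
#' An already-ultrametric rooted tree (e.g. a single-linkage dendrogram)
#' has its node heights rescaled linearly so the root sits at `interval[2]`
#' and the leaves at `interval[1]` (= 0). Any other tree is first rooted on
#' the declared outgroup, given node heights equal to the mean
#' half-patristic distance between the leaf sets of its child subtrees
#' (monotonized root-wards), and then rescaled the same way.
#'
#' @param t a `phylo` tree.
#' @param interval numeric `c(lo, hi)`; `lo` must be 0 (default `c(0, 10)`).
#' @param outgroup outgroup tip label for rooting non-ultrametric input.
#' @return rooted ultrametric `phylo` tree with root height `interval[2]`.
#' @export
make_ultrametric <- function(t, interval = c(0, 10), outgroup = NULL) {
  stopifnot(inherits(t, "phylo"))
  if (interval[1L] != 0 || interval[2L] <= 0) {
    stop("interval must be c(0, hi) with hi > 0")
  }
  hi <- interval[2L]
  if (ape::is.rooted(t) && ape::is.ultrametric(t, tol = 1e-6)) {
    ages <- ape::branching.times(t)
    f <- hi / max(ages)
    t$edge.length <- t$edge.length * f
    return(t)
  }
  if (!ape::is.rooted(t) || !is.null(outgroup)) {
    if (is.null(outgroup)) {
      stop("unrooted tree: an outgroup is required to root it")
    }
    if (!outgroup %in% t$tip.label) stop("outgroup not in tree: ", outgroup)
    t <- ape::root(t, outgroup = outgroup, resolve.root = TRUE)
  }
  t <- ape::multi2di(t)
  n <- ape::Ntip(t)
  coph <- ape::cophenetic.phylo(t)
  nnode <- t$Nnode
  h <- numeric(n + nnode)
  post <- ape::reorder.phylo(t, "postorder")
  kids <- split(post$edge[, 2L], post$edge[, 1L])
  tipsets <- vector("list", n + nnode)
  for (i in seq_len(n)) tipsets[[i]] <- t$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    node <- post$edge[e, 1L]
    if (!is.null(tipsets[[node]])) next
    ch <- kids[[as.character(node)]]
    sets <- lapply(ch, function(c) tipsets[[c]])
    tipsets[[node]] <- unlist(sets)
    cross <- 0
    npairs <- 0
    for (a in seq_len(length(sets) - 1L)) {
      for (b in seq.int(a + 1L, length(sets))) {
        cross <- cross + sum(coph[sets[[a]], sets[[b]]])
        npairs <- npairs + length(sets[[a]]) * length(sets[[b]])
      }
    }
    h[node] <- max(cross / npairs / 2, max(h[ch]) + 1e-9)
  }
  root <- n + 1L
  f <- hi / h[root]
  h <- h * f
  t$edge.length <- h[t$edge[, 1L]] - h[t$edge[, 2L]]
  t$edge.length[t$edge.length < 0] <- 0
  t
}
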