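#' Project per-sequence structures onto alignment columns
#'
#' Maps every row's base pairs (in ungapped sequence coordinates) through
#' that row's gap pattern to alignment column indices, giving a
#' sequence-structure alignment. Nesting is preserved by the monotone
#' index map.
#'
#' @param msa an [its2_msa].
#' @param structures list of [its2_structure] objects, one per row, whose
#'   lengths match the rows' ungapped lengths (matched by id).
#' @return an object of class `its2_salign` with fields `msa`,
#'   `projected_pairs` (per-row 2-column matrices of column indices) and
#'   `structures`.
#' @export
project_structures <- function(msa, structures) {
  stopifnot(inherits(msa, "its2_msa"))
  ids <- vapply(structures, function(s) s$seq_id, "")
  ord <- match(msa$seqs$id, ids)
  if (anyNA(ord)) {
    stop("missing structure(s) for row(s): ",
         paste(msa$seqs$id[is.na(ord)], collapse = ", "))
  }
  structures <- structures[ord]
  pp <- vector("list", length(ids))
  for (r in seq_along(msa$seqs$id)) {
    v <- strsplit(msa$seqs$residues[r], "")[[1L]]
    cols <- which(v != "-")
    s <- structures[[r]]
    if (nchar(s$dotbracket) != length(cols)) {
      stop("structure length (", nchar(s$dotbracket),
           ") does not match ungapped row length (", length(cols),
           ") for row ", msa$seqs$id[r])
    }
    p <- s$pairs
    proj <- cbind(cols[p[, 1L]], cols[p[, 2L]])
    colnames(proj) <- c("i", "j")
    pp[[r]] <- proj
  }
  names(pp) <- msa$seqs$id
  out <- list(msa = msa, projected_pairs = pp, structures = structures)
  class(out) <- "its2_salign"
  out
}

#' Classify one homologous base pair between two sequences
#'
#' CBC: both sides differ and both pairs are canonical; hemi-CBC: exactly
#' one side differs and both pairs are canonical; none: identical pair;
#' not-comparable: either pair is non-canonical or contains a gap or
#' ambiguity code.
#'
#' @param a_res,b_res length-2 character vectors: the two residues of the
#'   paired columns in sequences a and b.
#' @return one of `"CBC"`, `"hemi"`, `"none"`, `"not_comparable"`.
#' @export
classify_column_pair <- function(a_res, b_res) {
  classify_pairs_vec(a_res[1L], a_res[2L], b_res[1L], b_res[2L])
}

classify_pairs_vec <- function(a1, a2, b1, b2) {
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  ok <- paste0(a1, a2) %in% canon & paste0(b1, b2) %in% canon
  d1 <- a1 != b1
  d2 <- a2 != b2
  out <- rep("not_comparable", length(a1))
  out[ok & d1 & d2] <- "CBC"
  out[ok & xor(d1, d2)] <- "hemi"
  out[ok & !d1 & !d2] <- "none"
  out
}

#' Pairwise CBC and hemi-CBC counts on a sequence-structure alignment
#'
#' For every pair of rows, counts compensatory (CBC) and hemi-compensatory
#' base changes over the in-scope homologous column pairs: either the
#' intersection of the two rows' projected pair sets (default) or the pairs
#' of a consensus structure. Columns holding a gap or ambiguity on either
#' side never contribute. The CBC-zero partition is the set of connected
#' components of the graph joining rows with zero CBCs.
#'
#' @param sa an `its2_salign` from [project_structures()].
#' @param pair_scope `"intersection"` or `"consensus"`.
#' @param consensus a [consensus_structure()] result (required for
#'   `pair_scope = "consensus"`).
#' @return an object of class `its2_cbc` with fields `labels`,
#'   `cbc_counts`, `hcbc_counts`, `partition`.
#' @export
cbc_matrix <- function(sa, pair_scope = c("intersection", "consensus"),
                       consensus = NULL) {
  pair_scope <- match.arg(pair_scope)
  stopifnot(inherits(sa, "its2_salign"))
  ids <- sa$msa$seqs$id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 rows")
  rows <- strsplit(sa$msa$seqs$residues, "")
  keys <- lapply(sa$projected_pairs, function(p) paste(p[, 1L], p[, 2L]))
  if (pair_scope == "consensus") {
    if (is.null(consensus)) stop("consensus scope requires a consensus")
    cons_pairs <- consensus$pairs
  }
  cbc <- matrix(0L, n, n, dimnames = list(ids, ids))
  hcbc <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (r in seq_len(n - 1L)) {
    for (s in seq.int(r + 1L, n)) {
      if (pair_scope == "intersection") {
        hit <- match(keys[[r]], keys[[s]])
        sel <- which(!is.na(hit))
        if (length(sel) == 0L) next
        cols <- sa$projected_pairs[[r]][sel, , drop = FALSE]
      } else {
        cols <- cons_pairs
        if (NROW(cols) == 0L) next
      }
      a1 <- rows[[r]][cols[, 1L]]
      a2 <- rows[[r]][cols[, 2L]]
      b1 <- rows[[s]][cols[, 1L]]
      b2 <- rows[[s]][cols[, 2L]]
      cl <- classify_pairs_vec(a1, a2, b1, b2)
      cbc[r, s] <- cbc[s, r] <- sum(cl == "CBC")
      hcbc[r, s] <- hcbc[s, r] <- sum(cl == "hemi")
    }
  }
  out <- list(labels = ids, cbc_counts = cbc, hcbc_counts = hcbc,
              partition = zero_cbc_partition(cbc, ids))
  class(out) <- "its2_cbc"
  out
}

zero_cbc_partition <- function(cbc, ids) {
  n <- length(ids)
  adj <- cbc == 0L
  comp <- rep(0L, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    k <- k + 1L
    queue <- i
    comp[i] <- k
    while (length(queue) > 0L) {
      cur <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[cur, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  split(ids, comp)
}

#' @export
print.its2_cbc <- function(x, ...) {
  cat("CBC table:", length(x$labels), "sequences;",
      sum(x$cbc_counts[upper.tri(x$cbc_counts)] > 0), "pairs with CBC > 0;",
      length(x$partition), "CBC-zero groups\n")
  invisible(x)
}

#' Delimit sequences by the CBC-zero criterion
#'
#' Two sequences get the verdict "different" when at least one CBC
#' separates them and "same" otherwise; groups are the connected components
#' of the CBC-zero graph. The literature probabilities attached to these
#' verdicts (a CBC implies distinct species with probability ~0.93; no CBC
#' implies conspecificity with probability ~0.76) are reported as fixed
#' annotations, never used in computation.
#'
#' @param tab an `its2_cbc` from [cbc_matrix()].
#' @return list with `partition`, `verdicts` (character matrix) and
#'   `probabilities` (the annotation constants).
#' @export
delimit_by_cbc <- function(tab) {
  stopifnot(inherits(tab, "its2_cbc"))
  v <- ifelse(tab$cbc_counts > 0L, "different", "same")
  diag(v) <- "same"
  list(partition = tab$partition,
       verdicts = v,
       probabilities = c(different_given_cbc = 0.93,
                         same_given_no_cbc = 0.76))
}

#' Consensus secondary structure of a sequence-structure alignment
#'
#' Candidate column pairs are ranked by support (the fraction of rows
#' projecting that pair) and accepted greedily when the support reaches the
#' threshold and the pair neither crosses nor shares an endpoint with any
#' accepted pair; ties break by higher support, then shorter span, then
#' leftmost position.
#'
#' @param sa an `its2_salign`.
#' @param threshold minimum support fraction in (0, 1] (default 0.5).
#' @return an object of class `its2_consensus` with fields `dotbracket`
#'   (over alignment columns), `pairs`, `pair_support`, `n_domains`,
#'   `n_subdomains`, `type_label`.
#' @export
consensus_structure <- function(sa, threshold = 0.5) {
  stopifnot(inherits(sa, "its2_salign"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  n_rows <- length(sa$projected_pairs)
  if (n_rows == 0L) stop("empty alignment")
  all_pairs <- do.call(rbind, sa$projected_pairs)
  if (NROW(all_pairs) == 0L) {
    stop("no projected pairs in the alignment")
  }
  key <- paste(all_pairs[, 1L], all_pairs[, 2L])
  tab <- table(key)
  support <- as.numeric(tab) / n_rows
  uk <- names(tab)
  ij <- do.call(rbind, lapply(strsplit(uk, " "), as.integer))
  cand <- data.frame(i = ij[, 1L], j = ij[, 2L], support = support)
  cand <- cand[cand$support >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$support, cand$j - cand$i, cand$i), , drop = FALSE]
  acc <- matrix(integer(0), ncol = 2L)
  acc_support <- numeric(0)
  used <- logical(sa$msa$n_columns)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]
    j <- cand$j[r]
    if (used[i] || used[j]) next
    crosses <- FALSE
    if (nrow(acc) > 0L) {
      k <- acc[, 1L]
      l <- acc[, 2L]
      crosses <- any((k < i & i < l & l < j) | (i < k & k < j & j < l))
    }
    if (crosses) next
    acc <- rbind(acc, c(i, j))
    acc_support <- c(acc_support, cand$support[r])
    used[c(i, j)] <- TRUE
  }
  ord <- order(acc[, 1L])
  acc <- acc[ord, , drop = FALSE]
  colnames(acc) <- c("i", "j")
  db <- render_dotbracket(acc, sa$msa$n_columns)
  dom <- count_domains_db(db)
  out <- list(dotbracket = db, pairs = acc, pair_support = acc_support[ord],
              n_domains = dom$n_domains, n_subdomains = dom$n_subdomains,
              type_label = dom$type_label)
  class(out) <- "its2_consensus"
  out
}

#' @export
print.its2_consensus <- function(x, ...) {
  cat("Consensus structure: ", nrow(x$pairs), " pairs, ", x$type_label,
      " (", x$n_subdomains, " subdomains)\n", sep = "")
  invisible(x)
}

count_domains_db <- function(dotbracket) {
  pairs <- pair_table(dotbracket)
  np <- nrow(pairs)
  if (np == 0L) {
    return(list(n_domains = 0L, n_subdomains = 0L, type_label = "0-domain"))
  }
  # direct parent pair (nearest enclosing) of every pair
  parent <- rep(NA_integer_, np)
  for (p in seq_len(np)) {
    enc <- which(pairs[, 1L] < pairs[p, 1L] & pairs[, 2L] > pairs[p, 2L])
    if (length(enc) > 0L) {
      parent[p] <- enc[which.max(pairs[enc, 1L])]
    }
  }
  n_children <- tabulate(parent[!is.na(parent)], nbins = np)
  # a helix starts at an exterior pair or at a branch of a multiloop;
  # single-child continuations (stacks, bulges, internal loops) extend the
  # same helix
  starts <- is.na(parent) | n_children[ifelse(is.na(parent), 1L, parent)] >= 2L
  n_domains <- sum(starts & is.na(parent))
  n_subdomains <- sum(starts & !is.na(parent))
  list(n_domains = n_domains, n_subdomains = n_subdomains,
       type_label = paste0(n_domains, "-domain"))
}

#' Count structural domains of a consensus structure
#'
#' Domains are maximal helices emanating from the exterior loop;
#' subdomains are helices branching off internal multiloops.
#'
#' @param c an `its2_consensus` (or a dot-bracket string).
#' @return list with `n_domains`, `n_subdomains`, `type_label`.
#' @export
count_domains <- function(c) {
  db <- if (inherits(c, "its2_consensus")) c$dotbracket else c
  count_domains_db(db)
}
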