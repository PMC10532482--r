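#' Secondary structure object
#'
#' A nested (pseudoknot-free) secondary structure for one sequence:
#' dot-bracket string, 1-based base-pair index matrix, and the folding
#' objective value that produced it (if any).
#'
#' @param seq_id sequence identifier.
#' @param dotbracket dot-bracket string over `(`, `)`, `.`.
#' @param score folding objective value (`NA` for imported structures).
#' @param seq optional residue string; if given, every pair is checked to be
#'   canonical (`AU`, `UA`, `GC`, `CG`, `GU`, `UG`).
#' @return an object of class `its2_structure` with fields `seq_id`,
#'   `dotbracket`, `pairs` (2-column matrix, `i < j`), `score`.
#' @export
its2_structure <- function(seq_id, dotbracket, score = NA_real_, seq = NULL) {
  pairs <- pair_table(dotbracket)
  if (!is.null(seq)) {
    v <- strsplit(seq, "")[[1L]]
    if (length(v) != nchar(dotbracket)) {
      stop("sequence and structure lengths differ for ", seq_id)
    }
    if (nrow(pairs) > 0L) {
      pp <- paste0(v[pairs[, 1L]], v[pairs[, 2L]])
      bad <- !pp %in% c("AU", "UA", "GC", "CG", "GU", "UG")
      if (any(bad)) {
        stop("non-canonical pair(s) in structure of ", seq_id, ": ",
             paste(unique(pp[bad]), collapse = " "))
      }
    }
  }
  out <- list(seq_id = seq_id, dotbracket = dotbracket, pairs = pairs,
              score = score)
  class(out) <- "its2_structure"
  out
}

#' @export
print.its2_structure <- function(x, ...) {
  cat("Structure ", x$seq_id, ": ", nrow(x$pairs), " pairs",
      if (!is.na(x$score)) paste0(", score ", x$score), "\n", sep = "")
  invisible(x)
}

#' Decode a dot-bracket string into base pairs
#'
#' Stack-based decoding; inverse of [render_dotbracket()]. Indices are
#' 1-based.
#'
#' @param dotbracket a balanced dot-bracket string.
#' @return integer matrix with columns `i`, `j` (`i < j`), one row per pair,
#'   ordered by `i`.
#' @export
pair_table <- function(dotbracket) {
  check_balanced(dotbracket)
  v <- strsplit(dotbracket, "")[[1L]]
  open <- integer(0)
  res <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("i", "j")))
  for (k in seq_along(v)) {
    if (v[k] == "(") open <- c(open, k)
    else if (v[k] == ")") {
      res <- rbind(res, c(open[length(open)], k))
      open <- open[-length(open)]
    }
  }
  res[order(res[, 1L]), , drop = FALSE]
}

#' Render base pairs as a dot-bracket string
#'
#' @param pairs 2-column integer matrix of 1-based pairs (`i < j`), nested.
#' @param n structure length.
#' @return dot-bracket string of length `n`.
#' @export
render_dotbracket <- function(pairs, n) {
  v <- rep(".", n)
  if (NROW(pairs) > 0L) {
    v[pairs[, 1L]] <- "("
    v[pairs[, 2L]] <- ")"
  }
  paste(v, collapse = "")
}

#' Folding parameters
#'
#' The simplified nearest-neighbour objective: pair rewards GC = 3, AU = 2,
#' GU = 1, a +1 bonus per stacked pair, and a minimum hairpin loop size.
#' Only the loop size is tunable; the rewards define the model.
#'
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return a list of folding parameters.
#' @export
fold_params <- function(min_loop = 3L) {
  min_loop <- as.integer(min_loop)
  if (is.na(min_loop) || min_loop < 0L) stop("min_loop must be >= 0")
  list(min_loop = min_loop)
}

fold_one <- function(id, residues, params) {
  v <- strsplit(residues, "")[[1L]]
  # ambiguity codes are unpairable: mask them so the DP cannot pair them
  v[v %in% AMBIGUITY_CHARS] <- "N"
  res <- .fold_dp(paste(v, collapse = ""), params$min_loop)
  its2_structure(id, res$dotbracket, score = as.numeric(res$score))
}

#' Predict a minimum-free-energy-style secondary structure
#'
#' Dynamic programming over all nested canonical pairings, maximizing the
#' simplified objective of [fold_params()]. The traceback is deterministic:
#' pairing the interval start is preferred over leaving it unpaired, with
#' the smallest pairing partner, and stacked continuations are preferred
#' inside helices. Unpairable sequences fold to all dots.
#'
#' @param seqs an [its2_seqs] collection (or a single residue string).
#' @param params folding parameters from [fold_params()].
#' @return a list of [its2_structure] objects (single object for a single
#'   string input).
#' @export
fold_mfe <- function(seqs, params = fold_params()) {
  if (is.character(seqs) && length(seqs) == 1L) {
    return(fold_one("seq", canonicalize_residues(seqs), params))
  }
  stopifnot(inherits(seqs, "its2_seqs"))
  out <- lapply(seq_along(seqs$id), function(i) {
    fold_one(seqs$id[i], seqs$residues[i], params)
  })
  names(out) <- seqs$id
  out
}

enumerate_structures <- function(n, pairable, min_loop) {
  # all nested sets of canonical pairs on 1..n, as list of 2-col matrices
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2L)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)                     # i unpaired
    ks <- if (i + min_loop + 1L <= j) seq.int(i + min_loop + 1L, j)
          else integer(0)
    for (k in ks) {
      if (pairable[i, k]) {
        inner <- rec(i + 1L, k - 1L)
        rest <- rec(k + 1L, j)
        for (a in inner) for (b in rest) {
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  if (n < min_loop + 2L) return(list(matrix(integer(0), ncol = 2L)))
  rec(1L, n)
}

score_pairs <- function(v, pairs) {
  if (NROW(pairs) == 0L) return(0)
  pp <- paste0(v[pairs[, 1L]], v[pairs[, 2L]])
  reward <- c(GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1)[pp]
  key <- paste(pairs[, 1L], pairs[, 2L])
  stacked <- paste(pairs[, 1L] + 1L, pairs[, 2L] - 1L) %in% key
  sum(reward) + sum(stacked)
}

#' Exhaustive folding oracle
#'
#' Enumerates every nested canonical structure of a short sequence and
#' returns an optimum of the same objective as [fold_mfe()]. Intended as an
#' independent check of the dynamic program; refuses sequences longer than
#' 18 nt.
#'
#' @param seq a residue string (length at most 18).
#' @param params folding parameters from [fold_params()].
#' @return an [its2_structure] with the optimal score.
#' @export
brute_force_fold <- function(seq, params = fold_params()) {
  seq <- canonicalize_residues(seq)
  n <- nchar(seq)
  if (n > 18L) stop("brute_force_fold refuses sequences longer than 18 nt")
  if (n == 0L) stop("empty sequence")
  v <- strsplit(seq, "")[[1L]]
  v[v %in% AMBIGUITY_CHARS] <- "N"
  pairable <- matrix(FALSE, n, n)
  canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i - 1L >= params$min_loop) {
      pairable[i, j] <- paste0(v[i], v[j]) %in% canon
    }
  }
  cands <- enumerate_structures(n, pairable, params$min_loop)
  scores <- vapply(cands, function(p) score_pairs(v, p), 0)
  best <- which(scores == max(scores))
  # deterministic tie-break: most pairs, then lexicographically smallest
  # dot-bracket rendering
  if (length(best) > 1L) {
    np <- vapply(cands[best], NROW, 0L)
    best <- best[np == max(np)]
    db <- vapply(cands[best], render_dotbracket, "", n = n)
    best <- best[order(db)][1L]
  }
  its2_structure("seq", render_dotbracket(cands[[best]], n),
                 score = max(scores))
}
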