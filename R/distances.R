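#' Edit distance between dot-bracket structures
#'
#' Global alignment over the three-letter dot-bracket alphabet with unit
#' costs (match 0, substitution 1, insertion/deletion 1) by default.
#' Handles structures of different lengths; symmetric.
#'
#' @param a,b [its2_structure] objects or dot-bracket strings.
#' @param costs named list with elements `sub`, `indel` (defaults 1, 1).
#' @return non-negative numeric distance.
#' @export
structure_edit_distance <- function(a, b, costs = list(sub = 1, indel = 1)) {
  da <- if (inherits(a, "its2_structure")) a$dotbracket else a
  db <- if (inherits(b, "its2_structure")) b$dotbracket else b
  check_balanced(da)
  check_balanced(db)
  as.numeric(utils::adist(da, db,
                          costs = list(ins = costs$indel, del = costs$indel,
                                       sub = costs$sub)))
}

#' Base-pair set distance
#'
#' Size of the symmetric difference between the two pair sets. Requires
#' equal structure lengths; for unequal lengths use
#' [structure_edit_distance()].
#'
#' @param a,b [its2_structure] objects.
#' @return non-negative integer.
#' @export
base_pair_distance <- function(a, b) {
  stopifnot(inherits(a, "its2_structure"), inherits(b, "its2_structure"))
  if (nchar(a$dotbracket) != nchar(b$dotbracket)) {
    stop("structures have different lengths; use structure_edit_distance")
  }
  ka <- paste(a$pairs[, 1L], a$pairs[, 2L])
  kb <- paste(b$pairs[, 1L], b$pairs[, 2L])
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Alignment-free (AF) distance matrix from secondary structures
#'
#' @param structures list of [its2_structure] objects with unique ids.
#' @param metric `"edit"` (default; dot-bracket edit distance, handles
#'   unequal lengths) or `"bp"` (base-pair set distance, equal lengths).
#' @return an [its2_dist].
#' @export
af_matrix <- function(structures, metric = c("edit", "bp")) {
  metric <- match.arg(metric)
  n <- length(structures)
  if (n < 2L) stop("need at least 2 structures")
  ids <- vapply(structures, function(s) s$seq_id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate structure ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (metric == "edit") {
    dbs <- vapply(structures, function(s) s$dotbracket, "")
    m <- utils::adist(dbs, dbs)
    storage.mode(m) <- "double"
  } else {
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- base_pair_distance(structures[[i]],
                                               structures[[j]])
    }
  }
  its2_dist(m, ids)
}

#' Pairwise evolutionary distance between two aligned rows
#'
#' Sites with a gap or an ambiguity code in either row are excluded
#' (pairwise deletion). Models: JC69 `d = -(3/4) log(1 - (4/3) p)`; K80 from
#' transition/transversion proportions `P`, `Q`; F84 by the standard
#' closed form with empirical base frequencies computed from the two rows.
#' The `tstv` argument is retained for interface compatibility with
#' DNAdist-style configuration; the moment estimators determine the
#' transition/transversion ratio from the observed proportions, so it does
#' not enter the computation.
#'
#' @param row_a,row_b equal-length aligned residue strings.
#' @param model `"F84"` (default), `"K80"` or `"JC69"`.
#' @param tstv assumed transition/transversion ratio (default 2.0; see
#'   Details).
#' @return non-negative numeric distance (substitutions per site).
#' @export
pairwise_seq_distance <- function(row_a, row_b,
                                  model = c("F84", "K80", "JC69"),
                                  tstv = 2.0) {
  model <- match.arg(model)
  va <- strsplit(row_a, "")[[1L]]
  vb <- strsplit(row_b, "")[[1L]]
  if (length(va) != length(vb)) stop("aligned rows have different lengths")
  pairwise_dist_vec(va, vb, model)
}

pairwise_dist_vec <- function(va, vb, model) {
  ok <- va %in% c("A", "C", "G", "U") & vb %in% c("A", "C", "G", "U")
  va <- va[ok]
  vb <- vb[ok]
  n <- length(va)
  if (n == 0L) stop("zero comparable sites between rows")
  diff <- va != vb
  p <- mean(diff)
  purine <- function(x) x %in% c("A", "G")
  ts <- diff & (purine(va) == purine(vb))   # transitions: A<->G, C<->U
  P <- mean(ts)
  Q <- p - P
  if (model == "JC69") {
    arg <- 1 - 4 / 3 * p
    if (arg <= 0) stop("saturation: JC69 undefined (p = ", format(p), ")")
    return(-3 / 4 * log(arg))
  }
  if (model == "K80") {
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    if (a1 <= 0 || a2 <= 0) {
      stop("saturation: K80 undefined (P = ", format(P), ", Q = ",
           format(Q), ")")
    }
    return(-1 / 2 * log(a1) - 1 / 4 * log(a2))
  }
  # F84 with empirical frequencies from both rows pooled
  fr <- table(factor(c(va, vb), levels = c("A", "C", "G", "U"))) / (2 * n)
  piA <- fr[["A"]]; piC <- fr[["C"]]; piG <- fr[["G"]]; piU <- fr[["U"]]
  piR <- piA + piG
  piY <- piC + piU
  if (piR <= 0 || piY <= 0) stop("degenerate base frequencies for F84")
  A <- piC * piU / piY + piA * piG / piR
  B <- piC * piU + piA * piG
  C <- piR * piY
  a1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  a2 <- 1 - Q / (2 * C)
  if (a1 <= 0 || a2 <= 0) {
    stop("saturation: F84 undefined (P = ", format(P), ", Q = ",
         format(Q), ")")
  }
  d <- -2 * A * log(a1) + 2 * (A - B - C) * log(a2)
  max(d, 0)
}

#' Alignment-based (AB) distance matrix from an alignment
#'
#' All pairwise model distances under [pairwise_seq_distance()]. Saturated
#' pairs are an error listing the offending pairs unless `cap` is given, in
#' which case their distance is truncated at `cap`.
#'
#' @param msa an [its2_msa].
#' @param model substitution model (see [pairwise_seq_distance()]).
#' @param tstv transition/transversion ratio argument (passed through).
#' @param cap optional maximum distance substituted for saturated pairs.
#' @return an [its2_dist].
#' @export
ab_matrix <- function(msa, model = c("F84", "K80", "JC69"), tstv = 2.0,
                      cap = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(msa, "its2_msa"))
  ids <- msa$seqs$id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 rows")
  m <- matrix(0, n, n)
  saturated <- character(0)
  rows <- strsplit(msa$seqs$residues, "")
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d <- tryCatch(
      pairwise_dist_vec(rows[[i]], rows[[j]], model),
      error = function(e) {
        if (grepl("saturation", conditionMessage(e)) && !is.null(cap)) {
          return(cap)
        }
        if (grepl("saturation", conditionMessage(e))) {
          return(structure(NA_real_, pair = paste(ids[i], ids[j], sep = "/")))
        }
        stop(e)
      })
    if (is.na(d)) {
      saturated <- c(saturated, attr(d, "pair"))
      d <- 0
    }
    m[i, j] <- m[j, i] <- d
  }
  if (length(saturated) > 0L) {
    stop("saturated pair(s): ", paste(saturated, collapse = ", "),
         "; rerun with a cap to truncate instead")
  }
  its2_dist(m, ids)
}
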