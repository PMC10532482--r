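#' Double-center a dissimilarity matrix into a cross-product matrix
#'
#' Computes `S = -1/2 * Xi %*% Delta %*% t(Xi)` with centering matrix
#' `Xi = I - 1 m'` for mass vector `m`, where `Delta` is the (optionally
#' element-squared) dissimilarity matrix. With uniform masses this is the
#' classical Torgerson transform; weighted row/column means of `S` are zero.
#'
#' @param d an [its2_dist] or a square symmetric matrix.
#' @param masses positive weights summing to 1 (default uniform).
#' @param square_first square the dissimilarities first (default `TRUE`,
#'   the classical convention for metric scaling).
#' @return symmetric cross-product matrix.
#' @export
double_center <- function(d, masses = NULL, square_first = TRUE) {
  delta <- if (inherits(d, "its2_dist")) d$values else as.matrix(d)
  n <- nrow(delta)
  if (is.null(masses)) masses <- rep(1 / n, n)
  if (any(masses <= 0)) stop("masses must be positive")
  if (abs(sum(masses) - 1) > 1e-10) stop("masses must sum to 1")
  if (square_first) delta <- delta^2
  xi <- diag(n) - matrix(1, n, 1) %*% matrix(masses, 1, n)
  s <- -0.5 * xi %*% delta %*% t(xi)
  (s + t(s)) / 2
}

#' MFA-normalize a cross-product matrix
#'
#' Divides by the largest eigenvalue so the normalized table has first
#' eigenvalue 1 (the "MFA" table normalization).
#'
#' @param s symmetric matrix with positive first eigenvalue.
#' @param tol degeneracy tolerance on the first eigenvalue.
#' @return list with `matrix` (the normalized table) and `lambda1`.
#' @export
mfa_normalize <- function(s, tol = 1e-12) {
  lambda1 <- eigen(s, symmetric = TRUE, only.values = TRUE)$values[1L]
  if (!is.finite(lambda1) || lambda1 <= tol) {
    stop("degenerate table: first eigenvalue ", format(lambda1))
  }
  list(matrix = s / lambda1, lambda1 = lambda1)
}

#' RV coefficient between two cross-product matrices
#'
#' `RV = trace(s1 s2) / sqrt(trace(s1 s1) trace(s2 s2))`; lies in \[0, 1\]
#' for positive semidefinite inputs.
#'
#' @param s1,s2 symmetric matrices of identical shape.
#' @return the RV coefficient.
#' @export
rv_coefficient <- function(s1, s2) {
  if (!all(dim(s1) == dim(s2))) stop("matrices have different shapes")
  n1 <- sum(s1 * s1)
  n2 <- sum(s2 * s2)
  if (n1 <= 0 || n2 <= 0) stop("zero-norm input to RV coefficient")
  sum(s1 * s2) / sqrt(n1 * n2)
}

#' DISTATIS compromise of distance matrices
#'
#' Fuses two or more distance tables over the same taxa into a single
#' compromise: each table is double-centered and MFA-normalized, the
#' between-table RV-coefficient matrix `C` is formed, table weights `alpha`
#' are the (positive) first eigenvector of `C` rescaled to sum 1, and the
#' compromise is `S+ = sum_k alpha_k * S_k~`. The compromise-derived
#' distances are `d+_ij = s_ii + s_jj - 2 s_ij`.
#'
#' @param tables list of [its2_dist] objects with identical label sets
#'   (order is reconciled by label against the first table).
#' @param masses optional mass vector (default uniform).
#' @param square_first square dissimilarities before centering
#'   (default `TRUE`).
#' @param n_factors_kept number of compromise factors kept for the
#'   projection output (default 2; reporting only, the compromise distance
#'   uses the full matrix).
#' @return an object of class `its2_distatis` with fields `tables`,
#'   `cross_products`, `normalized`, `first_eigenvalues`, `rv_matrix`,
#'   `alpha`, `compromise`, `compromise_distance`, `factor_scores`,
#'   `eigenvalues`, `n_factors_kept`.
#' @export
distatis <- function(tables, masses = NULL, square_first = TRUE,
                     n_factors_kept = 2L) {
  if (length(tables) < 2L) stop("need at least 2 tables")
  stopifnot(all(vapply(tables, inherits, TRUE, "its2_dist")))
  labels <- tables[[1L]]$labels
  tables <- lapply(seq_along(tables), function(k) {
    tk <- tables[[k]]
    missing <- setdiff(labels, tk$labels)
    extra <- setdiff(tk$labels, labels)
    if (length(missing) || length(extra)) {
      stop("table ", k, " label mismatch; missing: ",
           paste(missing, collapse = ", "), "; extra: ",
           paste(extra, collapse = ", "))
    }
    ord <- match(labels, tk$labels)
    its2_dist(tk$values[ord, ord], labels)
  })
  ss <- lapply(tables, double_center, masses = masses,
               square_first = square_first)
  norm <- lapply(ss, mfa_normalize)
  s_tilde <- lapply(norm, `[[`, "matrix")
  lambda1 <- vapply(norm, `[[`, 0, "lambda1")
  K <- length(tables)
  C <- diag(1, K)
  for (a in seq_len(K - 1L)) for (b in seq.int(a + 1L, K)) {
    C[a, b] <- C[b, a] <- rv_coefficient(s_tilde[[a]], s_tilde[[b]])
  }
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-10)) stop("first eigenvector of RV matrix not positive")
  v <- pmax(v, 0)
  alpha <- v / sum(v)
  s_plus <- Reduce(`+`, Map(`*`, alpha, s_tilde))
  s_plus <- (s_plus + t(s_plus)) / 2
  evs <- eigen(s_plus, symmetric = TRUE)
  if (min(evs$values) < -1e-8) {
    # non-Euclidean input tables give indefinite cross-products; the
    # compromise distances below remain valid (d_ij = s_ii + s_jj - 2 s_ij
    # recovers a non-negative dissimilarity by the centering identity)
    warning("compromise not positive semidefinite (min eigenvalue ",
            format(min(evs$values)), "); input tables are non-Euclidean")
  }
  nf <- min(as.integer(n_factors_kept), sum(evs$values > 1e-12))
  fs <- evs$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(pmax(evs$values[seq_len(nf)], 0)), nf)
  rownames(fs) <- labels
  out <- list(tables = tables,
              cross_products = ss,
              normalized = s_tilde,
              first_eigenvalues = lambda1,
              rv_matrix = C,
              alpha = alpha,
              compromise = s_plus,
              compromise_distance = compromise_to_distance(s_plus, labels),
              factor_scores = fs,
              eigenvalues = evs$values,
              min_eigenvalue = min(evs$values),
              n_factors_kept = nf)
  class(out) <- "its2_distatis"
  out
}

#' @export
print.its2_distatis <- function(x, ...) {
  cat("DISTATIS compromise of", length(x$tables), "tables over",
      length(x$tables[[1L]]$labels), "taxa\n")
  cat("  table weights alpha:", paste(round(x$alpha, 4), collapse = ", "),
      "\n")
  cat("  RV matrix (off-diagonal):",
      paste(round(x$rv_matrix[upper.tri(x$rv_matrix)], 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Convert a compromise cross-product matrix to distances
#'
#' `d_ij = s_ii + s_jj - 2 s_ij`; zero diagonal, symmetric, non-negative
#' for positive semidefinite input. Tiny negatives (above `-1e-8`) from
#' round-off are clamped to zero; anything lower is an error.
#'
#' @param s_plus symmetric matrix.
#' @param labels taxon labels.
#' @return an [its2_dist].
#' @export
compromise_to_distance <- function(s_plus, labels = rownames(s_plus)) {
  dg <- diag(s_plus)
  d <- outer(dg, dg, `+`) - 2 * s_plus
  if (min(d) < -1e-8) {
    stop("negative compromise distance ", format(min(d)),
         ": input not positive semidefinite")
  }
  d[d < 0] <- 0
  diag(d) <- 0
  its2_dist(d, labels)
}
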