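#' @useDynLib its2delimit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

IUPAC_CHARS <- c("A", "C", "G", "U", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")
AMBIGUITY_CHARS <- setdiff(IUPAC_CHARS, c("A", "C", "G", "U"))
GAP <- "-"

#' Canonicalize residue strings
#'
#' Uppercases, maps T to U (T and U are synonyms internally; canonical form
#' is U) and maps the gap characters `-` and `.` both to `-`. Idempotent.
#'
#' @param x character vector of residue strings.
#' @param allow_gaps logical; if `FALSE` (default) a gap character is an error.
#' @return character vector of canonical residue strings.
#' @export
canonicalize_residues <- function(x, allow_gaps = FALSE) {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  x <- gsub(".", "-", x, fixed = TRUE)
  bad <- setdiff(unique(unlist(strsplit(x, ""))), c(IUPAC_CHARS, GAP))
  if (length(bad) > 0L) {
    stop("invalid residue character(s): ", paste(bad, collapse = " "))
  }
  if (!allow_gaps && any(grepl("-", x, fixed = TRUE))) {
    stop("gap characters are not allowed in unaligned sequences")
  }
  x
}

#' Annotated sequence collection
#'
#' The basic sequence container of the package: parallel vectors of unique
#' identifiers and canonical residue strings (RNA alphabet, U not T),
#' with an optional species label and an outgroup flag per record.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of residue strings (canonicalized).
#' @param species optional character vector of species labels (`NA` allowed).
#' @param outgroup logical vector flagging outgroup records.
#' @param gapped logical; `TRUE` for alignment rows that may contain `-`.
#' @return an object of class `its2_seqs`.
#' @export
its2_seqs <- function(id, residues, species = NA_character_,
                      outgroup = FALSE, gapped = FALSE) {
  id <- as.character(id)
  n <- length(id)
  if (n == 0L) stop("empty sequence collection")
  if (any(!nzchar(id)) || anyNA(id)) stop("sequence ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "))
  }
  residues <- canonicalize_residues(as.character(residues), allow_gaps = gapped)
  if (length(residues) != n) stop("id and residues lengths differ")
  if (any(!nzchar(gsub("-", "", residues, fixed = TRUE)))) {
    stop("sequences must contain at least one residue")
  }
  out <- list(id = id,
              residues = residues,
              species = rep_len(as.character(species), n),
              outgroup = rep_len(as.logical(outgroup), n))
  class(out) <- "its2_seqs"
  out
}

#' @export
print.its2_seqs <- function(x, ...) {
  cat("ITS2 sequence collection:", length(x$id), "records\n")
  len <- nchar(gsub("-", "", x$residues, fixed = TRUE))
  cat("  lengths:", min(len), "-", max(len), "nt\n")
  if (any(x$outgroup)) {
    cat("  outgroup:", paste(x$id[x$outgroup], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.its2_seqs <- function(x) length(x$id)

subset_seqs <- function(seqs, keep) {
  its2_seqs(seqs$id[keep], seqs$residues[keep], seqs$species[keep],
            seqs$outgroup[keep],
            gapped = any(grepl("-", seqs$residues, fixed = TRUE)))
}

#' Read a FASTA file
#'
#' One record per header, order preserved, residues canonicalized (U not T).
#' Duplicate identifiers and empty files are errors.
#'
#' @param path path to a FASTA file.
#' @param gapped logical; allow gap characters (aligned FASTA).
#' @return an [its2_seqs] collection.
#' @export
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       seqtype = "AA"),
    error = function(e) stop("could not read FASTA from ", path, ": ",
                             conditionMessage(e)))
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  its2_seqs(names(recs), vapply(recs, as.character, ""), gapped = gapped)
}

#' Write a FASTA file
#'
#' @param seqs an [its2_seqs] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(inherits(seqs, "its2_seqs"))
  writeLines(paste0(">", seqs$id, "\n", seqs$residues), path)
  invisible(path)
}

#' Multiple sequence alignment container
#'
#' Equal-length gapped rows over the canonical alphabet.
#'
#' @param seqs an [its2_seqs] collection with gapped rows.
#' @return an object of class `its2_msa` with fields `seqs` and `n_columns`.
#' @export
its2_msa <- function(seqs) {
  stopifnot(inherits(seqs, "its2_seqs"))
  len <- nchar(seqs$residues)
  if (length(unique(len)) != 1L) {
    off <- seqs$id[len != len[1L]]
    stop("ragged alignment rows (length differs from first row): ",
         paste(off, collapse = ", "))
  }
  out <- list(seqs = seqs, n_columns = len[1L])
  class(out) <- "its2_msa"
  out
}

#' @export
print.its2_msa <- function(x, ...) {
  cat("ITS2 alignment:", length(x$seqs$id), "rows x", x$n_columns,
      "columns\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file (equal-length rows; `-` and `.`
#'   both accepted as gaps and normalized to `-`).
#' @return an [its2_msa].
#' @export
read_alignment <- function(path) {
  its2_msa(read_fasta(path, gapped = TRUE))
}

#' Write an aligned FASTA file
#'
#' @param msa an [its2_msa].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  stopifnot(inherits(msa, "its2_msa"))
  write_fasta(msa$seqs, path)
}

check_balanced <- function(db) {
  v <- strsplit(db, "")[[1L]]
  depth <- 0L
  for (i in seq_along(v)) {
    if (v[i] == "(") depth <- depth + 1L
    else if (v[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    } else if (v[i] != ".") {
      stop("invalid dot-bracket character '", v[i], "' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("unbalanced '(' (", depth, " unclosed) at end of string")
  }
  invisible(TRUE)
}

#' Read a Vienna dot-bracket file
#'
#' Three-line records: `>header`, sequence, dot-bracket structure (an
#' optional trailing parenthesized energy on the structure line is ignored).
#' The structure must be balanced and as long as the sequence.
#'
#' @param path path to a Vienna file.
#' @return a list with `seqs` (an [its2_seqs]) and `structures` (a list of
#'   [its2_structure] objects in the same order).
#' @export
read_vienna <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty Vienna file: ", path)
  if (length(lines) %% 3L != 0L) {
    stop("Vienna file is not made of header/sequence/structure triplets")
  }
  idx <- seq(1L, length(lines), by = 3L)
  ids <- character(0)
  res <- character(0)
  structs <- list()
  for (i in idx) {
    hdr <- lines[i]
    if (!startsWith(hdr, ">")) stop("expected header at line ", i)
    id <- sub("^>\\s*", "", hdr)
    id <- strsplit(id, "\\s+")[[1L]][1L]
    seq <- canonicalize_residues(trimws(lines[i + 1L]))
    db <- trimws(lines[i + 2L])
    db <- sub("\\s+\\(\\s*-?[0-9.]+\\s*\\)$", "", db)
    if (nchar(db) != nchar(seq)) {
      stop("structure length (", nchar(db), ") != sequence length (",
           nchar(seq), ") for record ", id)
    }
    check_balanced(db)
    ids <- c(ids, id)
    res <- c(res, seq)
    structs[[length(structs) + 1L]] <- its2_structure(id, db, seq = seq)
  }
  list(seqs = its2_seqs(ids, res), structures = structs)
}

#' Write a Vienna dot-bracket file
#'
#' @param seqs an [its2_seqs] collection.
#' @param structures list of [its2_structure] objects, same order/ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(seqs, structures, path) {
  stopifnot(inherits(seqs, "its2_seqs"),
            length(structures) == length(seqs$id))
  db <- unname(vapply(structures, function(s) s$dotbracket, ""))
  sid <- unname(vapply(structures, function(s) s$seq_id, ""))
  if (!identical(sid, seqs$id)) stop("structure ids do not match sequence ids")
  writeLines(paste0(">", seqs$id, "\n", seqs$residues, "\n", db), path)
  invisible(path)
}

#' Labelled symmetric distance matrix
#'
#' @param values numeric square matrix of non-negative dissimilarities.
#' @param labels character vector of unique taxon labels (defaults to
#'   `rownames(values)`).
#' @param tol symmetry tolerance; asymmetry up to `tol` is averaged away.
#' @return an object of class `its2_dist` with fields `labels` and `values`.
#' @export
its2_dist <- function(values, labels = rownames(values), tol = 1e-8) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("label count does not match matrix dimension")
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("distance matrix has non-finite entries")
  asym <- max(abs(values - t(values)))
  if (asym > tol) stop("matrix asymmetry ", format(asym), " exceeds tolerance")
  values <- (values + t(values)) / 2
  if (any(values < 0)) stop("negative distances are not allowed")
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  out <- list(labels = labels, values = values)
  class(out) <- "its2_dist"
  out
}

#' @export
print.its2_dist <- function(x, ...) {
  cat("Distance matrix:", length(x$labels), "taxa; range [",
      format(min(x$values)), ",", format(max(x$values)), "]\n")
  invisible(x)
}

#' @export
as.matrix.its2_dist <- function(x, ...) x$values

#' Read a square or lower-triangular PHYLIP distance matrix
#'
#' First token is the taxon count; each row is a label followed by its
#' distances (full square or lower-triangle dialect, both detected from the
#' token count). The matrix is symmetrized by averaging when the asymmetry
#' is at most `tol`, and rejected otherwise.
#'
#' @param path path to a PHYLIP distance file.
#' @param tol symmetry tolerance (default `1e-8`).
#' @return an [its2_dist].
#' @export
read_phylip_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) stop("file not found: ", path)
  tok <- scan(path, what = character(), quiet = TRUE)
  if (length(tok) < 1L) stop("empty PHYLIP file: ", path)
  n <- suppressWarnings(as.integer(tok[1L]))
  if (is.na(n) || n < 2L) stop("invalid taxon count in PHYLIP header")
  tok <- tok[-1L]
  n_full <- n * (n + 1L)           # n labels + n*n numbers
  n_lower <- n + n * (n - 1L) / 2L
  if (length(tok) == n_full) {
    lower <- FALSE
  } else if (length(tok) == n_lower) {
    lower <- TRUE
  } else {
    stop("token count ", length(tok), " matches neither full (", n_full,
         ") nor lower-triangular (", n_lower, ") dialect for n = ", n)
  }
  labels <- character(n)
  m <- matrix(0, n, n)
  pos <- 1L
  for (i in seq_len(n)) {
    labels[i] <- tok[pos]
    pos <- pos + 1L
    k <- if (lower) i - 1L else n
    if (k > 0L) {
      vals <- suppressWarnings(as.numeric(tok[pos:(pos + k - 1L)]))
      if (anyNA(vals)) stop("non-numeric distance in row ", labels[i])
      if (lower) m[i, seq_len(k)] <- vals else m[i, ] <- vals
      pos <- pos + k
    }
  }
  if (lower) m <- m + t(m)
  its2_dist(m, labels, tol = tol)
}

#' Write a square PHYLIP distance matrix
#'
#' @param d an [its2_dist].
#' @param path output path.
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(d, path, digits = 6) {
  stopifnot(inherits(d, "its2_dist"))
  n <- length(d$labels)
  rows <- vapply(seq_len(n), function(i) {
    paste(formatC(d$labels[i], width = -10),
          paste(formatC(d$values[i, ], format = "f", digits = digits),
                collapse = "  "))
  }, "")
  writeLines(c(as.character(n), rows), path)
  invisible(path)
}
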