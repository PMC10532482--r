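#' Pipeline configuration
#'
#' Collects every option of the integrated delimitation workflow. Inputs
#' may be file paths or in-memory objects. A YAML file with the same field
#' names can be loaded with [read_pipeline_config()]; explicit arguments
#' override file values.
#'
#' @param sequences unaligned sequences: path to FASTA or an [its2_seqs].
#' @param alignment the matching alignment: path to aligned FASTA or an
#'   [its2_msa].
#' @param structures optional pre-computed structures: path to a Vienna
#'   file or a list of [its2_structure] objects; when absent, sequences are
#'   folded with [fold_mfe()].
#' @param min_loop hairpin loop minimum for folding (default 3).
#' @param ab_model substitution model for the AB matrix (default `"F84"`).
#' @param tstv transition/transversion ratio setting (default 2.0).
#' @param cap optional saturation cap for AB distances.
#' @param af_metric structure distance (`"edit"` or `"bp"`).
#' @param square_first square distances before double-centering (default
#'   `FALSE`, matching the behaviour of the DistatisR call the original
#'   workflow prints, which centers the distance tables as given;
#'   `TRUE` gives the classical Torgerson convention).
#' @param n_factors_kept compromise factors kept for reporting (default 2).
#' @param minkowski_p Minkowski exponent for the compromise tree
#'   (default 2).
#' @param nboot bootstrap replicates for compromise-tree support
#'   (default 1000).
#' @param seed RNG seed, mandatory (drives the bootstrap).
#' @param outgroup outgroup id; `NULL` takes the flagged outgroup of the
#'   input, if any.
#' @param tree_interval ultrametric depth interval (default `c(0, 10)`).
#' @param gmyc_mode `"single"` or `"multiple"` (default `"multiple"`).
#' @param gmyc_df LRT degrees of freedom (default 3).
#' @param min_cluster_size minimum ML-cluster size (default 2).
#' @param cbc_scope `"intersection"` or `"consensus"`.
#' @param consensus_threshold consensus pair support threshold
#'   (default 0.5).
#' @param out_dir optional output directory for report files.
#' @return a `its2_config` list.
#' @export
pipeline_config <- function(sequences, alignment, structures = NULL,
                            min_loop = 3L, ab_model = "F84", tstv = 2.0,
                            cap = NULL, af_metric = "edit",
                            square_first = FALSE, n_factors_kept = 2L,
                            minkowski_p = 2, nboot = 1000L, seed = 1L,
                            outgroup = NULL, tree_interval = c(0, 10),
                            gmyc_mode = "multiple", gmyc_df = 3,
                            min_cluster_size = 2L,
                            cbc_scope = "intersection",
                            consensus_threshold = 0.5, out_dir = NULL) {
  cfg <- list(sequences = sequences, alignment = alignment,
              structures = structures, min_loop = min_loop,
              ab_model = ab_model, tstv = tstv, cap = cap,
              af_metric = af_metric, square_first = square_first,
              n_factors_kept = n_factors_kept, minkowski_p = minkowski_p,
              nboot = as.integer(nboot), seed = as.integer(seed),
              outgroup = outgroup, tree_interval = tree_interval,
              gmyc_mode = gmyc_mode, gmyc_df = gmyc_df,
              min_cluster_size = min_cluster_size, cbc_scope = cbc_scope,
              consensus_threshold = consensus_threshold, out_dir = out_dir)
  for (f in c("sequences", "alignment", "structures")) {
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1L && !file.exists(v)) {
      stop("config file does not exist: ", f, " = ", v)
    }
  }
  if (is.na(cfg$seed)) stop("a seed is mandatory")
  class(cfg) <- "its2_config"
  cfg
}

#' Load pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @param ... overrides passed on to [pipeline_config()].
#' @return a `its2_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_stage <- function(verbose, ...) {
  if (verbose) message(sprintf("[its2delimit] %s", sprintf(...)))
}

#' Run the integrated delimitation pipeline
#'
#' Executes the full workflow: fold (or load) secondary structures, build
#' the alignment-free (AF) and alignment-based (AB) distance matrices, fuse
#' them with DISTATIS, build three trees (AB neighbor-joining, AF
#' neighbor-joining, compromise single-linkage with bootstrap support), run
#' GMYC on each tree after ultrametric conversion (outgroup excluded from
#' delimitation), and compute the CBC table, CBC partition and consensus
#' structures per delimited cluster. Fully deterministic given the seed.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log one line per stage (default `FALSE`).
#' @return an object of class `its2_report`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "its2_config"))
  seqs <- stage("input", {
    if (inherits(cfg$sequences, "its2_seqs")) cfg$sequences
    else read_fasta(cfg$sequences)
  })
  msa <- stage("input", {
    if (inherits(cfg$alignment, "its2_msa")) cfg$alignment
    else read_alignment(cfg$alignment)
  })
  stage("input", {
    if (!identical(sort(msa$seqs$id), sort(seqs$id))) {
      stop("alignment and sequence ids differ")
    }
    ungapped <- gsub("-", "", msa$seqs$residues, fixed = TRUE)
    bad <- msa$seqs$id[ungapped[match(seqs$id, msa$seqs$id)] != seqs$residues]
    if (length(bad) > 0L) {
      stop("alignment rows do not match sequences: ",
           paste(bad, collapse = ", "))
    }
  })
  log_stage(verbose, "input: %d sequences, %d alignment columns",
            length(seqs$id), msa$n_columns)
  outgroup <- cfg$outgroup
  if (is.null(outgroup) && any(seqs$outgroup)) {
    outgroup <- seqs$id[seqs$outgroup][1L]
  }
  structures <- stage("fold", {
    if (is.null(cfg$structures)) {
      fold_mfe(seqs, fold_params(cfg$min_loop))
    } else if (is.character(cfg$structures)) {
      read_vienna(cfg$structures)$structures
    } else cfg$structures
  })
  log_stage(verbose, "fold: %d structures", length(structures))
  af <- stage("af_matrix", af_matrix(structures, metric = cfg$af_metric))
  ab <- stage("ab_matrix", ab_matrix(msa, model = cfg$ab_model,
                                     tstv = cfg$tstv, cap = cfg$cap))
  log_stage(verbose, "distances: AB range [%.4g, %.4g], AF range [%g, %g]",
            min(ab$values[upper.tri(ab$values)]), max(ab$values),
            min(af$values[upper.tri(af$values)]), max(af$values))
  comp <- stage("distatis", distatis(list(AB = ab, AF = af),
                                     square_first = cfg$square_first,
                                     n_factors_kept = cfg$n_factors_kept))
  log_stage(verbose, "distatis: alpha = %s",
            paste(round(comp$alpha, 3), collapse = "/"))
  ab_tree <- stage("trees", neighbor_joining(ab))
  af_tree <- stage("trees", neighbor_joining(af))
  comp_tree <- stage("trees", bootstrap_support(
    comp$compromise_distance$values, n_boot = cfg$nboot, seed = cfg$seed,
    minkowski_p = cfg$minkowski_p))
  trees <- list(AB = ab_tree, AF = af_tree, compromise = comp_tree)
  ultra <- stage("ultrametric", lapply(trees, make_ultrametric,
                                       interval = cfg$tree_interval,
                                       outgroup = outgroup))
  gmyc_in <- lapply(ultra, function(t) {
    if (!is.null(outgroup) && outgroup %in% t$tip.label) {
      ape::drop.tip(t, outgroup)
    } else t
  })
  gmyc_fits <- stage("gmyc", lapply(gmyc_in, gmyc, mode = cfg$gmyc_mode,
                                    min_cluster_size = cfg$min_cluster_size,
                                    df = cfg$gmyc_df))
  log_stage(verbose, "gmyc: ML clusters %s",
            paste(vapply(gmyc_fits, `[[`, 0L, "n_ml_clusters"),
                  collapse = "/"))
  sa <- stage("cbc", project_structures(msa, structures))
  cbc <- stage("cbc", cbc_matrix(sa, pair_scope = cfg$cbc_scope))
  cbc_partition <- delimit_by_cbc(cbc)
  consensus_all <- stage("consensus", consensus_structure(
    sa, threshold = cfg$consensus_threshold))
  cluster_consensus <- stage("consensus", {
    part <- gmyc_fits$compromise$clusters
    part <- part[lengths(part) >= cfg$min_cluster_size]
    lapply(part, function(ids) {
      keep <- match(ids, msa$seqs$id)
      sub <- its2_msa(subset_seqs(msa$seqs, keep))
      consensus_structure(project_structures(sub, structures[keep]),
                          threshold = cfg$consensus_threshold)
    })
  })
  report <- list(config = cfg,
                 sequences = seqs,
                 ab_matrix = ab, af_matrix = af,
                 distatis = comp,
                 trees = trees, ultrametric = ultra,
                 gmyc = gmyc_fits,
                 cbc = cbc, cbc_partition = cbc_partition,
                 consensus = consensus_all,
                 cluster_consensus = cluster_consensus,
                 outgroup = outgroup)
  class(report) <- "its2_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.its2_report <- function(x, ...) {
  cat("Integrated ITS2 delimitation report\n")
  cat("  taxa:", length(x$sequences$id), "\n")
  cat("  DISTATIS alpha:", paste(round(x$distatis$alpha, 3),
                                 collapse = ", "), "\n")
  print(compare_trees(x))
  cat("  CBC-zero groups:", length(x$cbc$partition), "\n")
  invisible(x)
}

#' Per-tree GMYC comparison table
#'
#' One row per tree: method label, likelihood-ratio p-value, and the
#' number of ML clusters.
#'
#' @param report an `its2_report`.
#' @return a data.frame with columns `tree`, `lr_p_value`,
#'   `n_ml_clusters`.
#' @export
compare_trees <- function(report) {
  stopifnot(inherits(report, "its2_report"))
  fits <- report$gmyc
  if (length(fits) < 2L) stop("report holds fewer than 2 GMYC fits")
  data.frame(tree = names(fits),
             lr_p_value = vapply(fits, `[[`, 0, "p_value"),
             n_ml_clusters = vapply(fits, `[[`, 0L, "n_ml_clusters"),
             row.names = NULL)
}

#' Write report files
#'
#' Emits the distance matrices (PHYLIP), the three trees (Newick), the
#' structures (Vienna), the CBC matrices (TSV) and a JSON summary.
#'
#' @param report an `its2_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phylip_matrix(report$ab_matrix, file.path(dir, "ab.phylip"))
  write_phylip_matrix(report$af_matrix, file.path(dir, "af.phylip"))
  write_phylip_matrix(report$distatis$compromise_distance,
                      file.path(dir, "compromise.phylip"))
  for (nm in names(report$trees)) {
    writeLines(to_newick(report$trees[[nm]]),
               file.path(dir, paste0("tree_", nm, ".nwk")))
  }
  utils::write.table(report$cbc$cbc_counts,
                     file.path(dir, "cbc_counts.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(report$cbc$hcbc_counts,
                     file.path(dir, "hemi_cbc_counts.tsv"),
                     sep = "\t", quote = FALSE)
  jsonlite::write_json(report_summary(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' JSON-ready summary of a report
#'
#' A plain-list summary (weights, RV matrix, GMYC statistics, cluster
#' memberships, CBC partition, consensus typing) that serializes to JSON
#' and reloads losslessly.
#'
#' @param report an `its2_report`.
#' @return a nested list of plain values.
#' @export
report_summary <- function(report) {
  g <- lapply(report$gmyc, function(f) {
    list(mode = f$mode, null_loglik = f$null_loglik,
         best_loglik = f$best_loglik, lr_stat = f$lr_stat,
         p_value = f$p_value, n_ml_clusters = f$n_ml_clusters,
         n_entities = f$n_entities, thresholds = f$thresholds,
         rates = as.list(f$rates), clusters = f$clusters)
  })
  list(seed = report$config$seed,
       n_taxa = length(report$sequences$id),
       alpha = as.numeric(report$distatis$alpha),
       rv = report$distatis$rv_matrix[1L, 2L],
       gmyc = g,
       cbc_partition = report$cbc$partition,
       consensus_type = report$consensus$type_label,
       cluster_consensus_types = lapply(report$cluster_consensus,
                                        `[[`, "type_label"))
}
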