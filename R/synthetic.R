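with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Helix-layout specification for synthetic ITS2-like families
#'
#' Describes a multi-helix scaffold over a fixed sequence length: a leading
#' linker, then helices (paired stem, hairpin loop, closing stem) separated
#' by linkers. When two clades are generated, clade 1 uses the first
#' `n_helices[1]` helices and clade 2 all `max(n_helices)`; the extra
#' helices of the larger scaffold occupy regions that are unpaired in the
#' smaller one, so the leading helices are positionally homologous across
#' clades (the conserved scaffold where planted CBCs live).
#'
#' @param length total sequence length (default 260, mid-range ITS2).
#' @param n_helices helices per clade (scalar, or length-2 vector).
#' @param linker unpaired spacer length between helices (default 8).
#' @param lead unpaired leading segment length (default 10).
#' @return an object of class `its2_scaffold`.
#' @export
scaffold_spec <- function(length = 260L, n_helices = c(4L, 6L),
                          linker = 8L, lead = 10L) {
  nh <- max(n_helices)
  budget <- length - lead - nh * linker
  if (budget < nh * 11L) stop("scaffold length too small for ", nh, " helices")
  per <- budget %/% nh
  loop <- max(4L, per %/% 6L)
  stem <- (per - loop) %/% 2L
  helices <- vector("list", nh)
  pos <- lead + 1L
  for (h in seq_len(nh)) {
    left <- pos:(pos + stem - 1L)
    loop_idx <- (pos + stem):(pos + stem + loop - 1L)
    right <- (pos + stem + loop):(pos + 2L * stem + loop - 1L)
    helices[[h]] <- list(left = left, loop = loop_idx, right = right)
    pos <- pos + 2L * stem + loop + linker
  }
  out <- list(length = length, n_helices = n_helices, stem = stem,
              loop = loop, helices = helices)
  class(out) <- "its2_scaffold"
  out
}

scaffold_pairs <- function(scaffold, n_hel) {
  do.call(rbind, lapply(scaffold$helices[seq_len(n_hel)], function(h) {
    cbind(h$left, rev(h$right))
  }))
}

scaffold_dotbracket <- function(scaffold, n_hel) {
  render_dotbracket(scaffold_pairs(scaffold, n_hel), scaffold$length)
}

PAIR_SWAP <- c(GC = "AU", CG = "UA", AU = "GC", UA = "CG")
HEMI_STEP <- list(GC = c("G", "U"), CG = c("U", "G"),
                  AU = c("G", "U"), UA = c("U", "G"))

mutate_sites <- function(seq_chars, idx, prob) {
  hit <- idx[stats::runif(length(idx)) < prob]
  for (i in hit) {
    seq_chars[i] <- sample(setdiff(c("A", "C", "G", "U"), seq_chars[i]), 1L)
  }
  seq_chars
}

# Evolve loop-site variation down a genealogy; returns one character matrix
# row per tip. Paired-site events (at most one single-side
# canonical-preserving change per designated stem pair) are placed on a
# random edge so they are shared by a clade of tips — hemi-CBC-type
# variation only, which keeps within-species CBC counts at zero.
evolve_within <- function(anc_chars, genealogy, free_idx, within_div,
                          hemi_pairs) {
  k <- ape::Ntip(genealogy)
  depth <- max(ape::branching.times(genealogy))
  g <- genealogy
  g$edge.length <- g$edge.length / depth
  n_nodes <- k + g$Nnode
  seqs <- vector("list", n_nodes)
  root <- k + 1L
  seqs[[root]] <- anc_chars
  hemi_edge <- if (NROW(hemi_pairs) > 0L) {
    sample.int(nrow(g$edge), nrow(hemi_pairs), replace = TRUE)
  } else integer(0)
  pre <- ape::reorder.phylo(g, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]
    c2 <- pre$edge[e, 2L]
    el <- pre$edge.length[e]
    s <- mutate_sites(seqs[[p]], free_idx, within_div * el)
    hit <- which(hemi_edge == e)
    for (hp in hit) {
      i <- hemi_pairs[hp, 1L]
      j <- hemi_pairs[hp, 2L]
      key <- paste0(s[i], s[j])
      if (key %in% names(HEMI_STEP)) {
        s[c(i, j)] <- HEMI_STEP[[key]]
      }
    }
    seqs[[c2]] <- s
  }
  do.call(rbind, seqs[seq_len(k)])
}

#' Generate a synthetic ITS2-like family with planted CBCs
#'
#' Builds a shared multi-helix scaffold, evolves species from it (loop and
#' linker sites drift under a Jukes-Cantor-type process; clade-specific
#' helices differ between clades), plants species-diagnostic compensatory
#' double substitutions (full canonical pair swaps) at dedicated stem
#' positions of the conserved helices, and adds within-species variation
#' along a coalescent genealogy with at most one single-side
#' canonical-preserving stem change per pair per species, so within-species
#' CBC counts are exactly zero while every species pair is separated by at
#' least `2 * n_planted_cbcs` CBCs.
#'
#' @param n_species number of species (>= 1).
#' @param seqs_per_species tips per species (scalar or vector).
#' @param scaffold an [scaffold_spec()].
#' @param within_div expected within-species substitutions per free site
#'   (default 0.01).
#' @param between_div per-branch substitution probability at free sites for
#'   clade and species branches (default 0.10).
#' @param n_planted_cbcs planted CBC pairs per species (default 2).
#' @param seed RNG seed (mandatory; regeneration is bit-identical).
#' @param clades clade assignment per species (1-based; default all 1).
#' @param outgroup append a divergent outgroup sequence (default `FALSE`).
#' @return an object of class `its2_family` with fields `sequences`,
#'   `msa` (the gap-free true alignment), `true_partition`,
#'   `true_structures`, `planted_cbcs`, `params`.
#' @export
generate_family <- function(n_species, seqs_per_species,
                            scaffold = scaffold_spec(),
                            within_div = 0.01, between_div = 0.10,
                            n_planted_cbcs = 2L, seed = 1L,
                            clades = NULL, outgroup = FALSE) {
  if (n_species < 1L || any(seqs_per_species < 1L)) {
    stop("all counts must be >= 1")
  }
  if (within_div < 0 || within_div > 0.2 || between_div < 0 ||
      between_div > 0.2) {
    stop("divergence rates must lie in [0, 0.2]")
  }
  sizes <- rep_len(seqs_per_species, n_species)
  if (is.null(clades)) clades <- rep(1L, n_species)
  clades <- rep_len(clades, n_species)
  n_shared <- min(scaffold$n_helices)
  shared_pairs <- scaffold_pairs(scaffold, n_shared)
  need <- n_species * n_planted_cbcs + if (outgroup) 6L else 0L
  if (nrow(shared_pairs) < need + 2L) {
    stop("scaffold too small for the requested planted CBCs (need ", need,
         " stem pairs, have ", nrow(shared_pairs), ")")
  }
  with_seed(seed, {
    L <- scaffold$length
    all_pairs <- scaffold_pairs(scaffold, max(scaffold$n_helices))
    paired_all <- c(all_pairs)
    template <- character(L)
    template[setdiff(seq_len(L), paired_all)] <-
      sample(c("A", "C", "G", "U"), L - length(paired_all), replace = TRUE)
    stem_types <- sample(c("GC", "CG", "AU", "UA"), nrow(all_pairs),
                         replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
    for (r in seq_len(nrow(all_pairs))) {
      template[all_pairs[r, 1L]] <- substr(stem_types[r], 1L, 1L)
      template[all_pairs[r, 2L]] <- substr(stem_types[r], 2L, 2L)
    }
    # dedicate disjoint shared-helix stem pairs to species barcodes (and
    # the outgroup), keeping them away from all drift
    barcode_rows <- sample.int(nrow(shared_pairs), need)
    barcode_by_species <- split(barcode_rows[seq_len(n_species *
                                                       n_planted_cbcs)],
                                rep(seq_len(n_species),
                                    each = n_planted_cbcs))
    og_rows <- if (outgroup) {
      barcode_rows[seq.int(n_species * n_planted_cbcs + 1L, need)]
    } else integer(0)
    free_by_clade <- lapply(sort(unique(clades)), function(cl) {
      nh <- scaffold$n_helices[min(cl, length(scaffold$n_helices))]
      setdiff(seq_len(L), c(scaffold_pairs(scaffold, nh)))
    })
    # clade ancestors drift at their own free sites
    clade_anc <- lapply(seq_along(free_by_clade), function(ci) {
      mutate_sites(template, free_by_clade[[ci]], between_div)
    })
    ids <- character(0)
    species <- character(0)
    rows <- NULL
    structs <- list()
    planted <- NULL
    partition <- list()
    for (s in seq_len(n_species)) {
      cl <- clades[s]
      nh <- scaffold$n_helices[min(cl, length(scaffold$n_helices))]
      free_idx <- free_by_clade[[match(cl, sort(unique(clades)))]]
      anc <- mutate_sites(clade_anc[[match(cl, sort(unique(clades)))]],
                          free_idx, between_div)
      for (r in barcode_by_species[[s]]) {
        i <- shared_pairs[r, 1L]
        j <- shared_pairs[r, 2L]
        key <- paste0(template[i], template[j])
        swap <- PAIR_SWAP[[key]]
        planted <- rbind(planted,
                         data.frame(species = paste0("sp", s), i = i, j = j,
                                    from = key, to = swap))
        anc[i] <- substr(swap, 1L, 1L)
        anc[j] <- substr(swap, 2L, 2L)
      }
      k <- sizes[s]
      sp_pairs <- scaffold_pairs(scaffold, nh)
      bar_cols <- shared_pairs[unlist(barcode_by_species), 1L]
      if (length(og_rows) > 0L) {
        bar_cols <- c(bar_cols, shared_pairs[og_rows, 1L])
      }
      hemi_cand <- which(!sp_pairs[, 1L] %in% bar_cols)
      n_hemi <- min(length(hemi_cand), stats::rbinom(1L, nrow(sp_pairs),
                                                     within_div))
      hemi_pairs <- sp_pairs[hemi_cand[sample.int(length(hemi_cand),
                                                  n_hemi)], , drop = FALSE]
      sp_ids <- sprintf("sp%d_%02d", s, seq_len(k))
      if (k == 1L) {
        mrows <- matrix(mutate_sites(anc, free_idx, within_div), nrow = 1L)
      } else {
        genealogy <- ape::rcoal(k)
        mrows <- evolve_within(anc, genealogy, free_idx, within_div,
                               hemi_pairs)
      }
      db <- scaffold_dotbracket(scaffold, nh)
      for (r in seq_len(k)) {
        ids <- c(ids, sp_ids[r])
        species <- c(species, paste0("sp", s))
        rows <- rbind(rows, mrows[r, ])
        structs[[length(structs) + 1L]] <-
          its2_structure(sp_ids[r], db,
                         seq = paste(mrows[r, ], collapse = ""))
      }
      partition[[paste0("sp", s)]] <- sp_ids
    }
    og_flag <- rep(FALSE, length(ids))
    if (outgroup) {
      og <- mutate_sites(template, free_by_clade[[1L]], 0.2)
      og <- mutate_sites(og, free_by_clade[[1L]], 0.2)
      for (r in og_rows) {
        i <- shared_pairs[r, 1L]
        j <- shared_pairs[r, 2L]
        swap <- PAIR_SWAP[[paste0(template[i], template[j])]]
        og[i] <- substr(swap, 1L, 1L)
        og[j] <- substr(swap, 2L, 2L)
      }
      ids <- c(ids, "outgroup")
      species <- c(species, "outgroup")
      rows <- rbind(rows, og)
      og_flag <- c(og_flag, TRUE)
      structs[[length(structs) + 1L]] <-
        its2_structure("outgroup",
                       scaffold_dotbracket(scaffold, n_shared),
                       seq = paste(og, collapse = ""))
      partition[["outgroup"]] <- "outgroup"
    }
    seqs <- its2_seqs(ids, apply(rows, 1L, paste, collapse = ""),
                      species = species, outgroup = og_flag)
    fam <- list(sequences = seqs,
                msa = its2_msa(seqs),
                true_partition = partition,
                true_structures = structs,
                planted_cbcs = planted,
                params = list(n_species = n_species, sizes = sizes,
                              scaffold = scaffold, within_div = within_div,
                              between_div = between_div,
                              n_planted_cbcs = n_planted_cbcs, seed = seed,
                              clades = clades, outgroup = outgroup))
    class(fam) <- "its2_family"
    fam
  })
}

#' @export
print.its2_family <- function(x, ...) {
  cat("Synthetic ITS2-like family:", length(x$sequences$id), "sequences,",
      x$params$n_species, "species,",
      nrow(x$planted_cbcs), "planted CBC events\n")
  invisible(x)
}

#' The default Tulasnella-like synthetic family
#'
#' 142 ingroup sequences in 7 species across 2 clades (3 species with the
#' 4-helix scaffold, 4 with the 6-helix scaffold) plus one divergent
#' outgroup; fixed seed, 2 planted CBC pairs per species.
#'
#' The 400 nt scaffold reflects the long, highly divergent ribosomal
#' region of this genus; the within-species rate is set so the largest
#' intraspecific divergence stays roughly twenty-fold below the smallest
#' interspecific divergence, the same deep/shallow separation used in the
#' delimitation simulations.
#'
#' @param seed RNG seed (default 42).
#' @return an `its2_family` with 143 sequences.
#' @export
default_tulasnella_like <- function(seed = 42L) {
  generate_family(n_species = 7L,
                  seqs_per_species = c(24L, 22L, 18L, 22L, 20L, 20L, 16L),
                  scaffold = scaffold_spec(400L, c(4L, 6L)),
                  within_div = 0.007, between_div = 0.10,
                  n_planted_cbcs = 2L, seed = seed,
                  clades = c(1L, 1L, 1L, 2L, 2L, 2L, 2L),
                  outgroup = TRUE)
}

#' Simulate an ultrametric tree with known species clusters
#'
#' A coalescent-shaped species backbone rescaled so its shallowest
#' divergence sits at `species_depth`, with per-species coalescent
#' genealogies (root depth uniform in `[coal_depth/2, coal_depth]`) grafted
#' onto the species tips. The deep/shallow separation is therefore at
#' least `species_depth / coal_depth`.
#'
#' @param n_species number of species (>= 2).
#' @param tips_per_species tips per species (scalar or vector; 1 allowed).
#' @param species_depth age of the shallowest species divergence
#'   (default 10).
#' @param coal_depth maximum within-species genealogy depth (default 0.5).
#' @param seed RNG seed.
#' @return list with `tree` (ultrametric `phylo`) and `partition`
#'   (true species blocks, tip labels).
#' @export
simulate_delimitation_tree <- function(n_species, tips_per_species,
                                       species_depth = 10,
                                       coal_depth = 0.5, seed = 1L) {
  stopifnot(n_species >= 2L)
  sizes <- rep_len(tips_per_species, n_species)
  with_seed(seed, {
    backbone <- ape::rcoal(n_species,
                           tip.label = paste0("sp", seq_len(n_species)))
    bt <- ape::branching.times(backbone)
    backbone$edge.length <- backbone$edge.length * species_depth / min(bt)
    partition <- list()
    tree <- backbone
    for (s in seq_len(n_species)) {
      labs <- paste0("sp", s, "_", seq_len(sizes[s]))
      partition[[paste0("sp", s)]] <- labs
      if (sizes[s] == 1L) {
        tree$tip.label[tree$tip.label == paste0("sp", s)] <- labs
        next
      }
      g <- ape::rcoal(sizes[s], tip.label = labs)
      h <- stats::runif(1L, coal_depth / 2, coal_depth)
      g$edge.length <- g$edge.length * h / max(ape::branching.times(g))
      tip <- which(tree$tip.label == paste0("sp", s))
      edge <- which(tree$edge[, 2L] == tip)
      tree$edge.length[edge] <- tree$edge.length[edge] - h
      tree <- ape::bind.tree(tree, g, where = which(tree$tip.label ==
                                                      paste0("sp", s)))
    }
    list(tree = tree, partition = partition)
  })
}
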