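#' Branching times of an ultrametric tree
#'
#' Internal-node ages sorted in descending order (root first); length is
#' the number of tips minus one.
#'
#' @param t rooted ultrametric `phylo` tree.
#' @param tol ultrametricity tolerance (default `1e-6`).
#' @return numeric vector of node ages, descending.
#' @export
branching_times <- function(t, tol = 1e-6) {
  stopifnot(inherits(t, "phylo"))
  if (ape::Ntip(t) < 2L) stop("need at least 2 tips")
  if (!ape::is.rooted(t)) stop("tree must be rooted")
  if (!ape::is.ultrametric(t, tol = tol)) {
    stop("tree is not ultrametric within tolerance ", tol)
  }
  sort(unname(ape::branching.times(t)), decreasing = TRUE)
}

# ---- internal machinery ----------------------------------------------------

# Node ages (height above the leaves) indexed by node number; robust to
# node labels (unlike branching.times, whose names follow labels).
node_ages <- function(t) {
  depth <- ape::node.depth.edgelength(t)
  ages <- max(depth[seq_len(ape::Ntip(t))]) - depth
  ages[seq_len(ape::Ntip(t))] <- 0
  ages
}

# Collapse clades of effectively identical tips (all branching within
# tol * root age of the present) to a single representative tip, returning
# the pruned tree and the representative -> members map. Zero-height
# branchings carry no waiting-time information and would otherwise create
# an artificial instantaneous-coalescence regime.
collapse_identical_tips <- function(t, tol = 1e-8) {
  n <- ape::Ntip(t)
  ages <- node_ages(t)
  cut <- tol * max(ages)
  zero_nodes <- which(ages <= cut)
  zero_nodes <- zero_nodes[zero_nodes > n]
  groups <- list()
  if (length(zero_nodes) > 0L) {
    pa <- rep(NA_integer_, n + t$Nnode)
    pa[t$edge[, 2L]] <- t$edge[, 1L]
    maximal <- zero_nodes[!pa[zero_nodes] %in% zero_nodes]
    drop <- character(0)
    for (nd in maximal) {
      tips <- ape::extract.clade(t, nd)$tip.label
      tips <- tips[order(match(tips, t$tip.label))]
      groups[[tips[1L]]] <- tips
      drop <- c(drop, tips[-1L])
    }
    if (length(drop) > 0L) t <- ape::drop.tip(t, drop)
  }
  list(tree = t, groups = groups)
}

# Precompute everything about the tree that candidate models share.
gmyc_prep <- function(t, tol = 1e-6) {
  if (ape::Ntip(t) < 3L) stop("GMYC needs at least 3 tips")
  if (!ape::is.rooted(t)) stop("tree must be rooted")
  if (!ape::is.binary(t)) t <- ape::multi2di(t)
  if (!ape::is.ultrametric(t, tol = tol)) {
    stop("tree is not ultrametric within tolerance ", tol)
  }
  n <- ape::Ntip(t)
  m <- t$Nnode
  ages <- node_ages(t)
  # tied or zero-height branchings (identical sequences) would give
  # zero-length waiting intervals; stagger ages upward in postorder so
  # every parent is strictly older than its children (deterministic
  # tie-break; the perturbation is a vanishing fraction of the root age)
  post_nodes <- unique(ape::reorder.phylo(t, "postorder")$edge[, 1L])
  eps <- 1e-6 * max(ages)
  kids_of <- split(t$edge[, 2L], t$edge[, 1L])
  for (nd in post_nodes) {
    ch <- kids_of[[as.character(nd)]]
    ages[nd] <- max(ages[nd], max(ages[ch]) + eps)
  }
  # events: internal nodes by age descending (root first); ties by node id
  ev_nodes <- (n + 1L):(n + m)
  ev_nodes <- ev_nodes[order(-ages[ev_nodes], ev_nodes)]
  ev_ages <- ages[ev_nodes]
  bounds <- c(ev_ages, 0)
  x <- ev_ages - bounds[-1L]               # interval lengths, 1..m
  mids <- (ev_ages + bounds[-1L]) / 2
  parent <- t$edge[, 1L]
  child <- t$edge[, 2L]
  # crossing[i, e]: edge e spans interval i
  crossing <- outer(mids, ages[child], `>`) & outer(mids, ages[parent], `<`)
  # tip sets per node
  tipsets <- vector("list", n + m)
  for (i in seq_len(n)) tipsets[[i]] <- i
  post <- ape::reorder.phylo(t, "postorder")
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]
    c2 <- post$edge[e, 2L]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[c2]])
  }
  # children lists and preorder
  pre <- rev(seq_len(nrow(post$edge)))
  list(tree = t, n = n, m = m, ages = ages,
       ev_nodes = ev_nodes, ev_ages = ev_ages, x = x,
       parent = parent, child = child, crossing = crossing,
       tipsets = tipsets, preorder_edges = post$edge[pre, , drop = FALSE],
       ev_index = stats::setNames(seq_len(m), ev_nodes))
}

# Classify edges and build interval statistics for a candidate model.
# s_nodes: logical over node ids (length n+m), TRUE = divergence node.
gmyc_stats <- function(prep, s_nodes) {
  n <- prep$n
  m <- prep$m
  root <- n + 1L
  # entity (cluster) id per node: 0 while inside the species tree
  entity <- integer(n + m)
  entity[root] <- if (s_nodes[root]) 0L else root
  for (e in seq_len(nrow(prep$preorder_edges))) {
    p <- prep$preorder_edges[e, 1L]
    c2 <- prep$preorder_edges[e, 2L]
    if (entity[p] != 0L) entity[c2] <- entity[p]
    else entity[c2] <- if (c2 > n && s_nodes[c2]) 0L else c2
  }
  sp_edge <- s_nodes[prep$parent]
  n_div <- as.numeric(prep$crossing[, sp_edge, drop = FALSE] %*%
                        rep(1, sum(sp_edge)))
  # cluster lineage counts per interval
  cl <- which(!sp_edge)
  ent_ids <- sort(unique(entity[prep$parent[cl]]))
  if (length(cl) > 0L) {
    z <- matrix(0, length(cl), length(ent_ids))
    z[cbind(seq_along(cl), match(entity[prep$parent[cl]], ent_ids))] <- 1
    counts <- prep$crossing[, cl, drop = FALSE] %*% z   # m x n_entities
  } else {
    counts <- matrix(0, m, 0L)
  }
  # events (non-root), classified for reporting
  ev_div <- s_nodes[prep$ev_nodes] & prep$ev_nodes != root
  ev_coal <- !s_nodes[prep$ev_nodes] & prep$ev_nodes != root
  nn <- counts * (counts - 1)
  keep <- nn > 0
  nn_vals <- nn[keep]
  nn_idx <- row(nn)[keep]
  b_sum <- function(p) {
    v <- numeric(m)
    if (length(nn_vals) > 0L) {
      agg <- rowsum(nn_vals^p, nn_idx)
      v[as.integer(rownames(agg))] <- agg[, 1L]
    }
    v
  }
  list(x = prep$x,
       a_base = n_div,
       b_sum = b_sum,
       coal_keep = keep,
       e_div = sum(ev_div), e_coal = sum(ev_coal),
       entity_roots = setdiff(unique(entity[entity != 0L]), 0L),
       entity = entity)
}

# Joint branching-rate log-likelihood. In every inter-event interval both
# processes compete: the diversification process over the species lineages
# (rate lambda_div * N^p_div) and the within-cluster coalescents (summed
# rate lambda_coal * sum_j (n_j (n_j - 1))^p_coal). A species lineage runs
# from its parent divergence node down to the MRCA of its cluster, so the
# first coalescence of every cluster draws its event rate from the total
# rate active just above it; every interval ending in an event contributes
# ln(total rate) - (total rate) * x, and the final tipward interval
# contributes its survival term only.
gmyc_loglik <- function(st, lambda_div, lambda_coal, p_div, p_coal) {
  r <- lambda_div * st$a_base^p_div * (st$a_base > 0) +
    lambda_coal * st$b_sum(p_coal)
  m <- length(st$x)
  ev <- seq_len(m - 1L)                 # intervals ending in an event
  if (any(r[ev] <= 0)) return(-Inf)
  sum(log(r[ev])) - sum(r * st$x)
}

gmyc_optimize <- function(st, p_bounds = c(0.1, 5), start = NULL) {
  has_div <- any(st$a_base > 0)
  has_coal <- any(st$coal_keep)
  m <- length(st$x)
  # moment-style initial rates: events per unit of scaled branch length
  init_rate <- function(bsum) {
    tot <- sum(bsum * st$x)
    if (tot <= 0) return(0)
    max((m - 1L) / tot, 1e-8)
  }
  fn <- function(q) {
    v <- gmyc_loglik(st, if (has_div) exp(q[["ld"]]) else 0,
                     if (has_coal) exp(q[["lc"]]) else 0,
                     q[["pd"]], q[["pc"]])
    if (!is.finite(v)) return(1e10)
    -v
  }
  p0 <- if (is.null(start)) c(1, 1) else {
    pmin(pmax(start, p_bounds[1L]), p_bounds[2L])
  }
  q0 <- c(ld = log(max(init_rate(st$a_base^p0[1L] * (st$a_base > 0)), 1e-8)),
          lc = log(max(init_rate(st$b_sum(p0[2L])), 1e-8)),
          pd = p0[1L], pc = p0[2L])
  lower <- c(ld = -30, lc = -30, pd = p_bounds[1L], pc = p_bounds[2L])
  upper <- c(ld = 30, lc = 30, pd = p_bounds[2L], pc = p_bounds[2L])
  lower[["pc"]] <- p_bounds[1L]
  free <- c(has_div, has_coal, has_div, has_coal)
  names(free) <- c("ld", "lc", "pd", "pc")
  sel <- names(free)[free]
  if (length(sel) == 0L) {
    return(list(lambda_div = 0, lambda_coal = 0, p_div = 1, p_coal = 1,
                loglik = 0))
  }
  fn_sel <- function(qs) {
    q <- q0
    q[sel] <- qs
    fn(q)
  }
  o <- tryCatch(
    stats::optim(q0[sel], fn_sel, method = "L-BFGS-B",
                 lower = lower[sel], upper = upper[sel],
                 control = list(maxit = 200)),
    error = function(e) list(par = q0[sel], value = fn_sel(q0[sel]),
                             convergence = 99L))
  if (o$convergence > 1L) {
    # L-BFGS-B can abort its line search on cliff-shaped surfaces; refine
    # with a bounded (clamped) Nelder-Mead pass from the best point so far
    fn_clamped <- function(qs) fn_sel(pmin(pmax(qs, lower[sel]), upper[sel]))
    o2 <- stats::optim(o$par, fn_clamped, method = "Nelder-Mead",
                       control = list(maxit = 500))
    o2$par <- pmin(pmax(o2$par, lower[sel]), upper[sel])
    if (o2$value <= o$value) o <- o2
    if (!is.finite(o$value) || o$value >= 1e10) {
      stop("rate optimization failed to converge")
    }
  }
  q <- q0
  q[sel] <- o$par
  list(lambda_div = if (has_div) exp(q[["ld"]]) else 0,
       lambda_coal = if (has_coal) exp(q[["lc"]]) else 0,
       p_div = q[["pd"]], p_coal = q[["pc"]],
       loglik = -o$value)
}

# Minimal number of distinct threshold times that can generate the
# delimitation (half-open interval piercing on entity boundary edges).
n_thresholds <- function(prep, s_nodes, st) {
  roots <- st$entity_roots
  root <- prep$n + 1L
  roots <- roots[roots != root]
  if (length(roots) == 0L) return(0L)
  par <- prep$parent[match(roots, prep$child)]
  lo <- prep$ages[roots]
  hi <- prep$ages[par]
  ord <- order(hi)
  lo <- lo[ord]
  hi <- hi[ord]
  t_count <- 1L
  cur <- hi[1L]
  for (i in seq_along(hi)[-1L]) {
    if (!(lo[i] < cur)) {
      t_count <- t_count + 1L
      cur <- hi[i]
    }
  }
  t_count
}

gmyc_model_fit <- function(prep, s_nodes, p_bounds, start = NULL) {
  st <- gmyc_stats(prep, s_nodes)
  opt <- gmyc_optimize(st, p_bounds, start)
  t_count <- n_thresholds(prep, s_nodes, st)
  has_div <- any(st$a_base > 0)
  has_coal <- any(st$coal_keep)
  k_par <- 2L * has_div + 2L * has_coal + t_count
  list(s_nodes = s_nodes, stats = st,
       lambda_div = opt$lambda_div, lambda_coal = opt$lambda_coal,
       p_div = opt$p_div, p_coal = opt$p_coal, loglik = opt$loglik,
       k = k_par, aic = 2 * k_par - 2 * opt$loglik, n_thresholds = t_count)
}

gmyc_partition <- function(prep, st) {
  labs <- prep$tree$tip.label
  roots <- st$entity_roots
  out <- lapply(roots, function(r) labs[prep$tipsets[[r]]])
  names(out) <- paste0("entity", seq_along(out))
  out
}

# ---- user-facing fits ------------------------------------------------------

#' GMYC species delimitation on an ultrametric tree
#'
#' Fits the generalized mixed Yule-coalescent model: branching events older
#' than a threshold belong to a diversification (Yule-type) process with
#' per-interval rate `lambda_div * n^p_div`; younger events belong to
#' within-cluster coalescent processes with rate
#' `lambda_coal * (n (n - 1))^p_coal` summed over clusters. Each
#' inter-event interval contributes `ln(total rate) - total rate * x` to
#' the log-likelihood (the two processes compete for every event); rates
#' and scaling exponents are optimized jointly by bounded quasi-Newton
#' search, the exponents within `p_bounds`. The null model is a single
#' coalescent-type process over the whole tree. `mode = "single"` sweeps
#' one threshold over all branching times; `mode = "multiple"` hill-climbs
#' over per-lineage threshold assignments starting from the
#' single-threshold optimum, accepting AIC-improving moves (model
#' complexity grows with the minimal number of distinct thresholds
#' consistent with the delimitation).
#'
#' @param t rooted ultrametric `phylo` tree (at least 3 tips).
#' @param mode `"single"` or `"multiple"`.
#' @param min_cluster_size minimum tips for an entity to count as an ML
#'   cluster (default 2).
#' @param df degrees of freedom for the likelihood-ratio test (default 3).
#' @param mixture use an equal-weights chi-square mixture
#'   (df and df - 1) for the LRT p-value instead of a plain chi-square.
#' @param p_bounds bounds for both scaling exponents (default `c(0.1, 2)`;
#'   larger upper bounds let the diversification term absorb bursts of
#'   tied merge heights in distance-derived dendrograms).
#' @param max_moves iteration cap for the multiple-threshold hill climb.
#' @param collapse_identical collapse zero-height clades (identical
#'   haplotypes) to a single representative tip before fitting and
#'   re-expand the delimited clusters afterwards (default `TRUE`;
#'   zero-length branchings carry no waiting-time information).
#' @return an object of class `its2_gmyc`; see Details for fields.
#' @export
gmyc <- function(t, mode = c("single", "multiple"), min_cluster_size = 2L,
                 df = 3, mixture = FALSE, p_bounds = c(0.1, 2),
                 max_moves = 200L, collapse_identical = TRUE) {
  mode <- match.arg(mode)
  groups <- list()
  if (collapse_identical) {
    coll <- collapse_identical_tips(t)
    if (ape::Ntip(coll$tree) >= 3L) {
      t <- coll$tree
      groups <- coll$groups
    }
  }
  prep <- gmyc_prep(t)
  n <- prep$n
  m <- prep$m
  root <- n + 1L
  null_s <- rep(FALSE, n + m)
  null_fit <- gmyc_model_fit(prep, null_s, p_bounds)

  slim <- function(fit) fit[c("s_nodes", "loglik", "lambda_div",
                              "lambda_coal", "p_div", "p_coal",
                              "k", "aic", "n_thresholds")]
  candidates <- list(slim(null_fit))
  best <- null_fit
  start <- c(1, 1)
  for (k in seq_len(m)) {
    s <- rep(FALSE, n + m)
    s[prep$ev_nodes[seq_len(k)]] <- TRUE
    fit <- gmyc_model_fit(prep, s, p_bounds, start)
    start <- c(fit$p_div, fit$p_coal)
    candidates[[length(candidates) + 1L]] <- slim(fit)
    if (fit$loglik > best$loglik + 1e-12) best <- fit
  }

  # parent lookup: pa[node] is the parent node id (NA for the root)
  pa <- rep(NA_integer_, n + m)
  pa[prep$child] <- prep$parent

  if (mode == "multiple") {
    incumbent <- if (best$aic < null_fit$aic) best else null_fit
    for (iter in seq_len(max_moves)) {
      s <- incumbent$s_nodes
      internal <- seq.int(n + 1L, n + m)
      adds <- internal[!s[internal] &
                         (internal == root |
                            (!is.na(pa[internal]) &
                               s[ifelse(is.na(pa[internal]), root,
                                        pa[internal])]))]
      rems <- which(s)
      rems <- rems[vapply(rems, function(nd) {
        ch <- prep$child[prep$parent == nd]
        !any(s[ch])
      }, TRUE)]
      moves <- c(adds, rems)
      if (length(moves) == 0L) break
      best_move <- NULL
      best_aic <- incumbent$aic
      for (nd in moves) {
        s2 <- s
        s2[nd] <- !s2[nd]
        st2 <- gmyc_stats(prep, s2)
        # quick score: incumbent parameters, no re-optimization
        ll2 <- gmyc_loglik(st2, incumbent$lambda_div,
                           incumbent$lambda_coal,
                           incumbent$p_div, incumbent$p_coal)
        t2 <- n_thresholds(prep, s2, st2)
        k2 <- 2L * any(st2$a_base > 0) + 2L * any(st2$coal_keep) + t2
        aic2 <- 2 * k2 - 2 * ll2
        if (is.finite(ll2) && aic2 < best_aic - 1e-9) {
          best_aic <- aic2
          best_move <- nd
        }
      }
      if (is.null(best_move)) break
      s[best_move] <- !s[best_move]
      fit <- gmyc_model_fit(prep, s, p_bounds,
                            c(incumbent$p_div, incumbent$p_coal))
      candidates[[length(candidates) + 1L]] <- slim(fit)
      if (fit$aic >= incumbent$aic - 1e-9) break
      incumbent <- fit
    }
    best <- incumbent   # AIC-selected model defines the delimitation
  }

  lr <- lr_test(null_fit$loglik, best$loglik, df = df, mixture = mixture)
  part <- gmyc_partition(prep, best$stats)
  if (length(groups) > 0L) {
    # re-expand collapsed identical-haplotype tips
    part <- lapply(part, function(tips) {
      unlist(lapply(tips, function(tp) {
        if (!is.null(groups[[tp]])) groups[[tp]] else tp
      }), use.names = FALSE)
    })
  }
  sizes <- lengths(part)
  thresholds <- threshold_times(prep, best)
  support <- node_support_akaike(candidates, prep)
  out <- list(mode = mode,
              null_loglik = null_fit$loglik,
              best_loglik = best$loglik,
              thresholds = thresholds,
              rates = c(lambda_div = best$lambda_div, p_div = best$p_div,
                        lambda_coal = best$lambda_coal,
                        p_coal = best$p_coal),
              lr_stat = 2 * (best$loglik - null_fit$loglik),
              p_value = lr,
              clusters = part,
              n_ml_clusters = sum(sizes >= min_cluster_size),
              n_entities = length(part),
              node_support = support,
              aic_best = best$aic,
              aic_null = null_fit$aic,
              n_candidates = length(candidates),
              tree = prep$tree)
  class(out) <- "its2_gmyc"
  out
}

threshold_times <- function(prep, fit) {
  roots <- fit$stats$entity_roots
  root <- prep$n + 1L
  roots <- roots[roots != root]
  if (length(roots) == 0L) return(numeric(0))
  par <- prep$parent[match(roots, prep$child)]
  lo <- prep$ages[roots]
  hi <- prep$ages[par]
  ord <- order(hi)
  lo <- lo[ord]
  hi <- hi[ord]
  pts <- numeric(0)
  cur <- NA_real_
  cur_lo <- -Inf
  for (i in seq_along(hi)) {
    if (is.na(cur) || !(lo[i] < cur)) {
      if (!is.na(cur)) pts <- c(pts, (max(cur_lo, 0) + cur) / 2)
      cur <- hi[i]
      cur_lo <- lo[i]
    } else {
      cur_lo <- max(cur_lo, lo[i])
      cur <- min(cur, hi[i])
    }
  }
  pts <- c(pts, (max(cur_lo, 0) + cur) / 2)
  sort(pts, decreasing = TRUE)
}

#' @export
print.its2_gmyc <- function(x, ...) {
  cat("GMYC (", x$mode, "-threshold) delimitation\n", sep = "")
  cat("  log-likelihood: null ", format(x$null_loglik), ", best ",
      format(x$best_loglik), "\n", sep = "")
  cat("  LR = ", format(x$lr_stat), ", p = ", format(x$p_value), "\n",
      sep = "")
  cat("  entities: ", x$n_entities, " (", x$n_ml_clusters,
      " ML clusters)\n", sep = "")
  cat("  threshold time(s): ", paste(signif(x$thresholds, 4),
                                     collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.its2_gmyc <- function(object, ...) {
  print(object)
  cat("  rates:", paste(names(object$rates),
                        signif(object$rates, 4), sep = " = ",
                        collapse = ", "), "\n")
  sizes <- sort(lengths(object$clusters), decreasing = TRUE)
  cat("  entity sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(object)
}

#' Likelihood-ratio test for the GMYC model
#'
#' Upper-tail chi-square p-value for `2 * (best - null)`; optionally an
#' equal-weights mixture of chi-square distributions with `df` and
#' `df - 1` degrees of freedom.
#'
#' @param null_loglik,best_loglik model log-likelihoods (`best >= null`).
#' @param df degrees of freedom (default 3).
#' @param mixture use the chi-square mixture (default `FALSE`).
#' @return p-value in \[0, 1\].
#' @export
lr_test <- function(null_loglik, best_loglik, df = 3, mixture = FALSE) {
  if (best_loglik < null_loglik - 1e-9) {
    stop("best log-likelihood is below the null log-likelihood")
  }
  stat <- max(2 * (best_loglik - null_loglik), 0)
  if (df < 1) stop("df must be >= 1")
  if (mixture) {
    0.5 * stats::pchisq(stat, df, lower.tail = FALSE) +
      0.5 * stats::pchisq(stat, max(df - 1, 1), lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df, lower.tail = FALSE)
  }
}

#' Akaike-weight node support for delimitation models
#'
#' Akaike weights `w_m = exp(-delta_m / 2) / sum(exp(-delta / 2))` over the
#' candidate models; the support of a node is the summed weight of the
#' models in which that node lies inside a delimited entity (i.e. is not a
#' divergence node).
#'
#' @param candidates list of fitted candidate models (internal structure
#'   produced during [gmyc()]), each with `aic` and `s_nodes`.
#' @param prep internal tree preparation (or a `phylo` tree, in which case
#'   candidates must carry compatible `s_nodes`).
#' @return named numeric vector over internal node ids, values in \[0, 1\].
#' @export
node_support_akaike <- function(candidates, prep) {
  if (length(candidates) == 0L) stop("empty candidate set")
  if (inherits(prep, "phylo")) prep <- gmyc_prep(prep)
  aics <- vapply(candidates, `[[`, 0, "aic")
  w <- exp(-(aics - min(aics)) / 2)
  w <- w / sum(w)
  nodes <- (prep$n + 1L):(prep$n + prep$m)
  supp <- vapply(nodes, function(nd) {
    sum(w[vapply(candidates, function(cd) !cd$s_nodes[nd], TRUE)])
  }, 0)
  names(supp) <- nodes
  supp
}
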