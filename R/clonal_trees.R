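# Clustering of CCF-scaled events and reconstruction of per-patient clone
# trees across timepoints under the sum rule and allele-phasing constraints.
#
# Trees over k event clusters are represented internally as an integer
# parent vector of length k, with 0 denoting the implicit normal-cell root.

#' Cluster events by CCF with a binomial mixture
#'
#' Events are modeled as binomial observations whose success probability is
#' the cluster's CCF times an event-specific scale: for a sequencing
#' variant the observation is (alt reads, depth) and the scale is the
#' expected VAF of a fully clonal event (`m*rho / (rho*n_t + (1-rho)*n_n)`);
#' estimates without raw counts (array-derived fractions) enter as
#' pseudo-counts at scale 1 via an effective size. Clustering directly on
#' the counts avoids the boundary distortion of clamped point estimates.
#' A k-component mixture is fit by EM for `k = 1..max_k` with 10
#' deterministic restarts each; `k` is selected by BIC; clusters whose
#' centers lie within `merge_tol` at every timepoint are merged. Clusters
#' are relabeled in decreasing order of mean CCF.
#'
#' @param ccf Numeric matrix, events x timepoints, of CCF estimates in
#'   `[0,1]` (used for initialization, and as pseudo-observations where
#'   `x` is absent).
#' @param n_eff Matrix of the same shape: effective binomial sizes (depth
#'   for count-backed events).
#' @param x Optional matrix of observed success counts (alt reads); `NA`
#'   entries fall back to pseudo-counts `round(ccf * n_eff)`.
#' @param scale Optional matrix of per-event success-probability scales
#'   (defaults to 1, i.e. the observation lives on the CCF scale).
#' @param max_k Maximum number of clusters tried (default 6).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param merge_tol Merge threshold on center distance (default 0.05).
#' @return A list with `assignment` (integer per event), `centers`
#'   (clusters x timepoints, CCF scale), `k`, and `bic` (per candidate k).
#' @export
cluster_ccf <- function(ccf, n_eff, x = NULL, scale = NULL, max_k = 6,
                        seed = 1, merge_tol = 0.05) {
  ccf <- as.matrix(ccf); n_eff <- round(as.matrix(n_eff))
  stopifnot(all(dim(ccf) == dim(n_eff)), all(ccf >= -1e-9 & ccf <= 1 + 1e-9),
            all(n_eff >= 1))
  n <- nrow(ccf); tpn <- ncol(ccf)
  if (is.null(scale)) scale <- matrix(1, n, tpn)
  scale <- as.matrix(scale)
  if (is.null(x)) x <- matrix(NA_real_, n, tpn)
  x <- as.matrix(x)
  pseudo <- is.na(x)
  x[pseudo] <- round(clamp(ccf[pseudo], 0, 1) * n_eff[pseudo])
  scale[pseudo] <- 1
  stopifnot(all(x >= 0), all(x <= n_eff), all(scale > 0), all(scale <= 1))
  kmax <- min(max_k, n)
  fits <- vector("list", kmax)
  bic <- rep(NA_real_, kmax)
  for (k in seq_len(kmax)) {
    best <- NULL
    for (r in 1:10) {
      set.seed(substream_seed(seed, 104729, k, r))
      centers <- em_init_centers(ccf, k, r)
      fit <- em_binomial(x, n_eff, scale, centers)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fits[[k]] <- best
    n_par <- k * tpn + (k - 1)
    bic[k] <- -2 * best$loglik + n_par * log(n)
  }
  k_sel <- which.min(bic)
  fit <- fits[[k_sel]]
  res <- merge_close_clusters(fit$assignment, x, n_eff, scale, merge_tol)
  ord <- order(-rowMeans(res$centers))
  relabel <- match(seq_len(nrow(res$centers)), ord)
  list(assignment = relabel[res$assignment],
       centers = res$centers[ord, , drop = FALSE],
       k = nrow(res$centers), bic = bic)
}

em_init_centers <- function(ccf, k, restart) {
  n <- nrow(ccf)
  if (restart == 1) {
    # spread: events ranked by mean CCF, evenly spaced picks
    ord <- order(rowMeans(ccf))
    idx <- ord[pmax(1, round(seq(1, n, length.out = k)))]
  } else {
    idx <- sample.int(n, k, replace = FALSE)
  }
  centers <- ccf[idx, , drop = FALSE] + matrix(runif(k * ncol(ccf), -0.02, 0.02), k)
  clamp(centers, 0.01, 0.99)
}

# component log-likelihood of all events for one CCF center vector
em_comp_ll <- function(x, n_eff, scale, center) {
  p <- clamp(sweep(scale, 2, center, `*`), 1e-9, 1 - 1e-9)
  rowSums(dbinom(x, n_eff, p, log = TRUE))
}

# weighted MLE of a cluster's CCF at one timepoint given per-event scales:
# closed form when all scales agree, 1-d optimization otherwise
em_center_mle <- function(x, n, s, w) {
  if (sum(w) < 1e-12) return(0.5)
  if (max(s) - min(s) < 1e-12) {
    return(clamp(((sum(w * x) + 0.5) / (sum(w * n) + 1.0)) / s[1], 1e-6, 1))
  }
  obj <- function(cc) {
    p <- clamp(cc * s, 1e-9, 1 - 1e-9)
    -sum(w * (x * log(p) + (n - x) * log1p(-p)))
  }
  optimize(obj, c(1e-6, 1))$minimum
}

em_binomial <- function(x, n_eff, scale, centers, max_iter = 200, tol = 1e-6) {
  k <- nrow(centers); n <- nrow(x)
  log_pi <- rep(log(1 / k), k)
  prev <- -Inf
  resp <- matrix(1 / k, n, k)
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    ll <- matrix(0, n, k)
    for (c in seq_len(k)) {
      ll[, c] <- em_comp_ll(x, n_eff, scale, centers[c, ]) + log_pi[c]
    }
    norm <- row_logsumexp(ll)
    loglik <- sum(norm)
    resp <- exp(ll - norm)
    old_centers <- centers
    for (c in seq_len(k)) {
      for (t in seq_len(ncol(x))) {
        centers[c, t] <- em_center_mle(x[, t], n_eff[, t], scale[, t], resp[, c])
      }
    }
    log_pi <- log(pmax(colMeans(resp), 1e-12))
    log_pi <- log_pi - log(sum(exp(log_pi)))
    if (is.finite(loglik) &&
        (abs(loglik - prev) < tol || max(abs(centers - old_centers)) < 1e-5)) break
    prev <- loglik
  }
  assignment <- max.col(resp, ties.method = "first")
  list(loglik = loglik, centers = centers, assignment = assignment)
}

merge_close_clusters <- function(assignment, x, n_eff, scale, merge_tol) {
  repeat {
    labs <- sort(unique(assignment))
    k <- length(labs)
    assignment <- match(assignment, labs)
    centers <- matrix(0, k, ncol(x))
    for (c in seq_len(k)) {
      w <- as.numeric(assignment == c)
      for (t in seq_len(ncol(x))) {
        centers[c, t] <- em_center_mle(x[, t], n_eff[, t], scale[, t], w)
      }
    }
    if (k == 1) return(list(assignment = assignment, centers = centers))
    pair <- NULL
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (max(abs(centers[a, ] - centers[b, ])) < merge_tol) { pair <- c(a, b); break }
    }
    if (is.null(pair)) return(list(assignment = assignment, centers = centers))
    assignment[assignment == pair[2]] <- pair[1]
  }
}

# ---- enumeration under the sum rule ---------------------------------------

#' Enumerate candidate clone trees over clusters
#'
#' Exhaustively enumerates rooted trees on the clusters (the normal-cell
#' root is implicit: a cluster with parent 0 is the founding malignant
#' clone), keeping only trees that satisfy the CCF sum rule at every
#' timepoint within tolerance `epsilon`. Enumeration is a depth-first
#' search over parent assignments with incremental sum-rule pruning.
#' Results are ordered deterministically: fewest leaves first, then
#' lexicographic parent vector.
#'
#' @param centers Numeric matrix, clusters x timepoints, of mean CCFs.
#' @param epsilon Sum-rule tolerance (default 0.05).
#' @param max_clusters Hard cap on the number of clusters (default 8).
#' @param max_candidates Safety cap on candidates collected.
#' @return A list of integer parent vectors (0 = normal root).
#' @export
enumerate_trees <- function(centers, epsilon = 0.05, max_clusters = 8,
                            max_candidates = 50000) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k > max_clusters) {
    stop_fmt("%d clusters exceed the enumeration cap of %d; raise the merge threshold",
             k, max_clusters)
  }
  out <- tree_dfs(centers, epsilon, stop_at = max_candidates + 1L)
  if (length(out) > max_candidates) {
    stop_fmt("more than %d sum-rule-consistent trees; inputs are uninformative",
             max_candidates)
  }
  leaves <- vapply(out, function(p) sum(!(seq_len(k) %in% p)), integer(1))
  ord <- order(leaves, vapply(out, function(p) paste(sprintf("%02d", p), collapse = ""),
                              character(1)))
  out[ord]
}

#' Count sum-rule-consistent trees (early-stopping)
#'
#' Same search as [enumerate_trees()] but stops as soon as `stop_at` valid
#' trees are found. Used to verify identifiability of simulated truth trees.
#'
#' @inheritParams enumerate_trees
#' @param stop_at Stop after this many valid trees.
#' @return Integer count (at most `stop_at`).
#' @export
count_valid_trees <- function(centers, epsilon = 0.05, stop_at = 2L) {
  length(tree_dfs(as.matrix(centers), epsilon, stop_at = stop_at))
}

# DFS over parent vectors with incremental child-sum pruning. Cycles are
# excluded at completion by a reachability check from the implicit root.
tree_dfs <- function(centers, epsilon, stop_at) {
  k <- nrow(centers); tpn <- ncol(centers)
  results <- list()
  parent <- integer(k)
  csum <- matrix(0, k + 1, tpn)  # row 1 = normal root, row i+1 = cluster i
  cap <- rbind(rep(1 + epsilon, tpn), centers + epsilon)
  recurse <- function(i) {
    if (length(results) >= stop_at) return()
    if (i > k) {
      if (is_connected_to_root(parent)) results[[length(results) + 1L]] <<- parent
      return()
    }
    for (p in 0:k) {
      if (p == i) next
      new_sum <- csum[p + 1, ] + centers[i, ]
      if (all(new_sum <= cap[p + 1, ] + 1e-12)) {
        parent[i] <<- p
        csum[p + 1, ] <<- new_sum
        recurse(i + 1L)
        csum[p + 1, ] <<- csum[p + 1, ] - centers[i, ]
        if (length(results) >= stop_at) return()
      }
    }
  }
  recurse(1L)
  results
}

is_connected_to_root <- function(parent) {
  k <- length(parent)
  for (i in seq_len(k)) {
    cur <- i; steps <- 0
    while (cur != 0) {
      cur <- parent[cur]; steps <- steps + 1
      if (steps > k) return(FALSE)
    }
  }
  TRUE
}

#' Check the CCF sum rule on a clone tree
#'
#' At every node and timepoint, the children's CCFs must sum to at most the
#' parent's CCF plus `epsilon`; the root's CCF must not exceed `1 + epsilon`.
#'
#' @param tree A `clone_tree`.
#' @param epsilon Tolerance (default 0.05).
#' @return A list with `ok` (logical) and `violations` (data.frame of
#'   node, timepoint, excess).
#' @export
check_sum_rule <- function(tree, epsilon = 0.05) {
  ids <- vapply(tree$nodes, `[[`, character(1), "node_id")
  parents <- vapply(tree$nodes, function(n) {
    if (is.null(n$parent_id) || is.na(n$parent_id)) NA_character_ else n$parent_id
  }, character(1))
  tps <- as.character(tree$timepoints)
  viol <- list()
  ccfs <- do.call(rbind, lapply(tree$nodes, function(n) n$ccf[tps]))
  rownames(ccfs) <- ids
  # root vs 1
  root <- ids[is.na(parents)]
  slack <- epsilon + 1e-9  # guard against float noise at the boundary
  for (tp in tps) {
    excess <- ccfs[root, tp] - 1
    if (excess > slack) viol[[length(viol) + 1]] <-
        data.frame(node = "(root)", timepoint = tp, excess = excess)
  }
  for (id in ids) {
    kids <- ids[!is.na(parents) & parents == id]
    if (length(kids) == 0) next
    for (tp in tps) {
      excess <- sum(ccfs[kids, tp]) - ccfs[id, tp]
      if (excess > slack) viol[[length(viol) + 1]] <-
          data.frame(node = id, timepoint = tp, excess = excess)
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(node = character(0), timepoint = character(0), excess = numeric(0))
  list(ok = nrow(viol) == 0, violations = viol)
}

# total sum-rule excess of a parent vector (0 at epsilon = 0 means exact)
parent_vector_violation <- function(parent, centers) {
  k <- nrow(centers)
  total <- 0
  for (p in 0:k) {
    kids <- which(parent == p)
    if (length(kids) == 0) next
    cap <- if (p == 0) rep(1, ncol(centers)) else centers[p, ]
    total <- total + sum(pmax(0, colSums(centers[kids, , drop = FALSE]) - cap))
  }
  total
}

# ---- phasing constraints ---------------------------------------------------

#' Filter candidate trees by allele-phasing constraints
#'
#' Variants of one gene that lie within read-pair distance can be phased:
#' a `different_allele` pair cannot share a haplotype, so at most
#' `n_alleles` pairwise-different-allele events may be collinear on a single
#' root-to-leaf lineage (co-resident events count as collinear) unless the
#' locus carries a copy gain. A `same_allele` pair must be collinear
#' (an allele is inherited along a lineage).
#'
#' @param candidates List of parent vectors from [enumerate_trees()].
#' @param event_cluster Named integer vector mapping event id to cluster.
#' @param constraints data.frame with columns `event_a`, `event_b`,
#'   `relation` (`"different_allele"` / `"same_allele"`).
#' @param n_alleles Copies of the locus available (default 2; pass the local
#'   copy number when the gene sits under a gain).
#' @return The surviving candidates (possibly empty, with attribute
#'   `"diagnostic"` explaining an empty result).
#' @export
apply_phasing_constraints <- function(candidates, event_cluster, constraints,
                                      n_alleles = 2) {
  if (is.null(constraints) || nrow(constraints) == 0) return(candidates)
  unknown <- setdiff(unique(c(constraints$event_a, constraints$event_b)),
                     names(event_cluster))
  if (length(unknown) > 0) {
    stop_fmt("phasing constraint references unknown event '%s'", unknown[1])
  }
  keep <- vapply(candidates, function(parent) {
    phasing_ok(parent, event_cluster, constraints, n_alleles)
  }, logical(1))
  out <- candidates[keep]
  if (length(out) == 0) {
    attr(out, "diagnostic") <-
      "phasing constraints eliminated all sum-rule-consistent trees"
  }
  out
}

phasing_ok <- function(parent, event_cluster, constraints, n_alleles) {
  k <- length(parent)
  anc <- ancestor_matrix(parent)  # strict ancestor: anc[a, b] TRUE if a anc of b
  collinear <- function(ca, cb) ca == cb || anc[ca, cb] || anc[cb, ca]
  # same-allele pairs must be collinear
  sa <- constraints[constraints$relation == "same_allele", , drop = FALSE]
  for (i in seq_len(nrow(sa))) {
    ca <- event_cluster[[sa$event_a[i]]]; cb <- event_cluster[[sa$event_b[i]]]
    if (!collinear(ca, cb)) return(FALSE)
  }
  # different-allele cliques on any root-to-leaf path limited by n_alleles
  da <- constraints[constraints$relation == "different_allele", , drop = FALSE]
  if (nrow(da) == 0) return(TRUE)
  ev <- unique(c(da$event_a, da$event_b))
  leaves <- setdiff(seq_len(k), parent)
  for (leaf in leaves) {
    path <- leaf
    cur <- leaf
    while (parent[cur] != 0) { cur <- parent[cur]; path <- c(path, cur) }
    on_path <- ev[event_cluster[ev] %in% path]
    if (length(on_path) <= n_alleles) next
    if (max_da_clique(on_path, da) > n_alleles) return(FALSE)
  }
  TRUE
}

# size of the largest clique in the different-allele graph among `events`
max_da_clique <- function(events, da) {
  m <- length(events)
  adj <- matrix(FALSE, m, m, dimnames = list(events, events))
  for (i in seq_len(nrow(da))) {
    a <- da$event_a[i]; b <- da$event_b[i]
    if (a %in% events && b %in% events) adj[a, b] <- adj[b, a] <- TRUE
  }
  best <- 1L
  grow <- function(clique, cand) {
    if (length(cand) == 0) { best <<- max(best, length(clique)); return() }
    for (j in seq_along(cand)) {
      v <- cand[j]
      grow(c(clique, v), cand[-seq_len(j)][adj[v, cand[-seq_len(j)]]])
    }
    best <<- max(best, length(clique))
  }
  grow(integer(0), seq_len(m))
  best
}

ancestor_matrix <- function(parent) {
  k <- length(parent)
  anc <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    cur <- parent[i]
    while (cur != 0) { anc[cur, i] <- TRUE; cur <- parent[cur] }
  }
  anc
}

# ---- end-to-end reconstruction --------------------------------------------

#' Reconstruct a patient's clone tree from CCF-scaled events
#'
#' Pipeline: cluster events in CCF space, enumerate sum-rule-consistent
#' trees, filter by phasing constraints, and select the final tree by
#' (1) minimal total sum-rule excess, (2) fewest leaves (parsimony toward
#' linear evolution), (3) lexicographic parent vector. The number of
#' co-optimal trees is reported as an ambiguity measure. Event timepoints
#' at which an event was not observed contribute CCF 0 (clones may regress).
#'
#' @param events A long-format data.frame with columns `event_id`, `label`,
#'   `timepoint`, `ccf`, `n_eff` (effective binomial size of the CCF
#'   estimate), and optionally `x` (observed success counts, e.g. alt
#'   reads, with `n_eff` then the depth) and `scale` (expected success
#'   probability of a fully clonal event). One row per event per observed
#'   timepoint.
#' @param config Optional list: `epsilon` (default: `max(0.05, 2x mean
#'   Wilson CI half-width)`), `max_k` (6), `seed` (1), `merge_tol` (0.05),
#'   `constraints` (phasing data.frame), `n_alleles` (2),
#'   `patient_id` ("patient").
#' @return A `clone_tree` with attributes `event_nodes` (event id ->
#'   node id), `ambiguity` (list: n_candidates, n_cooptimal), `epsilon`,
#'   and per-node `residual` CCF stored on the nodes.
#' @export
reconstruct <- function(events, config = list()) {
  stopifnot(all(c("event_id", "timepoint", "ccf", "n_eff") %in% names(events)))
  if (nrow(events) == 0) stop_fmt("no events to reconstruct from")
  if (!"label" %in% names(events)) events$label <- events$event_id
  cfg <- utils::modifyList(
    list(epsilon = NULL, max_k = 6, seed = 1, merge_tol = 0.05,
         constraints = NULL, n_alleles = 2, patient_id = "patient"),
    config
  )
  tps <- sort(unique(events$timepoint))
  ev_ids <- unique(events$event_id)
  ccf <- matrix(0, length(ev_ids), length(tps),
                dimnames = list(ev_ids, as.character(tps)))
  n_eff <- matrix(NA_real_, length(ev_ids), length(tps),
                  dimnames = dimnames(ccf))
  x <- matrix(NA_real_, length(ev_ids), length(tps), dimnames = dimnames(ccf))
  scl <- matrix(NA_real_, length(ev_ids), length(tps), dimnames = dimnames(ccf))
  has_counts <- "x" %in% names(events)
  for (r in seq_len(nrow(events))) {
    i <- events$event_id[r]; j <- as.character(events$timepoint[r])
    ccf[i, j] <- events$ccf[r]
    n_eff[i, j] <- events$n_eff[r]
    if (has_counts) x[i, j] <- events$x[r]
    if ("scale" %in% names(events)) scl[i, j] <- events$scale[r]
  }
  # unobserved (event, timepoint): CCF 0 at the event's typical weight/scale
  med_n <- stats::median(events$n_eff)
  for (i in seq_len(nrow(ccf))) {
    miss <- is.na(n_eff[i, ])
    if (!any(miss)) next
    n_eff[i, miss] <- round(med_n)
    if (has_counts && any(!is.na(x[i, ]))) x[i, miss] <- 0
    row_scl <- scl[i, !miss]
    scl[i, miss] <- if (length(row_scl) && any(!is.na(row_scl)))
      stats::median(row_scl, na.rm = TRUE) else 1
  }
  scl[is.na(scl)] <- 1
  # tolerance scales with sampling noise: 2x mean Wilson half-width, floored
  if (is.null(cfg$epsilon)) {
    xw <- round(clamp(ccf, 0, 1) * n_eff)
    w <- wilson_ci(as.vector(xw), as.vector(n_eff))
    cfg$epsilon <- max(0.05, 2 * mean((w[, "high"] - w[, "low"]) / 2))
  }
  cl <- cluster_ccf(ccf, n_eff, x = if (has_counts) x else NULL, scale = scl,
                    max_k = cfg$max_k, seed = cfg$seed,
                    merge_tol = cfg$merge_tol)
  centers <- cl$centers
  candidates <- list()
  eps_used <- cfg$epsilon
  for (eps in cfg$epsilon * c(1, 2, 4)) {
    candidates <- enumerate_trees(centers, epsilon = eps)
    if (length(candidates) > 0) { eps_used <- eps; break }
  }
  if (length(candidates) == 0) {
    stop_fmt("reconstruction failure: no sum-rule-consistent tree at epsilon <= %.3g",
             cfg$epsilon * 4)
  }
  event_cluster <- setNames(cl$assignment, ev_ids)
  if (!is.null(cfg$constraints) && nrow(cfg$constraints) > 0) {
    candidates <- apply_phasing_constraints(candidates, event_cluster,
                                            cfg$constraints, cfg$n_alleles)
    if (length(candidates) == 0) {
      stop_fmt("reconstruction failure: %s", attr(candidates, "diagnostic"))
    }
  }
  # the document schema requires a single founding clone; prefer monoclonal
  single_root <- candidates[vapply(candidates, function(p) sum(p == 0) == 1, logical(1))]
  if (length(single_root) > 0) candidates <- single_root
  else stop_fmt("reconstruction failure: only polyclonal arrangements remain")
  viol <- vapply(candidates, parent_vector_violation, numeric(1), centers = centers)
  best_viol <- min(viol)
  co <- candidates[viol <= best_viol + 1e-12]
  # enumerate_trees already orders by leaves then lexicographic parent vector
  parent <- co[[1]]
  tree <- build_clone_tree(parent, centers, event_cluster, tps, cfg$patient_id)
  attr(tree, "ambiguity") <- list(n_candidates = length(candidates),
                                  n_cooptimal = length(co))
  attr(tree, "epsilon") <- eps_used
  lab_map <- events$label[match(ev_ids, events$event_id)]
  attr(tree, "event_labels") <- setNames(lab_map, ev_ids)
  tree
}

build_clone_tree <- function(parent, centers, event_cluster, timepoints,
                             patient_id) {
  k <- length(parent)
  ids <- paste0("C", seq_len(k))
  nodes <- lapply(seq_len(k), function(i) {
    evs <- names(event_cluster)[event_cluster == i]
    kids <- which(parent == i)
    resid <- centers[i, ] - if (length(kids)) colSums(centers[kids, , drop = FALSE]) else 0
    list(node_id = ids[i],
         parent_id = if (parent[i] == 0) NA_character_ else ids[parent[i]],
         events = evs,
         ccf = setNames(clamp(as.numeric(centers[i, ]), 0, 1),
                        as.character(timepoints)),
         residual = setNames(as.numeric(resid), as.character(timepoints)))
  })
  tree <- clone_tree(patient_id, nodes, timepoints)
  attr(tree, "event_nodes") <- setNames(ids[event_cluster], names(event_cluster))
  tree
}

# ---- tree queries ----------------------------------------------------------

tree_parent_ids <- function(tree) {
  ids <- vapply(tree$nodes, `[[`, character(1), "node_id")
  parents <- vapply(tree$nodes, function(n) {
    if (is.null(n$parent_id) || is.na(n$parent_id)) NA_character_ else n$parent_id
  }, character(1))
  setNames(parents, ids)
}

# strict-ancestor boolean matrix over node ids
tree_ancestor_matrix <- function(tree) {
  up <- tree_parent_ids(tree)
  ids <- names(up)
  anc <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (id in ids) {
    cur <- up[[id]]
    while (!is.na(cur)) { anc[cur, id] <- TRUE; cur <- up[[cur]] }
  }
  anc
}

#' Nested level of each node and event
#'
#' The founding malignant clone sits at level 1; a node's level is its
#' 1-based depth below the founder. An event's level is the level of the
#' node where it is first acquired. The tree's nested level is the depth of
#' the deepest node.
#'
#' @param tree A `clone_tree`.
#' @return A named numeric vector of event levels, with attribute
#'   `tree_level` (maximum node depth) and `node_levels`.
#' @export
nested_levels <- function(tree) {
  up <- tree_parent_ids(tree)
  depth <- function(id) {
    d <- 1; cur <- up[[id]]
    while (!is.na(cur)) { d <- d + 1; cur <- up[[cur]] }
    d
  }
  node_lv <- vapply(names(up), depth, numeric(1))
  ev_lv <- numeric(0)
  for (n in tree$nodes) {
    if (length(n$events)) {
      ev_lv <- c(ev_lv, setNames(rep(node_lv[[n$node_id]], length(n$events)),
                                 n$events))
    }
  }
  structure(ev_lv, tree_level = max(node_lv), node_levels = node_lv)
}

#' Pairwise ancestry relations between events of a tree
#'
#' Classifies every unordered event pair as `same` (one clone),
#' `a_anc_b` / `b_anc_a` (strict ancestry) or `parallel` (distinct
#' branches).
#'
#' @param tree A `clone_tree` whose nodes carry event labels.
#' @return data.frame with columns `a`, `b` (with `a < b`), `relation`.
#' @export
tree_event_relations <- function(tree) {
  node_of <- character(0)
  for (n in tree$nodes) {
    node_of <- c(node_of, setNames(rep(n$node_id, length(n$events)), n$events))
  }
  evs <- sort(names(node_of))
  if (length(evs) < 2) {
    return(data.frame(a = character(0), b = character(0),
                      relation = character(0)))
  }
  anc <- tree_ancestor_matrix(tree)
  pairs <- utils::combn(evs, 2)
  rel <- apply(pairs, 2, function(p) {
    na <- node_of[[p[1]]]; nb <- node_of[[p[2]]]
    if (na == nb) "same"
    else if (anc[na, nb]) "a_anc_b"
    else if (anc[nb, na]) "b_anc_a"
    else "parallel"
  })
  data.frame(a = pairs[1, ], b = pairs[2, ], relation = rel,
             stringsAsFactors = FALSE)
}

#' Compare a reconstructed tree against the truth
#'
#' Computes precision and recall of ordered ancestor-descendant event pairs
#' and the overall pairwise classification accuracy (same / ancestral /
#' parallel) over events present in both trees.
#'
#' @param truth,recon `clone_tree` objects sharing event labels.
#' @return A list with `precision`, `recall`, `accuracy`, `n_pairs`.
#' @export
compare_tree_relations <- function(truth, recon) {
  rt <- tree_event_relations(truth)
  rr <- tree_event_relations(recon)
  key <- function(d) paste(d$a, d$b)
  common <- intersect(key(rt), key(rr))
  rt <- rt[key(rt) %in% common, ]; rt <- rt[order(key(rt)), ]
  rr <- rr[key(rr) %in% common, ]; rr <- rr[order(key(rr)), ]
  anc_t <- rt$relation %in% c("a_anc_b", "b_anc_a")
  anc_r <- rr$relation %in% c("a_anc_b", "b_anc_a")
  tp <- sum(anc_t & anc_r & rt$relation == rr$relation)
  list(
    precision = if (sum(anc_r) == 0) 1 else tp / sum(anc_r),
    recall = if (sum(anc_t) == 0) 1 else tp / sum(anc_t),
    accuracy = if (nrow(rt) == 0) 1 else mean(rt$relation == rr$relation),
    n_pairs = nrow(rt)
  )
}
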