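# Ordered evolutionary trajectories: extraction from clone trees, cohort
# frequency filtering, permutation-based enrichment testing, and the
# weighted nested-level statistic.

#' Relabel tree events for trajectory analysis
#'
#' Maps a tree's event identifiers to analysis labels: an explicit
#' `labels` map (event id -> label, e.g. `"NOTCH1:136503000"` ->
#' `"NOTCH1"`) takes precedence; events encoded as
#' `cnv:<chrom>:<start>-<end>:<cn>:<loh>` are replaced by their
#' arm/chromosome class label via [cnv_label()]; anything else passes
#' through. Duplicate labels within one node are collapsed (two variants
#' of one gene in the same clone count once).
#'
#' @param tree A `clone_tree`.
#' @param labels Optional named character vector mapping event ids to
#'   labels (defaults to the `event_labels` attribute [reconstruct()]
#'   attaches).
#' @param build Genome build.
#' @return The relabeled tree.
#' @export
label_events <- function(tree, labels = attr(tree, "event_labels"),
                         build = "GRCh38") {
  tree$nodes <- lapply(tree$nodes, function(n) {
    evs <- vapply(n$events, function(e) {
      if (!is.null(labels) && e %in% names(labels)) {
        labels[[e]]
      } else if (grepl("^cnv:", e)) {
        parts <- strsplit(e, ":", fixed = TRUE)[[1]]
        coords <- strsplit(parts[3], "-", fixed = TRUE)[[1]]
        cnv_label(parts[2], as.numeric(coords[1]), as.numeric(coords[2]),
                  cn = as.integer(parts[4]), loh = as.logical(parts[5]),
                  build = build)
      } else e
    }, character(1), USE.NAMES = FALSE)
    n$events <- unique(evs)
    n
  })
  tree
}

trajectory_string <- function(labels) paste(labels, collapse = "->")

#' Extract ordered trajectories from one clone tree
#'
#' A length-2 trajectory `(e1, e2)` requires `e1` in a node strictly
#' ancestral to `e2`'s node; length-3 trajectories span three distinct nodes
#' in strict ancestor order. Events sharing a node are never ordered (their
#' relative order is unknowable). Each distinct trajectory is reported once
#' per tree.
#'
#' @param tree A labeled `clone_tree`.
#' @param max_len Maximum trajectory length, 2 or 3 (default 3).
#' @return Character vector of trajectory strings (`"A->B"`, `"A->B->C"`).
#' @export
extract_trajectories <- function(tree, max_len = 3) {
  stopifnot(max_len %in% c(2, 3))
  node_events <- lapply(tree$nodes, `[[`, "events")
  names(node_events) <- vapply(tree$nodes, `[[`, character(1), "node_id")
  anc <- tree_ancestor_matrix(tree)
  ids <- rownames(anc)
  out <- character(0)
  for (a in ids) for (b in ids) {
    if (!anc[a, b]) next
    for (e1 in node_events[[a]]) for (e2 in node_events[[b]]) {
      out <- c(out, trajectory_string(c(e1, e2)))
    }
    if (max_len >= 3) {
      for (c_ in ids) {
        if (!anc[b, c_]) next
        for (e1 in node_events[[a]]) for (e2 in node_events[[b]])
          for (e3 in node_events[[c_]]) {
            out <- c(out, trajectory_string(c(e1, e2, e3)))
          }
      }
    }
  }
  unique(out)
}

#' Cohort trajectory frequencies with the reporting filter
#'
#' Counts, per distinct trajectory, the number of cohort trees containing
#' it, and retains length-2 trajectories observed in at least `min_freq2`
#' (default 10%) and length-3 trajectories in at least `min_freq3` (default
#' 5%) of the trees. Both thresholds are inclusive.
#'
#' @param trees List of labeled `clone_tree` objects (one subgroup).
#' @param min_freq2,min_freq3 Frequency thresholds for lengths 2 and 3.
#' @param max_len Maximum trajectory length considered.
#' @return data.frame with `trajectory`, `length`, `support`, `frequency`.
#' @export
trajectory_frequencies <- function(trees, min_freq2 = 0.10, min_freq3 = 0.05,
                                   max_len = 3) {
  stopifnot(length(trees) >= 1)
  per_tree <- lapply(trees, extract_trajectories, max_len = max_len)
  tab <- table(unlist(per_tree))
  if (length(tab) == 0) {
    return(data.frame(trajectory = character(0), length = integer(0),
                      support = integer(0), frequency = numeric(0)))
  }
  len <- lengths(strsplit(names(tab), "->", fixed = TRUE))
  freq <- as.numeric(tab) / length(trees)
  keep <- (len == 2 & freq >= min_freq2) | (len == 3 & freq >= min_freq3)
  out <- data.frame(trajectory = names(tab), length = len,
                    support = as.integer(tab), frequency = freq,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out[order(-out$support, out$trajectory), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wrapper around
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in `(0,1]`.
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Permutation test for trajectory enrichment
#'
#' Null model: within each patient, the tree's event labels are reassigned
#' uniformly at random to its nodes, preserving the topology and the number
#' of labels per node. The test statistic is the cohort support (number of
#' trees containing the trajectory); `p = (1 + #{permutations with support
#' >= observed}) / (1 + n_perm)`. All trajectories share the same joint
#' permutations, and BH adjustment is applied within each length class.
#'
#' @param trees List of labeled `clone_tree` objects (one subgroup).
#' @param trajectories Character vector of trajectory strings to test;
#'   defaults to all trajectories passing [trajectory_frequencies()].
#' @param n_perm Number of permutations (default 10000; values below 100
#'   are refused).
#' @param seed Integer seed.
#' @return data.frame with `trajectory`, `length`, `support`, `frequency`,
#'   `p_value`, `p_adjusted`, `n_perm`, `seed`.
#' @export
trajectory_permutation_test <- function(trees, trajectories = NULL,
                                        n_perm = 10000, seed = 1) {
  if (n_perm < 100) stop_fmt("n_perm = %d is below the minimum of 100", n_perm)
  if (is.null(trajectories)) {
    trajectories <- trajectory_frequencies(trees)$trajectory
  }
  if (length(trajectories) == 0) {
    return(data.frame(trajectory = character(0), length = integer(0),
                      support = integer(0), frequency = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      n_perm = integer(0), seed = integer(0)))
  }
  labels_all <- sort(unique(c(
    unlist(lapply(trees, function(t) unlist(lapply(t$nodes, `[[`, "events")))),
    unlist(strsplit(trajectories, "->", fixed = TRUE))
  )))
  K <- length(labels_all)
  parsed <- strsplit(trajectories, "->", fixed = TRUE)
  len <- lengths(parsed)
  # per-tree precomputation: label slots, ancestor slot pairs/triples
  prep <- lapply(trees, prepare_tree_perm, labels_all = labels_all,
                 need_triples = any(len == 3))
  stopifnot(all(len %in% c(2, 3)))
  code2 <- vapply(parsed[len == 2], function(x) {
    (match(x[1], labels_all) - 1) * K + match(x[2], labels_all)
  }, numeric(1))
  code3 <- vapply(parsed[len == 3], function(x) {
    ((match(x[1], labels_all) - 1) * K + (match(x[2], labels_all) - 1)) * K +
      match(x[3], labels_all)
  }, numeric(1))
  support_fun <- function(permute) {
    s2 <- numeric(K * K); s3 <- if (any(len == 3)) numeric(K^3) else numeric(0)
    for (pt in prep) {
      labs <- if (permute) pt$labs[sample.int(pt$ns)] else pt$labs
      if (length(pt$pi)) {
        c2 <- unique((labs[pt$pi] - 1) * K + labs[pt$pj])
        s2[c2] <- s2[c2] + 1
      }
      if (any(len == 3) && length(pt$ti)) {
        c3 <- unique(((labs[pt$ti] - 1) * K + (labs[pt$tj] - 1)) * K + labs[pt$tk])
        s3[c3] <- s3[c3] + 1
      }
    }
    c(s2[code2], s3[code3])
  }
  set.seed(substream_seed(seed, 7741))
  obs <- support_fun(permute = FALSE)
  ge <- integer(length(trajectories))
  ord <- c(which(len == 2), which(len == 3))
  for (b in seq_len(n_perm)) {
    perm <- support_fun(permute = TRUE)
    ge[ord] <- ge[ord] + as.integer(perm >= obs)
  }
  p <- (1 + ge) / (1 + n_perm)
  obs_support <- integer(length(trajectories)); obs_support[ord] <- as.integer(obs)
  p_adj <- numeric(length(p))
  for (l in unique(len)) p_adj[len == l] <- bh_adjust(p[len == l])
  out <- data.frame(trajectory = trajectories, length = len,
                    support = obs_support,
                    frequency = obs_support / length(trees),
                    p_value = p, p_adjusted = p_adj,
                    n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
  out[order(out$p_value, out$trajectory), , drop = FALSE]
}

prepare_tree_perm <- function(tree, labels_all, need_triples = TRUE) {
  anc <- tree_ancestor_matrix(tree)
  slot_node <- integer(0); labs <- integer(0)
  for (i in seq_along(tree$nodes)) {
    evs <- tree$nodes[[i]]$events
    if (length(evs)) {
      slot_node <- c(slot_node, rep(i, length(evs)))
      labs <- c(labs, match(evs, labels_all))
    }
  }
  ns <- length(labs)
  pi <- integer(0); pj <- integer(0)
  ti <- integer(0); tj <- integer(0); tk <- integer(0)
  if (ns >= 2) {
    A <- anc[slot_node, slot_node, drop = FALSE]  # slot-level strict ancestry
    idx <- which(A, arr.ind = TRUE)
    pi <- idx[, 1]; pj <- idx[, 2]
    if (need_triples && ns >= 3 && length(pi)) {
      for (b in unique(pj)) {
        up <- pi[pj == b]; down <- pj[pi == b]
        if (length(up) && length(down)) {
          g <- expand.grid(a = up, c_ = down)
          ti <- c(ti, g$a); tj <- c(tj, rep(b, nrow(g))); tk <- c(tk, g$c_)
        }
      }
    }
  }
  list(ns = ns, labs = labs, pi = pi, pj = pj, ti = ti, tj = tj, tk = tk)
}

#' Weighted nested-level statistic
#'
#' Two scopes. `event_class`: the mean 1-based acquisition level of all
#' occurrences of a class of events across the cohort, each occurrence
#' weighted equally (a value near 1 marks a class of founding events).
#' `tree`: the mean tree depth over patients, each patient weighted by its
#' number of events, summarizing how deeply nested cohort evolution is.
#'
#' @param trees List of labeled `clone_tree` objects.
#' @param scope `"tree"` or `"event_class"`.
#' @param event_class For `scope = "event_class"`: regular expression (or
#'   fixed label set) selecting the event labels, e.g.
#'   `"^(del|LOH)_in_9p$"` for chr9p deletions/LOH.
#' @return A list with `value`, `scope`, `n`, `weighting`.
#' @export
weighted_nested_level <- function(trees, scope = c("tree", "event_class"),
                                  event_class = NULL) {
  scope <- match.arg(scope)
  stopifnot(length(trees) >= 1)
  lvls <- lapply(trees, nested_levels)
  if (scope == "tree") {
    depth <- vapply(lvls, attr, numeric(1), "tree_level")
    w <- vapply(lvls, length, numeric(1))
    if (sum(w) == 0) stop_fmt("no events in cohort trees")
    list(value = sum(depth * w) / sum(w), scope = "tree", n = length(trees),
         weighting = "patients weighted by event count")
  } else {
    stopifnot(!is.null(event_class))
    occ <- unlist(lapply(lvls, function(lv) {
      lv[grepl(event_class, names(lv))]
    }))
    if (length(occ) == 0) {
      stop_fmt("no occurrence of event class '%s' in the cohort", event_class)
    }
    list(value = mean(occ), scope = "event_class", n = length(occ),
         weighting = "occurrences weighted equally")
  }
}
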