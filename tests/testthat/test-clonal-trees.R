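# Clustering, exhaustive tree enumeration under the sum rule, phasing
# constraints, and end-to-end reconstruction.

test_that("well-separated CCF groups form the right clusters", {
  set.seed(1)
  depth <- 500
  # 3 events at CCF ~1.0 and 3 at ~0.3, observed as alt reads at the
  # clonal-VAF scale 0.5 (diploid, full purity)
  x <- matrix(c(rbinom(3, depth, 0.5), rbinom(3, depth, 0.15)), ncol = 1)
  n <- matrix(depth, 6, 1)
  s <- matrix(0.5, 6, 1)
  ccf <- pmin(1, x / (n * s))
  cl <- cluster_ccf(ccf, n, x = x, scale = s, seed = 1)
  expect_equal(cl$k, 2)
  expect_equal(cl$assignment[1:3], rep(1L, 3))   # high-CCF cluster first
  expect_equal(cl$assignment[4:6], rep(2L, 3))
  # brute force: the 2-component likelihood dominates the 1-component fit
  expect_lt(cl$bic[2], cl$bic[1])
  # singleton input
  expect_equal(cluster_ccf(matrix(0.4), matrix(500))$k, 1)
  # determinism
  cl2 <- cluster_ccf(ccf, n, x = x, scale = s, seed = 1)
  expect_identical(cl, cl2)
})

test_that("tree enumeration matches manual case analysis", {
  # clusters 1.0 and 0.4: of the 3 arrangements only nesting under 1.0 works
  out <- enumerate_trees(matrix(c(1.0, 0.4), 2, 1))
  expect_length(out, 1)
  expect_equal(out[[1]], c(0L, 1L))
  # clusters 0.6 and 0.5: parallel sums to 1.1 > 1 + eps, nesting is valid
  out <- enumerate_trees(matrix(c(0.6, 0.5), 2, 1))
  expect_length(out, 1)
  expect_equal(out[[1]], c(0L, 1L))
  # single cluster: exactly one tree
  expect_length(enumerate_trees(matrix(0.9)), 1)
  # cap on cluster count
  expect_error(enumerate_trees(matrix(runif(9 * 2), 9, 2)), "merge threshold")
})

test_that("enumeration equals brute force over all parent vectors", {
  brute_force <- function(centers, eps) {
    k <- nrow(centers)
    grid <- do.call(expand.grid, rep(list(0:k), k))
    valid <- 0
    for (r in seq_len(nrow(grid))) {
      parent <- as.integer(grid[r, ])
      if (any(parent == seq_len(k))) next
      # connectivity
      ok <- TRUE
      for (i in seq_len(k)) {
        cur <- i; steps <- 0
        while (cur != 0 && steps <= k) { cur <- parent[cur]; steps <- steps + 1 }
        if (cur != 0) { ok <- FALSE; break }
      }
      if (!ok) next
      for (p in 0:k) {
        kids <- which(parent == p)
        if (!length(kids)) next
        cap <- if (p == 0) rep(1, ncol(centers)) else centers[p, ]
        if (any(colSums(centers[kids, , drop = FALSE]) > cap + eps)) { ok <- FALSE; break }
      }
      if (ok) valid <- valid + 1
    }
    valid
  }
  set.seed(3)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    centers <- matrix(runif(k * 2, 0.05, 1), k, 2)
    centers <- centers[order(-rowMeans(centers)), , drop = FALSE]
    expect_equal(length(enumerate_trees(centers, epsilon = 0.05)),
                 brute_force(centers, 0.05))
  }
})

test_that("the sum rule check reports violations with magnitudes", {
  ok_tree <- make_tree(c(1.0, 0.6, 0.3), c(0, 1, 1))
  expect_true(check_sum_rule(ok_tree, 0.05)$ok)
  bad <- make_tree(c(0.5, 0.4, 0.3), c(0, 1, 1))
  chk <- check_sum_rule(bad, 0.05)
  expect_false(chk$ok)
  expect_equal(chk$violations$excess, 0.2, tolerance = 1e-12)
  # boundary: within tolerance passes
  expect_true(check_sum_rule(make_tree(c(1.0, 0.6, 0.45), c(0, 1, 1)), 0.05)$ok)
})

test_that("phasing constraints cut lineages exceeding the allele count", {
  # founder + two subclone clusters, CCFs allow chain and parallel
  centers <- matrix(c(1.0, 0.55, 0.30), 3, 1)
  candidates <- enumerate_trees(centers)
  expect_true(length(candidates) > 1)
  ev <- c(A = 2L, B = 2L, C = 3L, FOUND = 1L)  # A,B co-resident; C apart
  cons <- data.frame(event_a = c("A", "A", "B"), event_b = c("B", "C", "C"),
                     relation = "different_allele")
  kept <- apply_phasing_constraints(candidates, ev, cons, n_alleles = 2)
  # surviving topologies must not place clusters 2 and 3 on one lineage
  for (parent in kept) {
    expect_false(parent[3] == 2 || parent[2] == 3)
  }
  # with a copy gain (3 alleles) nothing is cut
  expect_length(apply_phasing_constraints(candidates, ev, cons, n_alleles = 3),
                length(candidates))
  # no constraints: identity
  expect_identical(apply_phasing_constraints(candidates, ev,
                                             cons[0, ], 2), candidates)
  # same-allele events must stay collinear
  cons_sa <- data.frame(event_a = "A", event_b = "C", relation = "same_allele")
  kept_sa <- apply_phasing_constraints(candidates, ev, cons_sa)
  for (parent in kept_sa) {
    expect_true(parent[3] == 2 || parent[2] == 3)
  }
})

test_that("three same-gene frameshifts with CCFs {a,a,b} force two branches", {
  # no copy gain: three pairwise different-allele variants cannot be
  # collinear, so the equal-CCF pair shares one branch and the third sits
  # on a parallel branch -- the only explanation consistent with the data
  events <- data.frame(
    event_id = c("PTEN:fs1", "PTEN:fs2", "PTEN:fs3", "NOTCH1:1"),
    label = c("PTEN", "PTEN", "PTEN", "NOTCH1"),
    timepoint = 0, ccf = c(0.55, 0.55, 0.30, 1.0), n_eff = 20000,
    x = NA_real_, scale = 1
  )
  cons <- data.frame(
    event_a = c("PTEN:fs1", "PTEN:fs1", "PTEN:fs2"),
    event_b = c("PTEN:fs2", "PTEN:fs3", "PTEN:fs3"),
    relation = "different_allele"
  )
  tree <- reconstruct(events, config = list(seed = 1, constraints = cons))
  amb <- attr(tree, "ambiguity")
  expect_equal(amb$n_cooptimal, 1)      # unique explanation
  nodes_of <- attr(tree, "event_nodes")
  expect_equal(nodes_of[["PTEN:fs1"]], nodes_of[["PTEN:fs2"]])  # co-resident
  expect_false(nodes_of[["PTEN:fs3"]] == nodes_of[["PTEN:fs1"]])
  rel <- tree_event_relations(tree)
  pick <- rel[rel$a == "PTEN:fs1" & rel$b == "PTEN:fs3", ]
  expect_equal(pick$relation, "parallel")
  # without constraints the chain arrangement survives too: ambiguity
  tree_nc <- reconstruct(events, config = list(seed = 1))
  expect_gt(attr(tree_nc, "ambiguity")$n_candidates, 1)
})

test_that("reconstruction recovers simple structures deterministically", {
  single <- data.frame(event_id = "NOTCH1", label = "NOTCH1", timepoint = 0,
                       ccf = 1.0, n_eff = 500, x = NA_real_, scale = 1)
  tr <- reconstruct(single)
  expect_length(tr$nodes, 1)
  lv <- nested_levels(tr)
  expect_equal(unname(lv[["NOTCH1"]]), 1)
  # determinism end to end
  cfg <- sim_config(clones_range = c(1, 5))
  a <- sim_and_reconstruct(321, cfg)
  b <- sim_and_reconstruct(321, cfg)
  expect_identical(a$recon, b$recon)
})

test_that("noiseless cohorts reconstruct to the exact truth", {
  cfg <- sim_config(clones_range = c(1, 5), read_noise = FALSE,
                    signal_noise = FALSE)
  res <- lapply(1:30, function(i) sim_and_reconstruct(5000 + i, cfg,
                                                      exact = TRUE)$cmp)
  expect_equal(mean(vapply(res, `[[`, numeric(1), "precision")), 1)
  expect_equal(mean(vapply(res, `[[`, numeric(1), "recall")), 1)
})
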