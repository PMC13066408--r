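# Trajectory extraction semantics, frequency filtering, the label-shuffle
# permutation test, BH adjustment, and nested-level statistics.

test_that("CNV labels follow the arm / whole-chromosome convention", {
  expect_equal(cnv_label("9", 1, 38e6, 1, FALSE), "del_in_9p")
  expect_equal(cnv_label("9", 1, 38e6, 2, TRUE), "LOH_in_9p")
  expect_equal(cnv_label("20", 1, 64444167, 3, FALSE), "dup20")
  expect_equal(cnv_label("6", 62e6, 1.7e8, 1, FALSE), "del_in_6q")
  # 90% rule: a segment crossing the centromere by more than 10% is
  # labeled at chromosome level
  expect_equal(cnv_label("9", 1, 60e6, 1, FALSE), "del9")
  expect_error(cnv_label("99", 1, 2, 1, FALSE), "99")
})

test_that("trajectory extraction follows strict-ancestor semantics", {
  linear <- make_tree(c(1.0, 0.7, 0.4), c(0, 1, 2),
                      events = list("e1", "e2", "e3"))
  tr <- extract_trajectories(linear)
  expect_setequal(tr, c("e1->e2", "e1->e3", "e2->e3", "e1->e2->e3"))
  star <- make_tree(c(1.0, 0.5, 0.4), c(0, 1, 1),
                    events = list("e1", "e2", "e3"))
  expect_setequal(extract_trajectories(star), c("e1->e2", "e1->e3"))
  # same-node events are never ordered
  multi <- make_tree(c(1.0, 0.5), c(0, 1),
                     events = list(c("e1", "e2"), "e3"))
  expect_setequal(extract_trajectories(multi), c("e1->e3", "e2->e3"))
})

test_that("a path of n single-event nodes yields C(n,2) pairs, C(n,3) triples", {
  for (n in 2:6) {
    tree <- make_tree(seq(1, 0.2, length.out = n), c(0, seq_len(n - 1)),
                      events = as.list(paste0("e", 1:n)))
    tr <- extract_trajectories(tree)
    len <- lengths(strsplit(tr, "->", fixed = TRUE))
    expect_equal(sum(len == 2), choose(n, 2))
    expect_equal(sum(len == 3), choose(n, 3))
  }
})

test_that("frequency filter is inclusive at 10% / 5%", {
  tree_with <- make_tree(c(1.0, 0.5), c(0, 1), events = list("X", "Y"))
  tree_without <- make_tree(1.0, 0, events = list("Z"))
  trees10 <- c(list(tree_with), rep(list(tree_without), 9))
  out <- trajectory_frequencies(trees10)
  expect_true("X->Y" %in% out$trajectory)   # exactly 10%: retained
  trees20 <- c(list(tree_with), rep(list(tree_without), 19))
  out <- trajectory_frequencies(trees20)
  expect_false("X->Y" %in% out$trajectory)  # 5% < 10%: dropped
  triple <- make_tree(c(1.0, 0.6, 0.3), c(0, 1, 2),
                      events = list("X", "Y", "W"))
  trees_t <- c(list(triple), rep(list(tree_without), 19))
  out <- trajectory_frequencies(trees_t)
  expect_true("X->Y->W" %in% out$trajectory)  # exactly 5%: retained
})

test_that("forced placements reproduce the exact binomial tail", {
  # 10 trees, each with X alone in the root and Y alone in the child:
  # a label shuffle keeps or swaps them with probability 1/2, so the null
  # cohort support is Binomial(10, 1/2) and P(support >= 10) = 2^-10
  trees <- replicate(10, make_tree(c(1.0, 0.5), c(0, 1),
                                   events = list("X", "Y")),
                     simplify = FALSE)
  res <- trajectory_permutation_test(trees, trajectories = "X->Y",
                                     n_perm = 4000, seed = 9)
  expect_equal(res$support, 10L)
  exact <- 2^-10
  # Monte Carlo estimate with the +1 correction stays near the exact tail
  expect_lt(res$p_value, 0.005)
  expect_gt(res$p_value, exact / 10)
  # determinism
  res2 <- trajectory_permutation_test(trees, trajectories = "X->Y",
                                      n_perm = 4000, seed = 9)
  expect_identical(res, res2)
  expect_error(trajectory_permutation_test(trees, "X->Y", n_perm = 50),
               "minimum")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  p <- c(0.001, 0.02, 0.04, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("nested levels count 1-based depth from the founding clone", {
  flat <- make_tree(1.0, 0, events = list(c("a", "b", "c")))
  lv <- nested_levels(flat)
  expect_true(all(lv == 1))
  expect_equal(attr(lv, "tree_level"), 1)
  chain <- make_tree(c(1, 0.8, 0.6, 0.4), c(0, 1, 2, 3),
                     events = list("a", "b", "c", "d"))
  lv <- nested_levels(chain)
  expect_equal(attr(lv, "tree_level"), 4)
  expect_equal(unname(lv[c("a", "c")]), c(1, 3))
})

test_that("weighted nested level matches hand-computed weighting", {
  t1 <- make_tree(c(1, 0.7, 0.4), c(0, 1, 2),
                  events = list("del_in_9p", "x", "y"))       # depth 3, 3 events
  t2 <- make_tree(c(1, 0.8, 0.6, 0.3), c(0, 1, 2, 3),
                  events = list("del_in_9p", "x", "y", "z"))  # depth 4, 4 events
  out <- weighted_nested_level(list(t1, t2), scope = "tree")
  expect_equal(out$value, (3 * 3 + 4 * 4) / 7)
  # equal event counts: plain mean
  t3 <- make_tree(c(1, 0.5), c(0, 1), events = list("a", "b"))
  t4 <- make_tree(c(1, 0.6, 0.4, 0.2), c(0, 1, 2, 3),
                  events = list(c("a", "b"), "c", "d", character(0)))
  expect_equal(weighted_nested_level(list(t3, t4), scope = "tree")$value,
               (2 * 2 + 4 * 4) / 6)
  # event-class scope: mean acquisition level of matching occurrences
  cls <- weighted_nested_level(list(t1, t2), scope = "event_class",
                               event_class = "^(del|LOH)_in_9p$")
  expect_equal(cls$value, 1)
  expect_error(weighted_nested_level(list(t1), scope = "event_class",
                                     event_class = "^dup20$"), "dup20")
})

test_that("the planted bias is detected far more often than in null cohorts", {
  cfg_b <- sim_config(identifiable = FALSE)
  trees <- lapply(1:40, function(i) {
    simulate_tree(cfg_b, "pediatric T-ALL",
                  patient_seed = substream_seed(606, i))$tree
  })
  res <- trajectory_permutation_test(trees, n_perm = 999, seed = 1)
  row <- res[res$trajectory == "LOH_in_9p->NOTCH1", ]
  expect_equal(nrow(row), 1)
  expect_lt(row$p_adjusted, 0.05)
})
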