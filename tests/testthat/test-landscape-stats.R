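# Burden summaries, age association and density normalization, mutual
# exclusivity, and the binned CNV frequency track.

make_clinical <- function(n, subgroup = "pediatric T-ALL") {
  parts <- strsplit(subgroup, " ")[[1]]
  data.frame(patient_id = paste0("P", seq_len(n)),
             entity = parts[2], age_group = parts[1],
             age_years = seq(5, 15, length.out = n),
             relapsed = FALSE, time_to_event_days = 1000,
             event_observed = FALSE,
             subgroup = subgroup, stringsAsFactors = FALSE)
}

test_that("burden summary gives per-subgroup mean and sd at primary samples", {
  clin <- make_clinical(2)
  calls <- data.frame(patient_id = c("P1", "P1", "P2", "P2", "P2", "P2"),
                      timepoint = 0L, gene = paste0("G", 1:6))
  out <- mutation_burden_summary(calls, clin)
  expect_equal(out$mean_snv, 3.0)
  expect_equal(out$sd_snv, sqrt(2))
  # relapse-sample variants are not counted in the primary burden
  calls2 <- rbind(calls, data.frame(patient_id = "P1", timepoint = 300L,
                                    gene = "G9"))
  expect_equal(mutation_burden_summary(calls2, clin)$mean_snv, 3.0)
  # single-patient subgroup: sd 0, flagged
  out1 <- mutation_burden_summary(calls[1:2, ], make_clinical(1))
  expect_equal(out1$sd_snv, 0)
  expect_true(out1$degenerate_sd)
  # Poisson sampling check
  set.seed(8)
  n <- 500
  clin_n <- make_clinical(n)
  burdens <- rpois(n, 3)
  calls_n <- data.frame(
    patient_id = rep(clin_n$patient_id, burdens),
    timepoint = 0L,
    gene = paste0("G", sequence(burdens))
  )
  out_n <- mutation_burden_summary(calls_n, clin_n)
  expect_lt(abs(out_n$mean_snv - 3), 3 * sqrt(3 / n))
})

test_that("age association reproduces the exact rank-sum case", {
  mat <- matrix(c(rep(TRUE, 3), rep(FALSE, 3)), 1,
                dimnames = list("G1", paste0("P", 1:6)))
  ages <- setNames(c(30, 35, 40, 5, 6, 7), paste0("P", 1:6))
  out <- gene_age_association(mat, ages, min_freq = 0.05)
  # fully separated ranks: two-sided exact p = 2 / C(6,3)
  expect_equal(out$p_value, 2 / choose(6, 3), tolerance = 1e-12)
  # frequency gate: a 4%-mutated gene is excluded at min_freq 5%
  mat2 <- matrix(c(TRUE, rep(FALSE, 24)), 1,
                 dimnames = list("G1", paste0("P", 1:25)))
  ages2 <- setNames(runif(25, 5, 60), paste0("P", 1:25))
  expect_equal(nrow(gene_age_association(mat2, ages2, min_freq = 0.05)), 0)
  # all-mutated genes are skipped with a note
  mat3 <- rbind(G1 = rep(TRUE, 6), G2 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  colnames(mat3) <- paste0("P", 1:6)
  out3 <- gene_age_association(mat3, ages)
  expect_equal(out3$gene, "G2")
  expect_true("G1" %in% attr(out3, "skipped"))
})

test_that("age-density normalization is flat when mutated ages mirror all", {
  set.seed(2)
  ages <- c(rgamma(150, 3, scale = 3), 18 + rgamma(150, 2, scale = 8))
  curve <- age_density_curve(ages, ages)
  expect_lt(max(curve$density) / min(curve$density), 1.05)
  # mutated only in the upper half: the ratio is higher there
  old <- ages[ages > median(ages)]
  curve2 <- age_density_curve(old, ages)
  upper <- curve2$grid > median(ages)
  expect_gt(mean(curve2$density[upper]), mean(curve2$density[!upper]))
  # doubling the bandwidth smooths the curve (total variation decreases)
  tv <- function(y) sum(abs(diff(y)))
  bw <- curve2$bandwidth
  curve3 <- age_density_curve(old, ages, bandwidth = 2 * bw)
  expect_lt(tv(curve3$density), tv(curve2$density))
  expect_error(age_density_curve(ages[1], ages), "at least 2")
})

test_that("mutual exclusivity odds ratios and symmetries", {
  mk <- function(n11, n10, n01, n00) {
    n <- n11 + n10 + n01 + n00
    a <- c(rep(TRUE, n11 + n10), rep(FALSE, n01 + n00))
    b <- c(rep(TRUE, n11), rep(FALSE, n10), rep(TRUE, n01), rep(FALSE, n00))
    m <- rbind(A = a, B = b)
    colnames(m) <- paste0("P", seq_len(n))
    m
  }
  m <- mk(1, 9, 9, 1)
  out <- mutual_exclusivity(m, "A", "B")
  expect_equal(out$odds_ratio, 1 / 81)
  expect_equal(unname(out$counts["n11"]), 1)
  # symmetric under swapping genes
  expect_equal(mutual_exclusivity(m, "B", "A")$odds_ratio, out$odds_ratio)
  expect_equal(mutual_exclusivity(m, "B", "A")$p_value, out$p_value)
  # symmetric under simultaneous negation of both indicators
  m_neg <- !m
  expect_equal(mutual_exclusivity(m_neg, "A", "B")$odds_ratio, out$odds_ratio)
  # n11 = 0 reports OR 0 (complete exclusivity)
  out0 <- mutual_exclusivity(mk(0, 10, 10, 5), "A", "B")
  expect_equal(out0$odds_ratio, 0)
  expect_false(out0$or_infinite)
  # vanishing denominator with n11 > 0 is flagged infinite
  outI <- mutual_exclusivity(mk(5, 0, 0, 5), "A", "B")
  expect_true(outI$or_infinite)
  # calibration: independent genes reject at ~5%
  set.seed(5)
  rej <- mean(replicate(400, {
    m2 <- rbind(A = runif(40) < 0.5, B = runif(40) < 0.5)
    colnames(m2) <- paste0("P", 1:40)
    mutual_exclusivity(m2, "A", "B")$p_value <= 0.05
  }))
  expect_lt(rej, 0.08)
})

test_that("CNV track frequencies are length-weighted and split-invariant", {
  pats <- paste0("P", 1:4)
  arm9p <- genome_arm_table()$centromere[genome_arm_table()$chrom == "9"]
  seg <- data.frame(patient_id = "P1", sample_id = "S", timepoint = 0L,
                    chrom = "9", start = 1, end = arm9p, cn = 1L, loh = FALSE)
  expect_equal(cnv_arm_frequency(seg, pats, "9", "p", "del"), 0.25,
               tolerance = 0.01)
  # half the arm deleted in one of four patients (1 Mb bin resolution)
  seg_half <- seg; seg_half$end <- floor(arm9p / 2)
  expect_lt(abs(cnv_arm_frequency(seg_half, pats, "9", "p", "del") - 0.125),
            0.005)
  # splitting a segment into abutting pieces changes nothing
  seg_split <- rbind(seg, seg)
  seg_split$end[1] <- 20e6; seg_split$start[2] <- 20e6 + 1
  t1 <- cnv_frequency_track(seg, pats)
  t2 <- cnv_frequency_track(seg_split, pats)
  expect_equal(t1, t2)
  expect_true(all(t1$frequency <= 1))
  expect_error(cnv_frequency_track(transform(seg, chrom = "chrZ"), pats),
               "unknown chromosome")
})

test_that("co-occurrence rates count patients with both events", {
  pe <- list(P1 = c("NOTCH1", "del_in_9p"), P2 = c("NOTCH1"),
             P3 = c("NOTCH1", "del_in_9p"), P4 = "PTEN", P5 = character(0))
  expect_equal(cooccurrence_rate(pe, "NOTCH1", "del_in_9p"), 0.4)
  expect_equal(cooccurrence_rate(pe, "NOTCH1", "dup20"), 0)
  # identical event lists: rate equals each event's frequency
  pe2 <- list(P1 = c("A", "B"), P2 = c("A", "B"), P3 = character(0))
  expect_equal(cooccurrence_rate(pe2, "A", "B"), 2 / 3)
})
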