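# Cohort-level mutational-landscape statistics: burden summaries, age
# associations, age-normalized mutation density, mutual exclusivity, and
# length-weighted copy-number frequency tracks.

#' Per-subgroup mutation burden summary
#'
#' Mean and SD of the number of distinct small variants (and, when segments
#' are given, CNV segments) per patient, using each patient's primary
#' sample (earliest timepoint). Patients without calls count as zero
#' burden. Subgroups with a single patient report SD 0 with a flag.
#'
#' @param calls Variant calls (as from [read_variant_table()]).
#' @param clinical Clinical table (as from [read_clinical_table()]).
#' @param segments Optional CNV segments for the CNV counterpart.
#' @return data.frame with `subgroup`, `n_patients`, `mean_snv`, `sd_snv`,
#'   and (with segments) `mean_cnv`, `sd_cnv`, plus `degenerate_sd` flag.
#' @export
mutation_burden_summary <- function(calls, clinical, segments = NULL) {
  primary_counts <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(integer(0))
    split_rows <- split(df, df$patient_id)
    vapply(split_rows, function(d) {
      sum(d$timepoint == min(d$timepoint))
    }, integer(1))
  }
  snv <- primary_counts(calls)
  cnv <- primary_counts(segments)
  out <- list()
  for (sg in unique(clinical$subgroup)) {
    pats <- clinical$patient_id[clinical$subgroup == sg]
    if (length(pats) == 0) { warn_fmt("subgroup '%s' has 0 patients; omitted", sg); next }
    s <- unname(snv[pats]); s[is.na(s)] <- 0L
    row <- data.frame(subgroup = sg, n_patients = length(pats),
                      mean_snv = mean(s),
                      sd_snv = if (length(pats) > 1) sd(s) else 0,
                      degenerate_sd = length(pats) == 1)
    if (!is.null(segments)) {
      cc <- unname(cnv[pats]); cc[is.na(cc)] <- 0L
      row$mean_cnv <- mean(cc)
      row$sd_cnv <- if (length(pats) > 1) sd(cc) else 0
    }
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}

#' Gene-by-patient mutation indicator matrix
#'
#' @param calls Variant calls.
#' @param clinical Clinical table (defines the patient universe).
#' @return Logical matrix, genes x patients.
#' @export
gene_mutation_matrix <- function(calls, clinical) {
  genes <- sort(unique(calls$gene))
  pats <- clinical$patient_id
  m <- matrix(FALSE, length(genes), length(pats),
              dimnames = list(genes, pats))
  hit <- unique(calls[calls$patient_id %in% pats, c("gene", "patient_id")])
  m[cbind(hit$gene, hit$patient_id)] <- TRUE
  m
}

#' Age association of gene mutations
#'
#' For each gene mutated in at least `min_freq` of the tested patients, a
#' two-sided Wilcoxon rank-sum test compares ages of mutated vs
#' non-mutated patients; p-values are BH-adjusted over the tested genes.
#' Genes mutated in all or none of the patients are skipped with a note.
#'
#' @param mat Logical gene x patient matrix (see [gene_mutation_matrix()]).
#' @param ages Named numeric vector of ages (names = patient ids).
#' @param min_freq Minimum mutation frequency (default 0.05, inclusive).
#' @return data.frame with `gene`, `n_mutated`, `frequency`, `p_value`,
#'   `p_adjusted`, plus attribute `skipped`.
#' @export
gene_age_association <- function(mat, ages, min_freq = 0.05) {
  pats <- colnames(mat)
  stopifnot(all(pats %in% names(ages)))
  ages <- ages[pats]
  freq <- rowMeans(mat)
  tested <- rownames(mat)[freq >= min_freq & freq < 1 & freq > 0]
  skipped <- setdiff(rownames(mat)[freq == 0 | freq == 1], tested)
  rows <- lapply(tested, function(g) {
    mut <- mat[g, ]
    p <- suppressWarnings(wilcox.test(ages[mut], ages[!mut],
                                      alternative = "two.sided")$p.value)
    data.frame(gene = g, n_mutated = sum(mut), frequency = freq[[g]],
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), n_mutated = integer(0),
               frequency = numeric(0), p_value = numeric(0))
  out$p_adjusted <- bh_adjust(out$p_value)
  attr(out, "skipped") <- skipped
  out
}

#' Age-normalized mutation density curve
#'
#' Gaussian kernel density of the ages of mutated patients divided
#' pointwise by the density of all patients' ages (same bandwidth,
#' Silverman's rule by default), i.e. mutation density normalized for the
#' baseline age distribution. The baseline is floored at `1e-6` of its
#' maximum; grid points below the floor are flagged.
#'
#' @param mutated_ages Ages of mutated patients (at least 2).
#' @param all_ages Ages of all patients.
#' @param grid Evaluation grid (default: 128 points spanning `all_ages`).
#' @param bandwidth Kernel bandwidth (default: Silverman on `all_ages`).
#' @return A list with `grid`, `density` (normalized ratio), `bandwidth`,
#'   `flagged` (logical per grid point: baseline under floor).
#' @export
age_density_curve <- function(mutated_ages, all_ages, grid = NULL,
                              bandwidth = NULL) {
  if (length(mutated_ages) < 2) {
    stop_fmt("need at least 2 mutated patients for a density curve")
  }
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(all_ages)
  if (is.null(grid)) {
    grid <- seq(min(all_ages), max(all_ages), length.out = 128)
  }
  eval_kde <- function(xs) {
    d <- density(xs, bw = bandwidth, from = min(grid), to = max(grid),
                 n = length(grid))
    d$y
  }
  num <- eval_kde(mutated_ages)
  den <- eval_kde(all_ages)
  floor_val <- 1e-6 * max(den)
  flagged <- den < floor_val
  den <- pmax(den, floor_val)
  list(grid = grid, density = num / den, bandwidth = bandwidth,
       flagged = flagged)
}

#' Mutual exclusivity of two genes
#'
#' Builds the 2x2 contingency table of mutation indicators over the given
#' patients, reports the sample odds ratio `(n11*n00)/(n10*n01)` (0 when
#' `n11 = 0`; flagged infinite when the denominator vanishes with
#' `n11 > 0`) and the two-sided Fisher exact p-value. Reported unadjusted:
#' exclusivity screens are exploratory.
#'
#' @param mat Logical gene x patient matrix.
#' @param gene_a,gene_b Gene names (rows of `mat`).
#' @param patients Optional subset of patient ids (default: all columns).
#' @return A list with `odds_ratio`, `or_infinite`, `p_value`, `counts`
#'   (n11, n10, n01, n00).
#' @export
mutual_exclusivity <- function(mat, gene_a, gene_b, patients = NULL) {
  if (is.null(patients)) patients <- colnames(mat)
  if (length(patients) == 0) stop_fmt("empty patient set")
  stopifnot(gene_a %in% rownames(mat), gene_b %in% rownames(mat))
  a <- mat[gene_a, patients]; b <- mat[gene_b, patients]
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b); n00 <- sum(!a & !b)
  or <- if (n11 == 0) 0
        else if (n10 * n01 == 0) Inf
        else (n11 * n00) / (n10 * n01)
  p <- fisher.test(matrix(c(n11, n01, n10, n00), 2))$p.value
  list(odds_ratio = or, or_infinite = is.infinite(or), p_value = p,
       counts = c(n11 = n11, n10 = n10, n01 = n01, n00 = n00))
}

#' Binned copy-number frequency track
#'
#' Partitions each chromosome into fixed-width bins and reports, per bin
#' and CNV class (del / LOH / dup), the fraction of patients with at least
#' one overlapping segment of that class. Abutting or split segments of
#' one patient are counted once per bin.
#'
#' @param segments CNV segments of one patient set (primary samples).
#' @param patients Character vector: the denominator patient set.
#' @param bin_size Bin width in bp (default 1e6).
#' @param build Genome build.
#' @return data.frame with `chrom`, `start`, `end`, `class`, `frequency`.
#' @export
cnv_frequency_track <- function(segments, patients, bin_size = 1e6,
                                build = "GRCh38") {
  arms <- genome_arm_table(build)
  bad <- setdiff(unique(normalize_chrom(segments$chrom)), arms$chrom)
  if (length(bad) > 0) stop_fmt("unknown chromosome '%s'", bad[1])
  segments <- segments[segments$patient_id %in% patients, , drop = FALSE]
  segments$class <- cnv_class_from_cn(segments$cn, segments$loh)
  segments <- segments[segments$class != "neutral", , drop = FALSE]
  rows <- list()
  for (ch in unique(normalize_chrom(segments$chrom))) {
    len <- arms$length[arms$chrom == ch]
    n_bins <- ceiling(len / bin_size)
    seg_ch <- segments[normalize_chrom(segments$chrom) == ch, , drop = FALSE]
    for (cls in unique(seg_ch$class)) {
      seg_c <- seg_ch[seg_ch$class == cls, , drop = FALSE]
      hit <- matrix(FALSE, n_bins, length(patients),
                    dimnames = list(NULL, patients))
      for (r in seq_len(nrow(seg_c))) {
        b1 <- floor((seg_c$start[r] - 1) / bin_size) + 1
        b2 <- min(n_bins, floor((seg_c$end[r] - 1) / bin_size) + 1)
        hit[b1:b2, seg_c$patient_id[r]] <- TRUE
      }
      freq <- rowMeans(hit)
      nz <- which(freq > 0)
      if (length(nz) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch,
        start = (nz - 1) * bin_size + 1,
        end = pmin(nz * bin_size, len),
        class = cls, frequency = freq[nz], stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0),
                      frequency = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Length-weighted arm frequency of a CNV class
#'
#' The arm-level weighted frequency: the length-weighted mean of per-bin
#' patient frequencies over all bins of one chromosome arm (bins without
#' any segment contribute zero).
#'
#' @inheritParams cnv_frequency_track
#' @param chrom Chromosome (e.g. `"9"`).
#' @param arm `"p"` or `"q"`.
#' @param class `"del"`, `"LOH"` or `"dup"`.
#' @return Single frequency in `[0,1]`.
#' @export
cnv_arm_frequency <- function(segments, patients, chrom, arm,
                              class = "del", bin_size = 1e6,
                              build = "GRCh38") {
  arms <- genome_arm_table(build)
  row <- arms[arms$chrom == normalize_chrom(chrom), ]
  if (nrow(row) == 0) stop_fmt("unknown chromosome '%s'", chrom)
  arm_start <- if (arm == "p") 1 else row$centromere + 1
  arm_end <- if (arm == "p") row$centromere else row$length
  track <- cnv_frequency_track(segments, patients, bin_size, build)
  track <- track[track$chrom == normalize_chrom(chrom) &
                   track$class == class, , drop = FALSE]
  # clip bins to the arm; weight by covered width
  total_w <- arm_end - arm_start + 1
  if (nrow(track) == 0) return(0)
  w <- pmax(0, pmin(track$end, arm_end) - pmax(track$start, arm_start) + 1)
  sum(w * track$frequency) / total_w
}

#' Co-occurrence rate of two events
#'
#' Fraction of patients harboring both events (in any clone or sample of
#' the primary disease).
#'
#' @param patient_events Named list: per patient, character vector of event
#'   labels.
#' @param event_a,event_b Event labels.
#' @return Fraction in `[0,1]`.
#' @export
cooccurrence_rate <- function(patient_events, event_a, event_b) {
  if (length(patient_events) == 0) return(0)
  mean(vapply(patient_events, function(ev) {
    event_a %in% ev && event_b %in% ev
  }, logical(1)))
}
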