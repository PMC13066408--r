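# Synthetic cohort generator: ground-truth clone trees with planted
# trajectory biases, noisy panel-sequencing reads, allele-specific array
# signals, and relapse outcomes whose log-hazard is linear in the
# NOTCH1-wild-type tumor fraction. Every downstream stage of the pipeline
# is testable against this generator without access to patient data.

SUBGROUPS <- c("pediatric T-ALL", "adult T-ALL", "pediatric T-LBL",
               "adult T-LBL")

#' Default event vocabulary with per-subgroup inclusion probabilities
#'
#' Gene and CNV labels mirroring the recurrently altered loci of T-cell
#' lymphoblastic neoplasia, with per-subgroup per-patient inclusion
#' probabilities chosen to match reported cohort frequencies (e.g. NOTCH1
#' mutated in ~78% of pediatric vs ~61% of adult T-ALL; chr9p deletions
#' more frequent in pediatric patients; dup20 concentrated in pediatric
#' T-LBL).
#'
#' @return data.frame with columns `label`, `kind`, and one probability
#'   column per subgroup.
#' @export
default_vocabulary <- function() {
  df <- data.frame(
    label = c("NOTCH1", "PHF6", "FBXW7", "PTEN", "BCL11B", "USP7", "KMT2D",
              "TP53", "del_in_9p", "LOH_in_9p", "dup_in_9p", "dup20",
              "del_in_6q"),
    kind = c(rep("gene", 8), rep("cnv", 5)),
    stringsAsFactors = FALSE
  )
  # chr9p deletion/LOH inclusion probabilities are anchored so that the
  # implied co-presence with NOTCH1 matches reported patient-level
  # co-occurrence (pediatric T-ALL: del 38.7%, LOH 35.5%; pediatric T-LBL:
  # del 15%, LOH 19%)
  df[["pediatric T-ALL"]] <- c(0.78, 0.19, 0.16, 0.18, 0.12, 0.08, 0.06,
                               0.05, 0.50, 0.46, 0.08, 0.05, 0.04)
  df[["adult T-ALL"]]     <- c(0.61, 0.37, 0.14, 0.10, 0.10, 0.06, 0.08,
                               0.06, 0.28, 0.25, 0.06, 0.05, 0.04)
  df[["pediatric T-LBL"]] <- c(0.60, 0.13, 0.18, 0.20, 0.10, 0.15, 0.08,
                               0.05, 0.25, 0.32, 0.15, 0.15, 0.05)
  df[["adult T-LBL"]]     <- c(0.49, 0.34, 0.12, 0.10, 0.08, 0.08, 0.17,
                               0.06, 0.21, 0.18, 0.06, 0.05, 0.04)
  df
}

# fixed fake panel loci for gene labels (GRCh38-like positions)
gene_locus_table <- function() {
  data.frame(
    gene = c("NOTCH1", "PHF6", "FBXW7", "PTEN", "BCL11B", "USP7", "KMT2D",
             "TP53"),
    chrom = c("9", "X", "4", "10", "14", "16", "12", "17"),
    pos = c(136503000, 134373000, 152328000, 87933000, 99272000, 8985000,
            49030000, 7675000),
    stringsAsFactors = FALSE
  )
}

# genomic regions emitted for CNV labels
cnv_region_table <- function() {
  data.frame(
    label = c("del_in_9p", "LOH_in_9p", "dup_in_9p", "dup20", "del_in_6q"),
    chrom = c("9", "9", "9", "20", "6"),
    start = c(1, 1, 1, 1, 62000000),
    end = c(39000000, 39000000, 39000000, 64444167, 170805979),
    cn = c(1L, 2L, 3L, 3L, 1L),
    loh = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults encode the
#' study conditions the package emulates: four subgroups (pediatric/adult x
#' T-ALL/T-LBL), clone trees of 1-8 clones over 1-4 timepoints, panel depth
#' 500x, and a planted relapse hazard ratio of 1.032 per percentage point
#' of NOTCH1-wild-type tumor fraction.
#'
#' @param n_per_subgroup Patients per subgroup (single integer or named
#'   vector over subgroups; default 50).
#' @param seed Master seed; all per-patient randomness derives from it.
#' @param clones_range Range of clones per tree (default `c(1, 8)`).
#' @param timepoint_probs Probabilities for 1..4 sampling timepoints.
#' @param vocabulary Event vocabulary (see [default_vocabulary()]).
#' @param trajectory_bias List of biases, each
#'   `list(from=, to=, mult=, subgroup=)`; default plants a 10x bias on
#'   `LOH_in_9p -> NOTCH1` in both pediatric subgroups.
#' @param mean_depth Mean panel depth (default 500).
#' @param purity_range Uniform purity range (default `c(0.7, 1)`).
#' @param baf_sd,logr_sd Gaussian noise SDs for the array signal.
#' @param hazard_beta Log-hazard per percentage point of NOTCH1-wild-type
#'   fraction (default `log(1.032)`).
#' @param baseline_hazard Baseline event rate per day (default 2e-4).
#' @param censoring_rate Independent exponential censoring rate per day.
#' @param ccf_gap Minimum CCF separation between any two clones at their
#'   most distinct timepoint (default 0.15).
#' @param read_noise,signal_noise Logical switches for binomial read noise
#'   and Gaussian array noise (both TRUE by default).
#' @param identifiable Rejection-sample truth trees until the clone
#'   architecture is the unique sum-rule-consistent tree given its CCFs
#'   (default TRUE; see the methods vignette).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_subgroup = 50, seed = 1,
                       clones_range = c(1, 8),
                       timepoint_probs = c(0.55, 0.25, 0.15, 0.05),
                       vocabulary = default_vocabulary(),
                       trajectory_bias = list(
                         list(from = "LOH_in_9p", to = "NOTCH1", mult = 10,
                              subgroup = "pediatric T-ALL"),
                         list(from = "LOH_in_9p", to = "NOTCH1", mult = 10,
                              subgroup = "pediatric T-LBL")
                       ),
                       mean_depth = 500, purity_range = c(0.7, 1),
                       baf_sd = 0.01, logr_sd = 0.05,
                       hazard_beta = log(1.032), baseline_hazard = 2e-4,
                       censoring_rate = 2.5e-4, ccf_gap = 0.15,
                       read_noise = TRUE, signal_noise = TRUE,
                       identifiable = TRUE) {
  if (length(n_per_subgroup) == 1) {
    n_per_subgroup <- setNames(rep(n_per_subgroup, 4), SUBGROUPS)
  }
  stopifnot(all(SUBGROUPS %in% names(n_per_subgroup)),
            clones_range[1] >= 1, clones_range[2] <= 8,
            clones_range[1] <= clones_range[2],
            length(timepoint_probs) == 4, all(timepoint_probs >= 0),
            sum(timepoint_probs) > 0,
            mean_depth > 0, purity_range[1] > 0, purity_range[2] <= 1,
            baf_sd > 0, logr_sd > 0, baseline_hazard > 0,
            censoring_rate > 0, ccf_gap > 0, ccf_gap < 1)
  if (nrow(vocabulary) == 0) stop_fmt("event vocabulary must be nonempty")
  stopifnot(all(SUBGROUPS %in% names(vocabulary)))
  structure(list(
    n_per_subgroup = n_per_subgroup, seed = seed,
    clones_range = clones_range, timepoint_probs = timepoint_probs,
    vocabulary = vocabulary, trajectory_bias = trajectory_bias,
    mean_depth = mean_depth, purity_range = purity_range,
    baf_sd = baf_sd, logr_sd = logr_sd, hazard_beta = hazard_beta,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    ccf_gap = ccf_gap, read_noise = read_noise, signal_noise = signal_noise,
    identifiable = identifiable
  ), class = "sim_config")
}

#' Simulate one patient's ground-truth clone tree
#'
#' Draws a rooted clone topology and per-timepoint CCFs that satisfy the
#' sum rule exactly, with every pair of clones separated by at least
#' `ccf_gap` at some timepoint. When `identifiable = TRUE` the draw is
#' rejected until the architecture is the unique sum-rule-consistent tree
#' given its CCFs (single-timepoint patients then receive linear
#' architectures of at most five clones, since deeper or branched
#' structures are not identifiable from one sample). Event labels are
#' assigned to clones from the vocabulary, with `trajectory_bias`
#' multipliers favoring placement of the `to` label in clones descended
#' from the `from` label.
#'
#' @param config A [sim_config()].
#' @param subgroup One of the four subgroup names.
#' @param patient_seed Integer seed for this patient's substream.
#' @param patient_id Identifier used in the truth record.
#' @return A truth record: list with `patient_id`, `subgroup`, `tree`
#'   (a `clone_tree` whose node events are labels), `timepoints`, `purity`
#'   (per timepoint), `covariate_pct` (NOTCH1-wild-type fraction at
#'   diagnosis).
#' @export
simulate_tree <- function(config, subgroup, patient_seed = config$seed,
                          patient_id = "P1") {
  stopifnot(inherits(config, "sim_config"), subgroup %in% SUBGROUPS)
  set.seed(patient_seed)
  n_tp <- sample.int(4, 1, prob = config$timepoint_probs)
  timepoints <- round(c(0, 300, 700, 1100)[seq_len(n_tp)] +
                        c(0, runif(max(0, n_tp - 1), -50, 50)))
  k <- sample(seq(config$clones_range[1], config$clones_range[2]), 1)
  if (n_tp == 1) k <- min(k, 5L)
  draw <- draw_tree_structure(k, n_tp, config)
  k <- draw$k
  labels <- draw_patient_labels(config, subgroup, k)
  assign <- assign_labels_to_nodes(labels, draw$parent, k, config, subgroup)
  nodes <- lapply(seq_len(k), function(i) {
    list(node_id = paste0("T", i),
         parent_id = if (draw$parent[i] == 0) NA_character_ else paste0("T", draw$parent[i]),
         events = assign$events[[i]],
         ccf = setNames(draw$ccf[i, ], as.character(timepoints)))
  })
  tree <- clone_tree(patient_id, nodes, timepoints)
  purity <- runif(n_tp, config$purity_range[1], config$purity_range[2])
  truth <- list(patient_id = patient_id, subgroup = subgroup, tree = tree,
                timepoints = timepoints, purity = setNames(purity, as.character(timepoints)))
  truth$covariate_pct <- notch_wt_fraction(tree, timepoint = timepoints[1])
  truth
}

# Draw topology + CCFs, rejection-sampling for clone separation and (when
# requested) identifiability. Falls back to fewer clones if no draw passes.
draw_tree_structure <- function(k, n_tp, config) {
  eps <- 0.05
  for (k_try in seq(k, 1)) {
    for (topo_try in 1:30) {
      parent <- if (n_tp == 1 || k_try == 1) {
        c(0L, seq_len(max(0, k_try - 1)))  # linear chain
      } else {
        c(0L, vapply(seq_len(k_try - 1), function(i) sample.int(i, 1), integer(1)))
      }
      for (ccf_try in 1:40) {
        ccf <- draw_ccfs(parent, n_tp, config$ccf_gap)
        if (is.null(ccf)) next
        if (config$identifiable &&
            count_valid_trees(ccf, epsilon = eps, stop_at = 2L) != 1L) next
        return(list(parent = parent, ccf = ccf, k = k_try))
      }
    }
  }
  stop_fmt("could not draw a valid clone architecture")  # unreachable: k=1 always works
}

draw_ccfs <- function(parent, n_tp, ccf_gap) {
  k <- length(parent)
  ccf <- matrix(0, k, n_tp)
  ccf[1, ] <- runif(n_tp, 0.95, 1)
  # Children of a node with several children split most of its CCF (the
  # siblings separate each other). A single child is separated from its
  # parent at one designated timepoint (a clone sweep/regression leaves a
  # window where the parent lineage is visible on its own); elsewhere the
  # child nearly exhausts the parent, which keeps the architecture
  # identifiable (no slack for foreign clones to attach).
  for (p in seq_len(k)) {
    kids <- which(parent == p)
    if (length(kids) == 0) next
    t_sep <- sample.int(n_tp, 1)
    for (t in seq_len(n_tp)) {
      leftover <- if (length(kids) == 1 && (t == t_sep || n_tp == 1)) {
        runif(1, ccf_gap + 0.005, ccf_gap + 0.05)
      } else {
        runif(1, 0.005, 0.05)
      }
      mass <- max(ccf[p, t] - leftover, 0)
      shares <- rgamma(length(kids), shape = 1.2)
      ccf[kids, t] <- mass * shares / sum(shares)
    }
  }
  # every clone must reach ccf_gap somewhere (it is observable) and every
  # clone pair must separate by ccf_gap at some timepoint
  if (k > 1 && any(apply(ccf, 1, max) < ccf_gap)) return(NULL)
  if (k > 1) {
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (max(abs(ccf[a, ] - ccf[b, ])) < ccf_gap) return(NULL)
    }
  }
  round(ccf, 6)
}

draw_patient_labels <- function(config, subgroup, k) {
  vocab <- config$vocabulary
  p <- vocab[[subgroup]]
  present <- runif(nrow(vocab)) < p
  labels <- vocab$label[present]
  # need at least one event per clone
  while (length(labels) < k) {
    pool <- setdiff(vocab$label, labels)
    if (length(pool) == 0) break
    w <- p[match(pool, vocab$label)]
    labels <- c(labels, sample(pool, 1, prob = w))
  }
  labels
}

# Assign labels to nodes. Biased (from, to) label pairs are placed jointly:
# the ordered node arrangement weight is multiplied by `mult` whenever the
# `from` node is a strict ancestor of the `to` node, which is the planted
# enrichment the trajectory test is meant to detect. Remaining labels are
# placed uniformly; a repair step then moves spare labels so every clone
# acquires at least one event, never touching biased-pair labels first.
assign_labels_to_nodes <- function(labels, parent, k, config, subgroup) {
  anc <- ancestor_matrix(parent)
  biases <- Filter(function(b) {
    b$subgroup == subgroup && all(c(b$from, b$to) %in% labels)
  }, config$trajectory_bias)
  node_of <- setNames(integer(length(labels)), labels)
  protected <- character(0)
  for (b in biases) {
    if (node_of[b$from] > 0 || node_of[b$to] > 0) next  # label already placed
    grid <- expand.grid(na = seq_len(k), nb = seq_len(k))
    w <- ifelse(anc[cbind(grid$na, grid$nb)], b$mult, 1)
    pick <- grid[sample.int(nrow(grid), 1, prob = w), ]
    node_of[b$from] <- pick$na
    node_of[b$to] <- pick$nb
    protected <- c(protected, b$from, b$to)
  }
  rest <- names(node_of)[node_of == 0]
  node_of[rest] <- sample.int(k, length(rest), replace = TRUE)
  # repair: every clone acquires at least one event
  empty <- setdiff(seq_len(k), unique(node_of))
  for (node in empty) {
    multi <- node_of %in% node_of[duplicated(node_of)]
    donors <- setdiff(names(node_of)[multi], protected)
    if (length(donors) == 0) donors <- names(node_of)[multi]
    if (length(donors) == 0) break
    mv <- donors[sample.int(length(donors), 1)]
    node_of[mv] <- node
  }
  list(events = lapply(seq_len(k), function(i) names(node_of)[node_of == i]),
       node_of = node_of)
}

#' Simulate panel-sequencing reads for a truth record
#'
#' For each gene event and timepoint, the expected VAF follows the forward
#' model of [expected_vaf()] (diploid locus, multiplicity 1); observed
#' depth is Poisson around `mean_depth` and alt reads are Binomial. With
#' `read_noise = FALSE` the exact expected VAF is emitted at fixed depth.
#'
#' @param truth A truth record from [simulate_tree()].
#' @param config A [sim_config()].
#' @return data.frame of variant calls (same columns as
#'   [read_variant_table()] output).
#' @export
simulate_reads <- function(truth, config) {
  loci <- gene_locus_table()
  lvls <- nested_levels(truth$tree)
  genes <- names(lvls)[!grepl("^(del|LOH|dup)", names(lvls))]
  if (length(genes) == 0) {
    return(empty_variant_frame())
  }
  node_ccf <- event_ccf_map(truth$tree)
  rows <- list()
  for (g in genes) {
    li <- loci[loci$gene == g, ]
    if (nrow(li) == 0) li <- data.frame(chrom = "1", pos = 1e6 + abs(sum(utf8ToInt(g))) * 1000)
    for (ti in seq_along(truth$timepoints)) {
      tp <- truth$timepoints[ti]
      v <- expected_vaf(node_ccf[[g]][ti], truth$purity[[ti]])
      if (v < 0 || v > 1) stop_fmt("inconsistent truth: expected VAF %.3f", v)
      if (config$read_noise) {
        depth <- max(1L, rpois(1, config$mean_depth))
        alt <- rbinom(1, depth, v)
        vaf <- alt / depth
      } else {
        depth <- as.integer(config$mean_depth)
        alt <- as.integer(round(v * depth))
        vaf <- v
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = truth$patient_id,
        sample_id = paste0(truth$patient_id, "_t", tp),
        timepoint = as.integer(tp), chrom = li$chrom[1],
        pos = as.integer(li$pos[1]), ref = "A", alt = "G", gene = g,
        protein_change = "", vaf = vaf, depth = depth, alt_reads = alt,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

empty_variant_frame <- function() {
  data.frame(patient_id = character(0), sample_id = character(0),
             timepoint = integer(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), gene = character(0),
             protein_change = character(0), vaf = numeric(0),
             depth = integer(0), alt_reads = integer(0))
}

#' Look up the true CCF of an event at one timepoint
#'
#' @param tree A `clone_tree` whose node events are labels.
#' @param event Event label.
#' @param timepoint Timepoint (must be on the tree's grid).
#' @return The CCF of the clone that acquired the event.
#' @export
event_ccf_lookup <- function(tree, event, timepoint) {
  tp <- as.character(timepoint)
  for (n in tree$nodes) {
    if (event %in% n$events) return(unname(n$ccf[[tp]]))
  }
  stop_fmt("event '%s' not found in tree", event)
}

# per-event CCF vectors over the tree's timepoint grid
event_ccf_map <- function(tree) {
  out <- list()
  for (n in tree$nodes) {
    for (e in n$events) out[[e]] <- as.numeric(n$ccf)
  }
  out
}

#' Simulate SNP-array segments for a truth record
#'
#' Each CNV event emits one segment per timepoint at which the carrying
#' clone is present (cell fraction > 0.01), with BAF and logR drawn from
#' the class-specific forward model of [cnv_signal()] plus Gaussian noise
#' (`baf_sd`, `logr_sd`); with `signal_noise = FALSE` the exact values are
#' emitted.
#'
#' @inheritParams simulate_reads
#' @return data.frame of CNV segments (same columns as
#'   [read_cnv_segments()] output).
#' @export
simulate_cnv_signal <- function(truth, config) {
  regions <- cnv_region_table()
  node_ccf <- event_ccf_map(truth$tree)
  cnv_events <- intersect(names(node_ccf), regions$label)
  rows <- list()
  for (lab in cnv_events) {
    reg <- regions[regions$label == lab, ]
    cls <- cnv_class_from_cn(reg$cn, reg$loh)
    for (ti in seq_along(truth$timepoints)) {
      tp <- truth$timepoints[ti]
      f <- node_ccf[[lab]][ti]
      if (f <= 0.01) next
      sig <- cnv_signal(cls, f, truth$purity[[ti]])
      baf <- sig$baf; logr <- sig$logr
      if (config$signal_noise) {
        baf <- clamp(baf + rnorm(1, 0, config$baf_sd), 0, 1)
        logr <- logr + rnorm(1, 0, config$logr_sd)
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = truth$patient_id,
        sample_id = paste0(truth$patient_id, "_t", tp),
        timepoint = as.integer(tp), chrom = reg$chrom,
        start = reg$start, end = reg$end, cn = reg$cn, loh = reg$loh,
        baf = baf, logr = logr, fraction = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(0), sample_id = character(0),
                      timepoint = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), cn = integer(0),
                      loh = logical(0), baf = numeric(0), logr = numeric(0),
                      fraction = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Simulate relapse outcomes from clone-composition covariates
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(hazard_beta * covariate)`; censoring is an
#' independent exponential at `censoring_rate`. The covariate is the
#' NOTCH1-wild-type tumor fraction at diagnosis, in percentage points.
#'
#' @param covariate_pct Numeric vector of covariates in `[0, 100]`.
#' @param config A [sim_config()].
#' @return data.frame with `covariate_pct`, `time_to_event_days`,
#'   `event_observed`.
#' @export
simulate_outcomes <- function(covariate_pct, config) {
  n <- length(covariate_pct)
  rate <- config$baseline_hazard * exp(config$hazard_beta * covariate_pct)
  t_event <- rexp(n, rate)
  t_cens <- rexp(n, config$censoring_rate)
  data.frame(
    covariate_pct = covariate_pct,
    time_to_event_days = pmax(1, round(pmin(t_event, t_cens))),
    event_observed = t_event <= t_cens
  )
}

simulate_age <- function(subgroup) {
  if (grepl("pediatric", subgroup)) {
    min(17.9, 0.5 + rgamma(1, shape = 3, scale = 3))
  } else {
    min(85, 18 + rgamma(1, shape = 1.5, scale = 8))
  }
}

#' Simulate a full cohort to disk
#'
#' Generates, per subgroup, `n_per_subgroup` patients: ground-truth trees
#' (written as clone-tree JSON under `trees/`), noisy variant and segment
#' tables, and a clinical table with simulated ages and relapse outcomes.
#' A manifest records the seed, a hash of the configuration and checksums
#' of all data files. Re-running with the same seed reproduces
#' byte-identical data files.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing non-empty directory (default FALSE).
#' @return Invisibly, a list with the truth records and file paths.
#' @export
simulate_cohort <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    stop_fmt("output directory '%s' exists and is not empty (use force = TRUE)",
             out_dir)
  }
  dir.create(file.path(out_dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  truths <- list(); variants <- list(); segments <- list(); clin <- list()
  idx <- 0
  for (sg in SUBGROUPS) {
    n_sg <- config$n_per_subgroup[[sg]]
    for (i in seq_len(n_sg)) {
      idx <- idx + 1
      pid <- sprintf("SIM%03d", idx)
      ps <- substream_seed(config$seed, 1009, match(sg, SUBGROUPS), i)
      truth <- simulate_tree(config, sg, patient_seed = ps, patient_id = pid)
      set.seed(substream_seed(ps, 2))
      variants[[idx]] <- simulate_reads(truth, config)
      set.seed(substream_seed(ps, 3))
      segments[[idx]] <- simulate_cnv_signal(truth, config)
      set.seed(substream_seed(ps, 4))
      age <- simulate_age(sg)
      outcome <- simulate_outcomes(truth$covariate_pct, config)
      clin[[idx]] <- data.frame(
        patient_id = pid,
        entity = sub("^(pediatric|adult) ", "", sg),
        age_group = sub(" .*$", "", sg),
        age_years = round(age, 1),
        relapsed = outcome$event_observed,
        time_to_event_days = outcome$time_to_event_days,
        event_observed = outcome$event_observed,
        stringsAsFactors = FALSE
      )
      truths[[pid]] <- truth
      write_tree_json(truth$tree, file.path(out_dir, "trees",
                                            paste0("truth_", pid, ".json")))
    }
  }
  paths <- list(
    variants = file.path(out_dir, "variants.tsv"),
    segments = file.path(out_dir, "segments.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(do.call(rbind, variants), paths$variants)
  write_tsv(do.call(rbind, segments), paths$segments)
  write_tsv(do.call(rbind, clin), paths$clinical)
  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(config[setdiff(names(config), "vocabulary")], cfg_file,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = config$seed,
    config_md5 = unname(md5sum(cfg_file)),
    n_patients = idx,
    checksums = as.list(md5sum(unlist(paths[c("variants", "segments",
                                              "clinical")]))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(truths = truths, paths = paths))
}
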