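# End-to-end orchestration: simulate or ingest a cohort, estimate CCFs,
# reconstruct trees, run trajectory / landscape / survival analyses, and
# write a run manifest. Patient-level failures are isolated: a tree that
# cannot be reconstructed is logged and excluded from cohort statistics,
# with counts reported.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param simulate Optional [sim_config()]; when given, a synthetic cohort
#'   is generated under `out_dir/cohort` and analyzed.
#' @param inputs Optional list with paths `variants`, `segments`,
#'   `clinical` for ingesting an existing cohort.
#' @param vaf_threshold Detection threshold on VAF (default 0.10).
#' @param n_perm Permutations for trajectory testing (default 1000).
#' @param seed Master seed.
#' @param build Genome build.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, inputs = NULL,
                            vaf_threshold = 0.10, n_perm = 1000, seed = 1,
                            build = "GRCh38") {
  if (is.null(simulate) == is.null(inputs)) {
    stop_fmt("exactly one of 'simulate' or 'inputs' must be given")
  }
  if (!is.null(inputs)) {
    need <- c("variants", "segments", "clinical")
    missing_keys <- setdiff(need, names(inputs))
    if (length(missing_keys) > 0) {
      stop_fmt("inputs is missing: %s", paste(missing_keys, collapse = ", "))
    }
    for (key in need) {
      if (!file.exists(inputs[[key]])) {
        stop_fmt("input file not found before any compute: %s", inputs[[key]])
      }
    }
  }
  structure(list(out_dir = out_dir, simulate = simulate, inputs = inputs,
                 vaf_threshold = vaf_threshold, n_perm = n_perm, seed = seed,
                 build = build),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: (1) simulate or ingest the cohort;
#' (2) per-sample purity and per-event CCF estimation; (3) per-patient
#' clone-tree reconstruction (failures isolated and logged); (4) per-
#' subgroup trajectory frequencies and permutation enrichment;
#' (5) landscape statistics (burden, age association, chr9p arm
#' frequencies, NOTCH1-PTEN exclusivity); (6) the NOTCH1-wild-type
#' fraction Cox relapse model. Outputs are tab-separated tables plus
#' clone-tree JSON under `out_dir`; a manifest records checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(config$out_dir, "trees"), recursive = TRUE,
             showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message("[clonetraj] ", line)
  }

  # stage 1: cohort
  if (!is.null(config$simulate)) {
    cohort_dir <- file.path(config$out_dir, "cohort")
    sim <- simulate_cohort(config$simulate, cohort_dir, force = TRUE)
    inputs <- sim$paths
  } else {
    inputs <- config$inputs
  }
  calls <- suppressMessages(
    read_variant_table(inputs$variants, vaf_threshold = config$vaf_threshold))
  segments <- read_cnv_segments(inputs$segments)
  clinical <- read_clinical_table(inputs$clinical)
  log_msg("cohort: %d patients, %d calls, %d segments",
          nrow(clinical), nrow(calls), nrow(segments))

  # stages 2-3: per-patient events and trees
  trees <- list(); failures <- character(0)
  for (pid in clinical$patient_id) {
    res <- tryCatch(
      reconstruct_patient(pid, calls, segments, config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, pid)
      log_msg("patient %s: reconstruction failed (%s)", pid,
              conditionMessage(res))
    } else {
      trees[[pid]] <- res
      write_tree_json(res, file.path(config$out_dir, "trees",
                                     paste0(pid, ".json")))
    }
  }
  if (length(trees) == 0) stop_fmt("pipeline error: zero reconstructed trees")
  log_msg("trees: %d reconstructed, %d failed", length(trees),
          length(failures))

  # stage 4: trajectories per subgroup (on gene/CNV labels, not variant ids)
  labeled <- lapply(trees, label_events, build = config$build)
  traj <- list()
  for (sg in unique(clinical$subgroup)) {
    pats <- intersect(clinical$patient_id[clinical$subgroup == sg],
                      names(trees))
    if (length(pats) < 2) next
    res <- trajectory_permutation_test(labeled[pats], n_perm = config$n_perm,
                                       seed = substream_seed(config$seed, 41,
                                                             match(sg, SUBGROUPS)))
    if (nrow(res) > 0) res$subgroup <- sg
    traj[[sg]] <- res
  }
  traj_df <- if (length(traj)) do.call(rbind, traj) else NULL

  # stage 5: landscape
  burden <- mutation_burden_summary(calls, clinical, segments)
  mat <- gene_mutation_matrix(calls, clinical)
  ages <- setNames(clinical$age_years, clinical$patient_id)
  age_assoc <- if (nrow(mat) > 0) gene_age_association(mat, ages) else NULL
  excl <- if (all(c("NOTCH1", "PTEN") %in% rownames(mat))) {
    mutual_exclusivity(mat, "NOTCH1", "PTEN")
  } else NULL
  arm_freq <- vapply(unique(clinical$subgroup), function(sg) {
    pats <- clinical$patient_id[clinical$subgroup == sg]
    prim <- segments[segments$patient_id %in% pats &
                       segments$timepoint == 0, , drop = FALSE]
    cnv_arm_frequency(prim, pats, "9", "p", class = "del",
                      build = config$build)
  }, numeric(1))

  # stage 6: survival
  surv_records <- survival_records(trees, clinical)
  cox <- if (nrow(surv_records) >= 2 && var(surv_records$covariate_pct) > 0 &&
             sum(surv_records$event_observed) >= 2) {
    fit_cox_ph(surv_records$time_to_event_days, surv_records$event_observed,
               surv_records$covariate_pct)
  } else NULL
  if (!is.null(cox)) {
    log_msg("cox: HR %.4f per percentage point (%.4f-%.4f), p = %.3g",
            cox$hr, cox$ci_low, cox$ci_high, cox$p_value)
  }

  # outputs + manifest
  write_tsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  out_paths <- c(
    if (!is.null(traj_df)) write_tsv(traj_df, "trajectories.tsv"),
    write_tsv(burden, "burden.tsv"),
    if (!is.null(age_assoc) && nrow(age_assoc) > 0)
      write_tsv(age_assoc, "age_association.tsv"),
    write_tsv(surv_records, "survival_records.tsv")
  )
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  manifest <- list(
    seed = config$seed,
    n_patients = nrow(clinical),
    n_trees = length(trees), n_failures = length(failures),
    checksums = as.list(md5sum(out_paths)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, trees = trees, failures = failures,
                 trajectories = traj_df, burden = burden,
                 age_association = age_assoc, exclusivity = excl,
                 chr9p_del_arm_frequency = arm_freq, cox = cox,
                 survival = surv_records, clinical = clinical))
}

# Reconstruct one patient's clone tree from calls + segments.
reconstruct_patient <- function(pid, calls, segments, config) {
  pc <- calls[calls$patient_id == pid, , drop = FALSE]
  ps <- segments[segments$patient_id == pid, , drop = FALSE]
  events <- ccf_event_table(pc, ps, build = config$build)
  reconstruct(events, config = list(seed = substream_seed(config$seed, 17,
                                                          sum(utf8ToInt(pid))),
                                    patient_id = pid))
}

#' Build the per-patient CCF event table
#'
#' Converts one patient's variant calls and CNV segments into the
#' long-format event table consumed by [reconstruct()]: per-sample purity
#' (estimated from CN-neutral VAFs unless supplied), multiplicity and
#' local copy number for each small variant, CCF/fraction estimates, and
#' the binomial observation model (alt reads + depth + clonal-VAF scale
#' for sequencing calls; delta-method effective sizes for array-derived
#' fractions).
#'
#' @param calls Variant calls of one patient.
#' @param segments CNV segments of the same patient.
#' @param purity Optional named numeric vector of per-timepoint purity
#'   overrides (names = timepoints); default: estimated per timepoint from
#'   CN-neutral calls.
#' @param build Genome build for CNV labeling.
#' @param baf_sd Assumed BAF noise SD for array effective sizes.
#' @param exact Treat the supplied VAFs/BAFs as noise-free: estimates are
#'   entered at a fixed high precision instead of their read-depth
#'   precision (used when validating against noise-free simulations).
#' @return data.frame with columns `event_id`, `label`, `kind`,
#'   `timepoint`, `ccf`, `n_eff`, `x`, `scale`.
#' @export
ccf_event_table <- function(calls, segments, purity = NULL,
                            build = "GRCh38", baf_sd = 0.01, exact = FALSE) {
  if (nrow(calls) + nrow(segments) == 0) stop_fmt("no events")
  tps <- sort(unique(c(calls$timepoint, segments$timepoint)))
  events <- list()
  for (tp in tps) {
    ct <- calls[calls$timepoint == tp, , drop = FALSE]
    st <- segments[segments$timepoint == tp, , drop = FALSE]
    rho <- if (!is.null(purity)) {
      unname(purity[[as.character(tp)]] %||% purity[[1]])
    } else {
      # purity from CN-neutral calls (not overlapping an aberrant segment),
      # floored by the aberrant cell fraction rho*f implied by each CNV's
      # BAF (a tumor fraction cannot be below any aberrant fraction)
      rho_vaf <- if (nrow(ct) > 0) {
        neutral <- !vapply(seq_len(nrow(ct)), function(i) {
          any(normalize_chrom(st$chrom) == ct$chrom[i] &
                st$start <= ct$pos[i] & st$end >= ct$pos[i])
        }, logical(1))
        tryCatch(estimate_purity(ct$vaf[neutral])$rho,
                 error = function(e) estimate_purity(ct$vaf)$rho)
      } else 0
      rho_seg <- 0
      for (i in seq_len(nrow(st))) {
        est <- tryCatch(cnv_fraction(st[i, ], purity = 1),
                        error = function(e) NULL)
        if (!is.null(est) && est$class != "neutral") {
          rho_seg <- max(rho_seg, est$f)
        }
      }
      max(min(1, max(rho_vaf, rho_seg)), 0.05)
    }
    for (i in seq_len(nrow(ct))) {
      seg_over <- which(normalize_chrom(st$chrom) == ct$chrom[i] &
                          st$start <= ct$pos[i] & st$end >= ct$pos[i])
      n_t <- if (length(seg_over) > 0) st$cn[seg_over[1]] else 2L
      if (n_t == 0) next  # variant inside homozygous deletion: flagged out
      m <- estimate_multiplicity(ct$vaf[i], rho, n_t)
      est <- compute_snv_ccf(ct$vaf[i], rho, local_cn = n_t, multiplicity = m,
                             depth = ct$depth[i], alt_reads = ct$alt_reads[i])
      events[[length(events) + 1]] <- data.frame(
        event_id = paste0(ct$gene[i], ":", ct$pos[i]), label = ct$gene[i],
        kind = "gene", timepoint = tp, ccf = est$ccf,
        n_eff = if (exact) 20000 else ct$depth[i],
        x = if (exact) NA_real_ else ct$alt_reads[i],
        scale = if (exact) 1 else expected_vaf(1, rho, n_t, m),
        stringsAsFactors = FALSE
      )
    }
    for (i in seq_len(nrow(st))) {
      est <- tryCatch(cnv_fraction(st[i, ], rho), error = function(e) NULL)
      if (is.null(est) || est$class == "neutral") next
      lab <- cnv_label(st$chrom[i], st$start[i], st$end[i], st$cn[i],
                       st$loh[i], build = build)
      events[[length(events) + 1]] <- data.frame(
        event_id = lab, label = lab, kind = "cnv", timepoint = tp,
        ccf = est$f,
        n_eff = if (exact) 20000 else cnv_effective_size(est, st[i, ], rho,
                                                         baf_sd = baf_sd),
        x = NA_real_, scale = 1,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(events) == 0) stop_fmt("no usable events")
  do.call(rbind, events)
}

# Delta-method effective binomial size for a BAF-derived fraction estimate:
# var(f) ~ (df/dBAF)^2 * baf_sd^2, n_eff = f(1-f)/var(f), clamped.
cnv_effective_size <- function(est, segment, purity, baf_sd = 0.01) {
  if (est$source != "baf") return(400)
  baf <- min(segment$baf, 1 - segment$baf)
  deriv <- switch(est$class,
    del = 1 / (purity * (1 - baf)^2),
    LOH = 2 / purity,
    dup = 1 / (purity * max(baf, 1e-3)^2)
  )
  v <- (deriv * baf_sd)^2
  f <- clamp(est$f, 0.05, 0.95)
  max(8, min(5000, round(f * (1 - f) / max(v, 1e-8))))
}

# Per-patient survival records: NOTCH1-wild-type fraction at diagnosis
# from the reconstructed tree, joined to the clinical outcome.
survival_records <- function(trees, clinical) {
  rows <- lapply(names(trees), function(pid) {
    cl <- clinical[clinical$patient_id == pid, ]
    if (nrow(cl) == 0) return(NULL)
    data.frame(patient_id = pid, subgroup = cl$subgroup,
               covariate_pct = notch_wt_fraction(trees[[pid]]),
               time_to_event_days = cl$time_to_event_days,
               event_observed = cl$event_observed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
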