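# Readers and writers for the external formats the pipeline consumes:
# small-variant tables (TSV or VCF), SEG-like copy-number segment tables,
# clinical tables, and clone-tree JSON documents.

VARIANT_COLUMNS <- c("patient_id", "sample_id", "timepoint", "chrom", "pos",
                     "ref", "alt", "gene", "vaf", "depth", "alt_reads")

#' Read a table of somatic small-variant calls
#'
#' Supports two dialects: a tab-separated table with a documented header, and
#' VCF 4.2 with `AD`/`DP` in FORMAT. Calls with VAF below `vaf_threshold` are
#' dropped (threshold inclusive: VAF equal to the threshold is kept); the
#' number of sub-threshold rows is reported via [message()]. The default
#' threshold of 0.10 matches routine panel reporting; a 0.01 sensitivity
#' setting is available through the same argument.
#'
#' When both a `vaf` column and `alt_reads`/`depth` are present and disagree
#' by more than `0.5/depth`, the read counts win and a warning is issued
#' (read counts are the primary evidence).
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"vcf"`.
#' @param vaf_threshold Minimum VAF retained, in `[0,1]` (default 0.10).
#' @return A data.frame of variant calls with columns `patient_id`,
#'   `sample_id`, `timepoint`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `protein_change`, `vaf`, `depth`, `alt_reads`.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               vaf_threshold = 0.10) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("variant file not found: %s", path)
  stopifnot(vaf_threshold >= 0, vaf_threshold <= 1)
  df <- if (dialect == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
  df <- validate_variants(df)
  below <- df$vaf < vaf_threshold
  if (any(below)) {
    message(sprintf("read_variant_table: %d of %d calls below VAF threshold %.3g dropped",
                    sum(below), nrow(df), vaf_threshold))
  }
  df[!below, , drop = FALSE]
}

read_variants_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = NA)
  required <- c("patient_id", "sample_id", "timepoint", "chrom", "pos",
                "ref", "alt", "gene")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_fmt("variant table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  if (!("vaf" %in% names(df)) && !all(c("alt_reads", "depth") %in% names(df))) {
    stop_fmt("variant table is missing required column(s): vaf (or alt_reads+depth)")
  }
  if (!"protein_change" %in% names(df)) df$protein_change <- ""
  if (!"depth" %in% names(df)) df$depth <- NA_integer_
  if (!"alt_reads" %in% names(df)) df$alt_reads <- NA_integer_
  if (!"vaf" %in% names(df)) df$vaf <- df$alt_reads / df$depth
  df
}

read_variants_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  n_var <- nrow(fix)
  info_field <- function(key) {
    vals <- vcfR::extract.info(vcf, element = key)
    if (is.null(vals)) rep(NA_character_, n_var) else vals
  }
  gene <- info_field("GENE")
  pchange <- info_field("PCHANGE")
  tp <- suppressWarnings(as.integer(info_field("TIMEPOINT")))
  pid <- info_field("PATIENT")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  dp <- suppressWarnings(apply(vcfR::extract.gt(vcf, element = "DP"), 2,
                               as.integer))
  dp <- matrix(dp, nrow = n_var)
  samples <- colnames(ad)
  rows <- list()
  for (j in seq_along(samples)) {
    alt_reads <- vapply(strsplit(ad[, j], ","), function(x) {
      suppressWarnings(as.integer(x[2]))
    }, integer(1))
    depth <- dp[, j]
    rows[[j]] <- data.frame(
      patient_id = ifelse(is.na(pid), samples[j], pid),
      sample_id = samples[j],
      timepoint = ifelse(is.na(tp), 0L, tp),
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      gene = ifelse(is.na(gene), "", gene),
      protein_change = ifelse(is.na(pchange), "", pchange),
      vaf = alt_reads / depth, depth = depth, alt_reads = alt_reads,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out[!is.na(out$depth) & out$depth > 0, , drop = FALSE]
}

validate_variants <- function(df) {
  bad <- which(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1))
  if (length(bad) > 0) {
    stop_fmt("vaf outside [0,1] at row %d (value %.4g)", bad[1], df$vaf[bad[1]])
  }
  bad <- which(!is.na(df$alt_reads) & !is.na(df$depth) & df$alt_reads > df$depth)
  if (length(bad) > 0) {
    stop_fmt("alt_reads exceeds depth at row %d", bad[1])
  }
  have_both <- !is.na(df$vaf) & !is.na(df$alt_reads) & !is.na(df$depth) & df$depth > 0
  if (any(have_both)) {
    vaf_reads <- df$alt_reads[have_both] / df$depth[have_both]
    off <- abs(df$vaf[have_both] - vaf_reads) > 0.5 / df$depth[have_both]
    if (any(off)) {
      warn_fmt("%d call(s) with vaf column contradicting alt_reads/depth; using read counts",
               sum(off))
      idx <- which(have_both)[off]
      df$vaf[idx] <- df$alt_reads[idx] / df$depth[idx]
    }
  }
  df$pos <- as.integer(df$pos)
  df$timepoint <- as.integer(df$timepoint)
  df$chrom <- normalize_chrom(df$chrom)
  df
}

#' Read a SEG-like table of copy-number/LOH segments
#'
#' Tab-separated with 1-based inclusive coordinates and columns `patient_id`,
#' `sample_id`, `timepoint`, `chrom`, `start`, `end`, `cn`, `loh`, and
#' optional `baf`, `logr`, `fraction`. Enforces `cn` in 0..4, `start <= end`,
#' and the LOH convention: `loh = TRUE` only with `cn = 2`.
#'
#' @param path File path.
#' @return A data.frame of segments sorted by patient, sample, chromosome and
#'   start position.
#' @export
read_cnv_segments <- function(path) {
  if (!file.exists(path)) stop_fmt("segment file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("patient_id", "sample_id", "timepoint", "chrom", "start",
                "end", "cn", "loh")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_fmt("segment table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  for (col in c("baf", "logr", "fraction")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df$loh <- as.logical(df$loh)
  df$cn <- as.integer(df$cn)
  bad <- which(df$cn < 0 | df$cn > 4)
  if (length(bad) > 0) stop_fmt("cn outside 0..4 at row %d (value %d)", bad[1], df$cn[bad[1]])
  bad <- which(df$loh & df$cn != 2)
  if (length(bad) > 0) stop_fmt("loh=TRUE requires cn=2 (row %d has cn=%d)", bad[1], df$cn[bad[1]])
  bad <- which(df$start > df$end)
  if (length(bad) > 0) stop_fmt("start > end at row %d", bad[1])
  bad <- which(!is.na(df$baf) & (df$baf < 0 | df$baf > 1))
  if (length(bad) > 0) stop_fmt("baf outside [0,1] at row %d", bad[1])
  df$chrom <- normalize_chrom(df$chrom)
  df[order(df$patient_id, df$sample_id, df$chrom, df$start), , drop = FALSE]
}

#' Read the clinical table
#'
#' Tab-separated, one row per patient, with columns `patient_id`, `entity`
#' (`T-ALL`/`T-LBL`), `age_group` (`pediatric`/`adult`), `age_years`,
#' `relapsed`, `time_to_event_days`, `event_observed`. A derived `subgroup`
#' column (`age_group` x `entity`) is added.
#'
#' @param path File path.
#' @return A data.frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop_fmt("clinical file not found: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  required <- c("patient_id", "entity", "age_group", "age_years", "relapsed",
                "time_to_event_days", "event_observed")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_fmt("clinical table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0) stop_fmt("duplicate patient_id: %s", dup[1])
  bad <- setdiff(unique(df$entity), c("T-ALL", "T-LBL"))
  if (length(bad) > 0) stop_fmt("unknown entity token: %s", bad[1])
  bad <- setdiff(unique(df$age_group), c("pediatric", "adult"))
  if (length(bad) > 0) stop_fmt("unknown age_group token: %s", bad[1])
  df$relapsed <- as.logical(df$relapsed)
  df$event_observed <- as.logical(df$event_observed)
  bad <- which(df$relapsed & !df$event_observed)
  if (length(bad) > 0) stop_fmt("relapsed=TRUE requires event_observed=TRUE (row %d)", bad[1])
  bad <- which(df$time_to_event_days <= 0)
  if (length(bad) > 0) stop_fmt("time_to_event_days must be positive (row %d)", bad[1])
  df$subgroup <- paste(df$age_group, df$entity)
  df
}

# ---- clone tree documents -------------------------------------------------

#' Construct a clone-tree document
#'
#' A clone tree is a rooted tree of clones; each node carries the set of
#' event labels first acquired in that clone and a CCF per timepoint. The
#' CCF of a node includes its descendants (nested convention), so the sum
#' rule reads: at each timepoint the children's CCFs sum to at most the
#' parent's CCF.
#'
#' @param patient_id Patient identifier.
#' @param nodes List of nodes; each node is a list with `node_id`,
#'   `parent_id` (`NA` for the founding clone), `events` (character vector),
#'   and `ccf` (numeric named by timepoint).
#' @param timepoints Numeric vector of timepoints (days since diagnosis).
#' @return An object of class `clone_tree`.
#' @export
clone_tree <- function(patient_id, nodes, timepoints) {
  tree <- structure(
    list(schema_version = 1L, patient_id = patient_id,
         timepoints = sort(as.numeric(timepoints)), nodes = nodes),
    class = "clone_tree"
  )
  validate_clone_tree(tree)
  tree
}

#' Validate a clone-tree document
#'
#' Checks the structural invariants: unique node ids, exactly one root,
#' acyclic parent references, CCFs in `[0,1]` defined on the tree's
#' timepoint grid.
#'
#' @param tree A `clone_tree`.
#' @return The tree, invisibly; errors on violation.
#' @export
validate_clone_tree <- function(tree) {
  ids <- vapply(tree$nodes, function(n) n$node_id, character(1))
  if (anyDuplicated(ids)) stop_fmt("duplicate node_id: %s", ids[duplicated(ids)][1])
  parents <- vapply(tree$nodes, function(n) {
    if (is.null(n$parent_id) || is.na(n$parent_id)) NA_character_ else n$parent_id
  }, character(1))
  roots <- which(is.na(parents))
  if (length(roots) != 1) stop_fmt("tree must have exactly one root (found %d)", length(roots))
  bad <- setdiff(parents[!is.na(parents)], ids)
  if (length(bad) > 0) stop_fmt("parent_id '%s' references no node", bad[1])
  # acyclicity: walk up from every node
  up <- setNames(parents, ids)
  for (id in ids) {
    seen <- character(0); cur <- id
    while (!is.na(up[[cur]])) {
      if (cur %in% seen) stop_fmt("cyclic parent references at node '%s'", cur)
      seen <- c(seen, cur); cur <- up[[cur]]
    }
  }
  tp_chr <- as.character(tree$timepoints)
  for (n in tree$nodes) {
    ccf <- n$ccf
    if (!all(tp_chr %in% names(ccf))) {
      stop_fmt("node '%s' lacks CCF for some timepoints", n$node_id)
    }
    if (any(ccf < -1e-12 | ccf > 1 + 1e-12)) {
      stop_fmt("node '%s' has CCF outside [0,1]", n$node_id)
    }
  }
  invisible(tree)
}

#' Write / read a clone tree as JSON
#'
#' The on-disk schema is versioned (`schema_version: 1`). `read_tree_json`
#' of `write_tree_json` is the identity, field for field.
#'
#' @param tree A `clone_tree`.
#' @param path Output path.
#' @return `write_tree_json` returns the path invisibly; `read_tree_json`
#'   returns a `clone_tree`.
#' @export
write_tree_json <- function(tree, path) {
  validate_clone_tree(tree)
  doc <- list(
    schema_version = 1L,
    patient_id = tree$patient_id,
    timepoints = as.numeric(tree$timepoints),
    nodes = lapply(tree$nodes, function(n) {
      node <- list(node_id = n$node_id,
                   events = as.list(n$events %||% character(0)),
                   ccf_by_timepoint = as.list(n$ccf))
      if (!is.null(n$parent_id) && !is.na(n$parent_id)) {
        node <- c(node[1], list(parent_id = n$parent_id), node[-1])
      }
      node
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop_fmt("unsupported clone-tree schema version in %s", path)
  }
  nodes <- lapply(doc$nodes, function(n) {
    ccf <- unlist(n$ccf_by_timepoint)
    pid <- unlist(n$parent_id)
    list(node_id = n$node_id,
         parent_id = if (length(pid) == 0 || is.na(pid)) NA_character_ else pid,
         events = as.character(unlist(n$events)),
         ccf = setNames(as.numeric(ccf), names(ccf)))
  })
  clone_tree(doc$patient_id, nodes, as.numeric(unlist(doc$timepoints)))
}
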