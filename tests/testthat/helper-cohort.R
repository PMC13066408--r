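# Shared harness: simulate one patient, push the observations through the
# CCF engine and tree reconstruction, and score against the truth.

sim_and_reconstruct <- function(patient_seed, config, exact = FALSE) {
  truth <- simulate_tree(config, "pediatric T-ALL",
                         patient_seed = patient_seed, patient_id = "P")
  set.seed(substream_seed(patient_seed, 2))
  calls <- simulate_reads(truth, config)
  set.seed(substream_seed(patient_seed, 3))
  segs <- simulate_cnv_signal(truth, config)
  events <- ccf_event_table(calls, segs, purity = truth$purity, exact = exact)
  recon <- reconstruct(events, config = list(seed = 1, patient_id = "P"))
  list(truth = truth, recon = recon,
       cmp = compare_tree_relations(truth$tree, recon))
}

write_variant_fixture <- function(path, vafs, depth = 500) {
  df <- data.frame(
    patient_id = "P1", sample_id = "P1_t0", timepoint = 0L,
    chrom = "9", pos = seq_along(vafs) * 1000L, ref = "A", alt = "G",
    gene = paste0("G", seq_along(vafs)), protein_change = "",
    vaf = vafs, depth = depth, alt_reads = round(vafs * depth)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_tree <- function(ccfs, parents, events = NULL, timepoints = 0) {
  # ccfs: matrix nodes x timepoints (or vector for one timepoint)
  if (is.null(dim(ccfs))) ccfs <- matrix(ccfs, ncol = length(timepoints))
  k <- nrow(ccfs)
  if (is.null(events)) events <- as.list(paste0("E", seq_len(k)))
  nodes <- lapply(seq_len(k), function(i) {
    list(node_id = paste0("N", i),
         parent_id = if (parents[i] == 0) NA_character_ else paste0("N", parents[i]),
         events = events[[i]],
         ccf = setNames(ccfs[i, ], as.character(timepoints)))
  })
  clone_tree("P", nodes, timepoints)
}
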