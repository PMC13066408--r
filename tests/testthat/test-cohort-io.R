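# Readers, validation, and clone-tree JSON round-trips.

test_that("variant reader applies the detection threshold inclusively", {
  path <- write_variant_fixture(tempfile(fileext = ".tsv"),
                                c(0.05, 0.09, 0.10, 0.25, 0.50))
  expect_message(calls <- read_variant_table(path, vaf_threshold = 0.10),
                 "below VAF threshold")
  expect_equal(nrow(calls), 3)          # 0.10 is kept: >= is inclusive
  expect_true(all(calls$vaf >= 0.10))
  # sensitivity mode keeps everything
  calls_all <- read_variant_table(path, vaf_threshold = 0.01)
  expect_equal(nrow(calls_all), 5)
  # raising the threshold never increases the number of calls
  counts <- vapply(c(0, 0.05, 0.1, 0.3, 0.6), function(thr) {
    nrow(suppressMessages(read_variant_table(path, vaf_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("variant reader validates columns, VAF range and read counts", {
  path <- write_variant_fixture(tempfile(fileext = ".tsv"), c(0.2, 0.4))
  df <- read.delim(path)
  # empty file with a valid header is fine
  empty <- tempfile(fileext = ".tsv")
  write.table(df[0, ], empty, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_variant_table(empty)), 0)
  # missing required column is named in the error
  broken <- tempfile(fileext = ".tsv")
  write.table(df[, setdiff(names(df), "gene")], broken, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(broken), "gene")
  # out-of-range VAF reports the row
  df_bad <- df; df_bad$vaf[2] <- 1.4; df_bad$alt_reads <- NULL
  write.table(df_bad, broken, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(broken), "row 2")
  # contradictory vaf column: read counts win with a warning
  df_con <- df; df_con$vaf[1] <- 0.9
  write.table(df_con, broken, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(calls <- read_variant_table(broken), "read counts")
  expect_equal(calls$vaf[1], df$alt_reads[1] / df$depth[1])
})

test_that("segment reader enforces the CN/LOH conventions and sorts", {
  seg <- data.frame(patient_id = "P1", sample_id = "S1", timepoint = 0L,
                    chrom = c("9", "9", "6"), start = c(5e6, 1, 62e6),
                    end = c(6e6, 38e6, 1e8), cn = c(2L, 1L, 1L),
                    loh = c(TRUE, FALSE, FALSE))
  path <- tempfile(fileext = ".tsv")
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_cnv_segments(path)
  expect_equal(nrow(out), 3)
  expect_equal(out$start[out$chrom == "9"], c(1, 5e6))  # sorted by start
  seg_bad <- seg; seg_bad$cn[1] <- 5L; seg_bad$loh[1] <- FALSE
  write.table(seg_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cnv_segments(path), "cn outside")
  seg_bad <- seg; seg_bad$cn[1] <- 1L  # loh = TRUE with cn != 2
  write.table(seg_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cnv_segments(path), "loh")
})

test_that("clinical reader derives subgroups and rejects inconsistencies", {
  cl <- data.frame(
    patient_id = paste0("P", 1:4),
    entity = c("T-ALL", "T-ALL", "T-LBL", "T-LBL"),
    age_group = c("pediatric", "adult", "pediatric", "adult"),
    age_years = c(8.8, 30, 10, 45),
    relapsed = c(TRUE, FALSE, FALSE, FALSE),
    time_to_event_days = c(400, 1500, 1200, 900),
    event_observed = c(TRUE, FALSE, FALSE, FALSE)
  )
  path <- tempfile(fileext = ".tsv")
  write.table(cl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- read_clinical_table(path)
  expect_equal(length(unique(out$subgroup)), 4)
  cl_bad <- cl; cl_bad$patient_id[2] <- "P1"
  write.table(cl_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical_table(path), "P1")
  cl_bad <- cl; cl_bad$entity[1] <- "B-ALL"
  write.table(cl_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_clinical_table(path), "B-ALL")
})

test_that("clone-tree JSON round-trips field for field", {
  single <- make_tree(1.0, 0, events = list("NOTCH1"))
  path <- tempfile(fileext = ".json")
  write_tree_json(single, path)
  expect_equal(read_tree_json(path), single)
  branched <- make_tree(
    rbind(c(1, 0.95, 0.9), c(0.6, 0.3, 0.1), c(0.3, 0.6, 0.75), c(0.1, 0.2, 0.5)),
    parents = c(0, 1, 1, 3),
    events = list("A", c("B", "C"), "D", "E"),
    timepoints = c(0, 300, 700)
  )
  write_tree_json(branched, path)
  expect_equal(read_tree_json(path), branched)
})

test_that("malformed trees are refused", {
  nodes <- list(
    list(node_id = "N1", parent_id = "N1", events = "A", ccf = c("0" = 1))
  )
  expect_error(clone_tree("P", nodes, 0), "root")
  nodes <- list(
    list(node_id = "N1", parent_id = NA, events = "A", ccf = c("0" = 1)),
    list(node_id = "N2", parent_id = "N3", events = "B", ccf = c("0" = 0.5)),
    list(node_id = "N3", parent_id = "N2", events = "C", ccf = c("0" = 0.5))
  )
  expect_error(clone_tree("P", nodes, 0), "cyclic|references")
  nodes <- list(
    list(node_id = "N1", parent_id = NA, events = "A", ccf = c("0" = 1.4))
  )
  expect_error(clone_tree("P", nodes, 0), "CCF")
})

test_that("VCF dialect yields the same calls as the TSV dialect", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=TIMEPOINT,Number=1,Type=Integer,Description=\"Days\">",
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "9\t1000\t.\tA\tG\t.\tPASS\tGENE=NOTCH1;TIMEPOINT=0;PATIENT=P1\tAD:DP\t250,250:500",
    "10\t2000\t.\tC\tT\t.\tPASS\tGENE=PTEN;TIMEPOINT=0;PATIENT=P1\tAD:DP\t460,40:500"
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  calls <- read_variant_table(path, dialect = "vcf", vaf_threshold = 0.05)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$gene, c("NOTCH1", "PTEN"))
  expect_equal(calls$vaf, c(0.5, 0.08))
  expect_equal(calls$patient_id, c("P1", "P1"))
  # threshold applies identically to this dialect
  expect_equal(nrow(read_variant_table(path, dialect = "vcf",
                                       vaf_threshold = 0.10)), 1)
})
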