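#' Chromosome arm table
#'
#' Approximate, cytoband-derived chromosome lengths and centromere midpoints
#' for the supported genome builds. Used to assign copy-number segments to a
#' chromosome arm when labeling events (e.g. `del_in_9p`, `dup20`).
#'
#' @param build Genome build, `"GRCh38"` (default) or `"GRCh37"`.
#' @return A data.frame with columns `chrom`, `length`, `centromere`
#'   (positions in bp, 1-based).
#' @export
genome_arm_table <- function(build = c("GRCh38", "GRCh37")) {
  build <- match.arg(build)
  if (build == "GRCh38") {
    data.frame(
      chrom = c(as.character(1:22), "X", "Y"),
      length = c(
        248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
        159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
        114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
        58617616, 64444167, 46709983, 50818468, 156040895, 57227415
      ),
      centromere = c(
        123400000, 93900000, 90900000, 50000000, 48800000, 59800000,
        60100000, 45200000, 43000000, 39800000, 53400000, 35500000,
        17700000, 17200000, 19000000, 36800000, 25100000, 18500000,
        26200000, 28100000, 12000000, 15000000, 61000000, 10400000
      ),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      chrom = c(as.character(1:22), "X", "Y"),
      length = c(
        249250621, 243199373, 198022430, 191154276, 180915260, 171115067,
        159138663, 146364022, 141213431, 135534747, 135006516, 133851895,
        115169878, 107349540, 102531392, 90354753, 81195210, 78077248,
        59128983, 63025520, 48129895, 51304566, 155270560, 59373566
      ),
      centromere = c(
        125000000, 93300000, 91000000, 50400000, 48400000, 61000000,
        59900000, 45600000, 49000000, 40200000, 53700000, 35800000,
        17900000, 17600000, 19000000, 36600000, 24000000, 17200000,
        26500000, 27500000, 13200000, 14700000, 60600000, 12500000
      ),
      stringsAsFactors = FALSE
    )
  }
}

normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Label a copy-number segment by class and genomic location
#'
#' Maps a segment to an event label of the form `del_in_9p` / `LOH_in_9p` /
#' `dup_in_9p` when at least `arm_fraction` of the segment lies within one
#' chromosome arm, and `del9` / `dup20`-style whole-chromosome labels
#' otherwise. The class is derived from the copy-number call: CN 0-1 are
#' deletions (`del`), CN 2 with allelic loss is copy-neutral LOH (`LOH`),
#' CN 3-4 are duplications (`dup`).
#'
#' @param chrom,start,end Segment coordinates (1-based inclusive; vectors).
#' @param cn Integer copy number in 0..4 (vector).
#' @param loh Logical LOH flag (vector; only meaningful for CN 2).
#' @param build Genome build passed to [genome_arm_table()].
#' @param arm_fraction Minimum fraction of the segment that must lie within a
#'   single arm for arm-level labeling (default 0.9).
#' @return Character vector of event labels.
#' @export
#' @examples
#' cnv_label("9", 1, 38e6, cn = 1, loh = FALSE)   # "del_in_9p"
#' cnv_label("20", 1, 64444167, cn = 3, loh = FALSE)  # "dup20"
cnv_label <- function(chrom, start, end, cn, loh,
                      build = "GRCh38", arm_fraction = 0.9) {
  arms <- genome_arm_table(build)
  chrom <- normalize_chrom(chrom)
  n <- length(chrom)
  cn <- rep_len(cn, n); loh <- rep_len(loh, n)
  start <- rep_len(as.numeric(start), n); end <- rep_len(as.numeric(end), n)
  cls <- ifelse(cn <= 1, "del", ifelse(cn >= 3, "dup", ifelse(loh, "LOH", NA)))
  if (anyNA(cls)) {
    stop_fmt("cannot label CN-neutral segment without LOH (row %d)",
             which(is.na(cls))[1])
  }
  out <- character(n)
  for (i in seq_len(n)) {
    row <- arms[arms$chrom == chrom[i], ]
    if (nrow(row) == 0) stop_fmt("chromosome '%s' missing from arm table", chrom[i])
    len <- end[i] - start[i] + 1
    p_part <- max(0, min(end[i], row$centromere) - start[i] + 1)
    q_part <- max(0, end[i] - max(start[i], row$centromere + 1) + 1)
    if (p_part / len >= arm_fraction) {
      out[i] <- paste0(cls[i], "_in_", chrom[i], "p")
    } else if (q_part / len >= arm_fraction) {
      out[i] <- paste0(cls[i], "_in_", chrom[i], "q")
    } else {
      out[i] <- paste0(cls[i], chrom[i])
    }
  }
  out
}
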