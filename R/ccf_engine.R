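# Conversion of observed variant allele frequencies and allele-specific
# array signals into cancer cell fractions (CCF), with purity and
# multiplicity handling. The forward models here are the exact inverses used
# by the synthetic cohort generator, so noise-free simulated observations
# recover the planted CCFs to machine precision.

#' Expected VAF under the standard purity/copy-number model
#'
#' For a variant present at multiplicity `m` in a fraction `ccf` of tumor
#' cells, with sample purity `rho` and local tumor copy number `n_t`
#' (normal copy number `n_n`), the expected variant allele frequency is
#' `v = ccf * m * rho / (rho * n_t + (1 - rho) * n_n)`.
#'
#' @param ccf Cancer cell fraction in `[0,1]`.
#' @param purity Tumor purity `rho` in `(0,1]`.
#' @param local_cn Tumor copy number at the locus (default 2).
#' @param multiplicity Mutated copies per tumor cell (default 1).
#' @param normal_cn Copy number in normal cells (default 2).
#' @return Expected VAF.
#' @export
expected_vaf <- function(ccf, purity, local_cn = 2, multiplicity = 1,
                         normal_cn = 2) {
  ccf * multiplicity * purity / (purity * local_cn + (1 - purity) * normal_cn)
}

#' Estimate sample purity from copy-number-neutral VAFs
#'
#' Deep targeted panels lack genome-wide purity estimators, so purity is
#' taken as `min(1, q95(2 * VAF))` over variants in CN-neutral (CN 2, no
#' LOH) regions: a clonal heterozygous variant has expected VAF `rho / 2`.
#' An explicit override (e.g. blast percentage from metadata) wins.
#'
#' @param vafs Numeric VAFs of calls in CN-neutral regions.
#' @param override Optional known purity in `(0,1]`.
#' @return A list with `rho` and `method` (`"from_metadata"` or `"from_vaf"`).
#' @export
estimate_purity <- function(vafs, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override > 0, override <= 1)
    return(list(rho = override, method = "from_metadata"))
  }
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) == 0) {
    stop_fmt("no CN-neutral calls available and no purity override given")
  }
  rho <- min(1, as.numeric(quantile(2 * vafs, 0.95)))
  list(rho = max(rho, 1e-6), method = "from_vaf")
}

#' Cancer cell fraction of a small variant
#'
#' Inverts [expected_vaf()]: `ccf_raw = v * (rho*n_t + (1-rho)*n_n) / (m*rho)`,
#' clamped to `[0,1]`. A model-violation flag is raised when the raw value
#' exceeds 1.1 (the observation is inconsistent with the assumed copy state).
#' When `depth` and `alt_reads` are supplied, a Wilson 95% interval on the
#' VAF is propagated through the linear map to a CCF confidence interval.
#'
#' @param vaf Observed VAF in `[0,1]`.
#' @param purity Tumor purity in `(0,1]`.
#' @param local_cn Tumor copy number at the locus (default 2).
#' @param multiplicity Mutated copies per tumor cell (default 1).
#' @param normal_cn Normal copy number (default 2).
#' @param depth,alt_reads Optional read counts for the confidence interval.
#' @param conf Confidence level (default 0.95).
#' @return A list with `ccf`, `ccf_raw`, `ci_low`, `ci_high`, `multiplicity`,
#'   `local_cn`, `purity`, `flag` (logical model violation).
#' @export
compute_snv_ccf <- function(vaf, purity, local_cn = 2, multiplicity = 1,
                            normal_cn = 2, depth = NULL, alt_reads = NULL,
                            conf = 0.95) {
  if (purity <= 0) stop_fmt("purity must be positive")
  if (multiplicity < 1) stop_fmt("multiplicity must be >= 1")
  stopifnot(vaf >= 0, vaf <= 1, local_cn >= 0)
  scale <- (purity * local_cn + (1 - purity) * normal_cn) / (multiplicity * purity)
  ccf_raw <- vaf * scale
  ci <- c(NA_real_, NA_real_)
  if (!is.null(depth) && !is.null(alt_reads) && !is.na(depth) && depth > 0 &&
      !is.na(alt_reads)) {
    w <- wilson_ci(alt_reads, depth, conf)
    ci <- clamp(c(w[1, "low"], w[1, "high"]) * scale, 0, 1)
  } else {
    ci <- clamp(c(ccf_raw, ccf_raw), 0, 1)
  }
  list(ccf = clamp(ccf_raw, 0, 1), ccf_raw = ccf_raw,
       ci_low = ci[1], ci_high = ci[2],
       multiplicity = multiplicity, local_cn = local_cn, purity = purity,
       flag = ccf_raw > 1.1)
}

#' Estimate mutation multiplicity
#'
#' Enumerates multiplicities `1..local_cn` and picks the one whose implied
#' CCF is closest to the feasible range `[0,1]`; ties break toward `m = 1`.
#' Overshoot up to `tol` above 1 is not penalized — a clonal variant read
#' at slightly more than its expected VAF must not be pushed to a higher
#' multiplicity (the same tolerance governs the model-violation flag of
#' [compute_snv_ccf()]).
#'
#' @inheritParams compute_snv_ccf
#' @param tol Unpenalized CCF overshoot above 1 (default 0.1).
#' @return Integer multiplicity.
#' @export
estimate_multiplicity <- function(vaf, purity, local_cn, normal_cn = 2,
                                  tol = 0.1) {
  if (local_cn < 1) {
    stop_fmt("multiplicity undefined inside homozygous deletion (local_cn = 0)")
  }
  ms <- seq_len(local_cn)
  penalty <- vapply(ms, function(m) {
    phi <- vaf * (purity * local_cn + (1 - purity) * normal_cn) / (m * purity)
    max(0, phi - 1 - tol) + max(0, -phi)
  }, numeric(1))
  ms[which.min(penalty)]  # which.min takes the first minimum, i.e. smallest m
}

#' Effective binomial size of a CCF estimate
#'
#' The clustering stage models each CCF estimate as a binomial proportion
#' with an effective number of trials chosen so that the implied variance
#' matches the delta-method variance of the CCF estimator:
#' `var(ccf_hat) = v(1-v)/depth * scale^2` with
#' `scale = (rho*n_t + (1-rho)*n_n)/(m*rho)`. Near the CCF boundaries the
#' binomial variance term is evaluated at a clamped CCF so the effective
#' size stays finite and honest.
#'
#' @inheritParams compute_snv_ccf
#' @param ccf The CCF estimate the size is attached to.
#' @return Integer effective size in `[8, 5000]`.
#' @export
snv_effective_size <- function(ccf, vaf, depth, purity, local_cn = 2,
                               multiplicity = 1, normal_cn = 2) {
  scale <- (purity * local_cn + (1 - purity) * normal_cn) /
    (multiplicity * purity)
  v <- clamp(vaf, 0.25 / depth, 1 - 0.25 / depth)
  var_ccf <- v * (1 - v) / depth * scale^2
  c_star <- clamp(ccf, 0.05, 0.95)
  as.integer(max(8, min(5000, round(c_star * (1 - c_star) / var_ccf))))
}

# ---- allele-specific array signal model -----------------------------------

cnv_class_from_cn <- function(cn, loh) {
  ifelse(cn <= 1, "del", ifelse(cn >= 3, "dup", ifelse(loh, "LOH", "neutral")))
}

#' Forward model for SNP-array BAF/logR of a CNV
#'
#' Expected B-allele frequency and logR for a heterozygous germline SNP
#' inside a segment carried by a fraction `f` of cells in a sample of purity
#' `rho` (aberrant cell fraction `rho * f`). Classes: one-copy deletion
#' (`del`), copy-neutral LOH (`LOH`), one-copy gain (`dup`); the deleted /
#' duplicated allele is taken to be the B allele.
#'
#' @param class `"del"`, `"LOH"` or `"dup"`.
#' @param f Fraction of tumor cells carrying the CNV, in `[0,1]`.
#' @param purity Tumor purity in `(0,1]`.
#' @return A list with `baf` and `logr`.
#' @export
cnv_signal <- function(class, f, purity = 1) {
  rf <- purity * f
  switch(class,
    del = list(baf = (1 - rf) / (2 - rf), logr = log2((2 - rf) / 2)),
    LOH = list(baf = (1 - rf) / 2, logr = 0),
    dup = list(baf = 1 / (2 + rf), logr = log2((2 + rf) / 2)),
    stop_fmt("unknown CNV class '%s'", class)
  )
}

#' Subclonal fraction of a copy-number segment
#'
#' Inverts the class-specific forward model of [cnv_signal()]. An explicit
#' `fraction` on the segment passes through untouched. Otherwise the BAF is
#' inverted (deletion: `f = (1-2*BAF)/(rho*(1-BAF))`; copy-neutral LOH:
#' `f = (1-2*BAF)/rho`; gain: `f = (1/BAF - 2)/rho`), clamped to `[0,1]`.
#' When logR is also present, the logR-implied fraction is reported as a
#' diagnostic (`f_logr`), but the BAF value wins.
#'
#' @param segment A one-row data.frame (or list) with fields `cn`, `loh`,
#'   and at least one of `baf`, `fraction` (optionally `logr`).
#' @param purity Tumor purity in `(0,1]`.
#' @return A list with `f`, `class`, `source`, and diagnostic `f_logr`.
#' @export
cnv_fraction <- function(segment, purity = 1) {
  cls <- cnv_class_from_cn(segment$cn, isTRUE(segment$loh) || isTRUE(as.logical(segment$loh)))
  if (cls == "neutral") {
    return(list(f = 0, class = "neutral", source = "class", f_logr = NA_real_))
  }
  if (!is.null(segment$fraction) && length(segment$fraction) == 1 &&
      !is.na(segment$fraction)) {
    return(list(f = clamp(segment$fraction, 0, 1), class = cls,
                source = "fraction", f_logr = NA_real_))
  }
  baf <- segment$baf
  if (is.null(baf) || is.na(baf)) {
    stop_fmt("segment carries neither BAF nor an explicit fraction")
  }
  # BAF of the minor allele: fold around 0.5
  baf <- min(baf, 1 - baf)
  f <- switch(cls,
    del = (1 - 2 * baf) / (purity * (1 - baf)),
    LOH = (1 - 2 * baf) / purity,
    dup = (1 / max(baf, 1e-9) - 2) / purity
  )
  f_logr <- NA_real_
  if (!is.null(segment$logr) && length(segment$logr) == 1 && !is.na(segment$logr)) {
    f_logr <- switch(cls,
      del = (2 - 2^(segment$logr + 1)) / purity,
      LOH = NA_real_,  # logR carries no signal for copy-neutral LOH
      dup = (2^(segment$logr + 1) - 2) / purity
    )
    if (!is.na(f_logr)) f_logr <- clamp(f_logr, 0, 1)
  }
  list(f = clamp(f, 0, 1), class = cls, source = "baf", f_logr = f_logr)
}
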