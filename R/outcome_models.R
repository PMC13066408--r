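# Clone-composition covariate and its relation to relapse outcomes:
# the NOTCH1-wild-type tumor fraction, a Cox proportional-hazards model
# with Efron tie handling, and a rank-based relapse-time comparison.

#' NOTCH1-wild-type tumor fraction of a clone tree
#'
#' The covariate of the relapse-hazard model: the difference, in percentage
#' points, between the CCF of the largest clone and the CCF of the largest
#' clone carrying a marker-gene event (a clone carries the marker if it or
#' any ancestor acquired it; under the nested CCF convention the maximal
#' carrying clone already includes its descendants). If no clone carries
#' the marker, the whole largest clone counts as wild-type.
#'
#' @param tree A `clone_tree`.
#' @param timepoint Timepoint at which to evaluate (default: the tree's
#'   first timepoint, i.e. diagnosis).
#' @param marker_gene Marker gene (default `"NOTCH1"`); any event label
#'   starting with this gene symbol counts.
#' @return Fraction in percentage points, clamped to `[0, 100]`.
#' @export
notch_wt_fraction <- function(tree, timepoint = NULL,
                              marker_gene = "NOTCH1") {
  if (is.null(timepoint)) timepoint <- tree$timepoints[1]
  tp <- as.character(timepoint)
  if (!tp %in% as.character(tree$timepoints)) {
    stop_fmt("tree has no timepoint %s", tp)
  }
  ccfs <- vapply(tree$nodes, function(n) unname(n$ccf[tp]), numeric(1))
  ids <- vapply(tree$nodes, `[[`, character(1), "node_id")
  anc <- tree_ancestor_matrix(tree)
  has_marker <- vapply(tree$nodes, function(n) {
    any(grepl(paste0("^", marker_gene, "($|[:_.])"), n$events)) ||
      any(n$events == marker_gene)
  }, logical(1))
  carries <- vapply(seq_along(ids), function(i) {
    has_marker[i] || any(has_marker[anc[, ids[i]]])
  }, logical(1))
  largest <- max(ccfs)
  largest_marker <- if (any(carries)) max(ccfs[carries]) else 0
  clamp(100 * (largest - largest_marker), 0, 100)
}

#' Fit a Cox proportional-hazards model (Efron ties)
#'
#' Maximizes the Cox partial likelihood with Efron's tie correction by
#' Newton-Raphson (with step halving) to a gradient norm below `tol`.
#' Day-granularity relapse times make ties common, hence Efron rather than
#' Breslow. Reports the per-unit hazard ratio with a Wald 95% confidence
#' interval and p-value.
#'
#' @param time Positive event/censoring times.
#' @param status Event indicator (1/TRUE = observed).
#' @param x Covariate vector (or single-column matrix).
#' @param tol Convergence tolerance on the gradient norm (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#' @return A list with `beta`, `hr`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `n`, `n_events`, `converged`, `monotone` (perfect-separation flag).
#' @export
fit_cox_ph <- function(time, status, x, tol = 1e-8, max_iter = 50) {
  x <- as.numeric(x)
  status <- as.logical(status)
  stopifnot(length(time) == length(status), length(x) == length(time),
            all(time > 0))
  if (sum(status) < 2) stop_fmt("need at least 2 observed events")
  if (var(x) == 0) stop_fmt("covariate is constant; no information")
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; x <- x[ord]
  beta <- 0
  ll_fun <- function(b) cox_efron_ll(b, time, status, x)
  cur <- ll_fun(beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (abs(cur$grad) < tol) { converged <- TRUE; break }
    step <- cur$grad / max(cur$info, 1e-12)
    # step halving to keep the partial likelihood increasing
    for (h in 0:20) {
      cand <- ll_fun(beta + step / 2^h)
      if (cand$ll >= cur$ll - 1e-12) { beta <- beta + step / 2^h; cur <- cand; break }
    }
    if (abs(beta) > 200) break  # monotone likelihood
  }
  monotone <- !converged && abs(beta) > 50
  se <- 1 / sqrt(max(cur$info, 1e-300))
  z <- qnorm(0.975)
  list(beta = beta, hr = exp(beta), se = se,
       ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       p_value = 2 * pnorm(-abs(beta / se)),
       n = length(time), n_events = sum(status),
       converged = converged, monotone = monotone)
}

# Efron partial log-likelihood, gradient and information for scalar beta.
# Inputs must be sorted by time.
cox_efron_ll <- function(beta, time, status, x) {
  n <- length(time)
  eta <- beta * x
  w <- exp(eta)
  # risk-set suffix sums
  S0 <- rev(cumsum(rev(w)))
  S1 <- rev(cumsum(rev(w * x)))
  S2 <- rev(cumsum(rev(w * x^2)))
  ll <- 0; grad <- 0; info <- 0
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1] == time[i]) j <- j + 1
    dead <- which(status[i:j]) + i - 1
    d <- length(dead)
    if (d > 0) {
      wd <- w[dead]; xd <- x[dead]
      s0_tie <- sum(wd); s1_tie <- sum(wd * xd); s2_tie <- sum(wd * xd^2)
      for (l in seq_len(d)) {
        frac <- (l - 1) / d
        e0 <- S0[i] - frac * s0_tie
        e1 <- S1[i] - frac * s1_tie
        e2 <- S2[i] - frac * s2_tie
        ll <- ll - log(e0)
        grad <- grad - e1 / e0
        info <- info + e2 / e0 - (e1 / e0)^2
      }
      ll <- ll + sum(eta[dead])
      grad <- grad + sum(xd)
    }
    i <- j + 1
  }
  list(ll = ll, grad = grad, info = info)
}

#' Compare time to relapse between mutated and wild-type patients
#'
#' Two-sided Wilcoxon rank-sum test on time-to-relapse among relapsed
#' patients, split by mutation status of one gene.
#'
#' @param times Positive times to relapse of relapsed patients.
#' @param mutated Logical vector: gene mutated at diagnosis.
#' @return A list with `p_value`, `n_mutated`, `n_wildtype`, `method`.
#' @export
time_to_relapse_by_status <- function(times, mutated) {
  mutated <- as.logical(mutated)
  stopifnot(length(times) == length(mutated))
  if (sum(mutated) < 2 || sum(!mutated) < 2) {
    stop_fmt("need at least 2 relapsed patients per status group")
  }
  ht <- wilcox.test(times[mutated], times[!mutated], exact = NULL,
                    alternative = "two.sided")
  list(p_value = ht$p.value, n_mutated = sum(mutated),
       n_wildtype = sum(!mutated), method = "Wilcoxon rank-sum")
}
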