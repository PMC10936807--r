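#' Estimate the mean sequencing error rate from per-read divergences
#'
#' The global error rate epsilon is the arithmetic mean of per-read observed
#' error rates, taken from each BAM record's `de` tag (aligner-reported
#' per-base divergence). Reads lacking the tag are skipped and counted; if
#' no read carries it, the mean per-base error derived from base qualities
#' is used as a fallback (with a message).
#'
#' @param de Numeric vector of per-read `de` tag values (NA where absent).
#' @param fallback Optional scalar fallback (e.g. mean quality-derived
#'   per-base error) used when no read carries a `de` tag.
#' @return Estimated epsilon (scalar probability).
#' @export
estimate_epsilon <- function(de, fallback = NULL) {
  if (length(de) == 0L) stop("cannot estimate epsilon from an empty read stream")
  usable <- de[!is.na(de)]
  n_skipped <- sum(is.na(de))
  if (length(usable) > 0L) {
    if (n_skipped > 0L) {
      warning(n_skipped, " read(s) lacked a 'de' tag and were skipped when estimating epsilon")
    }
    return(mean(usable))
  }
  if (!is.null(fallback) && is.finite(fallback)) {
    message("no reads carry a 'de' tag; falling back to mean per-base error from qualities (",
            signif(fallback, 4), ")")
    return(fallback)
  }
  stop("no usable sequencing error information ('de' tags or base qualities); ",
       "pass a global error rate via `epsilon`/--epsilon")
}

#' Expected number of haplotagging errors among phaseable reads
#'
#' Each haplotagging decision is treated as a Bernoulli trial that fails
#' with probability `epsilon/3` (a sequencing error to one specific wrong
#' base), ignoring the number of variants per read as a conservative
#' simplification; the error count over N phaseable reads is then negative
#' binomial with mean `N * epsilon / 3`. The alternative `N * epsilon`
#' reading is exposed via `mean_rule = "eps"` for sensitivity analysis.
#'
#' @param n_phaseable Number of phaseable reads N (>= 0).
#' @param epsilon Mean per-base sequencing error rate.
#' @param mean_rule `"eps3"` (default, `N * epsilon/3`) or `"eps"`
#'   (`N * epsilon`).
#' @return Expected error count (float).
#' @export
expected_error_count <- function(n_phaseable, epsilon, mean_rule = c("eps3", "eps")) {
  stopifnot(n_phaseable >= 0, epsilon >= 0)
  mean_rule <- match.arg(mean_rule)
  per_read <- if (mean_rule == "eps3") epsilon / 3 else epsilon
  n_phaseable * per_read
}

#' Relabel the lowest-scoring tagged reads to control the FDR
#'
#' Post-hoc error control, independent of the scoring model: with an
#' expected E errors among the N phaseable reads (see
#' [expected_error_count()]), the `k = floor(E * (1 - fdr))` tagged reads
#' with the lowest LLR are relabeled "untagged". `fdr = 0` is the disable
#' sentinel: the filter is skipped entirely. The filter never changes which
#' haplotype a surviving read is tagged with and never touches untaggable
#' reads. Ties at the cut are broken by read name for determinism.
#'
#' @param decisions Data frame of per-read decisions with columns `qname`,
#'   `label` (`tagged`/`untagged`/`untaggable`) and `llr`.
#' @param fdr Target false discovery rate in `[0, 1]`; 0 disables.
#' @param epsilon Mean sequencing error rate used for the expectation.
#' @param mean_rule Passed to [expected_error_count()].
#' @return List with `decisions` (updated data frame; relabeled rows get
#'   `filter_reason = "fdr_filter"`) and `report`
#'   (N, epsilon, expected errors, k).
#' @export
apply_fdr_filter <- function(decisions, fdr, epsilon,
                             mean_rule = c("eps3", "eps")) {
  stopifnot(fdr >= 0, fdr <= 1)
  mean_rule <- match.arg(mean_rule)
  n_phaseable <- sum(decisions$label %in% c("tagged", "untagged"))
  if (fdr == 0) {
    return(list(decisions = decisions,
                report = list(n_phaseable = n_phaseable, epsilon = epsilon,
                              expected_errors = NA_real_, k = 0L,
                              skipped = TRUE)))
  }
  expected <- expected_error_count(n_phaseable, epsilon, mean_rule)
  k <- as.integer(floor(expected * (1 - fdr)))
  tagged_i <- which(decisions$label == "tagged")
  if (k >= length(tagged_i) && length(tagged_i) > 0L) {
    warning("FDR filter would remove all ", length(tagged_i), " tagged reads")
    k <- length(tagged_i)
  }
  if (k > 0L) {
    ord <- tagged_i[order(decisions$llr[tagged_i], decisions$qname[tagged_i])]
    drop <- ord[seq_len(k)]
    decisions$label[drop] <- "untagged"
    decisions$haplotype[drop] <- NA_integer_
    if (!"filter_reason" %in% names(decisions)) {
      decisions$filter_reason <- NA_character_
    }
    decisions$filter_reason[drop] <- "fdr_filter"
  }
  list(decisions = decisions,
       report = list(n_phaseable = n_phaseable, epsilon = epsilon,
                     expected_errors = expected, k = k, skipped = FALSE))
}
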