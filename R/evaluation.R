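#' Classify haplotag decisions against truth labels
#'
#' Applies the confusion-matrix definitions used for simulated benchmarks:
#' a correct tag on a phaseable read is a true positive; a wrong tag on a
#' phaseable read is a false positive; a phaseable read left untagged (or
#' wrongly deemed untaggable) is a false negative; a nonphasable read
#' labeled untaggable is a true negative. A nonphasable read that somehow
#' received a tag would count as a false positive; the engine never produces
#' these, and [evaluate_tagging()] asserts the count is zero.
#'
#' @param label Character vector: `tagged`, `untagged` or `untaggable`.
#' @param haplotype Integer vector of assigned haplotypes (NA if untagged).
#' @param truth_haplotype Integer vector of true haplotypes of origin.
#' @param phaseable Logical: does the read overlap >= 1 phased het variant?
#' @return Character vector in `{"TP","FP","TN","FN"}`.
#' @export
classify_tags <- function(label, haplotype, truth_haplotype, phaseable) {
  n <- length(label)
  stopifnot(length(haplotype) == n, length(truth_haplotype) == n,
            length(phaseable) == n)
  out <- character(n)
  tagged <- label == "tagged"
  out[phaseable & tagged & haplotype == truth_haplotype] <- "TP"
  out[phaseable & tagged & haplotype != truth_haplotype] <- "FP"
  out[phaseable & !tagged] <- "FN"
  out[!phaseable & !tagged] <- "TN"
  out[!phaseable & tagged] <- "FP"  # not observed in practice; asserted zero
  out
}

#' Precision-recall curve over LLR thresholds
#'
#' Sweeps every distinct LLR value as a tagging threshold, from the most to
#' the least confident, and reports precision and recall at each point.
#' Reads with identical LLR enter together, so the curve is deterministic
#' under ties and invariant to monotone transforms of the score. The area
#' under the curve is computed by the trapezoid rule over recall.
#'
#' @param llr Numeric vector of per-read LLR scores (tagged reads).
#' @param is_correct Logical vector: was the tag correct?
#' @param n_positives Recall denominator; defaults to `length(llr)`. For
#'   benchmark evaluation this is the number of phaseable reads, so reads
#'   left untagged depress recall.
#' @return List with `points` (data frame: `threshold`, `recall`,
#'   `precision`) and `auc`.
#' @export
pr_curve <- function(llr, is_correct, n_positives = length(llr)) {
  stopifnot(length(llr) == length(is_correct), n_positives >= 1)
  if (sum(is_correct) == 0L) {
    o <- order(-llr)
    cum_tp <- cumsum(is_correct[o])
    cum_n <- seq_along(llr)
    last <- !duplicated(llr[o][length(llr):1])[length(llr):1]
    pts <- data.frame(threshold = llr[o][last],
                      recall = (cum_tp / n_positives)[last],
                      precision = (cum_tp / cum_n)[last])
    return(list(points = pts, auc = 0))
  }
  o <- order(-llr, !is_correct)
  s <- llr[o]
  correct <- is_correct[o]
  cum_tp <- cumsum(correct)
  cum_n <- seq_along(s)
  # keep the last entry of each distinct threshold (all ties included)
  last <- c(s[-1] != s[-length(s)], TRUE)
  thr <- s[last]
  recall <- (cum_tp / n_positives)[last]
  precision <- (cum_tp / cum_n)[last]
  # trapezoid over recall, anchored at recall 0 with the first precision
  r <- c(0, recall)
  p <- c(precision[1], precision)
  auc <- sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  list(points = data.frame(threshold = thr, recall = recall,
                           precision = precision),
       auc = auc)
}

#' Evaluate haplotagging decisions against a simulation truth table
#'
#' Joins the engine's per-read decision table with the simulator's truth
#' table on read name, determines phaseability by intersecting each read's
#' true alignment span with the variant store, and tabulates the confusion
#' matrix, the incorrect-haplotagging rate (IHR = FP / phaseable), the
#' false-negative rate (FNR = FN / phaseable), recall
#' (TP / phaseable), precision, and the precision-recall curve with its AUC.
#'
#' @param decisions Decision data frame from [haplotag_bam()] (columns
#'   `qname`, `label`, `haplotype`, `llr`).
#' @param truth Truth data frame (from the simulator's TSV: columns
#'   `read_name`, `haplotype`, `chrom`, `start`, `end`) or a path to it.
#' @param store A `variant_store` used to decide phaseability; if NULL, a
#'   `phaseable` column must already be present in `truth`.
#' @return An `eval_counts` object: tp/fp/tn/fn, `ihr`, `fnr`, `precision`,
#'   `recall`, `pr` (curve + AUC), and the joined per-read table.
#' @export
evaluate_tagging <- function(decisions, truth, store = NULL) {
  if (is.character(truth)) {
    truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
  }
  if (!"phaseable" %in% names(truth)) {
    if (is.null(store)) stop("need a variant_store (or a 'phaseable' truth column) to determine phaseability")
    tg <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$start, truth$end))
    truth$phaseable <- GenomicRanges::countOverlaps(tg, store$gr,
                                                    ignore.strand = TRUE) > 0L
  }
  m <- match(decisions$qname, truth$read_name)
  if (all(is.na(m))) stop("no read names shared between decisions and truth table")
  keep <- !is.na(m)
  d <- decisions[keep, , drop = FALSE]
  t <- truth[m[keep], , drop = FALSE]

  cls <- classify_tags(d$label, d$haplotype, t$haplotype, t$phaseable)
  counts <- c(tp = sum(cls == "TP"), fp = sum(cls == "FP"),
              tn = sum(cls == "TN"), fn = sum(cls == "FN"))
  phaseable_n <- sum(t$phaseable)
  tagged <- d$label == "tagged" & t$phaseable
  pr <- if (any(tagged)) {
    pr_curve(d$llr[tagged], cls[tagged] == "TP", n_positives = phaseable_n)
  } else NULL

  per_read <- data.frame(qname = d$qname, label = d$label,
                         haplotype = d$haplotype, llr = d$llr,
                         truth_haplotype = t$haplotype,
                         phaseable = t$phaseable, class = cls,
                         stringsAsFactors = FALSE)
  structure(list(
    tp = counts[["tp"]], fp = counts[["fp"]],
    tn = counts[["tn"]], fn = counts[["fn"]],
    n_phaseable = phaseable_n,
    ihr = counts[["fp"]] / phaseable_n,
    fnr = counts[["fn"]] / phaseable_n,
    recall = counts[["tp"]] / phaseable_n,
    precision = counts[["tp"]] / max(counts[["tp"]] + counts[["fp"]], 1L),
    pr = pr,
    per_read = per_read
  ), class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("haplotagging evaluation over %d phaseable reads:\n", x$n_phaseable))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  recall=%.4f%%  IHR=%.4f%%  FNR=%.4f%%  precision=%.6f\n",
              100 * x$recall, 100 * x$ihr, 100 * x$fnr, x$precision))
  if (!is.null(x$pr)) cat(sprintf("  PR-AUC=%.6f\n", x$pr$auc))
  invisible(x)
}

#' Rank test for concentration of haplotagging errors at low LLR
#'
#' One-sided Wilcoxon rank-sum test that incorrectly tagged reads have
#' stochastically lower LLR scores than correctly tagged reads.
#'
#' @param eval An `eval_counts` object from [evaluate_tagging()].
#' @return The `htest` object (p-value small when errors concentrate at low
#'   LLR), or NULL when either group is empty.
#' @export
llr_rank_test <- function(eval) {
  pr <- eval$per_read
  wrong <- pr$llr[pr$class == "FP"]
  right <- pr$llr[pr$class == "TP"]
  if (length(wrong) == 0L || length(right) == 0L) return(NULL)
  stats::wilcox.test(wrong, right, alternative = "less", exact = FALSE)
}

#' Write an evaluation report to TSV (and optionally plot the PR curve)
#'
#' @param eval An `eval_counts` object.
#' @param out_prefix Path prefix for `<prefix>.summary.tsv` and
#'   `<prefix>.per_read.tsv`.
#' @param plot If TRUE, writes `<prefix>.pr.pdf` with the PR curve.
#' @return Invisibly, the paths written.
#' @export
write_evaluation <- function(eval, out_prefix, plot = FALSE) {
  summary_path <- paste0(out_prefix, ".summary.tsv")
  per_read_path <- paste0(out_prefix, ".per_read.tsv")
  s <- data.frame(metric = c("tp", "fp", "tn", "fn", "n_phaseable",
                             "recall", "ihr", "fnr", "precision", "pr_auc"),
                  value = c(eval$tp, eval$fp, eval$tn, eval$fn, eval$n_phaseable,
                            eval$recall, eval$ihr, eval$fnr, eval$precision,
                            if (is.null(eval$pr)) NA else eval$pr$auc))
  utils::write.table(s, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(eval$per_read, per_read_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(summary_path, per_read_path)
  if (plot && !is.null(eval$pr)) {
    pdf_path <- paste0(out_prefix, ".pr.pdf")
    grDevices::pdf(pdf_path, width = 5, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(eval$pr$points$recall, eval$pr$points$precision, type = "l",
         xlab = "Recall", ylab = "Precision", ylim = c(0, 1),
         main = sprintf("PR curve (AUC = %.6f)", eval$pr$auc))
    paths <- c(paths, pdf_path)
  }
  invisible(paths)
}
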