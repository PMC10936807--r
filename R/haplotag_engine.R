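# End-to-end tagging engine. Primary mapped reads are intersected with the
# phased het SNVs of the variant store, the aligned base at each covered
# variant is recovered by walking the CIGAR, and the multinomial scoring
# chain labels every read tagged / untagged / untaggable.

# per-op alignment map for one read: reference-consuming ops with their
# reference interval and the query offset of their first base
build_op_table <- function(cigar, pos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  consumes_ref <- ops %in% c("M", "=", "X", "D", "N")
  consumes_query <- ops %in% c("M", "=", "X", "I", "S")
  ref_start <- pos + c(0L, cumsum(lens * consumes_ref))[seq_along(ops)]
  q_start <- 1L + c(0L, cumsum(lens * consumes_query))[seq_along(ops)]
  data.frame(op = ops, len = lens, ref_start = ref_start,
             ref_end = ref_start + ifelse(consumes_ref, lens, 0L) - 1L,
             q_start = q_start, stringsAsFactors = FALSE)[consumes_ref, ,
                                                          drop = FALSE]
}

# observations for one read over the variants it overlaps; deletions and
# reference skips at a variant yield no observation
read_observations_from_alignment <- function(seq_str, qual_str, cigar, pos,
                                             variants, epsilon_fallback) {
  opt <- build_op_table(cigar, pos)
  vp <- variants$pos
  idx <- findInterval(vp, opt$ref_start)
  ok <- idx >= 1L & vp <= opt$ref_end[pmax(idx, 1L)]
  aligned <- ok & opt$op[pmax(idx, 1L)] %in% c("M", "=", "X")
  if (!any(aligned)) {
    return(read_observations(character(0), numeric(0),
                             matrix(character(0), 0,
                                    sum(grepl("^allele_h", names(variants))))))
  }
  v <- variants[aligned, , drop = FALSE]
  i <- idx[aligned]
  qpos <- opt$q_start[i] + (v$pos - opt$ref_start[i])
  bases <- substring(seq_str, qpos, qpos)
  has_qual <- nzchar(qual_str) && qual_str != "*" &&
    nchar(qual_str) == nchar(seq_str)
  err <- if (has_qual) {
    q <- as.integer(charToRaw(qual_str)[qpos]) - 33L
    per_base_error(pmax(q, 0L))
  } else {
    rep(epsilon_fallback, length(qpos))
  }
  hap_cols <- grep("^allele_h", names(v), value = TRUE)
  read_observations(bases, clamp_error(err),
                    as.matrix(v[hap_cols]), pos = v$pos,
                    phase_set = v$phase_set)
}

#' Haplotag every read of a BAM file
#'
#' Iterates the primary, non-duplicate, mapped records of a
#' coordinate-sorted BAM, intersects each with the phased heterozygous SNVs
#' of the store, scores each phaseable read with the multinomial model
#' ([score_read()]) and labels it:
#' \itemize{
#'   \item `untaggable`: no overlapping het variant (no information);
#'   \item `untagged`: a score tie between haplotypes, or LLR not strictly
#'     above `llr_threshold`, or removed by the FDR filter;
#'   \item `tagged`: assigned to the argmax-LLR haplotype.
#' }
#' Reads spanning more than one phase set are scored within the phase set
#' contributing the most observations (a tie between phase sets leaves the
#' read untagged). When `fdr > 0` the negative-binomial error model
#' ([apply_fdr_filter()]) relabels the lowest-LLR tagged reads.
#'
#' When `out_dir` is given, output BAM(s) are written with the decision
#' appended to each record as tags: `HP:i` (1-based haplotype), `PS:i`
#' (phase set), `YT:Z` (label), `LL:f` (log10 LLR), `NV:i` (variants
#' covered), `MC:i`/`MM:i` (match/mismatch counts for the best haplotype)
#' and `EP:f` (mean epsilon used), plus a TSV summary.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM.
#' @param vcf Path to a phased VCF, or a pre-built `variant_store`.
#' @param sample Sample name in the VCF (defaults to its only sample).
#' @param out_dir Output directory; NULL returns decisions only.
#' @param prefix Output file prefix.
#' @param fdr Target FDR for the error model; 0 (default) disables it.
#' @param llr_threshold Minimum LLR (strict) for tagging; default 0.
#' @param epsilon Optional global error rate; estimated from `de` tags when
#'   NULL.
#' @param use_coefficient Include the multinomial coefficient in scores.
#' @param per_base_mode Use per-base quality-derived error rates (default);
#'   otherwise the global epsilon enters the likelihood for every base.
#' @param error_model_mean `"eps3"` or `"eps"`, see [expected_error_count()].
#' @param split_output Write three BAMs (tagged/untagged/untaggable) instead
#'   of one combined file.
#' @param tie_tol LLR tie tolerance.
#' @return A `haplotag_result` list: `decisions` (per-read data frame),
#'   `summary` (label counts), `epsilon`, `fdr_report`, and output paths
#'   when written.
#' @export
haplotag_bam <- function(bam, vcf, sample = NULL, out_dir = NULL,
                         prefix = "haplotag", fdr = 0, llr_threshold = 0,
                         epsilon = NULL, use_coefficient = TRUE,
                         per_base_mode = TRUE,
                         error_model_mean = c("eps3", "eps"),
                         split_output = FALSE, tie_tol = 1e-9) {
  error_model_mean <- match.arg(error_model_mean)
  store <- if (inherits(vcf, "variant_store")) vcf else parse_phased_vcf(vcf, sample)

  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    tag = "de", flag = flag)
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_reads <- length(b$qname)
  if (n_reads == 0L) stop("BAM contains no primary mapped reads")

  chroms <- as.character(b$rname)
  vcf_contigs <- unique(store$variants$chrom)
  missing_contigs <- setdiff(unique(chroms), vcf_contigs)
  if (length(missing_contigs)) {
    warning("BAM contig(s) absent from the VCF (reads there are untaggable): ",
            paste(missing_contigs, collapse = ", "))
  }

  seq_str <- as.character(b$seq)
  qual_str <- as.character(b$qual)
  widths <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  reads_gr <- GenomicRanges::GRanges(chroms,
                                     IRanges::IRanges(b$pos, width = widths))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(reads_gr, store$gr, ignore.strand = TRUE))
  hit_list <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  de <- if (!is.null(b$tag$de)) as.numeric(b$tag$de) else rep(NA_real_, n_reads)
  eps_fallback <- NULL
  if (all(is.na(de))) {
    # mean quality-derived per-base error over (a sample of) reads
    take <- seq_len(min(n_reads, 1000L))
    ok <- nchar(qual_str[take]) == nchar(seq_str[take]) & qual_str[take] != "*"
    eps_fallback <- if (any(ok)) {
      mean(vapply(take[ok], function(i) mean(phred_char_to_error(qual_str[i])),
                  numeric(1)))
    } else NULL
  }
  eps_global <- epsilon %||% estimate_epsilon(de, fallback = eps_fallback)

  labels <- rep("untaggable", n_reads)
  haplotype <- rep(NA_integer_, n_reads)
  phase_set <- rep(NA_integer_, n_reads)
  llr <- rep(NA_real_, n_reads)
  n_var <- integer(n_reads)
  n_match <- rep(NA_integer_, n_reads)
  n_mismatch <- rep(NA_integer_, n_reads)
  eps_used <- rep(NA_real_, n_reads)
  reason <- rep(NA_character_, n_reads)

  for (key in names(hit_list)) {
    i <- as.integer(key)
    variants <- store$variants[hit_list[[key]], , drop = FALSE]
    obs <- read_observations_from_alignment(seq_str[i], qual_str[i],
                                            b$cigar[i], b$pos[i], variants,
                                            eps_global)
    if (nrow(obs) == 0L) {
      # overlap exists but every variant base is deleted/skipped in the read
      labels[i] <- "untaggable"
      reason[i] <- "no_aligned_base_at_variants"
      next
    }
    # restrict scoring to the phase set with the most observations
    ps_counts <- table(obs$phase_set)
    if (length(ps_counts) > 1L) {
      top <- ps_counts[ps_counts == max(ps_counts)]
      if (length(top) > 1L) {
        labels[i] <- "untagged"
        reason[i] <- "cross_phase_set_tie"
        n_var[i] <- nrow(obs)
        next
      }
      obs <- obs[obs$phase_set == names(top), , drop = FALSE]
      reason[i] <- "multi_phase_set"
    }
    sc <- score_read(obs, ploidy = store$ploidy, epsilon_global = eps_global,
                     use_coefficient = use_coefficient,
                     per_base_mode = per_base_mode, tie_tol = tie_tol)
    n_var[i] <- sc$n_variants
    n_match[i] <- sc$n_matches_best
    n_mismatch[i] <- sc$n_mismatches_best
    eps_used[i] <- sc$mean_epsilon_used
    llr[i] <- sc$llr
    phase_set[i] <- as.integer(obs$phase_set[1])
    if (sc$tie) {
      labels[i] <- "untagged"
      reason[i] <- reason[i] %||% NA_character_
      if (is.na(reason[i])) reason[i] <- "llr_tie"
    } else if (sc$llr <= llr_threshold) {
      labels[i] <- "untagged"
      if (is.na(reason[i])) reason[i] <- "below_threshold"
    } else {
      labels[i] <- "tagged"
      haplotype[i] <- sc$best_haplotype
    }
  }

  decisions <- data.frame(
    qname = b$qname, flag = b$flag, chrom = chroms, pos = b$pos,
    label = labels, haplotype = haplotype, phase_set = phase_set,
    llr = llr, n_variants = n_var, n_matches = n_match,
    n_mismatches = n_mismatch, epsilon_used = eps_used, de = de,
    reason = reason, stringsAsFactors = FALSE)

  fdr_report <- NULL
  if (fdr > 0) {
    filt <- apply_fdr_filter(decisions, fdr, eps_global,
                             mean_rule = error_model_mean)
    decisions <- filt$decisions
    fdr_report <- filt$report
  }

  summary <- c(tagged = sum(decisions$label == "tagged"),
               untagged = sum(decisions$label == "untagged"),
               untaggable = sum(decisions$label == "untaggable"))

  result <- structure(list(decisions = decisions, summary = summary,
                           epsilon = eps_global, fdr = fdr,
                           fdr_report = fdr_report, store = store,
                           bam_in = bam), class = "haplotag_result")
  if (!is.null(out_dir)) {
    result$paths <- write_tagged_bam(result, bam, out_dir, prefix,
                                     split_output = split_output)
  }
  result
}

#' @export
print.haplotag_result <- function(x, ...) {
  cat(sprintf("haplotag result: %d tagged, %d untagged, %d untaggable (epsilon = %.4g)\n",
              x$summary[["tagged"]], x$summary[["untagged"]],
              x$summary[["untaggable"]], x$epsilon))
  if (!is.null(x$fdr_report) && !isTRUE(x$fdr_report$skipped)) {
    cat(sprintf("  FDR filter (%.2f): expected %.2f errors over %d phaseable reads; %d read(s) untagged\n",
                x$fdr, x$fdr_report$expected_errors,
                x$fdr_report$n_phaseable, x$fdr_report$k))
  }
  invisible(x)
}

# write decisions back onto the original records; every input record appears
# exactly once across the outputs (unprocessed secondary/supplementary/
# duplicate/unmapped records pass through to the untaggable stream)
write_tagged_bam <- function(result, bam, out_dir, prefix,
                             split_output = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- samtools_path()
  # --no-PG: keep identical inputs byte-identical in the outputs
  header <- system2(st, c("view", "--no-PG", "-H", shQuote(bam)), stdout = TRUE)
  body <- system2(st, c("view", "--no-PG", shQuote(bam)), stdout = TRUE)

  d <- result$decisions
  dkey <- paste(d$qname, d$flag, d$pos, sep = "|")
  f1 <- sub("\t.*$", "", body)
  rest <- sub("^[^\t]*\t", "", body)
  f2 <- sub("\t.*$", "", rest)
  rest <- sub("^[^\t]*\t[^\t]*\t", "", rest)
  f4 <- sub("\t.*$", "", rest)
  bkey <- paste(f1, f2, f4, sep = "|")
  m <- match(bkey, dkey)

  tag_suffix <- rep("", length(body))
  idx <- which(!is.na(m))
  dm <- d[m[idx], , drop = FALSE]
  parts <- paste0("\tYT:Z:", dm$label, "\tNV:i:", dm$n_variants)
  scored <- !is.na(dm$llr)
  parts[scored] <- paste0(parts[scored],
                          sprintf("\tLL:f:%.6g", dm$llr[scored]),
                          "\tMC:i:", dm$n_matches[scored],
                          "\tMM:i:", dm$n_mismatches[scored],
                          sprintf("\tEP:f:%.6g", dm$epsilon_used[scored]))
  tagged <- dm$label == "tagged"
  parts[tagged] <- paste0(parts[tagged],
                          "\tHP:i:", dm$haplotype[tagged],
                          "\tPS:i:", dm$phase_set[tagged])
  tag_suffix[idx] <- parts
  out_body <- paste0(body, tag_suffix)

  label_of <- rep("untaggable", length(body))
  label_of[idx] <- dm$label

  write_one <- function(lines, name) {
    sam <- file.path(out_dir, paste0(name, ".sam"))
    writeLines(c(header, lines), sam)
    bam_out <- file.path(out_dir, paste0(name, ".bam"))
    sam_to_bam(sam, bam_out)
    unlink(sam)
    bam_out
  }

  paths <- list()
  if (split_output) {
    for (lab in c("tagged", "untagged", "untaggable")) {
      paths[[lab]] <- write_one(out_body[label_of == lab],
                                paste0(prefix, ".", lab))
    }
  } else {
    paths$combined <- write_one(out_body, paste0(prefix, ".combined"))
  }
  summary_tsv <- file.path(out_dir, paste0(prefix, ".summary.tsv"))
  utils::write.table(result$decisions, summary_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$summary <- summary_tsv
  paths
}

#' Map a FASTQ with minimap2 (optional convenience)
#'
#' Thin wrapper over an external `minimap2` call with default long-read
#' parameters, followed by coordinate sorting and indexing. The core engine
#' never requires this; it exists so unmapped reads can enter the pipeline.
#'
#' @param fastq Path to a FASTQ file.
#' @param ref Path to the reference FASTA.
#' @param out_bam Output BAM path (default: alongside the FASTQ).
#' @return The output BAM path.
#' @export
map_fastq <- function(fastq, ref, out_bam = sub("\\.f(ast)?q$", ".bam", fastq)) {
  mm2 <- Sys.which("minimap2")
  if (!nzchar(mm2)) {
    stop("minimap2 is not available on PATH; install minimap2 or provide a pre-mapped BAM",
         call. = FALSE)
  }
  if (file.size(fastq) == 0L) warning("FASTQ is empty; producing an empty BAM")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  status <- system2(mm2, c("-a", shQuote(ref), shQuote(fastq)),
                    stdout = sam, stderr = FALSE)
  if (status != 0L) stop("minimap2 failed (exit ", status, ")")
  sam_to_bam(sam, out_bam)
  out_bam
}
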