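#' Parse phased heterozygous SNVs from a VCF into a variant store
#'
#' Reads a VCF (plain or bgzip-compressed) with `VariantAnnotation` and keeps
#' only records usable for haplotagging: phased ("|" separator),
#' heterozygous, single-nucleotide genotypes. Indels, structural and
#' symbolic alleles, unphased and homozygous genotypes are excluded;
#' exclusion counts are tallied by category. Multi-allelic sites are kept as
#' long as the two (or more) phased alleles are distinct single nucleotides.
#' Variants are grouped into phase sets by the FORMAT/PS tag; phased
#' genotypes lacking a PS tag are assigned a per-contig default phase set
#' and counted.
#'
#' @param vcf_path Path to a VCF file (.vcf or .vcf.gz).
#' @param sample Sample name; defaults to the only sample in single-sample
#'   files.
#' @return A `variant_store` object: a list with `variants` (data frame:
#'   `chrom`, `pos` 1-based, `ref`, `alt`, `phase_set`, `allele_h1`, ...,
#'   per-haplotype phased alleles), `gr` (a [GenomicRanges::GRanges] index),
#'   `sample`, `ploidy`, and `excluded` (named counts by category).
#' @export
parse_phased_vcf <- function(vcf_path, sample = NULL) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  samples <- colnames(vcf)
  if (is.null(sample)) {
    if (length(samples) != 1L) {
      stop("VCF has ", length(samples), " samples; pass `sample` (one of: ",
           paste(samples, collapse = ", "), ")")
    }
    sample <- samples[1L]
  }
  if (!sample %in% samples) {
    stop("sample '", sample, "' not found in VCF; available samples: ",
         paste(samples, collapse = ", "))
  }

  n_rec <- nrow(vcf)
  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, sample])
  ps_raw <- if ("PS" %in% names(VariantAnnotation::geno(vcf))) {
    VariantAnnotation::geno(vcf)$PS[, sample]
  } else rep(NA, n_rec)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt_list <- VariantAnnotation::alt(vcf)

  excluded <- c(no_genotype = 0L, unphased = 0L, homozygous = 0L,
                not_snv = 0L)
  n_default_ps <- 0L

  phased <- grepl("|", gt, fixed = TRUE) & !grepl("\\.", gt)
  no_gt <- is.na(gt) | gt %in% c(".", "./.", ".|.") | grepl("\\.", gt)
  excluded["no_genotype"] <- sum(no_gt)
  excluded["unphased"] <- sum(!phased & !no_gt)

  idx <- which(phased)
  alleles_idx <- strsplit(gt[idx], "|", fixed = TRUE)
  ploidies <- lengths(alleles_idx)
  l <- if (length(ploidies)) max(ploidies) else 2L
  if (length(ploidies) && length(unique(ploidies)) > 1L) {
    stop("mixed ploidy among phased genotypes is not supported")
  }

  keep <- logical(length(idx))
  allele_mat <- matrix(NA_character_, nrow = length(idx), ncol = l)
  for (k in seq_along(idx)) {
    i <- idx[k]
    ai <- suppressWarnings(as.integer(alleles_idx[[k]]))
    site_alleles <- c(ref[i], as.character(alt_list[[i]]))
    if (anyNA(ai) || any(ai + 1L > length(site_alleles))) {
      excluded["no_genotype"] <- excluded["no_genotype"] + 1L
      next
    }
    ha <- site_alleles[ai + 1L]
    if (length(unique(ha)) < 2L) {
      excluded["homozygous"] <- excluded["homozygous"] + 1L
      next
    }
    is_snv <- nchar(ref[i]) == 1L && all(nchar(ha) == 1L) &&
      all(ha %in% c("A", "C", "G", "T")) && ref[i] %in% c("A", "C", "G", "T")
    if (!is_snv) {
      excluded["not_snv"] <- excluded["not_snv"] + 1L
      next
    }
    keep[k] <- TRUE
    allele_mat[k, ] <- ha
  }

  kept <- idx[keep]
  if (length(kept) == 0L) {
    stop("VCF yields an empty variant store: no phased heterozygous SNVs for sample '",
         sample, "'")
  }
  allele_mat <- allele_mat[keep, , drop = FALSE]

  ps <- ps_raw[kept]
  ps_int <- suppressWarnings(as.integer(as.character(ps)))
  missing_ps <- is.na(ps_int)
  if (any(missing_ps)) {
    # per-contig default phase set in a reserved high range
    contig_index <- match(chrom[kept], unique(chrom[kept]))
    ps_int[missing_ps] <- 2000000000L + contig_index[missing_ps]
    n_default_ps <- sum(missing_ps)
    message(sum(missing_ps), " phased genotype(s) lacked a PS tag; assigned per-contig default phase set")
  }

  variants <- data.frame(
    chrom = chrom[kept], pos = pos[kept], ref = ref[kept],
    alt = vapply(as.list(alt_list[kept]), function(a) paste(as.character(a), collapse = ","), character(1)),
    phase_set = ps_int, stringsAsFactors = FALSE)
  for (i in seq_len(l)) variants[[paste0("allele_h", i)]] <- allele_mat[, i]
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  gr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, width = 1L))
  structure(list(variants = variants, gr = gr, sample = sample, ploidy = l,
                 n_records = n_rec, excluded = excluded,
                 n_default_ps = n_default_ps),
            class = "variant_store")
}

#' @export
print.variant_store <- function(x, ...) {
  cat(sprintf("variant_store: %d phased het SNVs for sample '%s' (ploidy %d) in %d phase set(s)\n",
              nrow(x$variants), x$sample, x$ploidy,
              length(unique(x$variants$phase_set))))
  exc <- x$excluded[x$excluded > 0]
  if (length(exc)) {
    cat("excluded records:", paste(names(exc), exc, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' List the phase sets of a variant store
#'
#' @param store A `variant_store`.
#' @return Named list of data frames, one per phase set id, each holding the
#'   member variants ordered by position.
#' @export
phase_sets <- function(store) {
  stopifnot(inherits(store, "variant_store"))
  split(store$variants, store$variants$phase_set)
}

#' Query phased variants overlapping a genomic window
#'
#' Coordinates are 0-based half-open (`[start, end)`), the convention of BAM
#' alignment arithmetic; VCF 1-based positions are converted internally. A
#' contig absent from the store yields an empty result, not an error.
#'
#' @param store A `variant_store`.
#' @param chrom Contig name.
#' @param start 0-based inclusive window start.
#' @param end 0-based exclusive window end.
#' @return Data frame of overlapping variants, sorted by position.
#' @export
query_overlaps <- function(store, chrom, start, end) {
  stopifnot(inherits(store, "variant_store"))
  if (start > end) stop("query start must be <= end")
  if (start == end) return(store$variants[0, , drop = FALSE])
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  # a contig absent from the store is a legitimate empty query, not an error
  hits <- tryCatch(
    suppressWarnings(GenomicRanges::findOverlaps(q, store$gr,
                                                 ignore.strand = TRUE)),
    error = function(e) NULL)
  if (is.null(hits)) return(store$variants[0, , drop = FALSE])
  out <- store$variants[S4Vectors::subjectHits(hits), , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}
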