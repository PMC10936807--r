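# Text-level VCF repair. This works below the level of VCF parsers on
# purpose: the defects being repaired (string PS tags, genotype fields not
# declared in FORMAT) make spec-compliant parsers reject the file.

# chromosome number for the PS suffix; X/Y/M get 24/25/26
contig_number <- function(chrom, fallback_env) {
  base <- sub("^chr", "", chrom, ignore.case = TRUE)
  if (grepl("^[0-9]+$", base)) return(as.integer(base))
  if (toupper(base) == "X") return(24L)
  if (toupper(base) == "Y") return(25L)
  if (toupper(base) %in% c("M", "MT")) return(26L)
  # unmappable contig names fall back to a deterministic index by appearance
  if (is.null(fallback_env$map[[chrom]])) {
    fallback_env$map[[chrom]] <- 27L + length(fallback_env$map)
    fallback_env$unmapped <- c(fallback_env$unmapped, chrom)
  }
  fallback_env$map[[chrom]]
}

is_snv_record <- function(ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)[[1]]
  nchar(ref) == 1L && ref %in% c("A", "C", "G", "T") &&
    all(nchar(alts) == 1L) && all(alts %in% c("A", "C", "G", "T"))
}

#' Repair a spec-noncompliant phased VCF
#'
#' Fixes the defect classes commonly seen in consortium phased VCFs so the
#' output parses under VCF 4.3:
#' \enumerate{
#'   \item String phase-set (PS) tags are transliterated to integers by
#'     concatenating a unique ordinal per distinct PS string with a
#'     two-digit chromosome number (X, Y and M map to 24, 25 and 26;
#'     other unmappable contigs get a deterministic index and are reported).
#'   \item The original PS string is preserved under a new FORMAT tag `OPS`.
#'   \item A sample column header reading `INTEGRATION` is replaced with
#'     `sample_name`.
#'   \item Genotype fields not declared in the FORMAT string are removed.
#'   \item Indel and structural-variant records are dropped; every SNV
#'     record is kept.
#' }
#'
#' @param vcf_in Path to the input VCF (.vcf or gzip/bgzip-compressed).
#' @param vcf_out Output path; a `.gz` suffix triggers bgzip compression and
#'   tabix indexing.
#' @param sample_name Sample name to place in the column header.
#' @return Invisibly, a rescue report: counts per repair category, the
#'   PS-string-to-integer map, and any contigs that needed the fallback
#'   numbering.
#' @export
rescue_vcf <- function(vcf_in, vcf_out, sample_name) {
  con <- if (grepl("\\.gz$", vcf_in)) gzfile(vcf_in, "rt") else file(vcf_in, "rt")
  lines <- readLines(con)
  close(con)

  is_meta <- startsWith(lines, "##")
  header_i <- which(startsWith(lines, "#CHROM"))
  if (length(header_i) != 1L) stop("input does not look like a VCF: no #CHROM header line")

  meta <- lines[is_meta]
  meta[grepl("^##fileformat=", meta)] <- "##fileformat=VCFv4.3"
  # PS must be Integer under 4.3; rewrite a String declaration
  ps_i <- grep("^##FORMAT=<ID=PS,", meta)
  if (length(ps_i)) {
    meta[ps_i] <- sub("Type=String", "Type=Integer", meta[ps_i])
  } else {
    meta <- c(meta, "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">")
  }
  if (!any(grepl("^##FORMAT=<ID=OPS,", meta))) {
    meta <- c(meta,
              "##FORMAT=<ID=OPS,Number=1,Type=String,Description=\"Original phase set identifier before integer transliteration\">")
  }

  header <- strsplit(lines[header_i], "\t", fixed = TRUE)[[1]]
  replaced_header <- any(header == "INTEGRATION")
  header[header == "INTEGRATION"] <- sample_name

  records <- lines[seq_along(lines) > header_i]
  records <- records[nzchar(records)]

  ps_ordinals <- new.env(parent = emptyenv())  # PS string -> ordinal
  fallback_env <- new.env(parent = emptyenv())
  fallback_env$map <- list()
  fallback_env$unmapped <- character(0)
  ps_map <- list()

  n_dropped <- 0L
  n_translit <- 0L
  n_gt_repaired <- 0L
  out_records <- character(0)
  out_records <- vector("list", length(records))
  kept <- 0L

  for (line in records) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10L) next
    if (!is_snv_record(f[4], f[5])) { n_dropped <- n_dropped + 1L; next }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    nfmt <- length(fmt)
    ps_pos <- match("PS", fmt)
    add_ops <- FALSE
    ops_vals <- character(length(f) - 9L)
    for (j in 10:length(f)) {
      g <- strsplit(f[j], ":", fixed = TRUE)[[1]]
      if (length(g) > nfmt) {  # undeclared trailing fields: remove
        g <- g[seq_len(nfmt)]
        n_gt_repaired <- n_gt_repaired + 1L
      }
      if (!is.na(ps_pos) && length(g) >= ps_pos) {
        psv <- g[ps_pos]
        if (!psv %in% c(".", "") && !grepl("^[0-9]+$", psv)) {
          if (is.null(ps_ordinals[[psv]])) {
            ps_ordinals[[psv]] <- length(ls(ps_ordinals)) + 1L
          }
          cn <- contig_number(f[1], fallback_env)
          new_ps <- as.integer(sprintf("%d%02d", ps_ordinals[[psv]], cn))
          key <- paste0(psv, "@", f[1])
          ps_map[[key]] <- new_ps
          g[ps_pos] <- as.character(new_ps)
          ops_vals[j - 9L] <- psv
          add_ops <- TRUE
          n_translit <- n_translit + 1L
        }
      }
      f[j] <- paste(g, collapse = ":")
    }
    if (add_ops) {
      f[9] <- paste(c(fmt, "OPS"), collapse = ":")
      for (j in 10:length(f)) {
        ov <- if (nzchar(ops_vals[j - 9L])) ops_vals[j - 9L] else "."
        f[j] <- paste(c(f[j], ov), collapse = ":")
      }
    }
    kept <- kept + 1L
    out_records[[kept]] <- paste(f, collapse = "\t")
  }

  # coordinate-sort records (contigs by first appearance) so the output can
  # be bgzip-compressed and tabix-indexed directly
  recs <- unlist(out_records[seq_len(kept)])
  if (kept > 0L) {
    rchrom <- sub("\t.*$", "", recs)
    rpos <- as.integer(sub("\t.*$", "", sub("^[^\t]*\t", "", recs)))
    recs <- recs[order(match(rchrom, unique(rchrom)), rpos)]
  }
  out_lines <- c(meta, paste(header, collapse = "\t"), recs)
  gz_out <- grepl("\\.gz$", vcf_out)
  plain <- if (gz_out) sub("\\.gz$", "", vcf_out) else vcf_out
  writeLines(out_lines, plain)
  if (gz_out) {
    Rsamtools::bgzip(plain, dest = vcf_out, overwrite = TRUE)
    unlink(plain)
    Rsamtools::indexTabix(vcf_out, format = "vcf")
  }

  report <- list(
    n_records = length(records),
    n_kept = kept,
    n_dropped_not_snv = n_dropped,
    n_ps_transliterated = n_translit,
    n_genotype_repaired = n_gt_repaired,
    header_sample_replaced = replaced_header,
    ps_map = unlist(ps_map),
    fallback_contigs = fallback_env$unmapped,
    out = vcf_out)
  if (length(fallback_env$unmapped)) {
    warning("contig name(s) without a standard chromosome number: ",
            paste(fallback_env$unmapped, collapse = ", "),
            "; used deterministic fallback indices")
  }
  invisible(report)
}
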