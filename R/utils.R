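# internal numeric and system helpers

# log10 sum of values given in log10 space, stable for large spreads
log10_sum <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log10(sum(10^(x - m)))
}

# probabilities passed to log() must stay inside (0,1): q=0 bases give e=1
.EPS_CLAMP <- 1e-12

clamp_error <- function(e) {
  pmin(pmax(e, .EPS_CLAMP), 1 - .EPS_CLAMP)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

samtools_path <- function() {
  st <- Sys.which("samtools")
  if (!nzchar(st)) {
    stop("samtools not found on PATH; it is required to read/write BAM output",
         call. = FALSE)
  }
  unname(st)
}

run_samtools <- function(args) {
  st <- samtools_path()
  status <- system2(st, args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) {
    stop("samtools ", paste(args, collapse = " "), " failed (exit ", status, ")",
         call. = FALSE)
  }
  invisible(status)
}

# SAM text -> coordinate-sorted, indexed BAM
sam_to_bam <- function(sam_path, bam_path) {
  # --no-PG keeps identical inputs byte-identical (no @PG command lines
  # embedding temp paths)
  run_samtools(c("sort", "--no-PG", "-O", "bam", "-o", shQuote(bam_path),
                 shQuote(sam_path)))
  run_samtools(c("index", shQuote(bam_path)))
  invisible(bam_path)
}

phred_char_to_error <- function(qual_string) {
  q <- as.integer(charToRaw(qual_string)) - 33L
  per_base_error(pmax(q, 0L))
}
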