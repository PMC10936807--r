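# Truth-labeled diploid long-read simulator. Reads are drawn from
# haplotype-specific consensus sequences and emitted directly as aligned
# BAM records: because only SNVs separate the haplotypes, consensus
# coordinates equal reference coordinates, so the true origin of each read
# gives its alignment (POS + CIGAR from the error-injection trace) exactly,
# with no external aligner in the loop.

.SIM_BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults emulate a MinION R10.4.1-like long-read run: mean read length
#' 25 kb (sd 20 kb, truncated to \[100 bp, 1 Mb\]), mean per-read accuracy
#' 0.98 (truncated normal on \[0.01, 1\]), and substitution:insertion:deletion
#' error proportions 23:31:46. The heterozygous SNV rate of 1/1500 bp
#' approximates human heterozygosity (individual genomes differ from the
#' reference at roughly 4-5 million sites). Depth is per haplotype.
#'
#' @param genome_length Contig length in bp.
#' @param het_snv_rate Expected phased het SNVs per bp.
#' @param depth Fold coverage drawn per haplotype.
#' @param length_mean,length_sd,length_min,length_max Read length law (bp):
#'   gamma moment-matched to mean/sd, then clipped to `[min, max]`.
#' @param accuracy_mean,accuracy_sd,accuracy_min,accuracy_max Per-read
#'   accuracy law (truncated normal).
#' @param error_ratio Integer triple of substitution:insertion:deletion
#'   weights.
#' @param seed Optional RNG seed for end-to-end deterministic datasets.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 1e6, het_snv_rate = 1 / 1500,
                       depth = 1,
                       length_mean = 25000, length_sd = 20000,
                       length_min = 100, length_max = 1000000,
                       accuracy_mean = 0.98, accuracy_sd = 0.02,
                       accuracy_min = 0.01, accuracy_max = 1.00,
                       error_ratio = c(23, 31, 46), seed = NULL) {
  cfg <- list(genome_length = genome_length, het_snv_rate = het_snv_rate,
              depth = depth, length_mean = length_mean, length_sd = length_sd,
              length_min = length_min, length_max = length_max,
              accuracy_mean = accuracy_mean, accuracy_sd = accuracy_sd,
              accuracy_min = accuracy_min, accuracy_max = accuracy_max,
              error_ratio = error_ratio, seed = seed)
  stopifnot(genome_length >= 1000, depth > 0,
            length_mean > 0, length_sd > 0, length_min >= 1,
            length_max >= length_min,
            accuracy_min > 0, accuracy_max <= 1,
            accuracy_mean >= accuracy_min, accuracy_mean <= accuracy_max,
            length(error_ratio) == 3, all(error_ratio >= 0),
            sum(error_ratio) > 0)
  if (het_snv_rate * genome_length < 1) {
    stop("het_snv_rate * genome_length must be >= 1 (need at least one variant)")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random reference genome and phased heterozygous SNVs
#'
#' Draws a uniform-random reference contig and scatters phased het SNVs at
#' the configured density (Poisson-distributed count, collision-free
#' positions). Each variant gets a random non-reference alternate allele
#' and a random phase orientation (`0|1` or `1|0`); all variants on the
#' contig share one phase set. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param contig Contig name.
#' @param sample Sample name written to the VCF.
#' @return List of paths: `fasta`, `vcf` (plain), `vcf_gz` (bgzip + tabix),
#'   plus the variant count `n_variants`.
#' @export
generate_truth_genome <- function(config, dir, contig = "sim1", sample = "SIM") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  glen <- as.integer(config$genome_length)
  ref_chars <- sample(.SIM_BASES, glen, replace = TRUE)

  n_var <- stats::rpois(1, config$het_snv_rate * glen)
  n_var <- max(n_var, 1L)
  pos <- sort(sample.int(glen, n_var))
  ref_at <- ref_chars[pos]
  # alternate allele: any of the three non-reference bases
  shift <- sample.int(3L, n_var, replace = TRUE)
  alt_at <- .SIM_BASES[((match(ref_at, .SIM_BASES) - 1L + shift) %% 4L) + 1L]
  flip <- stats::runif(n_var) < 0.5
  gt <- ifelse(flip, "1|0", "0|1")

  fasta <- file.path(dir, "reference.fa")
  dna <- Biostrings::DNAStringSet(paste(ref_chars, collapse = ""))
  names(dna) <- contig
  Biostrings::writeXStringSet(dna, fasta)
  Rsamtools::indexFa(fasta)

  vcf <- file.path(dir, "truth.vcf")
  header <- c(
    "##fileformat=VCFv4.3",
    sprintf("##contig=<ID=%s,length=%d>", contig, glen),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"))
  records <- paste(contig, pos, ".", ref_at, alt_at, ".", "PASS", ".",
                   "GT:PS", paste0(gt, ":1"), sep = "\t")
  writeLines(c(header, records), vcf)
  vcf_gz <- paste0(vcf, ".gz")
  Rsamtools::bgzip(vcf, dest = vcf_gz, overwrite = TRUE)
  Rsamtools::indexTabix(vcf_gz, format = "vcf")

  list(fasta = fasta, vcf = vcf, vcf_gz = vcf_gz, n_variants = n_var,
       contig = contig, sample = sample)
}

#' Build a haplotype-specific consensus sequence
#'
#' Applies one haplotype's phased alleles to the reference. Because only
#' SNVs are involved, coordinates are preserved, so consensus position i
#' equals reference position i.
#'
#' @param reference Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param store A `variant_store` (or a path/VCF parseable into one).
#' @param haplotype Haplotype index (1-based).
#' @param out_fasta Optional path; when given the consensus is written there.
#' @return A [Biostrings::DNAStringSet] with one consensus per contig.
#' @export
build_haplotype_consensus <- function(reference, store, haplotype,
                                      out_fasta = NULL) {
  dna <- if (is.character(reference)) {
    Biostrings::readDNAStringSet(reference)
  } else reference
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (is.character(store)) store <- parse_phased_vcf(store)
  stopifnot(inherits(store, "variant_store"),
            haplotype >= 1, haplotype <= store$ploidy)
  col <- paste0("allele_h", haplotype)
  v <- store$variants
  for (ctg in unique(v$chrom)) {
    if (!ctg %in% names(dna)) next
    rows <- v$chrom == ctg
    dna[[ctg]] <- Biostrings::replaceLetterAt(
      dna[[ctg]], v$pos[rows], paste(v[[col]][rows], collapse = ""))
  }
  if (!is.null(out_fasta)) {
    Biostrings::writeXStringSet(dna, out_fasta)
    Rsamtools::indexFa(out_fasta)
  }
  dna
}

# truncated normal by rejection
rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(max(n, 100L), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# draw read lengths until cumulative coverage target is met
draw_read_lengths <- function(target_bases, config, contig_length) {
  shape <- (config$length_mean / config$length_sd)^2
  rate <- config$length_mean / config$length_sd^2
  lens <- integer(0)
  while (sum(lens) < target_bases) {
    batch <- max(32L, ceiling((target_bases - sum(lens)) / config$length_mean))
    x <- as.integer(round(stats::rgamma(batch, shape = shape, rate = rate)))
    x <- pmax(pmin(x, config$length_max, contig_length), config$length_min)
    lens <- c(lens, x)
  }
  lens[seq_len(which(cumsum(lens) >= target_bases)[1])]
}

# inject substitution/insertion/deletion errors into one read drawn from the
# consensus; returns the erroneous sequence, the CIGAR versus the reference,
# the adjusted alignment start offset, and the realized error counts
inject_read_errors <- function(ref_chars, err_rate, error_ratio) {
  L <- length(ref_chars)
  n_err <- stats::rbinom(1L, L, min(err_rate, 0.75))
  if (n_err == 0L) {
    return(list(seq = paste(ref_chars, collapse = ""),
                cigar = paste0(L, "M"), start_offset = 0L, ref_span = L,
                n_sub = 0L, n_ins = 0L, n_del = 0L))
  }
  pos <- sort(sample.int(L, n_err))
  type <- sample(c("S", "I", "D"), n_err, replace = TRUE,
                 prob = error_ratio / sum(error_ratio))

  x <- ref_chars
  sub_pos <- pos[type == "S"]
  if (length(sub_pos)) {
    shift <- sample.int(3L, length(sub_pos), replace = TRUE)
    x[sub_pos] <- .SIM_BASES[((match(x[sub_pos], .SIM_BASES) - 1L + shift) %% 4L) + 1L]
  }
  del_pos <- pos[type == "D"]
  ins_pos <- pos[type == "I"]
  keep <- rep(TRUE, L)
  keep[del_pos] <- FALSE
  ins_chars <- sample(.SIM_BASES, length(ins_pos), replace = TRUE)
  # interleave: original bases sort before an insertion at the same position
  all_chars <- c(x[keep], ins_chars)
  all_keys <- c(2 * seq_len(L)[keep], 2 * ins_pos + 1)
  seq_out <- paste(all_chars[order(all_keys)], collapse = "")

  # CIGAR over indel events (substitutions stay M): between consecutive
  # events lies an M gap; a deletion consumes the reference base at its own
  # position, an insertion sits after it
  ev_pos <- c(del_pos, ins_pos)
  ev_type <- c(rep("D", length(del_pos)), rep("I", length(ins_pos)))
  o <- order(ev_pos + ifelse(ev_type == "I", 0.5, 0))
  ev_pos <- ev_pos[o]; ev_type <- ev_type[o]
  n_ev <- length(ev_pos)
  if (n_ev > 0L) {
    gap <- ev_pos - c(0L, ev_pos[-n_ev]) - (ev_type == "D")
    ops <- as.vector(rbind(rep("M", n_ev), ev_type))
    lens <- as.vector(rbind(gap, rep(1L, n_ev)))
    if (L - ev_pos[n_ev] > 0L) {
      ops <- c(ops, "M"); lens <- c(lens, L - ev_pos[n_ev])
    }
    pos_len <- lens > 0L
    ops <- ops[pos_len]; lens <- lens[pos_len]
  } else {
    ops <- "M"; lens <- L
  }
  # merge adjacent identical ops
  grp <- cumsum(c(TRUE, ops[-1] != ops[-length(ops)]))
  lens <- as.integer(rowsum(lens, grp))
  ops <- ops[!duplicated(grp)]
  # alignments cannot begin/end with D; leading/trailing I become soft clips
  start_offset <- 0L
  if (ops[1] == "D") { start_offset <- lens[1]; ops <- ops[-1]; lens <- lens[-1] }
  if (ops[length(ops)] == "D") { ops <- ops[-length(ops)]; lens <- lens[-length(lens)] }
  if (ops[1] == "I") ops[1] <- "S"
  if (ops[length(ops)] == "I") ops[length(ops)] <- "S"
  list(seq = seq_out,
       cigar = paste0(lens, ops, collapse = ""),
       start_offset = start_offset,
       ref_span = sum(lens[ops %in% c("M", "D")]),
       n_sub = length(sub_pos), n_ins = length(ins_pos),
       n_del = length(del_pos))
}

#' Simulate error-bearing long reads from haplotype consensus sequences
#'
#' Draws reads from each haplotype consensus up to `config$depth` coverage
#' per haplotype. Read lengths follow a gamma law moment-matched to the
#' configured mean/sd and clipped to `[length_min, length_max]`; per-read
#' accuracy follows a truncated normal; sequencing errors are placed
#' uniformly along the read with substitution:insertion:deletion
#' proportions given by `error_ratio`. Base qualities encode the Phred
#' equivalent of each read's error rate, and the realized per-read error
#' rate is written to the `de` tag. Records are emitted directly as an
#' aligned, coordinate-sorted, indexed BAM whose POS/CIGAR come from the
#' error-injection trace; the true haplotype and origin coordinates are
#' encoded in each read name (`sim!contig!h<i>!start!end!serial`) and in a
#' tab-separated truth table.
#'
#' @param consensus List of [Biostrings::DNAStringSet], one per haplotype
#'   (index = haplotype).
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @param emit_fastq Also write a FASTQ of the simulated reads (for true
#'   end-to-end runs through an external aligner).
#' @return List: `bam`, `truth` (data frame), `truth_tsv`, `n_reads`,
#'   error-type totals, and `fastq` when requested.
#' @export
simulate_reads <- function(consensus, config, dir, prefix = "sim",
                           emit_fastq = FALSE) {
  stopifnot(inherits(config, "sim_config"), length(consensus) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contigs <- names(consensus[[1]])
  clens <- Biostrings::width(consensus[[1]])

  sam_lines <- list()
  fq_lines <- list()
  t_name <- t_chrom <- character(0)
  t_hap <- t_start <- t_end <- t_len <- integer(0)
  t_acc <- numeric(0)
  serial <- 0L
  tot <- c(sub = 0L, ins = 0L, del = 0L)

  for (hap in seq_along(consensus)) {
    for (ci in seq_along(contigs)) {
      ctg <- contigs[ci]
      clen <- clens[ci]
      cons_str <- as.character(consensus[[hap]][[ci]])
      lens <- draw_read_lengths(config$depth * clen, config, clen)
      n <- length(lens)
      starts <- 1L + as.integer(floor(stats::runif(n) * (clen - lens + 1)))
      accs <- rtnorm(n, config$accuracy_mean, config$accuracy_sd,
                     config$accuracy_min, config$accuracy_max)
      hap_names <- character(n); hap_starts <- integer(n); hap_ends <- integer(n)
      for (i in seq_len(n)) {
        serial <- serial + 1L
        L <- lens[i]
        frag <- strsplit(substr(cons_str, starts[i], starts[i] + L - 1L), "",
                         fixed = TRUE)[[1]]
        err_rate <- 1 - accs[i]
        er <- inject_read_errors(frag, err_rate, config$error_ratio)
        pos0 <- starts[i] + er$start_offset
        end0 <- pos0 + er$ref_span - 1L
        qname <- sprintf("sim!%s!h%d!%d!%d!%06d", ctg, hap, pos0, end0, serial)
        n_err <- er$n_sub + er$n_ins + er$n_del
        de <- n_err / L
        q <- if (n_err == 0L) 60L else {
          as.integer(max(2L, min(60L, round(-10 * log10(de)))))
        }
        qual <- strrep(rawToChar(as.raw(q + 33L)), nchar(er$seq))
        sam_lines[[serial]] <- paste(
          qname, 0L, ctg, pos0, 60L, er$cigar, "*", 0L, 0L, er$seq, qual,
          sprintf("de:f:%.6g", de), sep = "\t")
        hap_names[i] <- qname; hap_starts[i] <- pos0; hap_ends[i] <- end0
        tot <- tot + c(sub = er$n_sub, ins = er$n_ins, del = er$n_del)
        if (emit_fastq) {
          fq_lines[[serial]] <- c(paste0("@", qname), er$seq, "+", qual)
        }
      }
      t_name <- c(t_name, hap_names)
      t_chrom <- c(t_chrom, rep(ctg, n))
      t_hap <- c(t_hap, rep(hap, n))
      t_start <- c(t_start, hap_starts)
      t_end <- c(t_end, hap_ends)
      t_len <- c(t_len, lens)
      t_acc <- c(t_acc, accs)
    }
  }

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", contigs, clens))
  sam_path <- file.path(dir, paste0(prefix, ".sam"))
  writeLines(c(header, unlist(sam_lines)), sam_path)
  bam_path <- file.path(dir, paste0(prefix, ".bam"))
  sam_to_bam(sam_path, bam_path)
  unlink(sam_path)

  truth_df <- data.frame(read_name = t_name, haplotype = t_hap,
                         chrom = t_chrom, start = t_start, end = t_end,
                         read_length = t_len, accuracy = t_acc,
                         stringsAsFactors = FALSE)
  truth_tsv <- file.path(dir, paste0(prefix, ".truth.tsv"))
  utils::write.table(truth_df, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- list(bam = bam_path, truth = truth_df, truth_tsv = truth_tsv,
              n_reads = serial, n_sub = tot[["sub"]], n_ins = tot[["ins"]],
              n_del = tot[["del"]])
  if (emit_fastq) {
    fq <- file.path(dir, paste0(prefix, ".fastq"))
    writeLines(unlist(fq_lines), fq)
    out$fastq <- fq
  }
  out
}

#' Parse truth fields back out of simulated read names
#'
#' @param qnames Read names produced by [simulate_reads()].
#' @return Data frame with `read_name`, `chrom`, `haplotype`, `start`, `end`.
#' @export
parse_truth_names <- function(qnames) {
  parts <- strsplit(qnames, "!", fixed = TRUE)
  bad <- lengths(parts) != 6L
  if (any(bad)) stop("not a simulated truth-encoded read name: ", qnames[bad][1])
  data.frame(
    read_name = qnames,
    chrom = vapply(parts, `[`, character(1), 2L),
    haplotype = as.integer(sub("^h", "", vapply(parts, `[`, character(1), 3L))),
    start = as.integer(vapply(parts, `[`, character(1), 4L)),
    end = as.integer(vapply(parts, `[`, character(1), 5L)),
    stringsAsFactors = FALSE)
}

#' Simulate a complete truth-labeled diploid dataset
#'
#' Convenience wrapper: random reference + phased het SNVs, two haplotype
#' consensus sequences, and error-bearing reads from both haplotypes,
#' written as FASTA (+fai), VCF (plain and bgzip+tabix), BAM (+bai) and a
#' truth TSV. Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return List with all output paths, the parsed `variant_store`, the
#'   truth table, and simulation tallies.
#' @export
simulate_diploid_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  config_inner <- config
  config_inner$seed <- NULL  # one RNG stream for the whole pipeline
  genome <- generate_truth_genome(config_inner, dir)
  store <- parse_phased_vcf(genome$vcf_gz, sample = genome$sample)
  cons <- lapply(1:2, function(h) {
    build_haplotype_consensus(genome$fasta, store, h)
  })
  reads <- simulate_reads(cons, config_inner, dir, prefix = "sim")
  c(genome, reads[setdiff(names(reads), "truth")],
    list(truth = reads$truth, store = store, config = config))
}
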