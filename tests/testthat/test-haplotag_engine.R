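# handcrafted alignments over a toy VCF: two phase sets on chr1
engine_fixture <- function(dir) {
  vcf <- file.path(dir, "vars.vcf")
  rec <- function(pos, ref, alt, gt, ps) {
    paste("chr1", pos, ".", ref, alt, ".", "PASS", ".", "GT:PS",
          paste0(gt, ":", ps), sep = "\t")
  }
  writeLines(c(
    "##fileformat=VCFv4.3",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    rec(1010, "A", "G", "0|1", 1),   # h1=A h2=G
    rec(1020, "C", "T", "0|1", 1),   # h1=C h2=T
    rec(1030, "G", "A", "0|1", 1),   # h1=G h2=A
    rec(2010, "T", "C", "0|1", 2),   # h1=T h2=C
    rec(2020, "A", "G", "0|1", 2)),  # h1=A h2=G
    vcf)
  parse_phased_vcf(vcf, "S1")
}

test_that("the engine labels reads by the alleles they carry", {
  dir <- withr::local_tempdir()
  store <- engine_fixture(dir)
  # 30-base reads starting at 1001 covering variants 1010/1020/1030
  h1_seq <- function() {
    s <- strrep("T", 30)
    substr(s, 10, 10) <- "A"; substr(s, 20, 20) <- "C"; substr(s, 30, 30) <- "G"
    s
  }
  h2_seq <- function() {
    s <- strrep("T", 30)
    substr(s, 10, 10) <- "G"; substr(s, 20, 20) <- "T"; substr(s, 30, 30) <- "A"
    s
  }
  neither_seq <- function() {  # single covered variant, base matches no allele
    s <- strrep("G", 10)
    substr(s, 10, 10) <- "C"
    s
  }
  records <- c(
    sam_record("read_h1", 1001, h1_seq(), extra = "de:f:0.02"),
    sam_record("read_h2", 1001, h2_seq(), extra = "de:f:0.02"),
    # deletion spanning the middle variant: only 2 observations remain
    sam_record("read_del", 1001, paste0(substr(h1_seq(), 1, 19), substr(h1_seq(), 21, 30)),
               cigar = "19M1D10M", extra = "de:f:0.02"),
    # no variant overlapped
    sam_record("read_far", 5000, strrep("A", 40), extra = "de:f:0.02"),
    # tie: one observation matching neither haplotype
    sam_record("read_tie", 1001, neither_seq(), extra = "de:f:0.02"))
  bam <- write_test_bam(dir, records)
  res <- haplotag_bam(bam, store)
  d <- res$decisions
  rownames(d) <- d$qname

  expect_equal(d["read_h1", "label"], "tagged")
  expect_equal(d["read_h1", "haplotype"], 1L)
  expect_equal(d["read_h1", "n_variants"], 3L)
  expect_equal(d["read_h1", "n_matches"], 3L)
  expect_equal(d["read_h2", "label"], "tagged")
  expect_equal(d["read_h2", "haplotype"], 2L)
  expect_equal(d["read_del", "label"], "tagged")
  expect_equal(d["read_del", "n_variants"], 2L)  # deleted base: no observation
  expect_equal(d["read_far", "label"], "untaggable")
  expect_equal(d["read_tie", "label"], "untagged")
  expect_equal(d["read_tie", "llr"], 0, tolerance = 1e-9)
})

test_that("reads spanning two phase sets are scored within the larger one", {
  dir <- withr::local_tempdir()
  store <- engine_fixture(dir)
  # spans variants 1010..2020: 3 obs in phase set 1, 2 in phase set 2
  s <- strrep("T", 1100)
  substr(s, 10, 10) <- "A"; substr(s, 20, 20) <- "C"; substr(s, 30, 30) <- "G"
  substr(s, 1010, 1010) <- "T"; substr(s, 1020, 1020) <- "A"
  bam <- write_test_bam(withr::local_tempdir(),
                        sam_record("read_span", 1001, s, extra = "de:f:0.02"))
  res <- haplotag_bam(bam, store)
  d <- res$decisions
  expect_equal(d$label, "tagged")
  expect_equal(d$n_variants, 3L)           # only phase set 1 scored
  expect_equal(d$phase_set, 1L)
  expect_equal(d$reason, "multi_phase_set")
})

test_that("LLR exactly at the threshold is not tagged", {
  dir <- withr::local_tempdir()
  store <- engine_fixture(dir)
  s <- strrep("G", 10); substr(s, 10, 10) <- "A"  # one obs matching h1
  bam <- write_test_bam(dir, sam_record("read_one", 1001, s, extra = "de:f:0.02"))
  sc <- haplotag_bam(bam, store)$decisions
  expect_equal(sc$label, "tagged")
  # with a threshold at its own LLR, strict inequality demotes it
  sc2 <- haplotag_bam(bam, store, llr_threshold = sc$llr)$decisions
  expect_equal(sc2$label, "untagged")
})

test_that("every input record appears exactly once across outputs", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  res <- haplotag_bam(sim$bam, sim$store, out_dir = file.path(dir, "out"),
                      split_output = TRUE)
  expect_equal(sum(res$summary), nrow(res$decisions))
  st <- Sys.which("samtools")
  count <- function(bam) as.integer(system2(st, c("view", "-c", bam), stdout = TRUE))
  n_out <- sum(vapply(unlist(res$paths[c("tagged", "untagged", "untaggable")]),
                      count, integer(1)))
  expect_equal(n_out, count(sim$bam))
  # the split counts agree with the decision summary
  expect_equal(count(res$paths$tagged), unname(res$summary[["tagged"]]))
})

test_that("tagged output carries the decision metadata tags", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  res <- haplotag_bam(sim$bam, sim$store, out_dir = file.path(dir, "out"))
  p <- Rsamtools::ScanBamParam(what = "qname",
                               tag = c("HP", "PS", "LL", "NV", "YT", "EP"))
  b <- Rsamtools::scanBam(res$paths$combined, param = p)[[1]]
  d <- res$decisions
  m <- match(b$qname, d$qname)
  tagged <- which(d$label[m] == "tagged")
  expect_gt(length(tagged), 0)
  expect_equal(b$tag$HP[tagged], d$haplotype[m][tagged])
  expect_equal(b$tag$NV[tagged], d$n_variants[m][tagged])
  expect_equal(b$tag$LL[tagged], d$llr[m][tagged], tolerance = 1e-5)
  expect_true(all(b$tag$YT[tagged] == "tagged"))
  expect_true(all(is.na(b$tag$HP[d$label[m] != "tagged"])))
})

test_that("the same run twice is byte-identical", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  r1 <- haplotag_bam(sim$bam, sim$store, out_dir = file.path(dir, "a"))
  r2 <- haplotag_bam(sim$bam, sim$store, out_dir = file.path(dir, "b"))
  expect_identical(unname(tools::md5sum(r1$paths$combined)),
                   unname(tools::md5sum(r2$paths$combined)))
  expect_identical(r1$decisions, r2$decisions)
})

test_that("the FDR filter can only shrink the tagged set", {
  sim <- small_sim()
  r0 <- haplotag_bam(sim$bam, sim$store, fdr = 0)
  r1 <- haplotag_bam(sim$bam, sim$store, fdr = 0.1)
  expect_lte(r1$summary[["tagged"]], r0$summary[["tagged"]])
  expect_equal(r0$summary[["untaggable"]], r1$summary[["untaggable"]])
  # filtered reads are the lowest-LLR tagged ones from the unfiltered run
  dropped <- setdiff(r0$decisions$qname[r0$decisions$label == "tagged"],
                     r1$decisions$qname[r1$decisions$label == "tagged"])
  if (length(dropped)) {
    kept_llr <- r1$decisions$llr[r1$decisions$label == "tagged"]
    drop_llr <- r0$decisions$llr[r0$decisions$qname %in% dropped]
    expect_lte(max(drop_llr), min(kept_llr) + 1e-9)
  }
})

test_that("error-free reads score at the closed-form LLR", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(genome_length = 2e5, depth = 1,
                    accuracy_mean = 1, accuracy_sd = 1e-9, seed = 12)
  sim <- simulate_diploid_dataset(cfg, dir)
  res <- haplotag_bam(sim$bam, sim$store)
  d <- res$decisions[res$decisions$label == "tagged", ]
  expect_gt(nrow(d), 0)
  # all-match reads at constant base quality 60: e = 1e-6 per base, and the
  # diploid LLR is twice the log-likelihood difference (coefficients cancel
  # only through the explicit per-haplotype count terms, all matches here)
  e <- 1e-6
  expected <- 2 * (d$n_variants * log10(1 - e) - d$n_variants * log10(e / 3))
  expect_equal(d$llr, expected, tolerance = 1e-6)
  expect_true(all(d$n_mismatches == 0))
  # perfect reads tag perfectly
  truth <- parse_truth_names(d$qname)
  expect_equal(d$haplotype, truth$haplotype)
})

test_that("contig mismatches between BAM and VCF warn and pass through", {
  dir <- withr::local_tempdir()
  store <- engine_fixture(dir)
  records <- c(sam_record("r1", 1001, strrep("A", 10), extra = "de:f:0.02",
                          contig = "chr9"))
  sam <- file.path(dir, "off.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr9\tLN:10000", records), sam)
  bam <- file.path(dir, "off.bam")
  st <- Sys.which("samtools")
  system2(st, c("sort", "-O", "bam", "-o", bam, sam), stdout = FALSE, stderr = FALSE)
  system2(st, c("index", bam), stdout = FALSE, stderr = FALSE)
  expect_warning(res <- haplotag_bam(bam, store), "absent from the VCF")
  expect_equal(res$decisions$label, "untaggable")
})

test_that("minimap2 wrapper maps simulated reads end to end", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(genome_length = 1e5, depth = 0.5,
                    length_mean = 3000, length_sd = 1000, seed = 4)
  withr::with_seed(4, {
    g <- generate_truth_genome(cfg, dir)
    store <- parse_phased_vcf(g$vcf_gz, "SIM")
    cons <- lapply(1:2, function(h) build_haplotype_consensus(g$fasta, store, h))
    reads <- simulate_reads(cons, cfg, dir, prefix = "fq", emit_fastq = TRUE)
  })
  bam <- map_fastq(reads$fastq, g$fasta, file.path(dir, "mapped.bam"))
  expect_true(file.exists(bam))
  res <- haplotag_bam(bam, store)
  expect_gt(res$summary[["tagged"]], 0)
  # the external aligner is named when missing
  withr::local_envvar(PATH = dir)
  expect_error(map_fastq(reads$fastq, g$fasta), "minimap2")
})
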