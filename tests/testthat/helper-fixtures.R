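# fixtures are built in code at test time; nothing binary ships with the
# package

# observation sets for the scoring model
make_obs <- function(bases, errors, h1, h2) {
  read_observations(bases, errors, cbind(h1, h2))
}

# a small, clean phased VCF
write_clean_vcf <- function(path, sample = "S1") {
  lines <- c(
    "##fileformat=VCFv4.3",
    "##contig=<ID=chr1,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"),
    paste("chr1", 100, ".", "A", "G", ".", "PASS", ".", "GT:PS", "0|1:77", sep = "\t"),
    paste("chr1", 200, ".", "C", "T", ".", "PASS", ".", "GT:PS", "1|0:77", sep = "\t"),
    paste("chr1", 300, ".", "G", "A", ".", "PASS", ".", "GT:PS", "1/0:77", sep = "\t"),
    paste("chr1", 400, ".", "A", "AT", ".", "PASS", ".", "GT:PS", "0|1:77", sep = "\t"),
    paste("chr1", 500, ".", "T", "C", ".", "PASS", ".", "GT:PS", "1|1:77", sep = "\t"))
  writeLines(lines, path)
  path
}

# a VCF exhibiting all five defect categories handled by rescue_vcf:
# string PS tags, an INTEGRATION sample header, genotype fields not declared
# in FORMAT, an indel record, and a symbolic structural-variant record
write_messy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##contig=<ID=chrX,length=10000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=String,Description=\"Phase set\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "INTEGRATION"), collapse = "\t"),
    paste("chr1", 100, ".", "A", "G", ".", "PASS", ".", "GT:PS", "0|1:PATMAT", sep = "\t"),
    paste("chr1", 200, ".", "C", "T", ".", "PASS", ".", "GT:PS:GQ", "1|0:PATMAT:50:XX", sep = "\t"),
    paste("chr1", 300, ".", "G", "GA", ".", "PASS", ".", "GT:PS", "0|1:PATMAT", sep = "\t"),
    paste("chr1", 400, ".", "T", "<DEL>", ".", "PASS", ".", "GT:PS", "0|1:PATMAT", sep = "\t"),
    paste("chrX", 500, ".", "A", "C", ".", "PASS", ".", "GT:PS", "0|1:PATMAT", sep = "\t"),
    paste("chr1", 600, ".", "G", "A", ".", "PASS", ".", "GT:PS", "0/1:HOMREF", sep = "\t"),
    paste("chr1", 700, ".", "C", "G", ".", "PASS", ".", "GT:PS", "1|1:PATMAT", sep = "\t"),
    paste("chr1", 800, ".", "A", "T", ".", "PASS", ".", "GT", "0|1", sep = "\t"))
  writeLines(lines, path)
  path
}

# build a BAM from hand-written alignment records over a toy contig
write_test_bam <- function(dir, records, contig = "chr1", contig_len = 10000) {
  sam <- file.path(dir, "reads.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len),
               records), sam)
  bam <- file.path(dir, "reads.bam")
  st <- Sys.which("samtools")
  system2(st, c("sort", "-O", "bam", "-o", bam, sam), stdout = FALSE, stderr = FALSE)
  system2(st, c("index", bam), stdout = FALSE, stderr = FALSE)
  bam
}

sam_record <- function(qname, pos, seq, cigar = paste0(nchar(seq), "M"),
                       qual = strrep("5", nchar(seq)), contig = "chr1",
                       flag = 0, extra = character(0)) {
  paste(c(qname, flag, contig, pos, 60, cigar, "*", 0, 0, seq, qual, extra),
        collapse = "\t")
}

# deterministic toy reference whose bases are known at the variant sites
toy_reference <- function(dir, contig = "chr1", len = 10000, seed = 42) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  })
  fa <- file.path(dir, "ref.fa")
  writeLines(c(paste0(">", contig), paste(chars, collapse = "")), fa)
  list(fasta = fa, chars = chars)
}
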