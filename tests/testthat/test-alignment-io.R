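test_that("read filter enforces the low-quality-base and mean rules", {
  reads <- data.frame(
    id = c("a", "b", "c"),
    mate = 0L,
    seq = strrep("A", 20),
    qual = c(qual_str(c(rep(19L, 5), rep(30L, 15))),   # exactly 5 below 20
             qual_str(c(rep(19L, 6), rep(40L, 14))),   # 6 below 20
             qual_str(rep(19L, 20))),                  # mean 19
    stringsAsFactors = FALSE
  )
  kept <- filter_reads(reads)
  expect_equal(kept$id, "a")
  # idempotent
  expect_identical(filter_reads(kept), kept)
  # empty input passes through
  expect_equal(nrow(filter_reads(reads[0, ])), 0L)
})

test_that("a failing mate drops the whole pair", {
  reads <- data.frame(
    id = c("p1", "p1", "p2", "p2"),
    mate = c(1L, 2L, 1L, 2L),
    seq = strrep("A", 10),
    qual = c(qual_str(rep(35L, 10)), qual_str(rep(10L, 10)),
             qual_str(rep(35L, 10)), qual_str(rep(35L, 10))),
    stringsAsFactors = FALSE
  )
  kept <- filter_reads(reads)
  expect_equal(unique(kept$id), "p2")
  expect_equal(nrow(kept), 2L)
})

ref20 <- "ACGTACGTACGTACGTACGT"

write_sam <- function(lines, ref_len = 20L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:ref\tLN:", ref_len), lines), path)
  path
}

test_that("SAM without indels stacks reads with zero gap columns", {
  sam <- write_sam(c(
    "r1\t0\tref\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r2\t0\tref\t6\t60\t10M\t*\t0\t0\tCGTACGTACG\tIIIIIIIIII"
  ))
  aln <- load_sam(sam, ref20)
  expect_equal(aln$ncol, 20L)
  expect_equal(aln$ref_row, ref20)
  # depth 2 exactly on the 5-column overlap
  expect_equal(sum(aln$depth == 2L), 5L)
  expect_equal(sum(aln$depth == 1L), 10L)
})

test_that("an insertion in one read opens shared gap columns", {
  # r1 inserts TT after reference position 10; r2 has no insertion
  sam <- write_sam(c(
    "r1\t0\tref\t6\t60\t5M2I5M\t*\t0\t0\tCGTACTTGTACG\tIIIIIIIIIIII",
    "r2\t0\tref\t6\t60\t10M\t*\t0\t0\tCGTACGTACG\tIIIIIIIIII"
  ))
  aln <- load_sam(sam, ref20)
  expect_equal(aln$ncol, 22L)  # ref_len + 2
  # non-inserting rows show "--" at the insertion block
  expect_equal(substr(aln$reads$row[2], 6, 7), "--")
  expect_equal(substr(aln$reads$row[1], 6, 7), "TT")
  # the reference row has gaps there and is recovered by stripping them
  expect_equal(substr(aln$ref_row, 11, 12), "--")
  expect_equal(gsub("-", "", aln$ref_row, fixed = TRUE), ref20)
})

test_that("a deletion shows as gaps against ungapped reference columns", {
  sam <- write_sam(
    "r1\t0\tref\t1\t60\t5M3D5M\t*\t0\t0\tACGTAGTACG\tIIIIIIIIII")
  aln <- load_sam(sam, ref20)
  expect_equal(aln$ncol, 20L)
  expect_equal(substr(aln$reads$row[1], 6, 8), "---")
})

test_that("header/reference mismatch and malformed SAM raise errors", {
  sam <- write_sam("r1\t0\tref\t1\t60\t4M\t*\t0\t0\tACGT\tIIII",
                   ref_len = 99L)
  expect_error(load_sam(sam, ref20), "reference length")
  bad <- tempfile(fileext = ".sam")
  writeLines("not a sam file at all", bad)
  expect_error(load_sam(bad, ref20), "malformed")
})

test_that("gap propagation keeps all rows consistent on simulated data", {
  cfg <- sim_config(ref_length = 400L, divergence = 0.02,
                    indel_prob = 0.01, depth_lowest = 10, seed = 7L)
  sim <- simulate_pool(make_haplotypes(cfg), cfg)
  aln <- pool_alignment(sim)
  with(aln$reads, {
    expect_true(all(nchar(row) == end_col - start_col + 1L))
    expect_true(all(end_col < aln$ncol))
  })
  # non-gap characters per row equal the read's aligned query length
  ops <- GenomicAlignments::explodeCigarOps(sim$sam$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(sim$sam$cigar)
  aligned_len <- mapply(function(o, l) sum(l[o %in% c("M", "I")]), ops,
                        lens)
  row_bases <- nchar(gsub("-", "", aln$reads$row, fixed = TRUE))
  expect_equal(row_bases, unname(aligned_len))
  # stripping gap columns restores the reference
  expect_equal(gsub("-", "", aln$ref_row, fixed = TRUE), sim$reference)
  # per-column depth equals the number of covering reads
  col <- sample.int(aln$ncol, 1L) - 1L
  expect_equal(aln$depth[col + 1L],
               sum(aln$reads$start_col <= col & aln$reads$end_col >= col))
})

test_that("FASTA writing round-trips and rejects unnamed sequences", {
  path <- tempfile(fileext = ".fasta")
  seqs <- c(H1 = strrep("ACGT", 40), H2 = "ACGTACGTA")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
  lines <- readLines(path)
  expect_equal(lines[1], ">H1")
  expect_true(all(nchar(lines[lines != ">H1" & lines != ">H2"]) <= 60))
  expect_error(write_fasta(unname(seqs), path), "named")
})

test_that("FASTQ round-trips through the read data frame", {
  reads <- data.frame(id = c("a", "b"), mate = 1L,
                      seq = c("ACGT", "GGGG"),
                      qual = c("IIII", "!!!!"), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path, mate = 1L)
  expect_equal(back$seq, reads$seq)
  expect_equal(back$qual, reads$qual)
  expect_equal(back$id, reads$id)
})
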