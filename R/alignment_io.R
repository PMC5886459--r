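#' Quality-filter short reads
#'
#' Mixed-sample read QC: a read is kept when it has at most `max_low` bases
#' below the Phred threshold `q_threshold` and a mean quality of at least
#' `min_mean`. When either mate of a pair fails, both mates are dropped so
#' downstream files stay pair-coherent.
#'
#' @param reads data frame with columns `id`, `mate` (1, 2 or 0 for unpaired),
#'   `seq` and `qual` (Phred+33 encoded string, same length as `seq`).
#' @param q_threshold Phred score below which a base counts as low quality
#'   (default 20).
#' @param max_low maximum number of low-quality bases tolerated per read
#'   (default 5).
#' @param min_mean minimum mean Phred score per read (default 20).
#' @return The retained rows of `reads`, in the original order.
#' @export
filter_reads <- function(reads, q_threshold = 20, max_low = 5,
                         min_mean = 20) {
  stopifnot(is.data.frame(reads),
            all(c("id", "mate", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0L) return(reads)
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence and quality strings differ in length")
  }
  ok <- vapply(reads$qual, function(q) {
    ph <- utf8ToInt(q) - 33L
    sum(ph < q_threshold) <= max_low && mean(ph) >= min_mean
  }, logical(1), USE.NAMES = FALSE)
  paired <- reads$mate %in% c(1L, 2L)
  bad_ids <- unique(reads$id[paired & !ok])
  keep <- ok & !(paired & reads$id %in% bad_ids)
  reads[keep, , drop = FALSE]
}

#' Read a SAM file of pooled reads into a gap-consistent alignment
#'
#' Mapped records are stacked against the reference and every insertion found
#' in any read opens a shared gap column, present in the reference row and in
#' all reads lacking that insertion, so that alignment columns are consistent
#' across the whole pileup. Soft-clipped bases are excluded; unmapped records
#' are skipped.
#'
#' @param path SAM file path.
#' @param reference reference nucleotide string the reads were mapped against.
#' @return A `gapped_alignment` object; see [gapped_alignment()].
#' @export
load_sam <- function(path, reference) {
  stopifnot(file.exists(path), is.character(reference),
            length(reference) == 1L)
  hdr <- tryCatch(
    Rsamtools::scanBamHeader(Rsamtools::asBam(
      path, tempfile(), overwrite = TRUE, indexDestination = FALSE)),
    error = function(e) stop("malformed SAM file '", path, "': ",
                             conditionMessage(e))
  )
  bam <- names(hdr)[1]
  ln <- hdr[[1]]$targets
  if (length(ln) != 1L || ln[1] != nchar(reference)) {
    stop("SAM header reference length (", paste(ln, collapse = ","),
         ") does not match the supplied reference (", nchar(reference), ")")
  }
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("seq", "qname", "flag")))
  mc <- S4Vectors::mcols(ga)
  gapped_alignment(
    pos = GenomicAlignments::start(ga),
    cigar = GenomicAlignments::cigar(ga),
    seq = as.character(mc$seq),
    id = mc$qname,
    reference = reference
  )
}

#' Build a gap-consistent multiple alignment from mapped-read fields
#'
#' The workhorse behind [load_sam()], usable directly on in-memory records
#' (e.g. the simulator's). Coordinates follow SAM convention on input
#' (1-based `pos`); alignment columns are 0-based internally.
#'
#' @param pos 1-based leftmost reference position per read.
#' @param cigar CIGAR string per read (`M`, `=`, `X`, `I`, `D`, `S`, `H`
#'   supported).
#' @param seq read sequence per read (as stored in the SAM record).
#' @param id read identifier per read.
#' @param reference reference nucleotide string.
#' @return An object of class `gapped_alignment`: a list with the gapped
#'   `ref_row`, `reference`, `ncol`, `col_of_ref` (0-based column of each
#'   reference base), a `reads` data frame (`id`, `start_col`, `end_col`,
#'   `row`), and the per-column `depth`.
#' @export
gapped_alignment <- function(pos, cigar, seq, id, reference) {
  n <- length(pos)
  stopifnot(length(cigar) == n, length(seq) == n, length(id) == n)
  L <- nchar(reference)
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)

  # pass 1: maximal insertion length at each inter-base anchor
  # anchor a = between reference positions a and a+1 (1-based), a in 0..L
  ins_len <- integer(L + 1L)
  for (r in seq_len(n)) {
    rp <- pos[r] - 1L  # reference bases consumed
    for (k in seq_along(ops[[r]])) {
      op <- ops[[r]][k]; w <- lens[[r]][k]
      if (op %in% c("M", "=", "X", "D")) {
        rp <- rp + w
      } else if (op == "I") {
        a <- rp + 1L
        if (w > ins_len[a]) ins_len[a] <- w
      } else if (!op %in% c("S", "H")) {
        stop("unsupported CIGAR op '", op, "' in read '", id[r], "'")
      }
      if (rp > L) stop("read '", id[r], "' extends past the reference")
    }
  }

  # column layout (0-based): insertion block at anchor a precedes ref base a+1
  shift <- cumsum(ins_len)                      # shift[a + 1]
  col_of_ref <- seq_len(L) - 1L + shift[seq_len(L)]
  ncol_aln <- L + shift[L + 1L]
  ref_chars <- rep("-", ncol_aln)
  ref_chars[col_of_ref + 1L] <- strsplit(reference, "", fixed = TRUE)[[1]]
  ref_row <- paste(ref_chars, collapse = "")

  rows <- character(n)
  start_col <- integer(n)
  end_col <- integer(n)
  for (r in seq_len(n)) {
    rp <- pos[r] - 1L
    q <- 0L
    bases <- strsplit(seq[r], "", fixed = TRUE)[[1]]
    first <- NA_integer_
    last <- NA_integer_
    buf <- NULL  # filled lazily once span known; collect (col, char) pairs
    cols_out <- integer(0)
    chars_out <- character(0)
    for (k in seq_along(ops[[r]])) {
      op <- ops[[r]][k]; w <- lens[[r]][k]
      if (op %in% c("M", "=", "X")) {
        cc <- col_of_ref[(rp + 1L):(rp + w)]
        cols_out <- c(cols_out, cc)
        chars_out <- c(chars_out, bases[(q + 1L):(q + w)])
        rp <- rp + w; q <- q + w
      } else if (op == "I") {
        a <- rp  # anchor index rp, block columns follow col of ref base rp
        base_col <- if (a == 0L) shift[1L] - ins_len[1L] else col_of_ref[a] + 1L
        cc <- base_col + seq_len(w) - 1L
        cols_out <- c(cols_out, cc)
        chars_out <- c(chars_out, bases[(q + 1L):(q + w)])
        q <- q + w
      } else if (op == "D") {
        rp <- rp + w
      } else if (op == "S") {
        q <- q + w
      }
    }
    if (length(cols_out) == 0L) stop("read '", id[r], "' aligns no bases")
    first <- min(cols_out)
    last <- max(cols_out)
    rowc <- rep("-", last - first + 1L)
    rowc[cols_out - first + 1L] <- chars_out
    rows[r] <- paste(rowc, collapse = "")
    start_col[r] <- first
    end_col[r] <- last
  }

  depth <- integer(ncol_aln)
  dd <- integer(ncol_aln + 1L)
  for (r in seq_len(n)) {
    dd[start_col[r] + 1L] <- dd[start_col[r] + 1L] + 1L
    dd[end_col[r] + 2L] <- dd[end_col[r] + 2L] - 1L
  }
  depth <- cumsum(dd[seq_len(ncol_aln)])

  structure(list(
    reference = reference,
    ref_row = ref_row,
    ncol = ncol_aln,
    col_of_ref = col_of_ref,
    reads = data.frame(id = id, start_col = start_col, end_col = end_col,
                       row = rows, stringsAsFactors = FALSE),
    depth = depth
  ), class = "gapped_alignment")
}

#' @export
print.gapped_alignment <- function(x, ...) {
  cat("Gapped alignment:", nrow(x$reads), "reads over", x$ncol, "columns (",
      nchar(x$reference), "reference bases,", x$ncol - nchar(x$reference),
      "insertion columns )\n")
  cat("Mean depth:", round(mean(x$depth), 1), " max:", max(x$depth), "\n")
  invisible(x)
}

#' Write named sequences as FASTA
#'
#' @param sequences named character vector of nucleotide strings.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a FASTQ file into the read data frame used by [filter_reads()]
#'
#' @param path FASTQ file path.
#' @param mate mate number to record (1, 2, or 0 for unpaired).
#' @return Data frame with columns `id`, `mate`, `seq`, `qual`.
#' @export
read_fastq <- function(path, mate = 0L) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", sub("/[12]$", "", names(x))),
    mate = as.integer(mate),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write a read data frame as FASTQ
#'
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
               con)
  }
  invisible(path)
}
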