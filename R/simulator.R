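#' Pool simulation settings
#'
#' Defines a synthetic pooled-amplicon experiment: a reference amplicon,
#' `n_hap` haplotypes diverged from it, and paired short reads drawn from the
#' haplotypes at the design proportions with uniform per-base sequencing
#' error. Defaults mirror a three-haplotype 1:2:5 pool of a ~5 kb amplicon
#' sequenced 2 x 151 bp.
#'
#' @param ref_length amplicon length in bp (default 5000).
#' @param n_hap number of haplotypes (default 3).
#' @param divergence per-site substitution probability of each haplotype
#'   against the base reference (default 0.01).
#' @param indel_prob per-site probability of a 1 bp indel (default 0;
#'   split evenly between insertion and deletion).
#' @param ratios mixing ratios (default `c(1, 2, 5)`).
#' @param depth_lowest target mean depth of the lowest-ratio haplotype
#'   (default 50).
#' @param read_length read length in bp (default 151).
#' @param fragment_mean,fragment_sd fragment length distribution in bp
#'   (defaults 400 and 50).
#' @param per_base_error uniform substitution error probability per
#'   sequenced base (default 0).
#' @param seed integer seed; all outputs are reproducible given the seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(ref_length = 5000L, n_hap = 3L, divergence = 0.01,
                       indel_prob = 0, ratios = c(1, 2, 5),
                       depth_lowest = 50, read_length = 151L,
                       fragment_mean = 400, fragment_sd = 50,
                       per_base_error = 0, seed = 1L) {
  stopifnot(ref_length >= read_length, n_hap >= 1L,
            divergence >= 0, divergence < 1,
            indel_prob >= 0, indel_prob < 1,
            length(ratios) == n_hap, all(ratios >= 0), any(ratios > 0),
            depth_lowest >= 1, read_length >= 1L,
            fragment_mean >= read_length, fragment_sd >= 0,
            per_base_error >= 0, per_base_error < 1)
  structure(list(ref_length = as.integer(ref_length),
                 n_hap = as.integer(n_hap), divergence = divergence,
                 indel_prob = indel_prob, ratios = ratios,
                 depth_lowest = depth_lowest,
                 read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 per_base_error = per_base_error, seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

# for each base, the three possible substitution targets
OTHER_BASES <- matrix(c("C", "G", "T",
                        "A", "G", "T",
                        "A", "C", "T",
                        "A", "C", "G"),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(BASES, NULL))

#' Generate a reference and diverged haplotypes
#'
#' Each haplotype differs from the random base reference by independent
#' per-site substitutions at rate `divergence` (and optional 1 bp indels at
#' rate `indel_prob`). A truth table of all variants is returned alongside a
#' reference-coordinate map per haplotype, from which read CIGAR strings are
#' later derived.
#'
#' @param config a [sim_config()].
#' @return List with `reference`, `haplotypes` (named character vector),
#'   `variants` (data frame: `hap`, `pos` 1-based reference position, `type`,
#'   `ref`, `alt`) and `maps` (per haplotype, the 1-based reference position
#'   of each haplotype base; `NA` for inserted bases).
#' @export
make_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    L <- config$ref_length
    ref <- sample(BASES, L, replace = TRUE)
    haps <- vector("list", config$n_hap)
    maps <- vector("list", config$n_hap)
    vars <- list()
    for (h in seq_len(config$n_hap)) {
      chars <- ref
      sub_at <- which(stats::runif(L) < config$divergence)
      if (length(sub_at)) {
        chars[sub_at] <- OTHER_BASES[cbind(
          match(ref[sub_at], BASES),
          sample.int(3L, length(sub_at), replace = TRUE))]
        vars[[length(vars) + 1L]] <- data.frame(
          hap = h, pos = sub_at, type = "sub", ref = ref[sub_at],
          alt = chars[sub_at], stringsAsFactors = FALSE)
      }
      map <- seq_len(L)
      if (config$indel_prob > 0) {
        u <- stats::runif(L)
        del_at <- which(u < config$indel_prob / 2)
        ins_at <- which(u >= config$indel_prob / 2 &
                          u < config$indel_prob)
        keep <- !(seq_len(L) %in% del_at)
        out_chars <- chars[keep]
        out_map <- map[keep]
        if (length(ins_at)) {
          ins_base <- sample(BASES, length(ins_at), replace = TRUE)
          # insert after each selected reference site
          pieces_c <- list()
          pieces_m <- list()
          prev <- 0L
          kept_pos <- which(keep)
          for (j in seq_along(ins_at)) {
            upto <- sum(kept_pos <= ins_at[j])
            pieces_c[[2L * j - 1L]] <- out_chars[seq_len(upto)][-seq_len(prev)]
            pieces_m[[2L * j - 1L]] <- out_map[seq_len(upto)][-seq_len(prev)]
            pieces_c[[2L * j]] <- ins_base[j]
            pieces_m[[2L * j]] <- NA_integer_
            prev <- upto
          }
          pieces_c[[2L * length(ins_at) + 1L]] <-
            out_chars[-seq_len(prev)]
          pieces_m[[2L * length(ins_at) + 1L]] <- out_map[-seq_len(prev)]
          out_chars <- unlist(pieces_c)
          out_map <- unlist(pieces_m)
          vars[[length(vars) + 1L]] <- data.frame(
            hap = h, pos = ins_at, type = "ins", ref = "-",
            alt = ins_base, stringsAsFactors = FALSE)
        }
        if (length(del_at)) {
          vars[[length(vars) + 1L]] <- data.frame(
            hap = h, pos = del_at, type = "del", ref = ref[del_at],
            alt = "-", stringsAsFactors = FALSE)
        }
        chars <- out_chars
        map <- out_map
      }
      haps[[h]] <- paste(chars, collapse = "")
      maps[[h]] <- map
    }
    variants <- if (length(vars)) do.call(rbind, vars) else
      data.frame(hap = integer(0), pos = integer(0), type = character(0),
                 ref = character(0), alt = character(0))
    variants <- variants[order(variants$hap, variants$pos), , drop = FALSE]
    rownames(variants) <- NULL
    hapv <- unlist(haps)
    names(hapv) <- paste0("H", seq_len(config$n_hap))
    list(reference = paste(ref, collapse = ""), haplotypes = hapv,
         variants = variants, maps = maps)
  })
}

# CIGAR + leftmost reference position for a haplotype interval [s, e]
# (1-based haplotype coordinates) given the haplotype->reference map
cigar_from_map <- function(map, s, e) {
  mm <- map[s:e]
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, w) {
    k <- length(ops)
    if (k > 0L && ops[k] == op) {
      lens[k] <<- lens[k] + w
    } else {
      ops[k + 1L] <<- op
      lens[k + 1L] <<- w
    }
  }
  prev_ref <- NA_integer_
  for (i in seq_along(mm)) {
    if (is.na(mm[i])) {
      push("I", 1L)
    } else {
      if (!is.na(prev_ref) && mm[i] > prev_ref + 1L) {
        push("D", mm[i] - prev_ref - 1L)
      }
      push("M", 1L)
      prev_ref <- mm[i]
    }
  }
  pos <- mm[!is.na(mm)][1]
  if (is.na(pos)) stop("read maps to no reference base")
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""))
}

# paste the columns of a character matrix into strings
col_paste <- function(m) do.call(paste0, split(m, row(m)))

# uniform substitution errors across a vector of equal-length sequences
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  rl <- nchar(seqs[1])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = rl)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit)) {
    m[hit] <- OTHER_BASES[cbind(match(m[hit], BASES),
                                sample.int(3L, length(hit),
                                           replace = TRUE))]
  }
  col_paste(m)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a pooled paired-read sequencing run
#'
#' Fragments are assigned to haplotypes with probability equal to the
#' normalized mixing ratios and placed so that amplicon ends stay covered
#' (fragment starts are drawn uniformly over an extended range and clipped to
#' the amplicon, emulating end-anchored fragments of amplicon tagmentation).
#' Each fragment yields a 2 x `read_length` read pair with uniform per-base
#' substitution error; the accompanying SAM records carry the true sampling
#' coordinates, so the decoder can be exercised without an external mapper.
#'
#' @param haps result of [make_haplotypes()].
#' @param config the same [sim_config()].
#' @return List of class `pool_sim` with elements `config`, `reference`,
#'   `haplotypes`, `reads` (data frame: `id`, `mate`, `seq` as sequenced,
#'   `qual`), `sam` (data frame: `id`, `mate`, `flag`, `pos`, `cigar`, `seq`
#'   on the reference strand, `qual`) and `truth` (data frame: `id`, `hap`,
#'   `hap_start` 0-based).
#' @export
simulate_pool <- function(haps, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    freqs <- config$ratios / sum(config$ratios)
    rl <- config$read_length
    L <- config$ref_length
    pos_freqs <- freqs[freqs > 0]
    n_pairs <- max(1L, round(config$depth_lowest * L /
                               (min(pos_freqs) * 2 * rl)))
    hap_idx <- sample.int(config$n_hap, n_pairs, replace = TRUE,
                          prob = freqs)
    hap_len <- nchar(haps$haplotypes)
    flen <- pmax(rl, round(stats::rnorm(n_pairs, config$fragment_mean,
                                        config$fragment_sd)))
    Lh <- hap_len[hap_idx]
    flen <- pmin(flen, Lh)
    # 0-based start over an extended range, then clipped: keeps ends covered
    lo <- -(flen - rl)
    hi <- Lh - rl
    start0 <- lo + floor(stats::runif(n_pairs) * (hi - lo + 1))
    fs <- pmax(0L, start0)
    fe <- pmin(Lh, start0 + flen)

    hseq <- haps$haplotypes[hap_idx]
    r1 <- substr(hseq, fs + 1L, fs + rl)
    r2f <- substr(hseq, fe - rl + 1L, fe)  # forward-strand representation
    r1 <- mutate_bases(r1, config$per_base_error)
    r2f <- mutate_bases(r2f, config$per_base_error)

    ids <- sprintf("frag%06d", seq_len(n_pairs))
    qual <- strrep(rawToChar(as.raw(33L + 30L)), rl)

    cig1 <- character(n_pairs)
    pos1 <- integer(n_pairs)
    cig2 <- character(n_pairs)
    pos2 <- integer(n_pairs)
    simple <- config$indel_prob == 0
    for (i in seq_len(n_pairs)) {
      if (simple) {
        pos1[i] <- fs[i] + 1L
        pos2[i] <- fe[i] - rl + 1L
        cig1[i] <- cig2[i] <- paste0(rl, "M")
      } else {
        m <- haps$maps[[hap_idx[i]]]
        a <- cigar_from_map(m, fs[i] + 1L, fs[i] + rl)
        b <- cigar_from_map(m, fe[i] - rl + 1L, fe[i])
        pos1[i] <- a$pos; cig1[i] <- a$cigar
        pos2[i] <- b$pos; cig2[i] <- b$cigar
      }
    }

    reads <- data.frame(
      id = rep(ids, 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      seq = c(r1, revcomp(r2f)),
      qual = qual,
      stringsAsFactors = FALSE
    )
    sam <- data.frame(
      id = rep(ids, 2L),
      mate = rep(c(1L, 2L), each = n_pairs),
      flag = rep(c(99L, 147L), each = n_pairs),
      pos = c(pos1, pos2),
      cigar = c(cig1, cig2),
      seq = c(r1, r2f),
      qual = qual,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(id = ids, hap = hap_idx, hap_start = fs,
                        stringsAsFactors = FALSE)
    structure(list(config = config, reference = haps$reference,
                   haplotypes = haps$haplotypes, reads = reads, sam = sam,
                   truth = truth),
              class = "pool_sim")
  })
}

#' Gapped alignment directly from a simulated pool
#'
#' Uses the simulator's ground-truth coordinates instead of an external
#' mapper.
#'
#' @param sim a [simulate_pool()] result.
#' @return A [gapped_alignment()].
#' @export
pool_alignment <- function(sim) {
  stopifnot(inherits(sim, "pool_sim"))
  gapped_alignment(pos = sim$sam$pos, cigar = sim$sam$cigar,
                   seq = sim$sam$seq,
                   id = paste0(sim$sam$id, "/", sim$sam$mate),
                   reference = sim$reference)
}

sam_lines <- function(sim) {
  s <- sim$sam
  mate1 <- s$mate == 1L
  pnext <- integer(nrow(s))
  key <- s$id
  p1 <- s$pos[mate1][match(key, s$id[mate1])]
  p2 <- s$pos[!mate1][match(key, s$id[!mate1])]
  pnext <- ifelse(mate1, p2, p1)
  c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:ref\tLN:", nchar(sim$reference)),
    paste(s$id, s$flag, "ref", s$pos, 60L, s$cigar, "=", pnext, 0L, s$seq,
          s$qual, sep = "\t")
  )
}

#' Write all simulator outputs to a directory
#'
#' Writes `ref.fasta`, `hap<N>.fasta`, `reads_1.fastq`, `reads_2.fastq`,
#' `reads.sam` (truth coordinates) and `truth.tsv`.
#'
#' @param sim a [simulate_pool()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_pool <- function(sim, dir) {
  stopifnot(inherits(sim, "pool_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(ref = sim$reference), file.path(dir, "ref.fasta"))
  for (h in seq_along(sim$haplotypes)) {
    write_fasta(sim$haplotypes[h], file.path(dir, paste0("hap", h,
                                                         ".fasta")))
  }
  for (m in 1:2) {
    rd <- sim$reads[sim$reads$mate == m, , drop = FALSE]
    rd$id <- paste0(rd$id, "/", m)
    write_fastq(rd, file.path(dir, paste0("reads_", m, ".fastq")))
  }
  writeLines(sam_lines(sim), file.path(dir, "reads.sam"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
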