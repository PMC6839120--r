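#' Load aligned reads from BAM or SAM
#'
#' Extracts, for every mapped primary alignment, the strand-aware 3' and
#' 5' end coordinates, the 3' soft-clip sequence and the 3'-terminal
#' mapped sequence, all in read orientation. Secondary (0x100) and
#' supplementary (0x800) alignments are skipped; unmapped reads are
#' skipped and counted. SAM input is converted on the fly with
#' [Rsamtools::asBam()].
#'
#' On the forward strand the 3' end is the rightmost aligned base and the
#' 3' soft clip is the right clip; on the reverse strand the 3' end is
#' the leftmost aligned base and the 3' soft clip is the left clip,
#' reverse-complemented into read orientation. Coordinates are 1-based
#' inclusive.
#'
#' @param path BAM or SAM file.
#' @param genome Optional named character vector from [load_genome()];
#'   when given, alignments must refer to known contigs.
#' @param mapped_tail_len Number of 3'-terminal aligned bases to keep as
#'   `mapped_tail_seq` (shorter when the alignment is shorter).
#' @param polya_min_as,polya_probe_len Poly(A)-evidence rule: a read
#'   carries poly(A) evidence when its 3' soft clip contains at least
#'   `polya_min_as` As within its first `polya_probe_len` bases (by
#'   default a 10-A start allowing one non-A in the first 11
#'   positions).
#' @return A data.frame with one row per alignment: `read_id`, `contig`,
#'   `strand`, `start`, `end`, `end3`, `end5`, `clip3_seq`,
#'   `mapped_tail_seq`, `has_polyA`. Attribute `n_skipped` counts
#'   unmapped/secondary/supplementary records that were dropped.
#' @export
load_reads <- function(path, genome = NULL, mapped_tail_len = 30L,
                       polya_min_as = 10L, polya_probe_len = 11L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  all_flags <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = "flag"))[[1]]$flag
  keep_mask <- bitwAnd(all_flags, 0x4L) == 0L &
    bitwAnd(all_flags, 0x100L) == 0L & bitwAnd(all_flags, 0x800L) == 0L
  n_skipped <- sum(!keep_mask)

  param <- Rsamtools::ScanBamParam(
    what = c("qname", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  md <- S4Vectors::mcols(ga)

  n <- length(ga)
  if (n == 0L) {
    out <- data.frame(read_id = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), end3 = integer(0), end5 = integer(0),
                      clip3_seq = character(0), mapped_tail_seq = character(0),
                      has_polyA = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }

  contig <- as.character(GenomicAlignments::seqnames(ga))
  strand <- as.character(GenomicAlignments::strand(ga))
  if (any(strand == "*")) stop("alignments without strand are not supported")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(contig), names(genome))
    if (length(unknown) > 0L) {
      stop("alignments refer to contig(s) absent from the genome: ",
           paste(unknown, collapse = ", "),
           " (genome has: ", paste(names(genome), collapse = ", "), ")")
    }
  }
  cig <- GenomicAlignments::cigar(ga)
  if (any(!grepl("[M=X]", cig))) {
    stop("CIGAR without alignment-consuming operations")
  }
  start <- GenomicAlignments::start(ga)
  end <- GenomicAlignments::end(ga)
  seq <- as.character(md$seq)
  seq_len <- nchar(seq)

  # soft-clip lengths at either end of the stored (reference-orientation)
  # sequence; hard clips may precede/follow them in the CIGAR string
  ls <- .lead_clip(cig)
  rs <- .trail_clip(cig)

  plus <- strand == "+"
  end3 <- ifelse(plus, end, start)
  end5 <- ifelse(plus, start, end)

  # mapped part of the stored sequence (between the soft clips)
  mapped <- substr(seq, ls + 1L, seq_len - rs)
  mlen <- nchar(mapped)
  tail_ref <- ifelse(plus,
                     substr(mapped, pmax(1L, mlen - mapped_tail_len + 1L), mlen),
                     substr(mapped, 1L, pmin(mlen, mapped_tail_len)))
  clip_ref <- ifelse(plus,
                     substr(seq, seq_len - rs + 1L, seq_len),
                     substr(seq, 1L, ls))
  mapped_tail_seq <- tail_ref
  clip3_seq <- clip_ref
  if (any(!plus)) {
    mapped_tail_seq[!plus] <- revcomp(tail_ref[!plus])
    clip3_seq[!plus] <- revcomp(clip_ref[!plus])
  }

  out <- data.frame(
    read_id = as.character(md$qname), contig = contig, strand = strand,
    start = start, end = end, end3 = end3, end5 = end5,
    clip3_seq = clip3_seq, mapped_tail_seq = mapped_tail_seq,
    stringsAsFactors = FALSE)
  out$has_polyA <- has_polya_evidence(out$clip3_seq, polya_min_as,
                                      polya_probe_len)
  attr(out, "n_skipped") <- n_skipped
  out
}

.lead_clip <- function(cig) {
  m <- regmatches(cig, regexpr("^(?:[0-9]+H)?([0-9]+)S", cig))
  out <- integer(length(cig))
  hit <- lengths(regmatches(cig, gregexpr("^(?:[0-9]+H)?[0-9]+S", cig))) > 0
  out[hit] <- as.integer(sub("S$", "", sub("^[0-9]+H", "", m)))
  out
}

.trail_clip <- function(cig) {
  m <- regmatches(cig, regexpr("([0-9]+)S(?:[0-9]+H)?$", cig))
  out <- integer(length(cig))
  hit <- grepl("[0-9]+S(?:[0-9]+H)?$", cig)
  out[hit] <- as.integer(sub("S.*$", "", m))
  out
}

#' Poly(A) evidence rule for 3' soft clips
#'
#' A cDNA read is taken to carry a sequenced poly(A) tail when its 3'
#' soft clip starts with a dense A run: at least `min_as` As within the
#' first `probe_len` clip bases.
#'
#' @param clip3 Character vector of 3' soft-clip sequences (read
#'   orientation).
#' @param min_as Minimum number of As.
#' @param probe_len Length of the probed clip prefix.
#' @return Logical vector.
#' @export
has_polya_evidence <- function(clip3, min_as = 10L, probe_len = 11L) {
  probe <- substr(clip3, 1L, probe_len)
  n_a <- nchar(probe) - nchar(gsub("A", "", probe, fixed = TRUE))
  n_a >= min_as
}

#' Per-strand read-end and coverage profile of a contig
#'
#' Builds integer arrays over all positions of `contig`: counts of read
#' 3' ends (`ends3`, all reads, and `ends3_polyA` restricted to reads
#' with poly(A) evidence), 5' ends (`ends5`), and `cov`, the number of
#' same-strand reads whose aligned interval contains each position.
#'
#' @param reads data.frame from [load_reads()] (or the simulator).
#' @param contig Contig name.
#' @param contig_length Length of the contig in bases.
#' @return An object of class `end_profile`: a list with `contig`, `len`
#'   and per-strand arrays under `$profile[["+"]]` / `[["-"]]`.
#' @export
build_end_profile <- function(reads, contig, contig_length) {
  L <- as.integer(contig_length)
  r <- reads[reads$contig == contig, , drop = FALSE]
  pa <- if ("has_polyA" %in% names(r)) r$has_polyA else
    rep(FALSE, nrow(r))
  one <- function(sub, sub_pa) {
    cov <- integer(L)
    if (nrow(sub) > 0L) {
      d <- integer(L + 1L)
      t1 <- tabulate(sub$start, nbins = L)
      t2 <- tabulate(pmin(sub$end + 1L, L + 1L), nbins = L + 1L)
      d[seq_len(L)] <- t1
      d <- d - t2
      cov <- cumsum(d[seq_len(L)])
    }
    list(
      ends3 = tabulate(sub$end3, nbins = L),
      ends3_polyA = tabulate(sub$end3[sub_pa], nbins = L),
      ends5 = tabulate(sub$end5, nbins = L),
      cov = cov
    )
  }
  structure(list(
    contig = contig, len = L,
    profile = list(
      `+` = one(r[r$strand == "+", , drop = FALSE], pa[r$strand == "+"]),
      `-` = one(r[r$strand == "-", , drop = FALSE], pa[r$strand == "-"]))
  ), class = "end_profile")
}

#' @export
print.end_profile <- function(x, ...) {
  cat("end_profile for contig", x$contig, "(", x$len, "bp )\n")
  for (s in c("+", "-")) {
    p <- x$profile[[s]]
    cat(sprintf("  %s strand: %d 3'-ends (%d poly(A)+), max coverage %d\n",
                s, sum(p$ends3), sum(p$ends3_polyA), max(p$cov, 0L)))
  }
  invisible(x)
}

# Windowed sums over a profile array: sum of v in [pos-half, pos+half],
# truncated at contig boundaries. Vectorized over pos.
.window_sum <- function(v, pos, half = 10L) {
  cs <- c(0L, cumsum(v))
  lo <- pmax(1L, pos - half)
  hi <- pmin(length(v), pos + half)
  cs[hi + 1L] - cs[lo]
}

#' Mirror reads onto the reverse-complemented genome
#'
#' Maps every alignment of a fixture onto the reverse complement of its
#' contig: coordinates are reflected, strands flipped; read-orientation
#' sequences (clips, mapped tails) are unchanged. Used for
#' strand-symmetry checks.
#'
#' @param reads data.frame of reads.
#' @param contig_length Contig length.
#' @return Mirrored reads data.frame.
#' @export
mirror_reads <- function(reads, contig_length) {
  L <- as.integer(contig_length)
  out <- reads
  out$start <- L + 1L - reads$end
  out$end <- L + 1L - reads$start
  out$strand <- ifelse(reads$strand == "+", "-", "+")
  out$end3 <- L + 1L - reads$end3
  out$end5 <- L + 1L - reads$end5
  out
}
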