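#' Load a reference genome from FASTA
#'
#' Reads one or more contigs, uppercases the sequence and converts U to T.
#' Only the characters A, C, G, T, N are accepted after normalization.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase sequence per contig,
#'   in file order.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record in ", path)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters (beyond N) in contig(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Reverse-complement plain character sequences
#'
#' @param x Character vector of DNA sequences over A,C,G,T,N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(out, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.get_contig <- function(genome, contig) {
  s <- genome[[contig]]
  if (is.null(s) || is.na(s)) stop("unknown contig: ", contig)
  s
}

#' Strand-aware upstream sequence of a genomic position
#'
#' Returns the `window` bases immediately upstream (transcript 5'
#' direction) of `pos`, excluding `pos` itself, in sense orientation
#' (5' to 3', so the last character is adjacent to `pos`). The window is
#' truncated at contig boundaries. Coordinates are 1-based.
#'
#' @param genome Named character vector from [load_genome()].
#' @param contig Contig name.
#' @param pos 1-based position.
#' @param strand `"+"` or `"-"`.
#' @param window Window size in nt.
#' @return A single character string (possibly shorter than `window`).
#' @export
upstream_seq <- function(genome, contig, pos, strand, window = 20L) {
  s <- .get_contig(genome, contig)
  L <- nchar(s)
  if (pos < 1L || pos > L) stop("position ", pos, " outside contig ", contig)
  if (strand == "+") {
    from <- max(1L, pos - window)
    if (from > pos - 1L) return("")
    substr(s, from, pos - 1L)
  } else if (strand == "-") {
    to <- min(L, pos + window)
    if (pos + 1L > to) return("")
    revcomp(substr(s, pos + 1L, to))
  } else {
    stop("invalid strand: ", strand)
  }
}

# Proximal-first character vector of the upstream window (first element is
# the base adjacent to pos, moving away 5'). Used by the A-count iteration.
.upstream_chars <- function(genome, contig, pos, strand, window = 20L) {
  s <- upstream_seq(genome, contig, pos, strand, window)
  if (nchar(s) == 0L) return(character(0))
  rev(strsplit(s, "", fixed = TRUE)[[1]])
}

#' Strand-aware sequence window centered on a position
#'
#' Sense-orientation sequence of `pos` with `flank` bases on each side.
#' Positions outside the contig are returned as `N`.
#'
#' @inheritParams upstream_seq
#' @param flank Flank size in nt.
#' @return Character string of length `2 * flank + 1`.
#' @export
centered_seq <- function(genome, contig, pos, strand, flank = 50L) {
  s <- .get_contig(genome, contig)
  L <- nchar(s)
  from <- pos - flank
  to <- pos + flank
  cf <- max(1L, from)
  ct <- min(L, to)
  core <- if (cf <= ct) substr(s, cf, ct) else ""
  pad_l <- strrep("N", cf - from)
  pad_r <- strrep("N", to - ct)
  out <- paste0(pad_l, core, pad_r)
  if (strand == "-") out <- revcomp(out)
  out
}
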