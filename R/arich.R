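#' Counter-based A-count of the upstream window
#'
#' Iterates the strand-aware upstream sequence starting at the base
#' adjacent to `pos` and moving away 5'. The counter starts at 0; each A
#' adds 1, every other base (including N) subtracts 1. Iteration halts
#' when the counter reaches -1 or after `window` bases. The A-count is
#' the maximum counter value observed (never negative). This scoring
#' weights adenines close to the site more heavily than a plain window
#' count while still seeing the broader neighborhood.
#'
#' @inheritParams upstream_seq
#' @return Integer in `[0, window]`.
#' @export
a_count_upstream <- function(genome, contig, pos, strand, window = 20L) {
  a_count_run(.upstream_chars(genome, contig, pos, strand, window))
}

#' A-count of a proximal-first base vector
#'
#' Low-level kernel of [a_count_upstream()]: `chars` is the upstream
#' window as single characters, proximal base first.
#'
#' @param chars Character vector of single bases.
#' @return Integer A-count.
#' @export
a_count_run <- function(chars) {
  if (length(chars) == 0L) return(0L)
  score <- cumsum(ifelse(chars == "A", 1L, -1L))
  halt <- match(-1L, score)
  if (!is.na(halt)) score <- score[seq_len(halt)]
  max(0L, score)
}

#' Longest run of As in the upstream window
#'
#' @inheritParams upstream_seq
#' @return Integer length of the longest consecutive-A run in the
#'   strand-aware `window` nt upstream of `pos`.
#' @export
max_consecutive_a <- function(genome, contig, pos, strand, window = 20L) {
  ch <- .upstream_chars(genome, contig, pos, strand, window)
  if (length(ch) == 0L) return(0L)
  r <- rle(ch == "A")
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Number of As in the 20-nt upstream window
#'
#' @inheritParams upstream_seq
#' @return Integer count of As in the strand-aware `window` nt upstream
#'   of `pos` (the classical primer-length window measure).
#' @export
a_in_20 <- function(genome, contig, pos, strand, window = 20L) {
  ch <- .upstream_chars(genome, contig, pos, strand, window)
  sum(ch == "A")
}

#' All three A-richness measures of a site's upstream window
#'
#' @inheritParams upstream_seq
#' @return A list with `a_count`, `max_consecutive_a` and `a_in_20`.
#' @export
arich_assessment <- function(genome, contig, pos, strand, window = 20L) {
  ch <- .upstream_chars(genome, contig, pos, strand, window)
  runs <- rle(ch == "A")
  list(
    a_count = a_count_run(ch),
    max_consecutive_a =
      if (any(runs$values)) max(runs$lengths[runs$values]) else 0L,
    a_in_20 = sum(ch == "A")
  )
}
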