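#' Detect raw poly(A)-site candidates from a cDNA end profile
#'
#' A genomic position becomes a raw candidate when at least `min_reads`
#' poly(A)+ reads end exactly there and those ends are at least
#' `min_frac` of the same-strand reads overlapping the position.
#' Positions with zero overlap never qualify.
#'
#' @param profile An `end_profile` built from cDNA reads (the poly(A)
#'   view, `ends3_polyA`, is used).
#' @param min_reads Minimum exact-position poly(A)+ end count.
#' @param min_frac Minimum ends/overlap fraction (0.001 = 0.1%).
#' @return data.frame of candidates: `contig`, `pos`, `strand`,
#'   `support`, `overlap`.
#' @export
detect_candidates <- function(profile, min_reads = 2L, min_frac = 0.001) {
  out <- lapply(c("+", "-"), function(s) {
    p <- profile$profile[[s]]
    e <- p$ends3_polyA
    cov <- p$cov
    idx <- which(e >= min_reads & cov > 0L & e >= min_frac * cov)
    if (length(idx) == 0L) return(NULL)
    data.frame(contig = profile$contig, pos = idx, strand = s,
               support = e[idx], overlap = cov[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), support = integer(0),
                      overlap = integer(0), stringsAsFactors = FALSE)
  }
  out[order(out$strand, out$pos), , drop = FALSE]
}

#' Keep only the window-maximal candidate per 21-nt window
#'
#' Among raw candidates within any `window`-nt stretch of one strand,
#' only the one with the highest poly(A)+ end count survives. Greedy
#' suppression: candidates are visited by decreasing support, ties
#' broken toward the transcript-3'-most position (larger coordinate on
#' `+`, smaller on `-`); each selected site suppresses others within
#' `(window - 1) / 2` nt. No two surviving same-strand sites are within
#' that distance of each other.
#'
#' @param cands data.frame from [detect_candidates()].
#' @param window Window size (odd; default 21).
#' @return Filtered candidates data.frame.
#' @export
select_window_maximum <- function(cands, window = 21L) {
  half <- (window - 1L) %/% 2L
  keep_rows <- integer(0)
  for (key in unique(paste(cands$contig, cands$strand))) {
    sub_idx <- which(paste(cands$contig, cands$strand) == key)
    sub <- cands[sub_idx, , drop = FALSE]
    s <- sub$strand[1]
    tie <- if (s == "+") -sub$pos else sub$pos
    ord <- order(-sub$support, tie)
    kept_pos <- integer(0)
    kept <- integer(0)
    for (i in ord) {
      if (length(kept_pos) == 0L || all(abs(kept_pos - sub$pos[i]) > half)) {
        kept <- c(kept, i)
        kept_pos <- c(kept_pos, sub$pos[i])
      }
    }
    keep_rows <- c(keep_rows, sub_idx[kept])
  }
  out <- cands[sort(keep_rows), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate candidate sites with window support, A-richness and
#' confidence
#'
#' Fills `window_support` (poly(A)+ ends within `pos +/- 10`), `overlap`
#' (same-strand covering reads at `pos`), the three A-richness measures
#' of the 20-nt upstream window, and `high_confidence`
#' (`window_support > 10`).
#'
#' @param sites Candidates data.frame.
#' @param genome Named character vector from [load_genome()].
#' @param profile cDNA `end_profile` of the sites' contig.
#' @param window Window size (default 21).
#' @param high_conf_min Strict lower bound for high confidence.
#' @return Annotated sites data.frame with classification initialized to
#'   `"UNCLASSIFIED"`.
#' @export
annotate_candidates <- function(sites, genome, profile, window = 21L,
                                high_conf_min = 10L) {
  half <- (window - 1L) %/% 2L
  n <- nrow(sites)
  ws <- integer(n); ov <- integer(n)
  ac <- integer(n); mca <- integer(n); a20 <- integer(n)
  for (s in c("+", "-")) {
    idx <- which(sites$strand == s & sites$contig == profile$contig)
    if (length(idx) == 0L) next
    p <- profile$profile[[s]]
    ws[idx] <- .window_sum(p$ends3_polyA, sites$pos[idx], half)
    ov[idx] <- p$cov[sites$pos[idx]]
  }
  for (i in seq_len(n)) {
    a <- arich_assessment(genome, sites$contig[i], sites$pos[i],
                          sites$strand[i])
    ac[i] <- a$a_count; mca[i] <- a$max_consecutive_a; a20[i] <- a$a_in_20
  }
  sites$window_support <- ws
  sites$overlap <- ov
  sites$a_count <- ac
  sites$max_consecutive_a <- mca
  sites$a_in_20 <- a20
  sites$high_confidence <- ws > high_conf_min
  sites$classification <- rep("UNCLASSIFIED", n)
  sites
}
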