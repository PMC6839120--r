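#' The twelve most commonly used human polyadenylation signals
#'
#' Canonical hexamers ordered most-common-first; the order defines the
#' rank used to resolve multi-motif windows in [find_pas()]. Editable:
#' pass any ordered character vector.
#'
#' @return Character vector of 12 hexamers.
#' @export
default_pas_motifs <- function() {
  c("AATAAA", "ATTAAA", "TATAAA", "AGTAAA", "AAGAAA", "AATATA",
    "AATACA", "CATAAA", "GATAAA", "AATGAA", "TTTAAA", "ACTAAA")
}

#' Detect the polyadenylation signal upstream of each site
#'
#' Scans the strand-aware `upstream` nt (default 40) before each site
#' for exact matches to the configured hexamers. When several motifs
#' match, the most common one (lowest rank) is assigned; among hits of
#' the same motif, the one whose distance is closest to
#' `expected_distance` wins. Distance is measured from the motif's 3'
#' end to the site position (a motif abutting the site has distance 1).
#'
#' @param sites Sites data.frame.
#' @param genome Named character vector.
#' @param upstream Scan window in nt (default 40).
#' @param motifs Ordered hexamer list (default [default_pas_motifs()]).
#' @param expected_distance Canonical signal-to-cleavage distance
#'   (default 25 nt).
#' @return `sites` with columns `pas_motif` (NA when absent),
#'   `pas_distance`, `pas_rank`.
#' @export
find_pas <- function(sites, genome, upstream = 40L,
                     motifs = default_pas_motifs(),
                     expected_distance = 25L) {
  n <- nrow(sites)
  motif <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  rank <- rep(NA_integer_, n)
  k <- nchar(motifs[1])
  for (i in seq_len(n)) {
    s <- upstream_seq(genome, sites$contig[i], sites$pos[i],
                      sites$strand[i], upstream)
    W <- nchar(s)
    if (W < k) next
    starts <- seq_len(W - k + 1L)
    subs <- substring(s, starts, starts + k - 1L)
    rk <- match(subs, motifs)
    hit <- which(!is.na(rk))
    if (length(hit) == 0L) next
    d <- W - (hit + k - 1L) + 1L  # motif 3' end to site
    ord <- order(rk[hit], abs(d - expected_distance), d)
    best <- hit[ord[1]]
    motif[i] <- subs[best]
    rank[i] <- rk[best]
    dist[i] <- W - (best + k - 1L) + 1L
  }
  sites$pas_motif <- motif
  sites$pas_distance <- dist
  sites$pas_rank <- rank
  sites
}

#' Histogram of PAS-to-site distances per classification
#'
#' @param sites Output of [find_pas()] with a `classification` column.
#' @return data.frame `classification`, `distance`, `count` (sites
#'   without a PAS are omitted).
#' @export
pas_distance_histogram <- function(sites) {
  keep <- !is.na(sites$pas_distance)
  if (!any(keep)) {
    return(data.frame(classification = character(0), distance = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(sites$classification[keep], sites$pas_distance[keep])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("classification", "distance", "count")
  df$distance <- as.integer(df$distance)
  df <- df[df$count > 0L, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Nucleotide composition around sites
#'
#' Per-position A/C/G/T frequencies over the strand-aware windows of
#' `+/- flank` nt centered on each site, one matrix per classification.
#' Offset 0 is the site itself. Ns (including positions beyond contig
#' ends) are left out of the denominator, so columns with at least one
#' observation sum to 1.
#'
#' @param sites Sites data.frame.
#' @param genome Named character vector.
#' @param flank Flank size (default 50).
#' @return Named list of 4 x (2 * flank + 1) matrices (rows A,C,G,T;
#'   columns offsets -flank..flank), one per classification present.
#' @export
nucleotide_composition <- function(sites, genome, flank = 50L) {
  width <- 2L * flank + 1L
  classes <- unique(sites$classification)
  out <- list()
  for (cl in classes) {
    idx <- which(sites$classification == cl)
    counts <- matrix(0L, nrow = 4L, ncol = width,
                     dimnames = list(c("A", "C", "G", "T"),
                                     as.character(-flank:flank)))
    for (i in idx) {
      w <- centered_seq(genome, sites$contig[i], sites$pos[i],
                        sites$strand[i], flank)
      ch <- strsplit(w, "", fixed = TRUE)[[1]]
      for (b in c("A", "C", "G", "T")) {
        counts[b, ] <- counts[b, ] + (ch == b)
      }
    }
    tot <- colSums(counts)
    freq <- sweep(counts, 2, pmax(tot, 1L), "/")
    freq[, tot == 0L] <- NA_real_
    out[[cl]] <- freq
  }
  out
}

#' Measure poly(A)-tail lengths by local alignment to a poly(A) stretch
#'
#' For each read, the query is the 3'-terminal `mapped_tail_len` nt of
#' the mapped part followed by the first `clip_len` nt of the 3' soft
#' clip (read orientation). The query is aligned to a stretch of
#' `target_len` As with the Smith-Waterman algorithm (match +2,
#' mismatch -3, gap -3 per base; against a homopolymer target this
#' linear gap cost is score-identical to affine opening/extension of
#' -3). The tail length is the number of A characters of the query
#' inside the best local alignment. This can overestimate tail length
#' when the mapped 3' terminus is itself A-rich, but is robust to
#' read errors inside the tail.
#'
#' @param reads data.frame from [load_reads()] (columns
#'   `mapped_tail_seq`, `clip3_seq`).
#' @param clip_len Clip prefix used (default 150).
#' @param target_len Length of the poly(A) target (default 180).
#' @param match,mismatch,gap Alignment scores (defaults +2, -3, -3).
#' @param polya_only Measure only reads with `has_polyA` evidence
#'   (default TRUE; set FALSE to measure every read).
#' @return data.frame `read_id`, `tail_length`, `sw_score` (one row per
#'   measured read, in input order).
#' @export
measure_tail <- function(reads, clip_len = 150L, target_len = 180L,
                         match = 2, mismatch = -3, gap = -3,
                         polya_only = TRUE) {
  r <- reads
  if (polya_only && "has_polyA" %in% names(r)) {
    r <- r[r$has_polyA, , drop = FALSE]
  }
  query <- paste0(r$mapped_tail_seq, substr(r$clip3_seq, 1L, clip_len))
  n <- length(query)
  tail_len <- integer(n)
  score <- integer(n)
  nonempty <- which(nchar(query) > 0L)
  if (length(nonempty) > 0L) {
    m <- .sw_matrix(match, mismatch)
    target <- strrep("A", target_len)
    aln <- Biostrings::pairwiseAlignment(
      query[nonempty], target, type = "local", substitutionMatrix = m,
      gapOpening = 0, gapExtension = -gap)
    sc <- Biostrings::score(aln)
    pat <- as.character(Biostrings::pattern(aln))
    pos_score <- sc > 0
    tail_len[nonempty[pos_score]] <- nchar(pat[pos_score]) -
      nchar(gsub("A", "", pat[pos_score], fixed = TRUE))
    score[nonempty] <- as.integer(round(pmax(sc, 0)))
  }
  data.frame(read_id = r$read_id, tail_length = tail_len,
             sw_score = score, stringsAsFactors = FALSE)
}

.sw_matrix <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N never matches
  m
}

#' Per-class poly(A)-tail length distribution at sites
#'
#' Assigns each measured read to the site whose 21-nt window contains
#' the read's 3' end (same contig and strand) and summarizes tail
#' lengths per site classification.
#'
#' @param measurements Output of [measure_tail()] for poly(A)+ reads.
#' @param reads The reads the measurements came from (for coordinates).
#' @param sites Classified sites.
#' @param window Site window (default 21).
#' @return A list: `assignments` (read_id, site index, classification,
#'   tail_length) and `summary` (per-class n, median, histogram as a
#'   table in the `hist` column list).
#' @export
tail_length_distribution <- function(measurements, reads, sites,
                                     window = 21L) {
  half <- (window - 1L) %/% 2L
  r <- reads[match(measurements$read_id, reads$read_id), , drop = FALSE]
  site_idx <- rep(NA_integer_, nrow(measurements))
  for (j in seq_len(nrow(sites))) {
    in_win <- r$contig == sites$contig[j] & r$strand == sites$strand[j] &
      abs(r$end3 - sites$pos[j]) <= half
    site_idx[in_win & is.na(site_idx)] <- j
  }
  assigned <- !is.na(site_idx)
  assignments <- data.frame(
    read_id = measurements$read_id[assigned],
    site = site_idx[assigned],
    classification = sites$classification[site_idx[assigned]],
    tail_length = measurements$tail_length[assigned],
    stringsAsFactors = FALSE)
  classes <- unique(assignments$classification)
  summary <- do.call(rbind, lapply(classes, function(cl) {
    x <- assignments$tail_length[assignments$classification == cl]
    data.frame(classification = cl, n = length(x),
               median = stats::median(x), stringsAsFactors = FALSE)
  }))
  hists <- lapply(classes, function(cl) {
    table(assignments$tail_length[assignments$classification == cl])
  })
  names(hists) <- classes
  list(assignments = assignments, summary = summary, hist = hists)
}

#' Read-end position profile around high-confidence sites
#'
#' For each high-confidence site, the fraction of its window's poly(A)+
#' read ends at each strand-aware offset (-flank .. +flank, positive =
#' downstream in transcript direction), averaged per classification.
#' Genuine cleavage is dispersed around the site whereas
#' template-switching ends pile at a single offset.
#'
#' @param sites Annotated, classified sites.
#' @param profile cDNA `end_profile`.
#' @param flank Offset range (default 10).
#' @param high_confidence_only Average only `window_support > 10` sites
#'   (default TRUE).
#' @return Matrix with one row per classification, columns
#'   -flank..flank; rows sum to 1.
#' @export
end_position_heatmap <- function(sites, profile, flank = 10L,
                                 high_confidence_only = TRUE) {
  use <- if (high_confidence_only) sites$high_confidence else
    rep(TRUE, nrow(sites))
  sub <- sites[use, , drop = FALSE]
  classes <- unique(sub$classification)
  width <- 2L * flank + 1L
  out <- matrix(NA_real_, nrow = length(classes), ncol = width,
                dimnames = list(classes, as.character(-flank:flank)))
  for (cl in classes) {
    idx <- which(sub$classification == cl)
    rows <- matrix(0, nrow = length(idx), ncol = width)
    for (k in seq_along(idx)) {
      i <- idx[k]
      p <- profile$profile[[sub$strand[i]]]
      lo <- sub$pos[i] - flank
      hi <- sub$pos[i] + flank
      v <- numeric(width)
      ok <- max(1L, lo):min(profile$len, hi)
      v[ok - lo + 1L] <- p$ends3_polyA[ok]
      if (sub$strand[i] == "-") v <- rev(v)
      if (sum(v) > 0) rows[k, ] <- v / sum(v)
    }
    out[cl, ] <- colMeans(rows)
  }
  out
}
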