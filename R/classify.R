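#' Classifier configuration
#'
#' All numeric thresholds of the template-switching classifier and its
#' companions. The logistic threshold on the read proportion is
#' `cap / (1 + 2^(-rate * (1 / (20 - n) - offset)))` where `n` is the
#' A-count of the site's upstream window.
#'
#' @param arich_site_min A site is "at an A-rich locus" when its A-count
#'   is at least this (default 3, matching the read-level run rule).
#' @param logistic_cap,logistic_rate,logistic_offset Constants of the
#'   logistic proportion threshold (defaults 0.8, 100, 0.08).
#' @param window Site window in nt (odd; default 21).
#' @param opposite_strand_fold Fold excess of opposite-strand 5' ends
#'   over same-strand poly(A)+ 3' ends that marks a site artifactual
#'   (inclusive; default 100).
#' @param exclusion_distance Artifacts within this many nt of a TES
#'   (same strand, inclusive) are excluded from downstream comparisons
#'   (default 50).
#' @param read_arich_run Minimum consecutive-A run that makes a read end
#'   "A-rich" (default 3).
#' @param a_count_window Upstream window of the A-count (default 20).
#' @return A list of class `ts_config`.
#' @export
ts_config <- function(arich_site_min = 3L, logistic_cap = 0.8,
                      logistic_rate = 100, logistic_offset = 0.08,
                      window = 21L, opposite_strand_fold = 100,
                      exclusion_distance = 50L, read_arich_run = 3L,
                      a_count_window = 20L) {
  cfg <- list(arich_site_min = arich_site_min, logistic_cap = logistic_cap,
              logistic_rate = logistic_rate, logistic_offset = logistic_offset,
              window = as.integer(window),
              opposite_strand_fold = opposite_strand_fold,
              exclusion_distance = as.integer(exclusion_distance),
              read_arich_run = as.integer(read_arich_run),
              a_count_window = as.integer(a_count_window))
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0 ||
                         identical(x, 0L), logical(1))),
            cfg$exclusion_distance >= 0L, cfg$window %% 2L == 1L)
  class(cfg) <- "ts_config"
  cfg
}

#' Logistic read-proportion threshold for A-rich sites
#'
#' The minimum fraction of overlapping reads that must end in a site's
#' window for the site to be accepted as a genuine end despite an
#' A-rich upstream region with A-count `n`. Increases steeply with `n`
#' and saturates at `logistic_cap`; at `n = 20` (the singular point of
#' `1 / (20 - n)`) the limiting value `logistic_cap` is returned.
#'
#' @param n Integer A-count(s) in `[0, 20]`.
#' @param cfg A [ts_config()].
#' @return Numeric threshold(s) in `(0, logistic_cap]`.
#' @export
logistic_threshold <- function(n, cfg = ts_config()) {
  if (any(n < 0 | n > cfg$a_count_window)) {
    stop("A-count outside [0, ", cfg$a_count_window, "]")
  }
  W <- cfg$a_count_window
  out <- numeric(length(n))
  lim <- n == W
  out[lim] <- cfg$logistic_cap
  k <- n[!lim]
  out[!lim] <- cfg$logistic_cap /
    (1 + 2^(-cfg$logistic_rate * (1 / (W - k) - cfg$logistic_offset)))
  out
}

#' Does a read end abut an A-rich genomic run?
#'
#' TRUE when a run of at least `cfg$read_arich_run` consecutive As
#' begins within the strand-aware 3 nt immediately upstream of the
#' read's 3' end — i.e. the genomic As a terminal poly(A) could have
#' aligned to abut the end.
#'
#' @param genome Named character vector.
#' @param contig,end3,strand Vectors describing read 3' ends.
#' @param cfg A [ts_config()].
#' @return Logical vector.
#' @export
read_end_is_arich <- function(genome, contig, end3, strand,
                              cfg = ts_config()) {
  run <- cfg$read_arich_run
  probe <- 3L + run - 1L
  n <- length(end3)
  out <- logical(n)
  for (i in seq_len(n)) {
    pf <- .upstream_chars(genome, contig[i], end3[i], strand[i], probe)
    hit <- FALSE
    for (j in 1:3) {
      if (j + run - 1L <= length(pf) && all(pf[j:(j + run - 1L)] == "A")) {
        hit <- TRUE
        break
      }
    }
    out[i] <- hit
  }
  out
}

#' Classify potential poly(A) sites as TES or TS artifact
#'
#' Sites whose upstream A-count is below `arich_site_min` are accepted
#' as transcriptional end sites outright. A site at an A-rich locus is
#' accepted as a TES when either (1) more of the poly(A)+ reads ending
#' in its 21-nt window end in non-A-rich genomic positions than in
#' A-rich ones, or (2) the fraction of overlapping reads ending in the
#' window exceeds [logistic_threshold()] at the site's A-count.
#' Otherwise it is a template-switching artifact. Finally the
#' opposite-strand rule ([opposite_strand_artifact()]) can override a
#' TES call to artifact.
#'
#' @param sites Annotated sites (see [annotate_candidates()]).
#' @param reads cDNA reads data.frame.
#' @param genome Named character vector.
#' @param profile cDNA `end_profile`.
#' @param cfg A [ts_config()].
#' @return `sites` with `classification` set to `"TES"` or
#'   `"TS_ARTIFACT"` and diagnostic columns `n_end_arich`,
#'   `n_end_nonarich`, `prop_threshold`, `opposite_strand_flag`.
#' @export
classify_sites <- function(sites, reads, genome, profile,
                           cfg = ts_config()) {
  n <- nrow(sites)
  if (n == 0L) return(sites)
  if (any(sites$overlap == 0L)) {
    stop("site with zero overlapping reads cannot be classified")
  }
  half <- (cfg$window - 1L) %/% 2L
  pa <- reads[reads$has_polyA, , drop = FALSE]
  cls <- character(n)
  n_ar <- integer(n); n_non <- integer(n); thr <- numeric(n)
  # A-richness of each distinct poly(A)+ read end, computed once
  key <- paste(pa$contig, pa$strand, pa$end3)
  uk <- !duplicated(key)
  end_ar <- read_end_is_arich(genome, pa$contig[uk], pa$end3[uk],
                              pa$strand[uk], cfg)
  names(end_ar) <- key[uk]
  read_ar <- end_ar[key]
  for (i in seq_len(n)) {
    thr[i] <- logistic_threshold(sites$a_count[i], cfg)
    if (sites$a_count[i] < cfg$arich_site_min) {
      cls[i] <- "TES"
      next
    }
    in_win <- pa$contig == sites$contig[i] &
      pa$strand == sites$strand[i] &
      abs(pa$end3 - sites$pos[i]) <= half
    n_ar[i] <- sum(read_ar[in_win])
    n_non[i] <- sum(in_win) - n_ar[i]
    crit_ends <- n_non[i] > n_ar[i]
    crit_prop <- sites$window_support[i] / sites$overlap[i] > thr[i]
    cls[i] <- if (crit_ends || crit_prop) "TES" else "TS_ARTIFACT"
  }
  opp <- opposite_strand_artifact(sites, profile, cfg)
  cls[opp] <- "TS_ARTIFACT"
  sites$classification <- cls
  sites$n_end_arich <- n_ar
  sites$n_end_nonarich <- n_non
  sites$prop_threshold <- thr
  sites$opposite_strand_flag <- opp
  sites
}

#' Opposite-strand 5'-end excess rule
#'
#' A site is flagged artifactual when the opposite strand contributes at
#' least `opposite_strand_fold` times more 5' ends than the site strand
#' contributes poly(A)+ 3' ends, summed over the site's window.
#'
#' @param sites Sites data.frame.
#' @param profile cDNA `end_profile`.
#' @param cfg A [ts_config()].
#' @return Logical vector (TRUE = artifactual).
#' @export
opposite_strand_artifact <- function(sites, profile, cfg = ts_config()) {
  half <- (cfg$window - 1L) %/% 2L
  n <- nrow(sites)
  out <- logical(n)
  for (s in c("+", "-")) {
    idx <- which(sites$strand == s & sites$contig == profile$contig)
    if (length(idx) == 0L) next
    opp <- if (s == "+") "-" else "+"
    own3 <- .window_sum(profile$profile[[s]]$ends3_polyA,
                        sites$pos[idx], half)
    opp5 <- .window_sum(profile$profile[[opp]]$ends5, sites$pos[idx], half)
    out[idx] <- opp5 >= cfg$opposite_strand_fold * own3
  }
  out
}

#' Exclude artifacts in the shadow of a TES
#'
#' Every TS artifact within `exclusion_distance` nt (same strand,
#' center-to-center, inclusive) of a TES is relabeled `"EXCLUDED"`, so
#' TES-derived features (its PAS, nearby dRNA ends) cannot leak into the
#' artifact class in comparisons. TES labels never change.
#'
#' @param sites Classified sites.
#' @param cfg A [ts_config()].
#' @return Sites with `classification` updated.
#' @export
exclude_near_tes <- function(sites, cfg = ts_config()) {
  arti <- which(sites$classification == "TS_ARTIFACT")
  tes <- which(sites$classification == "TES")
  for (i in arti) {
    near <- tes[sites$contig[tes] == sites$contig[i] &
                  sites$strand[tes] == sites$strand[i] &
                  abs(sites$pos[tes] - sites$pos[i]) <=
                    cfg$exclusion_distance]
    if (length(near) > 0L) sites$classification[i] <- "EXCLUDED"
  }
  sites
}

#' Merge per-experiment site calls
#'
#' Sites from separate experiments are matched on the same strand within
#' the site window; discordant calls resolve to TES (a site genuinely
#' used in any experiment is an end site). The merged site takes its
#' position and statistics from the member with the greatest window
#' support (ties toward the transcript-3'-most position); per-window
#' support columns are summed across experiments into `*_total` columns.
#'
#' @param site_list Named list of classified site data.frames, one per
#'   experiment.
#' @param cfg A [ts_config()].
#' @return Merged sites data.frame with `n_experiments`, `experiments`
#'   and `support_total`/`window_support_total` columns.
#' @export
merge_experiment_calls <- function(site_list, cfg = ts_config()) {
  if (is.null(names(site_list)) || any(names(site_list) == "")) {
    names(site_list) <- paste0("exp", seq_along(site_list))
  }
  all <- do.call(rbind, lapply(names(site_list), function(nm) {
    df <- site_list[[nm]]
    if (nrow(df) == 0L) return(NULL)
    df$source_experiment <- nm
    df
  }))
  if (is.null(all) || nrow(all) == 0L) return(all)
  half <- (cfg$window - 1L) %/% 2L
  tie <- ifelse(all$strand == "+", -all$pos, all$pos)
  ord <- order(-all$window_support, tie)
  assigned <- rep(FALSE, nrow(all))
  groups <- list()
  for (i in ord) {
    if (assigned[i]) next
    members <- which(!assigned & all$contig == all$contig[i] &
                       all$strand == all$strand[i] &
                       abs(all$pos - all$pos[i]) <= half)
    assigned[members] <- TRUE
    groups[[length(groups) + 1L]] <- list(rep = i, members = members)
  }
  merged <- do.call(rbind, lapply(groups, function(g) {
    rec <- all[g$rep, , drop = FALSE]
    mem <- all[g$members, , drop = FALSE]
    if (any(mem$classification == "TES")) rec$classification <- "TES"
    rec$n_experiments <- length(unique(mem$source_experiment))
    rec$experiments <- paste(sort(unique(mem$source_experiment)),
                             collapse = ",")
    rec$support_total <- sum(mem$support)
    rec$window_support_total <- sum(mem$window_support)
    rec
  }))
  merged <- merged[order(merged$contig, merged$strand, merged$pos), ,
                   drop = FALSE]
  rownames(merged) <- NULL
  merged
}
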