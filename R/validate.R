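#' Direct-RNA confirmation of poly(A) sites
#'
#' Because native RNA sequencing does not read through the terminal
#' poly(A) tail, every dRNA read 3' end is counted, with no poly(A)
#' evidence requirement. A site is confirmed when at least `min_frac`
#' (0.5% by default, inclusive) of the same-strand dRNA reads
#' overlapping the site end within its 21-nt window. Sites with zero
#' overlapping dRNA reads are not confirmed.
#'
#' @param sites Sites data.frame.
#' @param drna_profile `end_profile` built from dRNA reads.
#' @param min_frac Confirmation fraction (default 0.005).
#' @param window Window size (default 21).
#' @return Logical vector, one element per site.
#' @export
drna_confirms <- function(sites, drna_profile, min_frac = 0.005,
                          window = 21L) {
  half <- (window - 1L) %/% 2L
  n <- nrow(sites)
  out <- logical(n)
  for (s in c("+", "-")) {
    idx <- which(sites$strand == s & sites$contig == drna_profile$contig)
    if (length(idx) == 0L) next
    p <- drna_profile$profile[[s]]
    wend <- .window_sum(p$ends3, sites$pos[idx], half)
    ov <- p$cov[sites$pos[idx]]
    out[idx] <- ov > 0L & wend >= min_frac * ov
  }
  out
}

#' Conventional internal-priming filter
#'
#' Discards a site when its strand-aware 20-nt upstream window contains
#' a run of 6 or more consecutive As, or 12 or more As in total.
#'
#' @param sites Annotated sites (columns `max_consecutive_a`,
#'   `a_in_20`; recomputed from `genome` when absent).
#' @param genome Named character vector (only needed when the columns
#'   are absent).
#' @param min_run,min_total The two sub-rules (defaults 6 and 12).
#' @return Logical `keep` vector (FALSE = discard as internal priming).
#' @export
internal_priming_filter <- function(sites, genome = NULL, min_run = 6L,
                                    min_total = 12L) {
  sites <- .ensure_arich_cols(sites, genome)
  !(sites$max_consecutive_a >= min_run | sites$a_in_20 >= min_total)
}

#' SQANTI-style internal-priming filter
#'
#' Discards sites with more than 80% A-content in the upstream 20
#' nucleotides, i.e. at least 17 As out of 20 (the smallest integer
#' count strictly above 80%).
#'
#' @inheritParams internal_priming_filter
#' @param min_total A-count that triggers discard (default 17).
#' @return Logical `keep` vector.
#' @export
sqanti_like_filter <- function(sites, genome = NULL, min_total = 17L) {
  sites <- .ensure_arich_cols(sites, genome)
  sites$a_in_20 < min_total
}

.ensure_arich_cols <- function(sites, genome) {
  need <- setdiff(c("max_consecutive_a", "a_in_20"), names(sites))
  if (length(need) == 0L) return(sites)
  if (is.null(genome)) stop("genome needed to compute ", paste(need, collapse = ", "))
  n <- nrow(sites)
  mca <- integer(n); a20 <- integer(n)
  for (i in seq_len(n)) {
    a <- arich_assessment(genome, sites$contig[i], sites$pos[i],
                          sites$strand[i])
    mca[i] <- a$max_consecutive_a; a20[i] <- a$a_in_20
  }
  sites$max_consecutive_a <- mca
  sites$a_in_20 <- a20
  sites
}

#' Database-membership filter (PolyA_DB style)
#'
#' Keeps a site only when the database contains a poly(A) site on the
#' same contig and strand within the site's 21-nt window (`pos +/- 10`,
#' inclusive).
#'
#' @param sites Sites data.frame.
#' @param db data.frame with `contig`, `pos`, `strand` (see
#'   [read_polyadb()]).
#' @param window Window size (default 21).
#' @return Logical `keep` vector.
#' @export
polyadb_like_filter <- function(sites, db, window = 21L) {
  half <- (window - 1L) %/% 2L
  n <- nrow(sites)
  out <- logical(n)
  if (is.null(db) || nrow(db) == 0L) return(out)
  for (i in seq_len(n)) {
    out[i] <- any(db$contig == sites$contig[i] &
                    db$strand == sites$strand[i] &
                    abs(db$pos - sites$pos[i]) <= half)
  }
  out
}

#' Read a poly(A)-site database (BED or tabular dialect)
#'
#' Accepts BED (>= 3 columns, 0-based half-open; strand from column 6
#' when present) or a header-bearing TSV in the PolyA_DB style. For the
#' TSV, `col_map` names the chromosome/position/strand columns; the
#' position is taken as 1-based.
#'
#' @param path File path.
#' @param col_map Named character vector mapping `contig`, `pos`,
#'   `strand` to column names of the TSV dialect.
#' @return data.frame with `contig`, `pos` (1-based), `strand`.
#' @export
read_polyadb <- function(path,
                         col_map = c(contig = "Chromosome",
                                     pos = "Position", strand = "Strand")) {
  if (!file.exists(path)) stop("database file not found: ", path)
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t")[[1]]
  is_bed <- length(fields) >= 3L && !is.na(suppressWarnings(
    as.integer(fields[2]))) && !is.na(suppressWarnings(as.integer(fields[3])))
  if (is_bed) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    data.frame(contig = as.character(bed[[1]]),
               pos = as.integer(bed[[3]]),  # 0-based half-open end = 1-based pos
               strand = if (ncol(bed) >= 6L) as.character(bed[[6]]) else "+",
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    missing <- setdiff(unname(col_map), names(tab))
    if (length(missing) > 0L) {
      stop("database columns not found: ", paste(missing, collapse = ", "))
    }
    data.frame(contig = as.character(tab[[col_map[["contig"]]]]),
               pos = as.integer(tab[[col_map[["pos"]]]]),
               strand = as.character(tab[[col_map[["strand"]]]]),
               stringsAsFactors = FALSE)
  }
}

#' PPV/NPV evaluation of a filter against dRNA confirmation
#'
#' Positive predictive value = fraction of kept sites that are
#' dRNA-confirmed; negative predictive value = fraction of discarded
#' sites that are not. `EXCLUDED` sites are omitted entirely. Ratios
#' with empty denominators are reported as `NA`, never 0. A-count
#' strata report per-bin PPV (bins 0..9 individually and `">=10"`
#' merged).
#'
#' @param sites Sites data.frame with `classification` column.
#' @param keep Logical vector: the filter's verdicts (TRUE = keep).
#' @param confirmed Logical vector from [drna_confirms()].
#' @param high_confidence_only Restrict to `window_support > 10` sites.
#' @param filter_name Label carried into the result.
#' @return A list of class `filter_evaluation`: `filter_name`, `ppv`,
#'   `npv`, `n_kept`, `n_discarded`, `n_excluded`, `strata`
#'   (data.frame `a_count_bin`, `ppv`, `n`).
#' @export
evaluate_filter <- function(sites, keep, confirmed,
                            high_confidence_only = FALSE,
                            filter_name = "filter") {
  stopifnot(length(keep) == nrow(sites), length(confirmed) == nrow(sites))
  excl <- sites$classification == "EXCLUDED"
  n_excluded <- sum(excl)
  use <- !excl
  if (high_confidence_only) use <- use & sites$high_confidence
  keep <- keep[use]; confirmed <- confirmed[use]
  a_count <- sites$a_count[use]
  ratio <- function(x) if (length(x) == 0L) NA_real_ else mean(x)
  bins <- c(as.character(0:9), ">=10")
  bin_of <- ifelse(a_count >= 10L, ">=10", as.character(a_count))
  strata <- do.call(rbind, lapply(bins, function(b) {
    in_b <- bin_of == b & keep
    data.frame(a_count_bin = b, ppv = ratio(confirmed[in_b]),
               n = sum(in_b), stringsAsFactors = FALSE)
  }))
  structure(list(
    filter_name = filter_name,
    ppv = ratio(confirmed[keep]),
    npv = ratio(!confirmed[!keep]),
    n_kept = sum(keep), n_discarded = sum(!keep),
    n_excluded = n_excluded,
    high_confidence_only = high_confidence_only,
    strata = strata
  ), class = "filter_evaluation")
}

#' @export
print.filter_evaluation <- function(x, ...) {
  cat(sprintf("%s filter%s: PPV %s, NPV %s (kept %d, discarded %d, excluded %d)\n",
              x$filter_name,
              if (x$high_confidence_only) " (high-confidence sites)" else "",
              .fmt_pct(x$ppv), .fmt_pct(x$npv),
              x$n_kept, x$n_discarded, x$n_excluded))
  invisible(x)
}

.fmt_pct <- function(p) {
  if (is.na(p)) "NA" else sprintf("%.1f%%", 100 * p)
}

#' Run all filters and evaluate them against dRNA confirmation
#'
#' Computes verdicts of the template-switching classifier (keep = TES),
#' the internal-priming filter, the SQANTI-style filter and, when a
#' database is given, the database filter, then evaluates each with
#' [evaluate_filter()] over all sites and over high-confidence sites.
#'
#' @param sites Classified, annotated sites.
#' @param drna_profile dRNA `end_profile`.
#' @param genome Named character vector.
#' @param db Optional database data.frame.
#' @param drna_min_frac Confirmation fraction (default 0.005).
#' @return A list: `confirmed` (logical), `verdicts` (data.frame of
#'   keep columns), `evaluations` (list of `filter_evaluation`, names
#'   `TS`, `IP`, `SQANTI`, `POLYADB` with `_hc` variants).
#' @export
evaluate_all_filters <- function(sites, drna_profile, genome, db = NULL,
                                 drna_min_frac = 0.005) {
  confirmed <- drna_confirms(sites, drna_profile, min_frac = drna_min_frac)
  verdicts <- data.frame(
    TS = sites$classification == "TES",
    IP = internal_priming_filter(sites, genome),
    SQANTI = sqanti_like_filter(sites, genome))
  if (!is.null(db)) verdicts$POLYADB <- polyadb_like_filter(sites, db)
  evals <- list()
  for (f in names(verdicts)) {
    evals[[f]] <- evaluate_filter(sites, verdicts[[f]], confirmed,
                                  FALSE, f)
    evals[[paste0(f, "_hc")]] <- evaluate_filter(sites, verdicts[[f]],
                                                 confirmed, TRUE, f)
  }
  list(confirmed = confirmed, verdicts = verdicts, evaluations = evals)
}
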