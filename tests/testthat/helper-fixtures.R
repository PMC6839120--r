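# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Default end-to-end fixture: simulated bundle, full screen against
# dRNA, feature analyses, and truth matching. Built once per session.
default_fixture <- function(seed = 7L) {
  key <- paste0("fix", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  dir <- file.path(tempdir(), paste0("polyascreen_fixture_", seed))
  bundle <- simulate_polya_run(sim_config(seed = seed), dir = dir)
  genome <- bundle$genome
  screen <- screen_polya_reads(list(exp1 = bundle$cdna), genome,
                               drna_reads = bundle$drna)
  sites <- match_truth(screen$sites, bundle$truth)
  features <- run_features(
    structure(list(sites = sites,
                   per_experiment = screen$per_experiment,
                   evaluation = screen$evaluation,
                   config = screen$config), class = "pa_screen"),
    genome)
  fix <- list(bundle = bundle, genome = genome, screen = screen,
              sites = sites, features = features)
  .fixture_cache[[key]] <- fix
  fix
}

# Tail-distribution fixture: same tail model as the default study
# conditions but with ~2000 signal reads per class, the sampling size
# at which integer medians resolve below the comparison band. Truth
# classes are used directly (a generator-level check).
tail_fixture <- function(seed = 7L) {
  key <- paste0("tail", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config(seed = seed, signal_support_mean = 55,
                    cdna_depth = 5, drna_depth = 5)
  b <- simulate_polya_run(cfg)
  .fixture_cache[[key]] <- b
  b
}

# Attach nearest-truth columns to a site table (same strand, within 10
# nt; unmatched sites get NA).
match_truth <- function(sites, truth) {
  idx <- vapply(seq_len(nrow(sites)), function(i) {
    d <- abs(truth$pos - sites$pos[i]) +
      ifelse(truth$strand == sites$strand[i] &
               truth$contig == sites$contig[i], 0, 1e9)
    j <- which.min(d)
    if (d[j] <= 10) j else NA_integer_
  }, integer(1))
  sites$truth_idx <- idx
  sites$truth_kind <- truth$kind[idx]
  sites$truth_pos <- truth$pos[idx]
  sites$truth_style <- truth$arich_style[idx]
  sites$truth_a_count <- truth$planted_a_count[idx]
  sites
}

# A one-contig genome from a plain string.
mk_genome <- function(seq, name = "chr") {
  stats::setNames(toupper(seq), name)
}

# Construct an aligned-read table row set by 3' end positions.
mk_reads <- function(contig, strand, end3, has_polyA = TRUE, len = 100L,
                     clip3 = ifelse(has_polyA, strrep("A", 30L), ""),
                     id_prefix = "r") {
  n <- length(end3)
  has_polyA <- rep_len(has_polyA, n)
  clip3 <- rep_len(clip3, n)
  if (strand == "+") {
    start <- end3 - len + 1L
    end <- end3
  } else {
    start <- end3
    end <- end3 + len - 1L
  }
  data.frame(read_id = sprintf("%s%04d", id_prefix, seq_len(n)),
             contig = rep_len(contig, n), strand = rep_len(strand, n),
             start = as.integer(start), end = as.integer(end),
             end3 = as.integer(end3),
             end5 = as.integer(if (strand == "+") start else end),
             clip3_seq = clip3,
             mapped_tail_seq = rep_len(strrep("G", 30L), n),
             has_polyA = has_polyA, stringsAsFactors = FALSE)
}

# A minimal annotated site row for classifier/filter micro-fixtures.
mk_site <- function(contig, pos, strand, support = 5L,
                    window_support = support, overlap = 100L,
                    a_count = 0L, max_consecutive_a = 0L, a_in_20 = 0L,
                    classification = "UNCLASSIFIED",
                    high_confidence = window_support > 10L) {
  data.frame(contig = contig, pos = as.integer(pos), strand = strand,
             support = as.integer(support),
             overlap = as.integer(overlap),
             window_support = as.integer(window_support),
             a_count = as.integer(a_count),
             max_consecutive_a = as.integer(max_consecutive_a),
             a_in_20 = as.integer(a_in_20),
             high_confidence = high_confidence,
             classification = classification, stringsAsFactors = FALSE)
}

# Write a SAM file from header lines plus alignment records.
write_mini_sam <- function(records, contig = "chr", len = 200L,
                           path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", contig, len),
               records), path)
  path
}
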