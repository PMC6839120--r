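# Lay out a + strand genome whose 40-nt upstream window of the site is
# given in sense orientation (5' to 3', ending at the base adjacent to
# the site).
pas_genome <- function(window40) {
  stopifnot(nchar(window40) == 40L)
  mk_genome(paste0(strrep("G", 10), window40, "C", strrep("G", 10)))
}
PAS_SITE <- 51L

test_that("the most common signal wins over closer lower-rank hits", {
  # AATAAA ends at distance 25; ATTAAA closer to the site
  w <- paste0(strrep("C", 10), "AATAAA", strrep("C", 13), "ATTAAA",
              strrep("C", 5))
  site <- mk_site("chr", PAS_SITE, "+", classification = "TES")
  out <- find_pas(site, pas_genome(w))
  expect_identical(out$pas_motif, "AATAAA")
  expect_equal(out$pas_distance, 25L)
  expect_equal(out$pas_rank, 1L)
})

test_that("absent signals give NA", {
  out <- find_pas(mk_site("chr", PAS_SITE, "+"),
                  pas_genome(strrep("C", 40)))
  expect_true(is.na(out$pas_motif))
  expect_true(is.na(out$pas_distance))
})

test_that("equal-rank hits resolve to the distance closest to 25 nt", {
  # AATAAA at distances 31 and 18: |31-25| = 6 beats |18-25| = 7
  w <- paste0("CCCC", "AATAAA", strrep("C", 7), "AATAAA", strrep("C", 17))
  stopifnot(nchar(w) == 40L)
  out <- find_pas(mk_site("chr", PAS_SITE, "+"), pas_genome(w))
  expect_equal(out$pas_distance, 31L)
  # an exhaustive scan of the window agrees
  hits <- integer(0)
  for (j in 1:35) if (substr(w, j, j + 5L) == "AATAAA") {
    hits <- c(hits, 40L - (j + 5L) + 1L)
  }
  expect_identical(sort(hits), c(18L, 31L))
})

test_that("signal detection is invariant under strand mirroring", {
  w <- paste0(strrep("C", 9), "AATAAA", strrep("T", 25))
  g <- pas_genome(w)
  L <- nchar(g[[1]])
  gm <- mk_genome(revcomp(g[[1]]))
  a <- find_pas(mk_site("chr", PAS_SITE, "+"), g)
  b <- find_pas(mk_site("chr", L + 1L - PAS_SITE, "-"), gm)
  expect_identical(a$pas_motif, b$pas_motif)
  expect_identical(a$pas_distance, b$pas_distance)
})

test_that("distance histograms split by classification", {
  sites <- rbind(mk_site("chr", PAS_SITE, "+", classification = "TES"))
  w <- paste0(strrep("C", 10), "AATAAA", strrep("C", 24))
  out <- find_pas(sites, pas_genome(w))
  h <- pas_distance_histogram(out)
  expect_equal(h$count[h$classification == "TES" & h$distance == 25L], 1L)
  empty <- pas_distance_histogram(out[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("composition matrices are indicators for a single site", {
  g <- mk_genome(paste(rep(c("A", "C", "G", "T"), 30), collapse = ""))
  sites <- mk_site("chr", 60L, "+", classification = "TES")
  comp <- nucleotide_composition(sites, g, flank = 5L)$TES
  expect_equal(dim(comp), c(4L, 11L))
  expect_true(all(colSums(comp) == 1))
  expect_true(all(comp %in% c(0, 1)))
  # position 60 is a T in the ACGT repeat
  expect_equal(comp["T", "0"], 1)
})

test_that("composition is strand-symmetric on mirrored fixtures", {
  set.seed(51)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
             collapse = "")
  g <- mk_genome(s)
  gm <- mk_genome(revcomp(s))
  sites <- mk_site("chr", 150L, "+", classification = "TES")
  sites_m <- mk_site("chr", 300L - 150L + 1L, "-", classification = "TES")
  expect_equal(nucleotide_composition(sites, g, 20L)$TES,
               nucleotide_composition(sites_m, gm, 20L)$TES)
})

test_that("tail measurement reproduces the alignment worked examples", {
  reads <- data.frame(
    read_id = c("clean", "mismatch", "none"),
    contig = "chr", strand = "+", start = 1L, end = 30L, end3 = 30L,
    end5 = 1L,
    clip3_seq = c("AAAAAAAAAA", "AAAAATAAAA", "CCCCCCCCCC"),
    mapped_tail_seq = strrep("G", 2),
    has_polyA = TRUE, stringsAsFactors = FALSE)
  out <- measure_tail(reads)
  expect_equal(out$tail_length[out$read_id == "clean"], 10L)
  expect_equal(out$sw_score[out$read_id == "clean"], 20L)
  # one mismatch inside is kept in the alignment but not counted
  expect_equal(out$tail_length[out$read_id == "mismatch"], 9L)
  expect_equal(out$sw_score[out$read_id == "mismatch"], 15L)
  expect_equal(out$tail_length[out$read_id == "none"], 0L)
})

test_that("tail scores equal an independent full-DP aligner", {
  set.seed(52)
  n <- 200L
  qs <- vapply(seq_len(n), function(i) {
    len <- sample(1:60, 1)
    p_a <- if (i %% 2 == 0) 0.7 else 0.25
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c(p_a, rep((1 - p_a) / 3, 3))), collapse = "")
  }, character(1))
  reads <- data.frame(read_id = sprintf("q%03d", seq_len(n)),
                      contig = "chr", strand = "+", start = 1L, end = 30L,
                      end3 = 30L, end5 = 1L, clip3_seq = qs,
                      mapped_tail_seq = "", has_polyA = TRUE,
                      stringsAsFactors = FALSE)
  got <- measure_tail(reads)
  want <- vapply(qs, oracle_sw_score, numeric(1), USE.NAMES = FALSE)
  expect_equal(as.numeric(got$sw_score), want)
  # tails are bounded by the query's A content and imply the score
  n_a <- nchar(qs) - nchar(gsub("A", "", qs, fixed = TRUE))
  expect_true(all(got$tail_length <= n_a))
  expect_true(all(2 * got$tail_length >= got$sw_score))
})

test_that("clip bases beyond position 150 never affect the tail", {
  base <- strrep("A", 150)
  reads <- data.frame(read_id = c("short", "long"), contig = "chr",
                      strand = "+", start = 1L, end = 30L, end3 = 30L,
                      end5 = 1L,
                      clip3_seq = c(base, paste0(base, strrep("C", 100))),
                      mapped_tail_seq = "", has_polyA = TRUE,
                      stringsAsFactors = FALSE)
  out <- measure_tail(reads)
  expect_equal(out$tail_length[1], out$tail_length[2])
  expect_equal(out$sw_score[1], out$sw_score[2])
})

test_that("tail distributions assign reads to sites by window", {
  sites <- rbind(mk_site("chr", 100L, "+", classification = "TES"),
                 mk_site("chr", 500L, "+", classification = "TS_ARTIFACT"))
  reads <- rbind(mk_reads("chr", "+", c(100L, 105L, 95L)),
                 mk_reads("chr", "+", c(500L, 500L), id_prefix = "t"),
                 mk_reads("chr", "+", 300L, id_prefix = "far"))
  meas <- data.frame(read_id = reads$read_id,
                     tail_length = c(20L, 20L, 20L, 40L, 44L, 99L),
                     sw_score = 0L, stringsAsFactors = FALSE)
  td <- tail_length_distribution(meas, reads, sites)
  expect_equal(sort(unique(td$assignments$classification)),
               c("TES", "TS_ARTIFACT"))
  s <- td$summary
  expect_equal(s$median[s$classification == "TES"], 20)
  expect_equal(s$median[s$classification == "TS_ARTIFACT"], 42)
  expect_equal(nrow(td$assignments), 5L)  # the stray read is unassigned
})

test_that("end-position rows are per-site fractions that sum to one", {
  sites <- rbind(
    mk_site("chr", 100L, "+", window_support = 20L,
            classification = "TS_ARTIFACT"),
    mk_site("chr", 500L, "+", window_support = 21L,
            classification = "TES"))
  reads <- rbind(mk_reads("chr", "+", rep(100L, 20)),
                 mk_reads("chr", "+", rep(495L:501L, 3), id_prefix = "d"))
  prof <- build_end_profile(reads, "chr", 1000L)
  h <- end_position_heatmap(sites, prof)
  expect_equal(rowSums(h), c(TS_ARTIFACT = 1, TES = 1))
  expect_equal(h["TS_ARTIFACT", "0"], 1)  # point mass at the site
  expect_lt(max(h["TES", ]), 0.5)         # dispersed ends
})
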