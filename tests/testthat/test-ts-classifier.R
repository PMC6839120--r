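# Frozen 40-digit evaluations of the logistic proportion threshold at
# every integer A-count (independent arbitrary-precision computation).
LOGISTIC_REFERENCE <- c(
  0.0888888888888888889, 0.104355593076085757, 0.124162677927196524,
  0.149816783776665546, 0.183335463572391634, 0.227282922733320074,
  0.284550947080666849, 0.35750574377813492, 0.446005332780446317,
  0.544415656113452733, 0.64, 0.717016562106771369, 0.766141030140165134,
  0.789875580229541554, 0.798036205831435034, 0.79980473517207713,
  0.799993896530940773, 0.799999981076705284, 0.799999999999818101, 0.8)

test_that("logistic threshold matches the high-precision reference", {
  got <- logistic_threshold(0:19)
  expect_equal(got, LOGISTIC_REFERENCE, tolerance = 1e-14)
  expect_equal(logistic_threshold(10), 0.64)  # exactly representable case
  expect_identical(logistic_threshold(20), 0.8)  # the singular limit
})

test_that("logistic threshold is strictly increasing and bounded", {
  v <- logistic_threshold(0:20)
  expect_true(all(diff(v[1:20]) > 0))
  expect_true(all(v > 0 & v <= 0.8))
  expect_error(logistic_threshold(-1), "outside")
  expect_error(logistic_threshold(21), "outside")
})

test_that("read-end A-richness requires a 3-run starting within 3 nt", {
  # layouts written proximal-first, sites on a + genome
  cases <- list(
    list(pf = "AAATT", arich = TRUE),    # run at the end itself
    list(pf = "ACACA", arich = FALSE),   # no run anywhere
    list(pf = "CCAAA", arich = TRUE),    # run starts 2 nt upstream
    list(pf = "CCCAA", arich = FALSE),   # run starts beyond 3 nt
    list(pf = "ACAAA", arich = TRUE),    # offset-1 A does not break it
    list(pf = "AACCA", arich = FALSE))   # only a 2-run near the end
  for (cs in cases) {
    g <- mk_genome(paste0(paste(rev(strsplit(cs$pf, "")[[1]]),
                                collapse = ""), "GG"))
    got <- read_end_is_arich(g, "chr", 6L, "+")
    expect_identical(got, cs$arich, label = cs$pf)
  }
})

# Build a site + reads + profile micro-fixture on an A-rich locus with
# controllable support and overlap.
arich_micro <- function(n_signal, n_background, a_count_target = 10L) {
  # upstream of pos: 10 As then Cs (A-count 10), site base G
  up <- paste0(strrep("C", 70), strrep("A", a_count_target))
  g <- mk_genome(paste0(strrep("G", 200), up, "G", strrep("G", 200)))
  pos <- 200L + 70L + a_count_target + 1L
  reads <- rbind(
    mk_reads("chr", "+", rep(pos, n_signal), len = 150L),
    mk_reads("chr", "+", rep(pos + 60L, n_background), has_polyA = FALSE,
             len = 150L, id_prefix = "bg"))
  prof <- build_end_profile(reads, "chr", nchar(g[[1]]))
  sites <- annotate_candidates(
    data.frame(contig = "chr", pos = pos, strand = "+",
               support = n_signal, overlap = 0L, stringsAsFactors = FALSE),
    g, prof)
  list(g = g, reads = reads, prof = prof, sites = sites)
}

test_that("sites below the A-rich threshold are accepted outright", {
  g <- mk_genome(paste0(strrep("G", 100), "C", strrep("G", 100)))
  reads <- rbind(mk_reads("chr", "+", rep(101L, 3), len = 50L),
                 mk_reads("chr", "+", rep(140L, 200), has_polyA = FALSE,
                          len = 100L, id_prefix = "bg"))
  prof <- build_end_profile(reads, "chr", 201L)
  sites <- annotate_candidates(
    data.frame(contig = "chr", pos = 101L, strand = "+", support = 3L,
               overlap = 0L, stringsAsFactors = FALSE), g, prof)
  expect_lt(sites$a_count, 3L)
  out <- classify_sites(sites, reads, g, prof)
  expect_identical(out$classification, "TES")
})

test_that("the read-proportion criterion follows the logistic threshold", {
  m <- arich_micro(50L, 50L)   # support 50 of overlap 100 = 0.5 < 0.64
  expect_equal(m$sites$a_count, 10L)
  out <- classify_sites(m$sites, m$reads, m$g, m$prof)
  expect_identical(out$classification, "TS_ARTIFACT")
  m2 <- arich_micro(50L, 20L)  # 50 of 70 = 0.714 > 0.64
  out2 <- classify_sites(m2$sites, m2$reads, m2$g, m2$prof)
  expect_identical(out2$classification, "TES")
})

test_that("a majority of non-A-rich read ends rescues an A-rich site", {
  m <- arich_micro(5L, 200L)
  # plant 12 poly(A)+ reads ending 8 nt downstream where the genome is
  # G-rich: those window reads end outside any A run
  extra <- mk_reads("chr", "+", rep(m$sites$pos + 8L, 12L), len = 150L,
                    id_prefix = "nonar")
  reads <- rbind(m$reads, extra)
  prof <- build_end_profile(reads, "chr", nchar(m$g[[1]]))
  sites <- annotate_candidates(m$sites[, 1:5], m$g, prof)
  out <- classify_sites(sites, reads, m$g, prof)
  expect_gt(out$n_end_nonarich, out$n_end_arich)
  expect_identical(out$classification, "TES")
})

test_that("criterion-2 calls never flip to artifact as support grows", {
  prev <- "TS_ARTIFACT"
  for (n_signal in c(20L, 40L, 60L, 80L)) {
    m <- arich_micro(n_signal, 100L - n_signal)
    out <- classify_sites(m$sites, m$reads, m$g, m$prof)
    if (prev == "TES") expect_identical(out$classification, "TES")
    prev <- out$classification
  }
  expect_identical(prev, "TES")
})

test_that("opposite-strand 5'-end excess is inclusive at 100-fold", {
  g <- mk_genome(strrep("G", 400))
  mk_case <- function(n_opp) {
    own <- mk_reads("chr", "+", rep(200L, 2), len = 50L)
    # minus-strand reads whose 5' end (their right end) is at 200
    opp <- mk_reads("chr", "-", rep(151L, n_opp), len = 50L,
                    has_polyA = FALSE, id_prefix = "o")
    prof <- build_end_profile(rbind(own, opp), "chr", 400L)
    sites <- annotate_candidates(
      data.frame(contig = "chr", pos = 200L, strand = "+", support = 2L,
                 overlap = 0L, stringsAsFactors = FALSE), g, prof)
    opposite_strand_artifact(sites, prof)
  }
  expect_true(mk_case(250L))   # 125-fold
  expect_false(mk_case(150L))  # 75-fold
  expect_true(mk_case(200L))   # exactly 100-fold, inclusive
})

test_that("artifacts within 50 nt of a TES are excluded, inclusively", {
  sites <- rbind(
    mk_site("chr", 100L, "+", classification = "TES"),
    mk_site("chr", 120L, "+", classification = "TS_ARTIFACT"),
    mk_site("chr", 150L, "+", classification = "TS_ARTIFACT"),
    mk_site("chr", 151L, "+", classification = "TS_ARTIFACT"),
    mk_site("chr", 130L, "-", classification = "TS_ARTIFACT"))
  out <- exclude_near_tes(sites)
  expect_identical(out$classification,
                   c("TES", "EXCLUDED", "EXCLUDED", "TS_ARTIFACT",
                     "TS_ARTIFACT"))
})

test_that("discordant multi-experiment calls resolve to TES", {
  a <- mk_site("chr", 500L, "+", support = 5L, window_support = 8L,
               classification = "TS_ARTIFACT")
  b <- mk_site("chr", 502L, "+", support = 9L, window_support = 14L,
               classification = "TES")
  merged <- merge_experiment_calls(list(exp1 = a, exp2 = b))
  expect_equal(nrow(merged), 1L)
  expect_identical(merged$classification, "TES")
  expect_equal(merged$pos, 502L)  # from the higher-support experiment
  expect_equal(merged$n_experiments, 2L)
  expect_equal(merged$window_support_total, 22L)
})

test_that("concordant and singleton calls keep their labels", {
  a <- mk_site("chr", 500L, "+", classification = "TES")
  b <- mk_site("chr", 500L, "+", classification = "TES")
  merged <- merge_experiment_calls(list(a, b))
  expect_identical(merged$classification, "TES")
  lone <- mk_site("chr", 900L, "-", classification = "TS_ARTIFACT")
  m2 <- merge_experiment_calls(list(exp1 = a, exp2 = lone))
  expect_equal(nrow(m2), 2L)
  expect_identical(m2$classification[m2$pos == 900L], "TS_ARTIFACT")
})
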