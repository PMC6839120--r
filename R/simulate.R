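#' Simulation configuration
#'
#' Generative settings of the synthetic fixture: a random genome with
#' planted genuine transcript end sites (TES), template-switching (TS)
#' artifact loci at mildly A-rich positions, and internal-priming (IP)
#' artifact loci, plus cDNA and dRNA read sets over them.
#'
#' The defaults encode the contrasts the classifier targets: genuine
#' cleavage positions are dispersed (`tes_cleavage_sd`) while artifact
#' ends sit at a single nucleotide; TES and TS reads share one poly(A)
#' tail-length distribution (artifact tails are produced from the
#' genuine tail template, so they are not shorter); IP tails are
#' primer-length; TS loci carry only 3-5 upstream As; dRNA reads never
#' carry a sequenced tail and their 3' ends cluster only at genuine
#' TESs. A fraction `tes_arich_frac` of TESs sits in windows that are
#' A-rich by the classical window measures (many scattered/distal As)
#' while the proximal counter-based A-count stays below 3 — the regime
#' where window-count filters discard genuine sites. Poly(A)+ site
#' support averages about 10% of the local coverage, the low-proportion
#' regime the logistic criterion addresses.
#'
#' @param seed Integer seed; a given seed reproduces the bundle
#'   byte-identically.
#' @param genome_length,gc_content Genome size and G+C fraction.
#' @param n_tes,n_ts_artifacts,n_ip_artifacts Locus counts.
#' @param artifact_acount_range Inclusive A-count range of TS loci.
#' @param tes_cleavage_sd SD (nt) of genuine cleavage dispersion.
#' @param tail_mean,tail_sd Poly(A) tail length distribution shared by
#'   TES and TS reads (nt).
#' @param ip_tail_len Mean IP tail length (anchored-primer length, nt).
#' @param cdna_depth,drna_depth Mean background/overlap coverage per
#'   locus (reads).
#' @param signal_support_mean Mean number of poly(A)+ (or dRNA-ending)
#'   reads per locus.
#' @param pas_distance Planted signal-to-cleavage distance (nt).
#' @param tes_arich_frac Fraction of TESs with classically A-rich
#'   windows.
#' @param read_len_range Aligned read length range (nt).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 60000L, gc_content = 0.5,
                       n_tes = 40L, n_ts_artifacts = 30L,
                       n_ip_artifacts = 10L,
                       artifact_acount_range = c(3L, 5L),
                       tes_cleavage_sd = 2, tail_mean = 50, tail_sd = 15,
                       ip_tail_len = 20L, cdna_depth = 100, drna_depth = 50,
                       signal_support_mean = 12,
                       pas_distance = 25L, tes_arich_frac = 0.2,
                       read_len_range = c(300L, 800L)) {
  cfg <- as.list(environment())
  stopifnot(cfg$cdna_depth > 0, cfg$drna_depth > 0,
            cfg$genome_length > 2000L,
            all(artifact_acount_range >= 1L),
            artifact_acount_range[1] <= artifact_acount_range[2])
  class(cfg) <- "sim_config"
  cfg
}

.sample_base <- function(n, p_a, p_c, p_g, p_t) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c(p_a, p_c, p_g, p_t))
}

# Write proximal-first upstream bases into a genome character vector.
# On "+" the bases go leftward from pos-1; on "-" rightward from pos+1,
# complemented (proximal-first upstream of a "-" site reads the
# reverse-complement strand).
.set_upstream <- function(gv, pos, strand, bases_pf, offset = 1L) {
  k <- length(bases_pf)
  idx <- offset:(offset + k - 1L)
  if (strand == "+") {
    gv[pos - idx] <- bases_pf
  } else {
    gv[pos + idx] <- chartr("ACGTN", "TGCAN", bases_pf)
  }
  gv
}

# A 20-nt proximal-first window with a target counter A-count and
# constrained classical measures (no >=6-run, bounded window A total).
.tes_window <- function(target_a, max_a20 = 11L) {
  repeat {
    non_a <- .sample_base(target_a + 1L, 0, 1 / 3, 1 / 3, 1 / 3)
    rest_n <- 20L - (2L * target_a + 1L)
    rest <- .sample_base(rest_n, 0.15, 0.30, 0.30, 0.25)
    pf <- c(rep("A", target_a), non_a, rest)
    ok_run <- {
      r <- rle(pf == "A")
      !any(r$lengths[r$values] >= 6L)
    }
    if (ok_run && sum(pf == "A") < max_a20) return(pf)
  }
}

.ts_window <- function(k) .tes_window(k)

.arich_tes_window <- function() {
  # proximal non-A shield halts the A-count iteration immediately, but
  # the window carries a long A run: A-count 0, yet >=12/20 As and a
  # >=6-run, so the classical internal-priming rule fires. Three shield
  # bases keep the property stable under the 1-2 nt cleavage dispersion
  # of genuine sites.
  c("C", "C", "G", rep("A", 13L), .sample_base(4L, 0, 1 / 3, 1 / 3, 1 / 3))
}

.ip_window <- function() {
  c(rep("A", 13L), .sample_base(7L, 0.15, 0.30, 0.30, 0.25))
}

#' Generate a synthetic genome with planted truth loci
#'
#' Random genome at the configured base composition with engineered
#' upstream windows at each planted locus: TES loci get an A-count
#' below 3 and an AATAAA signal at the configured distance; TS loci get
#' an exact target A-count in `artifact_acount_range` (and stay below
#' the internal-priming thresholds); IP loci get 13 proximal As.
#' Strands alternate across loci; loci are at least 200 nt apart.
#'
#' @param cfg A [sim_config()]. The caller controls the RNG seed (see
#'   [simulate_polya_run()]).
#' @return A list: `genome` (named character vector, contig `"sim1"`)
#'   and `truth` (data.frame `contig`, `pos`, `strand`, `kind`,
#'   `planted_a_count`, `pas_motif`, `pas_distance`, `arich_style`).
#' @export
generate_genome <- function(cfg) {
  L <- cfg$genome_length
  gc <- cfg$gc_content
  gv <- .sample_base(L, (1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  n_loci <- cfg$n_tes + cfg$n_ts_artifacts + cfg$n_ip_artifacts
  margin <- 400L
  spacing <- (L - 2L * margin) / n_loci
  if (spacing < 220) stop("genome too short for the requested locus count")
  pos <- as.integer(round(margin + (seq_len(n_loci) - 0.5) * spacing +
                            sample(-50:50, n_loci, replace = TRUE)))
  kind <- sample(c(rep("TES", cfg$n_tes),
                   rep("TS_ARTIFACT", cfg$n_ts_artifacts),
                   rep("IP_ARTIFACT", cfg$n_ip_artifacts)))
  strand <- rep(c("+", "-"), length.out = n_loci)
  n_arich <- round(cfg$tes_arich_frac * cfg$n_tes)
  tes_idx <- which(kind == "TES")
  arich_tes <- tes_idx[seq_len(n_arich)]
  planted_a <- integer(n_loci)
  pas_motif <- rep(NA_character_, n_loci)
  pas_dist <- rep(NA_integer_, n_loci)
  style <- rep(NA_character_, n_loci)
  for (i in seq_len(n_loci)) {
    if (kind[i] == "TES") {
      pf <- if (i %in% arich_tes) .arich_tes_window() else
        .tes_window(sample(0:2, 1L))
      style[i] <- if (i %in% arich_tes) "arich_window" else "plain"
      gv <- .set_upstream(gv, pos[i], strand[i], pf)
      # cleavage occurs at a CA-style dinucleotide: a non-A cleavage
      # base keeps the upstream window stable under cleavage dispersion
      gv <- .set_upstream(gv, pos[i], strand[i],
                          sample(c("C", "G", "T"), 1L), offset = 0L)
      # plant AATAAA with its 3' end pas_distance nt upstream of the site
      d <- cfg$pas_distance
      sig <- strsplit("AATAAA", "")[[1]]
      gv <- .set_upstream(gv, pos[i], strand[i], rev(sig), offset = d)
      pas_motif[i] <- "AATAAA"
      pas_dist[i] <- d
    } else if (kind[i] == "TS_ARTIFACT") {
      k <- sample(seq(cfg$artifact_acount_range[1],
                      cfg$artifact_acount_range[2]), 1L)
      pf <- .ts_window(k)
      gv <- .set_upstream(gv, pos[i], strand[i], pf)
    } else {
      gv <- .set_upstream(gv, pos[i], strand[i], .ip_window())
    }
    planted_a[i] <- a_count_run(
      if (strand[i] == "+") gv[pos[i] - 1:20]
      else chartr("ACGTN", "TGCAN", gv[pos[i] + 1:20]))
  }
  genome <- c(sim1 = paste(gv, collapse = ""))
  truth <- data.frame(contig = "sim1", pos = pos, strand = strand,
                      kind = kind, planted_a_count = planted_a,
                      pas_motif = pas_motif, pas_distance = pas_dist,
                      arich_style = style, stringsAsFactors = FALSE)
  list(genome = genome, truth = truth)
}

# One batch of simulated reads in the internal alignment representation.
.mk_reads <- function(prefix, n, contig, strand, end3, len, tail, L) {
  if (n == 0L) {
    return(data.frame(read_id = character(0), contig = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), end3 = integer(0),
                      end5 = integer(0), tail_len = integer(0),
                      stringsAsFactors = FALSE))
  }
  end3 <- pmin(pmax(end3, 30L), L - 30L)
  if (strand == "+") {
    start <- pmax(1L, end3 - len + 1L)
    end <- end3
  } else {
    start <- end3
    end <- pmin(L, end3 + len - 1L)
  }
  data.frame(read_id = sprintf("%s_%06d", prefix, seq_len(n)),
             contig = contig, strand = strand,
             start = as.integer(start), end = as.integer(end),
             end3 = as.integer(end3),
             end5 = as.integer(if (strand == "+") start else end),
             tail_len = as.integer(tail), stringsAsFactors = FALSE)
}

# Fill clip3_seq / mapped_tail_seq / has_polyA from the genome so the
# simulated table matches what load_reads() would produce.
.finish_reads <- function(reads, genome, mapped_tail_len = 30L) {
  if (nrow(reads) == 0L) {
    reads$clip3_seq <- character(0)
    reads$mapped_tail_seq <- character(0)
    reads$has_polyA <- logical(0)
    return(reads)
  }
  s <- genome[[reads$contig[1]]]
  plus <- reads$strand == "+"
  mt <- character(nrow(reads))
  mt[plus] <- substr(rep(s, sum(plus)),
                     pmax(reads$start[plus],
                          reads$end[plus] - mapped_tail_len + 1L),
                     reads$end[plus])
  if (any(!plus)) {
    mt[!plus] <- revcomp(substr(rep(s, sum(!plus)), reads$start[!plus],
                                pmin(reads$end[!plus],
                                     reads$start[!plus] + mapped_tail_len - 1L)))
  }
  reads$clip3_seq <- strrep("A", reads$tail_len)
  reads$mapped_tail_seq <- mt
  reads$has_polyA <- has_polya_evidence(reads$clip3_seq)
  reads
}

#' Simulate cDNA reads over the planted loci
#'
#' Each locus receives poly(A)+ signal reads — dispersed around genuine
#' TESs, at the exact position for TS and IP artifacts — plus
#' background coverage reads without poly(A) evidence whose 3' ends lie
#' 40-150 nt downstream of the locus. TES and TS tails are drawn from
#' one normal distribution (truncated at 5 nt); IP tails are
#' primer-length.
#'
#' @param cfg A [sim_config()].
#' @param truth,genome From [generate_genome()].
#' @return Reads data.frame compatible with [load_reads()] output, plus
#'   `tail_len` and `locus` columns.
#' @export
simulate_cdna <- function(cfg, truth, genome) {
  L <- nchar(genome[[1]])
  batches <- vector("list", 2L * nrow(truth))
  for (i in seq_len(nrow(truth))) {
    n_sig <- max(2L, stats::rpois(1L, cfg$signal_support_mean))
    jitter <- if (truth$kind[i] == "TES") {
      as.integer(round(stats::rnorm(n_sig, 0, cfg$tes_cleavage_sd)))
    } else 0L
    tails <- if (truth$kind[i] == "IP_ARTIFACT") {
      pmax(5L, as.integer(round(stats::rnorm(n_sig, cfg$ip_tail_len, 2))))
    } else {
      pmax(5L, as.integer(round(stats::rnorm(n_sig, cfg$tail_mean,
                                             cfg$tail_sd))))
    }
    len <- sample(cfg$read_len_range[1]:cfg$read_len_range[2], n_sig,
                  replace = TRUE)
    sig <- .mk_reads(sprintf("cdna_sig%03d", i), n_sig, truth$contig[i],
                     truth$strand[i], truth$pos[i] + jitter, len, tails, L)
    sig$locus <- rep(i, nrow(sig))
    n_bg <- stats::rpois(1L, cfg$cdna_depth)
    off <- sample(40:150, n_bg, replace = TRUE)
    bg_end3 <- if (truth$strand[i] == "+") truth$pos[i] + off else
      truth$pos[i] - off
    bg <- .mk_reads(sprintf("cdna_bg%03d", i), n_bg, truth$contig[i],
                    truth$strand[i], bg_end3,
                    sample(cfg$read_len_range[1]:cfg$read_len_range[2],
                           n_bg, replace = TRUE),
                    0L, L)
    bg$locus <- rep(NA_integer_, nrow(bg))
    batches[[2L * i - 1L]] <- sig
    batches[[2L * i]] <- bg
  }
  .finish_reads(do.call(rbind, batches), genome)
}

#' Simulate dRNA reads
#'
#' Native RNA reads carry no sequenced poly(A) tail. Reads of genuine
#' transcripts end within 2 nt of their TES; artifact loci receive only
#' read-through coverage whose 3' ends fall 40-150 nt downstream,
#' outside every confirmation window.
#'
#' @inheritParams simulate_cdna
#' @return Reads data.frame (all `tail_len` 0, `has_polyA` FALSE).
#' @export
simulate_drna <- function(cfg, truth, genome) {
  L <- nchar(genome[[1]])
  batches <- vector("list", 2L * nrow(truth))
  for (i in seq_len(nrow(truth))) {
    # read-through coverage at every locus: 3' ends land 40-150 nt
    # downstream, outside the confirmation window
    n_bg <- stats::rpois(1L, cfg$drna_depth)
    off <- sample(40:150, n_bg, replace = TRUE)
    bg_end3 <- if (truth$strand[i] == "+") truth$pos[i] + off else
      truth$pos[i] - off
    bg <- .mk_reads(sprintf("drna_bg%03d", i), n_bg, truth$contig[i],
                    truth$strand[i], bg_end3,
                    sample(cfg$read_len_range[1]:cfg$read_len_range[2],
                           n_bg, replace = TRUE), 0L, L)
    bg$locus <- rep(NA_integer_, nrow(bg))
    batches[[2L * i]] <- bg
    if (truth$kind[i] != "TES") next
    # terminating reads only at genuine ends
    n <- max(1L, stats::rpois(1L, cfg$drna_depth))
    end3 <- truth$pos[i] + sample(-2:2, n, replace = TRUE)
    b <- .mk_reads(sprintf("drna_%03d", i), n, truth$contig[i],
                   truth$strand[i], end3,
                   sample(cfg$read_len_range[1]:cfg$read_len_range[2], n,
                          replace = TRUE), 0L, L)
    b$locus <- rep(i, nrow(b))
    batches[[2L * i - 1L]] <- b
  }
  batches <- batches[!vapply(batches, is.null, logical(1))]
  .finish_reads(do.call(rbind, batches), genome)
}

#' Write simulated reads as SAM
#'
#' Emits a coordinate-sorted single-end SAM with correct soft-clip
#' CIGARs: the poly(A) tail is appended as a right `S` clip on `+`
#' alignments and a left `S` clip (stored as Ts, reference orientation)
#' on `-` alignments.
#'
#' @param reads Simulated reads data.frame (with `tail_len`).
#' @param genome Named character vector.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  reads <- reads[order(match(reads$contig, names(genome)), reads$start), ,
                 drop = FALSE]
  n <- nrow(reads)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  s <- genome[reads$contig]
  mapped <- substr(s, reads$start, reads$end)
  mlen <- reads$end - reads$start + 1L
  plus <- reads$strand == "+"
  tl <- reads$tail_len
  seq <- ifelse(plus, paste0(mapped, strrep("A", tl)),
                paste0(strrep("T", tl), mapped))
  cig <- ifelse(tl > 0L,
                ifelse(plus, paste0(mlen, "M", tl, "S"),
                       paste0(tl, "S", mlen, "M")),
                paste0(mlen, "M"))
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                   reads$read_id, ifelse(plus, 0L, 16L), reads$contig,
                   reads$start, cig, seq)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Write simulated reads as FASTA (read orientation)
#'
#' @inheritParams write_sam
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, genome, path) {
  s <- genome[reads$contig]
  mapped <- substr(s, reads$start, reads$end)
  plus <- reads$strand == "+"
  mapped[!plus] <- revcomp(mapped[!plus])
  full <- paste0(mapped, strrep("A", reads$tail_len))
  ss <- Biostrings::DNAStringSet(full)
  names(ss) <- reads$read_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write the simulation truth table
#'
#' @param truth Truth data.frame from [generate_genome()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` (1-based) and
#'   `<prefix>.bed` (0-based half-open, name = kind, score =
#'   planted A-count).
#' @return Character vector of the two paths, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  utils::write.table(truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed_df <- data.frame(truth$contig, truth$pos - 1L, truth$pos,
                       truth$kind, truth$planted_a_count, truth$strand)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(tsv = tsv, bed = bed))
}

#' Simulate a complete fixture bundle
#'
#' Seeds the RNG from `cfg$seed`, generates the genome and truth table,
#' simulates cDNA and dRNA reads, and (optionally) writes
#' `genome.fa`, `cdna.sam`, `drna.sam`, `cdna_reads.fa`, `truth.tsv`,
#' `truth.bed` and `sim_config.yaml` into `dir`. A given seed
#' reproduces every file byte-identically.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` keeps the
#'   bundle in memory only.
#' @return A list: `config`, `genome`, `truth`, `cdna`, `drna`, and
#'   `paths` (when written).
#' @export
simulate_polya_run <- function(cfg = sim_config(), dir = NULL) {
  withr::local_seed(cfg$seed)
  gen <- generate_genome(cfg)
  cdna <- simulate_cdna(cfg, gen$truth, gen$genome)
  drna <- simulate_drna(cfg, gen$truth, gen$genome)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(dir, f)
    ss <- Biostrings::DNAStringSet(gen$genome)
    Biostrings::writeXStringSet(ss, p("genome.fa"))
    write_sam(cdna, gen$genome, p("cdna.sam"))
    write_sam(drna, gen$genome, p("drna.sam"))
    write_reads_fasta(cdna, gen$genome, p("cdna_reads.fa"))
    write_truth(gen$truth, p("truth"))
    yaml::write_yaml(unclass(cfg), p("sim_config.yaml"))
    paths <- c(genome = p("genome.fa"), cdna = p("cdna.sam"),
               drna = p("drna.sam"), cdna_fasta = p("cdna_reads.fa"),
               truth_tsv = p("truth.tsv"), truth_bed = p("truth.bed"),
               config = p("sim_config.yaml"))
  }
  list(config = cfg, genome = gen$genome, truth = gen$truth,
       cdna = cdna, drna = drna, paths = paths)
}
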