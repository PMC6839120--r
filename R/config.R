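#' Master pipeline configuration
#'
#' Every numeric threshold of the pipeline in one place, serializable
#' to YAML so a run can be reproduced from its manifest. Classifier
#' constants live in the nested [ts_config()].
#'
#' @param min_reads,min_frac Candidate detection: minimum exact-position
#'   poly(A)+ ends (2) and minimum fraction of overlapping reads
#'   (0.001 = 0.1%).
#' @param window Site window in nt (21).
#' @param high_conf_min High-confidence bound: window support must
#'   exceed this (10).
#' @param polya_min_as,polya_probe_len Poly(A)-evidence rule for 3'
#'   soft clips (>= 10 As in the first 11 clip bases).
#' @param mapped_tail_len 3'-terminal mapped bases kept per read (30).
#' @param drna_min_frac dRNA confirmation fraction (0.005 = 0.5%).
#' @param pas_upstream,pas_expected_distance PAS scan window (40 nt)
#'   and canonical signal distance (25 nt).
#' @param pas_motifs Ordered hexamer list.
#' @param clip_len,sw_target_len,sw_match,sw_mismatch,sw_gap Tail
#'   measurement: clip prefix (150), poly(A) target length (180) and
#'   Smith-Waterman scores (+2/-3/-3).
#' @param flank_composition,flank_heatmap Flanks of the composition
#'   (50) and end-position (10) profiles.
#' @param classifier A [ts_config()].
#' @return A list of class `ps_config`.
#' @export
ps_config <- function(min_reads = 2L, min_frac = 0.001, window = 21L,
                      high_conf_min = 10L, polya_min_as = 10L,
                      polya_probe_len = 11L, mapped_tail_len = 30L,
                      drna_min_frac = 0.005, pas_upstream = 40L,
                      pas_expected_distance = 25L,
                      pas_motifs = default_pas_motifs(),
                      clip_len = 150L, sw_target_len = 180L,
                      sw_match = 2, sw_mismatch = -3, sw_gap = -3,
                      flank_composition = 50L, flank_heatmap = 10L,
                      classifier = ts_config()) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_reads >= 1L, cfg$min_frac >= 0, cfg$window %% 2L == 1L,
            inherits(cfg$classifier, "ts_config"))
  class(cfg) <- "ps_config"
  cfg
}

#' Write a pipeline configuration as YAML
#'
#' @param cfg A [ps_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ps_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$classifier <- unclass(x$classifier)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults.
#'
#' @param path YAML path.
#' @return A [ps_config()].
#' @export
read_ps_config <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$classifier
  x$classifier <- NULL
  base <- ps_config()
  for (k in names(x)) base[[k]] <- x[[k]]
  if (!is.null(cls)) {
    tc <- ts_config()
    for (k in names(cls)) tc[[k]] <- cls[[k]]
    base$classifier <- tc
  }
  base
}
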