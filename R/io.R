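#' Write a site table as TSV and BED
#'
#' The TSV carries every column with 1-based positions; the BED6 is
#' 0-based half-open with the classification in the name field and the
#' window support as score (capped at 1000).
#'
#' @param sites Sites data.frame.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.bed`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_sites <- function(sites, prefix) {
  tsv <- paste0(prefix, ".tsv")
  bed <- paste0(prefix, ".bed")
  utils::write.table(sites, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (nrow(sites) > 0L) {
    score <- if ("window_support" %in% names(sites)) {
      pmin(sites$window_support, 1000L)
    } else sites$support
    cls <- if ("classification" %in% names(sites)) sites$classification
      else "UNCLASSIFIED"
    bed_df <- data.frame(sites$contig, sites$pos - 1L, sites$pos, cls,
                         score, sites$strand)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(bed)
  }
  invisible(c(tsv = tsv, bed = bed))
}

#' Read a site table written by [write_sites()]
#'
#' @param tsv Path to the TSV.
#' @return Sites data.frame.
#' @export
read_sites <- function(tsv) {
  utils::read.delim(tsv, stringsAsFactors = FALSE,
                    colClasses = c(contig = "character"))
}
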