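#' Translation-based quality control
#'
#' Translates each sequence in all three forward reading frames under the
#' invertebrate mitochondrial genetic code (NCBI table 5 by default) and
#' flags putative pseudogenes or miscalled sequences: a record fails when
#' even its best frame (the one with the fewest internal stop codons, ties
#' broken toward the lowest frame index) contains at least one internal
#' stop.
#'
#' A functional COI fragment translates without internal stops, so this is
#' the standard screen against nuclear mitochondrial pseudogenes (numts)
#' and frame-shifting sequencing errors.
#'
#' @param aln A \code{coi_alignment}.
#' @param numcode NCBI genetic code number passed to
#'   [seqinr::translate()]; 5 = invertebrate mitochondrial.
#' @return A data frame of class \code{translation_qc} with columns
#'   \code{id}, \code{frame} (0, 1 or 2), \code{stop_codons}, \code{pass}.
#' @export
translate_qc <- function(aln, numcode = 5L) {
  ids <- rownames(aln)
  res <- t(vapply(seq_len(nrow(aln)), function(i) {
    chars <- tolower(unclass(aln)[i, ])
    stops <- vapply(0:2, function(f) {
      n_codon <- (length(chars) - f) %/% 3L
      if (n_codon < 1L) return(Inf)
      aa <- seqinr::translate(chars, frame = f, numcode = numcode)
      # trailing stop is legitimate; count internal ones only
      if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
      sum(aa == "*")
    }, numeric(1))
    f <- which.min(stops) - 1L  # which.min takes the first (lowest frame) on ties
    c(frame = f, stop_codons = stops[f + 1L])
  }, numeric(2)))
  out <- data.frame(id = ids, frame = as.integer(res[, "frame"]),
                    stop_codons = as.integer(res[, "stop_codons"]),
                    pass = res[, "stop_codons"] == 0,
                    stringsAsFactors = FALSE)
  class(out) <- c("translation_qc", "data.frame")
  out
}
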