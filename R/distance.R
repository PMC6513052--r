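#' Pairwise genetic distances between aligned sequences
#'
#' Wraps [ape::dist.dna()] with pairwise deletion: a site is excluded for a
#' given pair whenever either member carries \code{N} or a gap at that
#' site.
#'
#' @param aln A \code{coi_alignment}.
#' @param model One of \code{"p"} (proportion of differing sites),
#'   \code{"K2P"} (Kimura two-parameter) or \code{"raw"} (absolute count
#'   of differing sites).
#' @return A symmetric numeric matrix with sequence ids as dimnames and a
#'   \code{model} attribute. Undefined K2P distances (logarithm of a
#'   non-positive argument at saturation) are returned as \code{NaN} with a
#'   warning.
#' @export
pairwise_distances <- function(aln, model = c("p", "K2P", "raw")) {
  model <- match.arg(model)
  dnab <- aln_to_dnabin(aln)
  ape_model <- switch(model, p = "raw", K2P = "K80", raw = "N")
  d <- ape::dist.dna(dnab, model = ape_model, pairwise.deletion = TRUE,
                     as.matrix = TRUE)
  if (model == "K2P" && any(!is.finite(d))) {
    warning("K2P distance undefined for ", sum(!is.finite(d[upper.tri(d)])),
            " pair(s) (saturation); reported as NaN")
  }
  attr(d, "model") <- model
  d
}

aln_to_dnabin <- function(aln) {
  m <- tolower(unclass(aln))
  ape::as.DNAbin(m)
}

#' Count of differing sites between two sequences
#'
#' The molecular distance used for AMOVA and haplotype networks: the
#' number of sites at which the two sequences carry different unambiguous
#' bases, sites with \code{N} in either sequence being skipped (pairwise
#' deletion).
#'
#' @param a,b Nucleotide strings of equal length.
#' @return Non-negative integer.
#' @export
molecular_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) stop("sequences differ in length")
  ok <- ca != "N" & cb != "N" & ca != "-" & cb != "-"
  sum(ca[ok] != cb[ok])
}

# pairwise difference-count matrix for a set of sequence strings
diff_count_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(0L, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  chars <- do.call(rbind, strsplit(seqs, ""))
  valid <- chars != "N" & chars != "-"
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    d <- sum(chars[i, ok] != chars[j, ok])
    m[i, j] <- m[j, i] <- d
  }
  m
}
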