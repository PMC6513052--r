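#' Collapse aligned sequences into haplotypes
#'
#' Records with identical sequences are merged into one haplotype and
#' counted per sampling site. By default sequences are compared by exact
#' string match, so two sequences differing only at an ambiguous position
#' (\code{N}) remain distinct haplotypes; with
#' \code{n_as_wildcard = TRUE} a sequence is merged into the first earlier
#' haplotype it matches at all unambiguous positions.
#'
#' Haplotypes are named \code{H1..Hk} in order of decreasing total
#' frequency, ties broken by first appearance in the input.
#'
#' @param aln A \code{coi_alignment}.
#' @param n_as_wildcard Treat \code{N} as matching any base when comparing
#'   sequences.
#' @return An object of class \code{haplotype_table}: a list with
#'   \describe{
#'     \item{haplotype}{character vector of distinct sequences, named
#'       \code{H1..Hk}}
#'     \item{counts}{integer matrix haplotype x site (single column
#'       \code{all} when no site labels are present)}
#'     \item{assignment}{named character vector mapping record id to
#'       haplotype name}
#'   }
#' @export
collapse_haplotypes <- function(aln, n_as_wildcard = FALSE) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  ids <- rownames(aln)
  if (n_as_wildcard) {
    key <- integer(length(seqs))
    reps <- character(0)
    for (i in seq_along(seqs)) {
      hit <- 0L
      if (length(reps)) {
        for (j in seq_along(reps)) {
          if (seq_match_wildcard(seqs[i], reps[j])) { hit <- j; break }
        }
      }
      if (hit == 0L) { reps <- c(reps, seqs[i]); hit <- length(reps) }
      key[i] <- hit
    }
  } else {
    key <- match(seqs, unique(seqs))
    reps <- unique(seqs)
  }
  tot <- tabulate(key, nbins = length(reps))
  ord <- order(-tot, seq_along(tot))  # frequency desc, then first appearance
  rank <- match(seq_along(tot), ord)
  hap_names <- paste0("H", rank)

  sites <- site_of(aln)
  site_f <- if (all(is.na(sites))) rep("all", length(key)) else as.character(sites)
  site_levels <- unique(site_f)
  counts <- table(factor(hap_names[key], levels = paste0("H", seq_along(reps))),
                  factor(site_f, levels = site_levels))
  counts <- matrix(as.integer(counts), nrow = length(reps),
                   dimnames = list(paste0("H", seq_along(reps)), site_levels))

  haps <- stats::setNames(reps[ord], paste0("H", seq_along(reps)))
  structure(list(haplotype = haps,
                 counts = counts,
                 assignment = stats::setNames(hap_names[key], ids)),
            class = "haplotype_table")
}

seq_match_wildcard <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  all(ca == cb | ca == "N" | cb == "N")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype table: %d haplotypes, %d sequences, %d site(s)\n",
              length(x$haplotype), sum(x$counts), ncol(x$counts)))
  tot <- rowSums(x$counts)
  show <- utils::head(order(-tot), 10L)
  for (i in show)
    cat(sprintf("  %-4s n=%-4d %s\n", rownames(x$counts)[i], tot[i],
                substr(x$haplotype[rownames(x$counts)[i]], 1, 40)))
  if (length(tot) > 10L) cat("  ...\n")
  invisible(x)
}

#' Number of haplotypes
#' @param ht A \code{haplotype_table}.
#' @param by_site Return per-site haplotype counts instead of the total.
#' @export
n_haplotypes <- function(ht, by_site = FALSE) {
  if (!by_site) return(length(ht$haplotype))
  colSums(ht$counts > 0L)
}

#' Expand a haplotype table back to one sequence per record
#'
#' Inverse of [collapse_haplotypes()]: rebuilds the multiset of input
#' sequences from the haplotype sequences and the per-record assignment.
#' @param ht A \code{haplotype_table}.
#' @return Named character vector of sequences, one per original record.
#' @export
expand_haplotypes <- function(ht) {
  stats::setNames(unname(ht$haplotype[ht$assignment]), names(ht$assignment))
}

#' Write a haplotype table to TSV
#'
#' Columns: haplotype, sequence, then one count column per site.
#' @param ht A \code{haplotype_table}.
#' @param path Output path.
#' @export
write_haplotype_table <- function(ht, path) {
  df <- data.frame(haplotype = rownames(ht$counts),
                   sequence = unname(ht$haplotype[rownames(ht$counts)]),
                   ht$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
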