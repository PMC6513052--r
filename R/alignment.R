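#' Construct an alignment from sequence records
#'
#' A \code{coi_alignment} is a character matrix (one row per sequence, one
#' column per site) carrying per-record site and species labels as
#' attributes. All sequences must have equal length; use [trim_to_common()]
#' to get there from raw records.
#'
#' @param records A \code{coi_records} data frame (see [read_coi_fasta()]),
#'   or a named character vector of equal-length sequence strings.
#' @param site_code,species_label Optional per-record labels, recycled
#'   against the records when \code{records} is a character vector.
#' @return A \code{coi_alignment}.
#' @export
as_alignment <- function(records, site_code = NULL, species_label = NULL) {
  if (is.character(records)) {
    ids <- names(records)
    if (is.null(ids)) ids <- paste0("s", seq_along(records))
    records <- data.frame(id = ids, seq = unname(records),
                          site_code = if (is.null(site_code)) NA_character_ else site_code,
                          species_label = if (is.null(species_label)) NA_character_ else species_label,
                          stringsAsFactors = FALSE)
  }
  lens <- nchar(records$seq)
  if (length(unique(lens)) != 1L)
    stop("sequences differ in length; call trim_to_common() first")
  m <- do.call(rbind, strsplit(records$seq, ""))
  rownames(m) <- records$id
  structure(m,
            site = stats::setNames(records$site_code, records$id),
            species = stats::setNames(records$species_label, records$id),
            class = c("coi_alignment", class(m)))
}

#' @export
print.coi_alignment <- function(x, ...) {
  cat(sprintf("COI alignment: %d sequences x %d sites\n", nrow(x), ncol(x)))
  st <- site_of(x)
  if (!all(is.na(st))) {
    tab <- table(st, useNA = "no")
    cat("sites:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

site_of <- function(aln) attr(aln, "site")
species_of <- function(aln) attr(aln, "species")

#' @rdname as_alignment
#' @param aln A \code{coi_alignment}.
#' @export
as_records <- function(aln) {
  structure(data.frame(id = rownames(aln),
                       seq = apply(unclass(aln), 1L, paste, collapse = ""),
                       site_code = unname(site_of(aln)),
                       species_label = unname(species_of(aln)),
                       stringsAsFactors = FALSE),
            class = c("coi_records", "data.frame"))
}

# subset an alignment, preserving the label attributes
aln_subset <- function(aln, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(aln))
  if (is.null(cols)) cols <- seq_len(ncol(aln))
  m <- unclass(aln)[rows, cols, drop = FALSE]
  structure(m,
            site = site_of(aln)[rownames(m)],
            species = species_of(aln)[rownames(m)],
            class = c("coi_alignment", class(m)))
}

#' Trim co-anchored sequences to the shortest common length
#'
#' COI amplicons from a common primer pair share their 5' anchor, so a
#' gap-free alignment is obtained by truncating every sequence to the
#' shortest sequence present. Optionally, each record is first re-anchored
#' against a reference by the ungapped offset minimizing mismatches
#' (\code{anchor_to}), a cheap stand-in for a full multiple alignment that
#' is exact for indel-free markers.
#'
#' Columns containing a gap character in any record are removed after
#' trimming (complete deletion), so downstream statistics see gap-free data.
#'
#' @param records \code{coi_records} or named character vector of sequences.
#' @param anchor_to Optional single reference sequence string; each record
#'   is shifted by the ungapped offset (search window
#'   \code{max_offset}) that minimizes mismatches against it.
#' @param max_offset Maximum leading offset searched during anchoring.
#' @param min_length Warn if the common length falls below this.
#' @return A \code{coi_alignment} of width equal to the minimum input length.
#' @export
trim_to_common <- function(records, anchor_to = NULL, max_offset = 60L,
                           min_length = 100L) {
  if (is.character(records)) records <- as_alignment_records(records)
  if (inherits(records, "coi_alignment")) records <- as_records(records)
  if (nrow(records) < 2L) stop("need at least two sequences")
  if (any(!nzchar(records$seq))) stop("empty sequence present")
  if (!is.null(anchor_to)) {
    records$seq <- vapply(records$seq, anchor_offset_trim, character(1),
                          ref = anchor_to, max_offset = max_offset)
  }
  L <- min(nchar(records$seq))
  if (L < min_length)
    warning("common trimmed length is only ", L, " sites")
  records$seq <- substr(records$seq, 1L, L)
  aln <- as_alignment(records)
  drop_gap_columns(aln)
}

as_alignment_records <- function(x) {
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("s", seq_along(x))
  data.frame(id = ids, seq = unname(x), site_code = NA_character_,
             species_label = NA_character_, stringsAsFactors = FALSE)
}

# best ungapped leading offset of seq against ref (drops the overhang)
anchor_offset_trim <- function(seq, ref, max_offset = 60L) {
  s <- strsplit(seq, "")[[1]]
  r <- strsplit(ref, "")[[1]]
  best <- 0L; best_mm <- Inf
  for (off in 0:min(max_offset, length(s) - 1L)) {
    n <- min(length(s) - off, length(r))
    if (n < 50L && off > 0L) break
    mm <- sum(s[(off + 1L):(off + n)] != r[1:n]) / n
    if (mm < best_mm) { best_mm <- mm; best <- off }
  }
  paste(s[(best + 1L):length(s)], collapse = "")
}

#' Remove alignment columns containing gaps
#'
#' Any column with a \code{-} in at least one record is dropped (complete
#' deletion), mirroring the usable-loci convention of standard population
#' genetics software on a gap-free marker.
#'
#' @param aln A \code{coi_alignment}.
#' @return The alignment restricted to gap-free columns.
#' @export
drop_gap_columns <- function(aln) {
  keep <- colSums(unclass(aln) == "-") == 0L
  aln_subset(aln, cols = which(keep))
}
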