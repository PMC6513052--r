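#' Read COI sequences from a FASTA file
#'
#' Reads a FASTA file into a set of sequence records. Headers may carry
#' population metadata using the pipe-delimited convention
#' \code{id|site|species} (both metadata tokens optional); a metadata table
#' supplied via \code{metadata} (or [read_metadata()]) overrides header tokens.
#'
#' Sequences are uppercased and RNA \code{U} is mapped to \code{T}. Only the
#' characters \code{A C G T N -} and IUPAC ambiguity codes are accepted;
#' ambiguity codes other than \code{N} are recoded to \code{N}.
#'
#' @param path Path to a FASTA file.
#' @param metadata Optional data frame with columns \code{id},
#'   \code{site_code} and optionally \code{species_label}, \code{country},
#'   \code{group}; see [read_metadata()].
#' @return A data frame of class \code{coi_records} with columns \code{id},
#'   \code{seq} (nucleotide string), \code{site_code}, \code{species_label}.
#' @seealso [trim_to_common()], [read_metadata()]
#' @export
read_coi_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                       whole.header = TRUE),
    error = function(e) stop("empty or malformed FASTA file: ", path,
                             call. = FALSE))
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  headers <- vapply(raw, function(x) attr(x, "name"), character(1))
  seqs <- toupper(vapply(raw, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)

  tok <- strsplit(headers, "|", fixed = TRUE)
  ids <- trimws(vapply(tok, `[`, character(1), 1L))
  sites <- trimws(vapply(tok, function(x) if (length(x) >= 2) x[2] else NA_character_,
                         character(1)))
  species <- trimws(vapply(tok, function(x) if (length(x) >= 3) x[3] else NA_character_,
                           character(1)))

  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGTNRYSWKMBDHV-]", seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  # ambiguity codes other than N carry no information for the exact-match
  # statistics downstream; recode them to N
  seqs <- gsub("[RYSWKMBDHV]", "N", seqs)

  rec <- data.frame(id = ids, seq = unname(seqs),
                    site_code = ifelse(nzchar(sites), sites, NA_character_),
                    species_label = ifelse(nzchar(species), species, NA_character_),
                    stringsAsFactors = FALSE)
  if (!is.null(metadata)) rec <- apply_metadata(rec, metadata)
  class(rec) <- c("coi_records", "data.frame")
  rec
}

#' Read a sample metadata table
#'
#' Tab-delimited with a header; required columns \code{id} and
#' \code{site_code}, optional \code{country}, \code{species_label},
#' \code{group}.
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "site_code")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$id)) stop("duplicate ids in metadata")
  md
}

apply_metadata <- function(rec, md) {
  i <- match(rec$id, md$id)
  hit <- !is.na(i)
  rec$site_code[hit] <- md$site_code[i[hit]]
  if ("species_label" %in% names(md)) {
    rec$species_label[hit] <- md$species_label[i[hit]]
  }
  rec
}

#' Write sequence records to FASTA
#'
#' Headers use the \code{id|site|species} convention when the corresponding
#' fields are present.
#'
#' @param records A \code{coi_records} data frame or a \code{coi_alignment}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_coi_fasta <- function(records, path) {
  if (inherits(records, "coi_alignment")) records <- as_records(records)
  hdr <- records$id
  has_site <- !is.na(records$site_code)
  has_sp <- !is.na(records$species_label)
  hdr <- ifelse(has_site | has_sp,
                paste(records$id, ifelse(has_site, records$site_code, ""),
                      sep = "|"), hdr)
  hdr <- ifelse(has_sp, paste(hdr, records$species_label, sep = "|"), hdr)
  seqinr::write.fasta(as.list(records$seq), names = hdr, file.out = path,
                      nbchar = 70)
  invisible(path)
}
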