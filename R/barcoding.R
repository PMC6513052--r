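#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration (via [ape::nj()]) with negative branch lengths
#' clamped to zero, as is conventional for barcoding trees.
#'
#' @param dm Symmetric distance matrix (as from [pairwise_distances()]) or
#'   a \code{dist} object; at least 3 taxa, no missing entries.
#' @return An unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(m))) stop("distance matrix contains missing entries")
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the point-estimate NJ tree from the full alignment, then
#' resamples alignment columns with replacement \code{replicates} times;
#' the support of each internal edge is the percentage of replicate trees
#' containing the same bipartition, stored in \code{node.label}.
#'
#' @param aln A \code{coi_alignment}.
#' @param replicates Number of bootstrap replicates (the conventional
#'   choice is 1000).
#' @param seed Integer seed for the resampling.
#' @param model Distance model, see [pairwise_distances()].
#' @return A \code{phylo} tree with bootstrap percentages as
#'   \code{node.label}; attribute \code{degenerate} is \code{TRUE} when the
#'   alignment carries no variation (the topology is then arbitrary).
#' @export
bootstrap_nj <- function(aln, replicates = 1000L, seed = NULL,
                         model = c("p", "K2P", "raw")) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  point <- neighbor_joining(pairwise_distances(aln, model))
  L <- ncol(aln)
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    boots[[b]] <- neighbor_joining(pairwise_distances(aln_subset(aln, cols = cols),
                                                      model))
  }
  cnt <- ape::prop.clades(point, boots, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  point$node.label <- round(100 * cnt / replicates, 1)
  attr(point, "degenerate") <- all(pairwise_distances(aln, "raw") == 0)
  point
}

#' Assign species labels by nearest reference
#'
#' A local stand-in for web-based barcode identification: each query is
#' assigned the species of its nearest reference sequence. The call is
#' flagged ambiguous when the margin between the best and second-best
#' species' nearest distances falls below \code{threshold}.
#'
#' Queries and references must be co-anchored; they are truncated to their
#' common length before distances are computed.
#'
#' @param queries A \code{coi_alignment} (species labels ignored).
#' @param references A \code{coi_alignment} whose \code{species} attribute
#'   is populated (e.g. via \code{id|site|species} FASTA headers).
#' @param model Distance model, see [pairwise_distances()].
#' @param threshold Ambiguity margin on the distance scale of
#'   \code{model} (default 0.02 for proportion distances).
#' @return A data frame of class \code{species_assignment} with columns
#'   \code{id}, \code{species}, \code{distance}, \code{margin},
#'   \code{ambiguous}, \code{note}.
#' @export
assign_species <- function(queries, references, model = c("p", "K2P", "raw"),
                           threshold = 0.02) {
  model <- match.arg(model)
  ref_sp <- species_of(references)
  if (all(is.na(ref_sp))) stop("reference alignment carries no species labels")
  L <- min(ncol(queries), ncol(references))
  q <- aln_subset(queries, cols = seq_len(L))
  r <- aln_subset(references, cols = seq_len(L))
  comb <- as_alignment(c(stats::setNames(apply(unclass(q), 1, paste, collapse = ""),
                                         paste0("q.", rownames(q))),
                         stats::setNames(apply(unclass(r), 1, paste, collapse = ""),
                                         paste0("r.", rownames(r)))))
  d <- pairwise_distances(comb, model)
  nq <- nrow(q)
  block <- d[seq_len(nq), nq + seq_len(nrow(r)), drop = FALSE]

  out <- lapply(seq_len(nq), function(i) {
    di <- block[i, ]
    if (all(!is.finite(di))) {
      return(data.frame(id = rownames(q)[i], species = NA_character_,
                        distance = NA_real_, margin = NA_real_,
                        ambiguous = NA, note = "no overlap with references",
                        stringsAsFactors = FALSE))
    }
    per_sp <- tapply(di, ref_sp, min, na.rm = TRUE)
    per_sp <- sort(per_sp)
    margin <- if (length(per_sp) > 1L) unname(per_sp[2] - per_sp[1]) else Inf
    data.frame(id = rownames(q)[i], species = names(per_sp)[1],
               distance = unname(per_sp[1]), margin = margin,
               ambiguous = margin < threshold, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("species_assignment", "data.frame")
  out
}
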