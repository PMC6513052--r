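#' Minimum-spanning haplotype network
#'
#' Builds the minimum spanning network over the pairwise difference-count
#' matrix of the haplotypes: Kruskal's algorithm yields one canonical MST
#' (ties broken by lexicographic haplotype-pair order, so the result is
#' deterministic), and every edge that belongs to at least one MST is
#' retained. An edge (u, v) of weight w belongs to some MST exactly when
#' u and v lie in different components of the subgraph of strictly
#' lighter edges, and to every MST exactly when removing it disconnects u
#' from v among edges of weight <= w; edges in some-but-not-every MST are
#' flagged as alternative (tie) connections, matching the "alternative
#' links" notion of standard software.
#'
#' @param ht A \code{haplotype_table} (from [collapse_haplotypes()]), or a
#'   named character vector of haplotype sequences.
#' @param counts Optional haplotype x site count matrix (taken from
#'   \code{ht} when it is a \code{haplotype_table}).
#' @return Object of class \code{haplotype_network}: list with
#'   \code{edges} (data frame: from, to, steps, alternative),
#'   \code{nodes} (data frame: haplotype, total, one column per site),
#'   \code{dist} (difference-count matrix), \code{mst_weight} (total
#'   weight of one MST).
#' @export
build_msn <- function(ht, counts = NULL) {
  if (inherits(ht, "haplotype_table")) {
    haps <- ht$haplotype
    counts <- ht$counts
  } else {
    haps <- ht
    if (is.null(counts))
      counts <- matrix(1L, length(haps), 1L, dimnames = list(names(haps), "all"))
  }
  k <- length(haps)
  d <- diff_count_matrix(haps)
  nodes <- data.frame(haplotype = names(haps), total = rowSums(counts),
                      counts, check.names = FALSE, stringsAsFactors = FALSE)

  if (k == 1L) {
    return(structure(list(edges = data.frame(from = character(0),
                                             to = character(0),
                                             steps = integer(0),
                                             alternative = logical(0)),
                          nodes = nodes, dist = d, mst_weight = 0),
                     class = "haplotype_network"))
  }

  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ed <- data.frame(i = pairs[, 1], j = pairs[, 2], w = d[pairs])
  ed <- ed[order(ed$w, ed$i, ed$j), ]

  # canonical MST by Kruskal with deterministic tie order
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  in_mst <- logical(nrow(ed))
  for (e in seq_len(nrow(ed))) {
    ri <- find(ed$i[e]); rj <- find(ed$j[e])
    if (ri != rj) { parent[ri] <- rj; in_mst[e] <- TRUE }
  }
  mst_weight <- sum(ed$w[in_mst])

  in_some <- vapply(seq_len(nrow(ed)), function(e)
    !connected_without(ed, k, ed$i[e], ed$j[e], max_w = ed$w[e] - 1L,
                       drop = NA_integer_), logical(1))
  in_all <- vapply(seq_len(nrow(ed)), function(e)
    !connected_without(ed, k, ed$i[e], ed$j[e], max_w = ed$w[e], drop = e),
    logical(1))

  keep <- which(in_some)
  edges <- data.frame(from = names(haps)[ed$i[keep]],
                      to = names(haps)[ed$j[keep]],
                      steps = as.integer(ed$w[keep]),
                      alternative = !in_all[keep],
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, dist = d,
                 mst_weight = mst_weight),
            class = "haplotype_network")
}

# are nodes a and b connected using edges of weight <= max_w, excluding edge `drop`?
connected_without <- function(ed, k, a, b, max_w, drop) {
  use <- ed$w <= max_w
  if (!is.na(drop)) use[drop] <- FALSE
  if (!any(use)) return(FALSE)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in which(use)) {
    ri <- find(ed$i[e]); rj <- find(ed$j[e])
    if (ri != rj) parent[ri] <- rj
  }
  find(a) == find(b)
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype network: %d haplotypes, %d edges (%d alternative), MST weight %d\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$alternative),
              x$mst_weight))
  if ("haplogroup" %in% names(x$nodes))
    cat("haplogroups:", paste(sort(unique(x$nodes$haplogroup)), collapse = ", "), "\n")
  invisible(x)
}

#' Delineate haplogroups by a mutational-step cutoff
#'
#' Removes network edges longer than \code{cutoff} mutational steps; the
#' remaining connected components are the haplogroups, labeled
#' \code{G1, G2, ...} in order of decreasing total haplotype count. The
#' cutoff makes the visual clustering of published networks reproducible
#' and is deliberately exposed as a parameter: deeply separated clusters
#' (e.g. 9+ steps) come out identically for any cutoff below the
#' separation.
#'
#' @param net A \code{haplotype_network}.
#' @param cutoff Maximum number of steps kept within a haplogroup
#'   (default 5).
#' @return The network with a \code{haplogroup} column added to
#'   \code{nodes} and a \code{cutoff} element recorded.
#' @export
assign_haplogroups <- function(net, cutoff = 5L) {
  stopifnot(cutoff >= 1L)
  g <- igraph::graph_from_data_frame(
    net$edges[net$edges$steps <= cutoff, c("from", "to")],
    directed = FALSE, vertices = net$nodes$haplotype)
  comp <- igraph::components(g)$membership
  tot <- tapply(net$nodes$total, comp[net$nodes$haplotype], sum)
  ord <- order(-tot, as.integer(names(tot)))
  relabel <- stats::setNames(paste0("G", seq_along(ord)), names(tot)[ord])
  net$nodes$haplogroup <- unname(relabel[as.character(comp[net$nodes$haplotype])])
  net$cutoff <- cutoff
  net
}

#' Minimum mutational separation between haplogroups
#'
#' For each pair of haplogroups, the smallest pairwise difference count
#' between a haplotype of one group and a haplotype of the other.
#'
#' @param net A \code{haplotype_network} with haplogroups assigned.
#' @return Data frame with columns \code{group1}, \code{group2},
#'   \code{min_steps}; zero rows when only one group exists.
#' @export
min_steps_between <- function(net) {
  if (!"haplogroup" %in% names(net$nodes))
    stop("assign haplogroups first (assign_haplogroups)")
  grp <- stats::setNames(net$nodes$haplogroup, net$nodes$haplotype)
  gs <- sort(unique(grp))
  if (length(gs) < 2L)
    return(data.frame(group1 = character(0), group2 = character(0),
                      min_steps = integer(0)))
  out <- list()
  for (i in 1:(length(gs) - 1L)) for (j in (i + 1L):length(gs)) {
    a <- names(grp)[grp == gs[i]]; b <- names(grp)[grp == gs[j]]
    out[[length(out) + 1L]] <- data.frame(
      group1 = gs[i], group2 = gs[j],
      min_steps = min(net$dist[a, b, drop = FALSE]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Haplogroup composition per sampling site
#'
#' Fraction of each site's individuals carried by each haplogroup (the
#' numbers behind per-site pie charts on a phylogeographic map).
#'
#' @param net A \code{haplotype_network} with haplogroups assigned.
#' @return Matrix site x haplogroup of fractions; rows sum to 1.
#' @export
haplogroup_composition <- function(net) {
  if (!"haplogroup" %in% names(net$nodes))
    stop("assign haplogroups first (assign_haplogroups)")
  site_cols <- setdiff(names(net$nodes), c("haplotype", "total", "haplogroup"))
  cnt <- as.matrix(net$nodes[, site_cols, drop = FALSE])
  grp <- net$nodes$haplogroup
  agg <- rowsum(cnt, grp)            # haplogroup x site
  comp <- t(agg)                      # site x haplogroup
  comp / rowSums(comp)
}

#' Export a haplotype network
#'
#' \code{write_network_tsv} writes an edge list (hap1, hap2, steps,
#' alternative flag) and a node table (haplotype, counts, haplogroup if
#' assigned); \code{network_to_dot} renders the network as Graphviz DOT
#' text for plotting.
#'
#' @param net A \code{haplotype_network}.
#' @param edge_path,node_path Output paths for the two tables.
#' @return Paths (invisibly), or the DOT text as a character scalar.
#' @export
write_network_tsv <- function(net, edge_path, node_path) {
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edge_path, node_path))
}

#' @rdname write_network_tsv
#' @export
network_to_dot <- function(net) {
  grp <- if ("haplogroup" %in% names(net$nodes)) net$nodes$haplogroup else "G1"
  pal <- c("lightblue", "salmon", "palegreen", "gold", "plum", "grey80")
  col <- pal[(as.integer(factor(grp)) - 1L) %% length(pal) + 1L]
  lines <- c("graph haplotype_network {", "  node [shape=circle];")
  lines <- c(lines, sprintf(
    '  "%s" [width=%.2f, style=filled, fillcolor=%s, label="%s\\n%d"];',
    net$nodes$haplotype, 0.4 + 0.12 * sqrt(net$nodes$total), col,
    net$nodes$haplotype, net$nodes$total))
  if (nrow(net$edges))
    lines <- c(lines, sprintf('  "%s" -- "%s" [label="%d"%s];',
                              net$edges$from, net$edges$to, net$edges$steps,
                              ifelse(net$edges$alternative, ", style=dashed", "")))
  paste(c(lines, "}"), collapse = "\n")
}
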