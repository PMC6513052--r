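#' Per-site diversity, neutrality and mismatch summary table
#'
#' Computes, for every sampling site in the alignment, the sample size,
#' haplotype count, haplotype diversity h (with SD), nucleotide diversity
#' in percent (with SD), Tajima's D and Fu's Fs with coalescent
#' p-values, and the mismatch-distribution goodness-of-fit statistics
#' (SSD and raggedness with parametric-bootstrap p-values). Statistics
#' that are undefined for a site (monomorphic sample, or n below the
#' statistic's requirement) come back \code{NA}.
#'
#' @param aln A \code{coi_alignment} with site labels.
#' @param nsim Coalescent replicates for the D/Fs p-values (0 to skip).
#' @param B Parametric-bootstrap replicates for SSD/raggedness p-values
#'   (0 to skip the mismatch fit entirely).
#' @param seed Base seed; per-site streams are derived from it.
#' @param min_n Sites with fewer sequences are reported but carry only n
#'   and the haplotype count.
#' @return Data frame of class \code{diversity_table}, one row per site.
#' @export
diversity_table <- function(aln, nsim = 1000L, B = 200L, seed = NULL,
                            min_n = 2L) {
  pop <- as.character(site_of(aln))
  sites <- unique(pop)
  rows <- lapply(seq_along(sites), function(si) {
    s <- sites[si]
    sub <- aln_subset(aln, rows = which(pop == s))
    n <- nrow(sub)
    ht <- collapse_haplotypes(sub)
    row <- data.frame(site = s, n = n, n_hap = n_haplotypes(ht),
                      h = NA_real_, h_sd = NA_real_,
                      pi_pct = NA_real_, pi_sd = NA_real_,
                      tajima_D = NA_real_, p_D = NA_real_,
                      fu_Fs = NA_real_, p_Fs = NA_real_,
                      ssd = NA_real_, p_ssd = NA_real_,
                      raggedness = NA_real_, p_raggedness = NA_real_,
                      stringsAsFactors = FALSE)
    if (n < min_n) return(row)
    seed_i <- if (is.null(seed)) NULL else (seed + si) %% .Machine$integer.max
    hd <- haplotype_diversity(rowSums(ht$counts))
    nd <- nucleotide_diversity(sub, percent = TRUE)
    row$h <- hd$h; row$h_sd <- hd$sd
    row$pi_pct <- nd$pi; row$pi_sd <- nd$sd
    if (segregating_sites(sub) >= 1L) {
      td <- tajimas_d(sub, nsim = nsim, seed = seed_i)
      row$tajima_D <- td$D; row$p_D <- td$p_value
      fs <- fus_fs(sub, nsim = nsim, seed = seed_i)
      row$fu_Fs <- fs$Fs; row$p_Fs <- fs$p_value
      if (B > 0L) {
        mm <- mismatch_distribution(sub)
        if (length(mm) >= 2L) {
          fit <- fit_sudden_expansion(mm, n = n, L = ncol(sub), B = B,
                                      seed = seed_i)
          row$ssd <- fit$ssd; row$p_ssd <- fit$p_ssd
          row$raggedness <- fit$raggedness
          row$p_raggedness <- fit$p_raggedness
        }
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Read / parse grouping schemes
#'
#' A grouping scheme names ordered groups of site codes (e.g. candidate
#' population clusters separated by oceanographic barriers). The plain
#' text format has one scheme per line:
#' \preformatted{scheme7<TAB>Ka | Sh,St,No,Ra,Mo | An,Sa,Be,Bb,Ma | Sm,Ta,Fd<TAB>barrier note}
#' Groups are separated by \code{|}, sites within a group by commas; the
#' trailing barrier annotation is optional. Lines starting with \code{#}
#' are ignored.
#'
#' @param path Path to the scheme file.
#' @return Named list of grouping schemes; each scheme is a named list of
#'   character vectors of site codes with a \code{barrier} attribute.
#' @export
read_grouping_schemes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed scheme line: ", ln)
    groups <- strsplit(f[2], "|", fixed = TRUE)[[1]]
    scheme <- lapply(groups, function(g) trimws(strsplit(g, ",")[[1]]))
    names(scheme) <- paste0("group", seq_along(scheme))
    attr(scheme, "barrier") <- if (length(f) >= 3L) f[3] else ""
    out[[trimws(f[1])]] <- scheme
  }
  out
}

#' Evaluate a list of grouping schemes by hierarchical AMOVA
#'
#' Runs [amova()] under every scheme and reports PhiCT with its
#' permutation p-value, flagging the scheme with the largest significant
#' PhiCT (the conventional way a "best" barrier hypothesis is selected).
#'
#' @param aln A \code{coi_alignment} with site labels.
#' @param schemes Named list of grouping schemes (see
#'   [read_grouping_schemes()]).
#' @param nperm Permutations per scheme.
#' @param seed Base seed.
#' @param alpha Significance level for the "best scheme" flag.
#' @return Data frame (scheme, n_groups, PhiCT, p, best flag) with the
#'   full \code{amova} objects attached as attribute \code{fits}.
#' @export
scan_grouping_schemes <- function(aln, schemes, nperm = 10000L, seed = NULL,
                                  alpha = 0.05) {
  fits <- lapply(seq_along(schemes), function(i) {
    amova(aln, grouping = schemes[[i]], nperm = nperm,
          seed = if (is.null(seed)) NULL else seed + i)
  })
  names(fits) <- names(schemes)
  df <- data.frame(
    scheme = names(schemes),
    n_groups = vapply(schemes, length, integer(1)),
    phi_ct = vapply(fits, function(f) unname(f$phi["PhiCT"]), numeric(1)),
    p = vapply(fits, function(f) unname(f$p_value["PhiCT"]), numeric(1)),
    stringsAsFactors = FALSE)
  sig <- !is.na(df$p) & df$p <= alpha
  df$best <- FALSE
  if (any(sig)) df$best[sig][which.max(df$phi_ct[sig])] <- TRUE
  attr(df, "fits") <- fits
  df
}

#' Split a dataset by species
#'
#' Uses metadata species labels where present; otherwise queries are
#' barcoded against a labeled reference panel via [assign_species()].
#' Records that cannot be assigned (no labels and no reference overlap,
#' or an ambiguous call) are excluded with a warning and listed in the
#' \code{unassigned} element.
#'
#' @param records A \code{coi_records} data frame.
#' @param references Optional labeled reference \code{coi_alignment}.
#' @param model,threshold Passed to [assign_species()].
#' @return List with one \code{coi_records} per species plus an
#'   \code{unassigned} data frame.
#' @export
run_species_split <- function(records, references = NULL,
                              model = "p", threshold = 0.02) {
  labeled <- !is.na(records$species_label)
  species <- records$species_label
  unassigned <- records[0, ]
  if (any(!labeled)) {
    if (is.null(references))
      stop("unlabeled records present and no reference panel supplied")
    todo <- records[!labeled, , drop = FALSE]
    L <- min(nchar(todo$seq), ncol(references))
    q <- as_alignment(stats::setNames(substr(todo$seq, 1, L), todo$id))
    asg <- assign_species(q, aln_subset(references, cols = seq_len(L)),
                          model = model, threshold = threshold)
    ok <- !is.na(asg$species) & !asg$ambiguous
    species[!labeled][ok] <- asg$species[ok]
    if (any(!ok)) {
      warning(sum(!ok), " record(s) could not be assigned a species; excluded")
      unassigned <- records[!labeled, , drop = FALSE][!ok, , drop = FALSE]
    }
  }
  keep <- !is.na(species)
  split_rec <- split(records[keep, , drop = FALSE], species[keep])
  split_rec <- lapply(split_rec, function(r) {
    class(r) <- c("coi_records", "data.frame"); r
  })
  c(split_rec, list(unassigned = unassigned))
}

#' Run the full COI population-genetics workflow
#'
#' From records to a report bundle: trim to the common length, translation
#' QC, haplotype collapsing, per-site diversity/neutrality/mismatch
#' statistics, overall AMOVA, hierarchical AMOVA over each configured
#' grouping scheme, pairwise PhiST with Holm correction, Mantel test
#' against a geographic distance matrix when given, and the
#' minimum-spanning haplotype network with haplogroups. All tables are
#' written as TSV under \code{out_dir} (when not \code{NULL}) together
#' with a run log recording parameters and seeds; every number in the
#' bundle comes from the corresponding module function.
#'
#' Sites with fewer than \code{min_n} sequences are excluded from the
#' structure analyses (AMOVA, pairwise PhiST, Mantel) but retained in the
#' haplotype table and network.
#'
#' @param records A \code{coi_records} data frame (see
#'   [read_coi_fasta()]).
#' @param out_dir Output directory for TSV reports, or \code{NULL} to
#'   skip writing.
#' @param grouping_schemes Named list of grouping schemes.
#' @param geo_dist Square geographic distance matrix (site codes as
#'   dimnames) or path to such a CSV.
#' @param nperm Permutations for AMOVA/PhiST/Mantel.
#' @param nsim Coalescent replicates for neutrality p-values.
#' @param B Parametric-bootstrap replicates for the mismatch fit.
#' @param haplogroup_cutoff Mutational-step cutoff for haplogroups.
#' @param min_n Minimum per-site sample size for structure analyses.
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class \code{coipop_run} with elements \code{alignment},
#'   \code{qc}, \code{haplotypes}, \code{diversity}, \code{amova_overall},
#'   \code{amova_schemes}, \code{pairwise}, \code{mantel}, \code{network},
#'   \code{log}.
#' @export
run_full <- function(records, out_dir = NULL, grouping_schemes = NULL,
                     geo_dist = NULL, nperm = 10000L, nsim = 1000L,
                     B = 200L, haplogroup_cutoff = 5L, min_n = 3L,
                     seed = 1L) {
  log <- list(seed = seed, nperm = nperm, nsim = nsim, B = B,
              min_n = min_n, haplogroup_cutoff = haplogroup_cutoff,
              n_records = nrow(records), started = format(Sys.time()))

  aln <- trim_to_common(records)
  qc <- translate_qc(aln)
  ht <- collapse_haplotypes(aln)
  log$L <- ncol(aln); log$n_haplotypes <- n_haplotypes(ht)

  div <- diversity_table(aln, nsim = nsim, B = B, seed = seed)

  pop <- as.character(site_of(aln))
  sizes <- table(pop)
  big <- names(sizes)[sizes >= min_n]
  small <- setdiff(names(sizes), big)
  if (length(small))
    log$excluded_from_structure <- paste(small, collapse = ", ")
  struct_aln <- aln_subset(aln, rows = which(pop %in% big))

  amova_overall <- pw <- mant <- NULL
  schemes_tab <- NULL
  if (length(big) >= 2L) {
    amova_overall <- amova(struct_aln, nperm = nperm, seed = seed + 101L)
    pw <- pairwise_phist(struct_aln, nperm = nperm, seed = seed + 202L)
    if (!is.null(grouping_schemes)) {
      schemes <- lapply(grouping_schemes, function(sch)
        lapply(sch, intersect, y = big))
      schemes <- lapply(schemes, function(sch) sch[lengths(sch) > 0])
      schemes <- schemes[vapply(schemes, length, integer(1)) >= 2L]
      if (length(schemes))
        schemes_tab <- scan_grouping_schemes(struct_aln, schemes,
                                             nperm = nperm, seed = seed + 303L)
    }
    if (!is.null(geo_dist)) {
      if (is.character(geo_dist)) geo_dist <- read_geo_distances(geo_dist)
      common <- intersect(rownames(pw$phi), rownames(geo_dist))
      if (length(common) >= 3L) {
        mant <- mantel_test(pw$phi[common, common],
                            as.matrix(geo_dist)[common, common],
                            nperm = nperm, seed = seed + 404L)
      } else log$mantel_skipped <- "fewer than 3 sites shared with geo matrix"
    }
  } else {
    log$structure_skipped <- "fewer than 2 sites meet the min_n threshold"
  }

  net <- assign_haplogroups(build_msn(ht), cutoff = haplogroup_cutoff)

  res <- structure(list(alignment = aln, qc = qc, haplotypes = ht,
                        diversity = div, amova_overall = amova_overall,
                        amova_schemes = schemes_tab, pairwise = pw,
                        mantel = mant, network = net, log = log),
                   class = "coipop_run")
  if (!is.null(out_dir)) write_run_bundle(res, out_dir)
  res
}

#' @export
print.coipop_run <- function(x, ...) {
  cat("COI population-genetics run\n")
  cat(sprintf("  %d sequences, %d sites, %d haplotypes\n",
              nrow(x$alignment), x$log$L, x$log$n_haplotypes))
  if (!is.null(x$amova_overall))
    cat(sprintf("  overall PhiST = %.4f (p = %.4g)\n",
                max(x$amova_overall$phi["PhiST"], 0),
                x$amova_overall$p_value["PhiST"]))
  gr <- unique(x$network$nodes$haplogroup)
  cat(sprintf("  haplogroups at cutoff %d: %d\n", x$network$cutoff, length(gr)))
  invisible(x)
}

#' Read a geographic distance matrix
#'
#' Square CSV with a header row and the site codes in the first column.
#' @param path CSV path.
#' @return Symmetric numeric matrix.
#' @export
read_geo_distances <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) stop("geographic distance matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("geographic distance matrix must be symmetric")
  m
}

write_run_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  tsv(res$qc, "translation_qc.tsv")
  write_haplotype_table(res$haplotypes, file.path(out_dir, "haplotypes.tsv"))
  tsv(res$diversity, "diversity.tsv")
  if (!is.null(res$amova_overall)) {
    tsv(res$amova_overall$components, "amova_overall.tsv")
    phi_df <- data.frame(statistic = names(res$amova_overall$phi),
                         value = unname(res$amova_overall$phi),
                         p = unname(res$amova_overall$p_value))
    tsv(phi_df, "amova_overall_phi.tsv")
  }
  if (!is.null(res$amova_schemes))
    tsv(res$amova_schemes, "amova_schemes.tsv")
  if (!is.null(res$pairwise)) {
    utils::write.table(res$pairwise$phi, file.path(out_dir, "pairwise_phist.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(res$pairwise$p_holm,
                       file.path(out_dir, "pairwise_phist_p_holm.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(res$mantel)) {
    tsv(data.frame(Z = res$mantel$Z, r = res$mantel$r,
                   p = res$mantel$p_value, nperm = res$mantel$nperm),
        "mantel.tsv")
  }
  write_network_tsv(res$network, file.path(out_dir, "network_edges.tsv"),
                    file.path(out_dir, "network_nodes.tsv"))
  writeLines(network_to_dot(res$network), file.path(out_dir, "network.dot"))
  log_df <- data.frame(key = names(res$log),
                       value = vapply(res$log, function(v)
                         paste(as.character(v), collapse = ","), character(1)))
  tsv(log_df, "run_log.tsv")
  invisible(out_dir)
}
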