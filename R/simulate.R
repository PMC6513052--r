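#' Simulation configurations
#'
#' \code{island_config} describes a finite island model: \code{demes}
#' demes sampled with sizes \code{n} (recycled), per-deme mutation scale
#' \code{theta} (the expected pairwise difference count within a deme at
#' equilibrium without structure), scaled migration parameter \code{M}
#' (per-lineage migration rate M/theta on the mutational timescale, i.e.
#' the usual "number of migrants" knob: large M mixes demes, M = 0
#' isolates them), and sequence length \code{L}.
#'
#' \code{expansion_config} describes a single population whose scaled
#' size changed instantaneously from \code{theta0} to \code{theta1} at
#' mutational time \code{tau/2} before the present (so a pair of lineages
#' that survives the recent epoch accumulates on average \code{tau}
#' differences across it).
#'
#' Defaults mirror a COI phylogeography study design: a handful of demes
#' with 10-25 sequences each, a 563-site amplicon, and for the expansion
#' model a star-like post-expansion sample.
#'
#' @param demes Number of demes.
#' @param n Sample size(s); recycled across demes for
#'   \code{island_config}, scalar for \code{expansion_config}.
#' @param theta,theta0,theta1 Scaled mutation parameters (>= 0).
#' @param M Scaled migration parameter (>= 0).
#' @param tau Mutational time since expansion (>= 0).
#' @param divergence Star depth (expected mutations per deme root branch)
#'   joining fully isolated demes; only reached when M = 0.
#' @param L Sequence length in sites.
#' @param seed Integer seed; \code{NULL} leaves the RNG stream alone.
#' @return A config list of the corresponding class.
#' @export
island_config <- function(demes = 4L, n = 15L, theta = 2, M = 10, L = 563L,
                          divergence = 10, seed = NULL) {
  stopifnot(demes >= 1L, all(n >= 1L), theta > 0, M >= 0, L >= 1L,
            divergence >= 0)
  n <- rep_len(as.integer(n), demes)
  structure(list(demes = as.integer(demes), n = n, theta = theta, M = M,
                 L = as.integer(L), divergence = divergence, seed = seed),
            class = "island_config")
}

#' @rdname island_config
#' @export
expansion_config <- function(n = 50L, tau = 4, theta0 = 0.5, theta1 = 50,
                             L = 563L, seed = NULL) {
  stopifnot(n >= 2L, tau >= 0, theta0 >= 0, theta1 >= theta0, L >= 1L)
  structure(list(n = as.integer(n), tau = tau, theta0 = theta0,
                 theta1 = theta1, L = as.integer(L), seed = seed),
            class = "expansion_config")
}

#' Simulate an island-model sample
#'
#' Haploid structured coalescent simulated backwards in time on the
#' mutational timescale (each lineage mutates at rate 1, a within-deme
#' pair coalesces at rate 2/theta, each lineage migrates to a uniformly
#' chosen other deme at rate M/theta). Mutations follow the
#' infinite-sites model: each mutation occupies its own previously unused
#' column, so pairwise difference counts equal mutation counts on the
#' separating branches exactly. Same seed, same output.
#'
#' @param cfg An [island_config()].
#' @return A \code{coi_alignment} with deme labels \code{d1, d2, ...} in
#'   its site attribute.
#' @export
simulate_island_model <- function(cfg) {
  stopifnot(inherits(cfg, "island_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ntot <- sum(cfg$n)
  deme0 <- rep(seq_len(cfg$demes), cfg$n)
  muts <- coalesce_with_mutations(deme = deme0, theta = cfg$theta,
                                  mig_rate = if (cfg$demes > 1L) cfg$M / cfg$theta else 0,
                                  epochs = NULL, divergence = cfg$divergence)
  aln <- mutations_to_alignment(ntot, muts, cfg$L,
                                ids = paste0("d", deme0, "_", sequence(cfg$n)),
                                site = paste0("d", deme0))
  aln
}

#' Simulate a sudden-expansion sample
#'
#' Single-population coalescent with an instantaneous size change
#' \code{theta0 -> theta1} at mutational time \code{tau/2} before the
#' present, infinite-sites mutations on \code{L} columns.
#'
#' @param cfg An [expansion_config()].
#' @return A \code{coi_alignment} (single site label \code{pop}).
#' @export
simulate_expansion <- function(cfg) {
  stopifnot(inherits(cfg, "expansion_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  epochs <- if (cfg$tau > 0)
    list(boundary = cfg$tau / 2, theta_recent = cfg$theta1,
         theta_ancient = cfg$theta0)
  else NULL
  theta <- if (is.null(epochs)) cfg$theta0 else cfg$theta1
  muts <- coalesce_with_mutations(deme = rep(1L, cfg$n), theta = theta,
                                  mig_rate = 0, epochs = epochs)
  mutations_to_alignment(cfg$n, muts, cfg$L,
                         ids = paste0("s", seq_len(cfg$n)),
                         site = rep("pop", cfg$n))
}

# Gillespie simulation of the (structured) coalescent on the mutational
# timescale. `deme` assigns each starting lineage to a deme; `epochs`
# optionally defines a single instantaneous size change at `boundary`
# (recent theta applies before it, ancient theta after). Mutations are
# Poisson on each lineage-interval; each is recorded as the set of tips
# below it. Returns a list of integer tip-sets.
coalesce_with_mutations <- function(deme, theta, mig_rate, epochs = NULL,
                                    divergence = 0) {
  n <- length(deme)
  tips <- as.list(seq_len(n))
  cur_deme <- deme
  t_now <- 0
  muts <- list()
  theta_now <- function(t) {
    if (is.null(epochs)) theta
    else if (t < epochs$boundary) epochs$theta_recent
    else epochs$theta_ancient
  }
  repeat {
    k <- length(tips)
    if (k == 1L) break
    th <- theta_now(t_now)
    per_deme <- table(factor(cur_deme, levels = unique(cur_deme)))
    pairs_w <- sum(per_deme * (per_deme - 1))
    coal_rate <- if (th > 0) pairs_w / th else Inf     # C(k_i,2) * 2/theta
    mig_total <- k * mig_rate
    rate <- coal_rate + mig_total
    if (rate == 0) {
      # fully isolated demes, each already down to its root lineage: join the
      # roots in a star at depth `divergence` (deep-split regime, M = 0)
      muts <- c(muts, drop_mutations(tips, divergence))
      break
    }
    wait <- if (is.finite(rate)) stats::rexp(1, rate) else 0
    if (!is.null(epochs) && t_now < epochs$boundary &&
        t_now + wait >= epochs$boundary) {
      # epoch boundary crossed: mutations accrue up to it, then rates change
      dt <- epochs$boundary - t_now
      muts <- c(muts, drop_mutations(tips, dt))
      t_now <- epochs$boundary
      next
    }
    muts <- c(muts, drop_mutations(tips, wait))
    t_now <- t_now + wait
    p_coal <- if (is.finite(rate)) coal_rate / rate else 1
    if (stats::runif(1) < p_coal) {
      # coalescence: choose a deme weighted by k_i(k_i - 1), then a pair
      dn <- names(per_deme)
      w <- as.numeric(per_deme * (per_deme - 1))
      dsel <- sample(dn, 1L, prob = w)
      idx <- which(cur_deme == dsel)
      pair <- sample(idx, 2L)
      tips[[pair[1L]]] <- c(tips[[pair[1L]]], tips[[pair[2L]]])
      tips[[pair[2L]]] <- NULL
      cur_deme <- cur_deme[-pair[2L]]
    } else {
      # migration: uniform lineage moves to a uniformly chosen other deme
      l <- sample.int(k, 1L)
      demes_all <- unique(deme)
      if (length(demes_all) > 1L) {
        cur_deme[l] <- sample(setdiff(demes_all, cur_deme[l]), 1L)
      }
    }
  }
  muts
}

# Poisson mutations over interval dt for each active lineage
drop_mutations <- function(tips, dt) {
  out <- list()
  for (l in seq_along(tips)) {
    m <- stats::rpois(1L, dt)
    if (m > 0L) out <- c(out, rep(tips[l], m))
  }
  out
}

# place mutations on distinct columns (infinite sites) and build sequences
mutations_to_alignment <- function(n, muts, L, ids, site) {
  K <- length(muts)
  if (K > L) stop("more mutations (", K, ") than sites (", L,
                  "); increase L or lower theta/tau")
  cols <- if (K > 0L) sample.int(L, K) else integer(0)
  m <- matrix("A", n, L)
  bases <- c("C", "G", "T")
  for (i in seq_len(K)) {
    m[muts[[i]], cols[i]] <- sample(bases, 1L)
  }
  rownames(m) <- ids
  structure(m, site = stats::setNames(site, ids),
            species = stats::setNames(rep(NA_character_, n), ids),
            class = c("coi_alignment", class(m)))
}

#' Simulate a multi-species reference/query barcoding panel
#'
#' Generates \code{k} species ancestors by mutating a random base
#' sequence at a per-site rate of \code{divergence}, then draws reference
#' and query individuals per species at a per-site rate of
#' \code{within_variation} from their species ancestor. Truth labels are
#' carried in the species attribute of both alignments.
#'
#' @param k Number of species.
#' @param divergence Expected per-site divergence between a species
#'   ancestor and the panel root (must exceed \code{within_variation}).
#' @param within_variation Expected per-site variation within species.
#' @param L Sequence length.
#' @param n_ref,n_query References and queries per species.
#' @param seed Integer seed.
#' @return List with \code{references} and \code{queries} (both
#'   \code{coi_alignment} with species labels) and \code{truth} (named
#'   character vector: query id -> true species).
#' @export
simulate_species_panel <- function(k = 5L, divergence = 0.10,
                                   within_variation = 0.01, L = 563L,
                                   n_ref = 3L, n_query = 5L, seed = NULL) {
  stopifnot(k >= 1L, divergence > within_variation, within_variation >= 0)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, L, replace = TRUE)
  mutate <- function(s, rate) {
    nm <- stats::rbinom(1L, L, rate)
    if (nm == 0L) return(s)
    pos <- sample.int(L, nm)
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1L),
                     character(1))
    s
  }
  sp_names <- paste0("sp", seq_len(k))
  anc <- lapply(sp_names, function(s) mutate(root, divergence))
  names(anc) <- sp_names

  mk <- function(prefix, nper) {
    seqs <- character(0); sp <- character(0)
    for (s in sp_names) for (i in seq_len(nper)) {
      seqs <- c(seqs, paste(mutate(anc[[s]], within_variation), collapse = ""))
      sp <- c(sp, s)
    }
    names(seqs) <- paste0(prefix, "_", sp, "_", sequence(rep(nper, k)))
    as_alignment(seqs, species_label = sp)
  }
  refs <- mk("ref", n_ref)
  qry <- mk("q", n_query)
  list(references = refs, queries = qry,
       truth = stats::setNames(as.character(species_of(qry)), rownames(qry)))
}
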