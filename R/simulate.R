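#' Draw a lognormal metacommunity
#'
#' The regional species pool feeding the neutral and filtered samplers:
#' relative abundances are lognormal draws normalised to sum one. The single
#' shape parameter `meta_sigma` controls evenness (near 0 gives a uniform
#' pool; 2 gives the long-tailed rank-abundance curve typical of 16S
#' surveys).
#'
#' @param S Number of taxa (>= 2).
#' @param meta_sigma Lognormal sdlog (> 0).
#' @param seed Optional integer seed.
#' @return Tibble with columns `taxon_id`, `p` (relative abundance, sums to 1).
#' @export
make_metacommunity <- function(S, meta_sigma = 2, seed = NULL) {
  if (!is.numeric(S) || length(S) != 1 || S < 2) {
    abort("S must be a single integer >= 2", class = "ncmtools_parameter_error")
  }
  if (!is.numeric(meta_sigma) || meta_sigma <= 0) {
    abort("meta_sigma must be > 0", class = "ncmtools_parameter_error")
  }
  p <- with_seed_or_current(seed, rlnorm(S, meanlog = 0, sdlog = meta_sigma))
  tibble::tibble(taxon_id = sprintf("tax%04d", seq_len(S)), p = p / sum(p))
}

meta_probs <- function(meta) {
  p <- if (is.data.frame(meta)) meta$p else as.numeric(meta)
  if (any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
    abort("metacommunity abundances must be positive and sum to 1",
          class = "ncmtools_parameter_error")
  }
  ids <- if (is.data.frame(meta)) meta$taxon_id else sprintf("tax%04d", seq_along(p))
  list(p = p, ids = ids)
}

check_sim_config <- function(N, m, depth) {
  if (N < 1) abort("N must be >= 1", class = "ncmtools_parameter_error")
  if (m <= 0 || m > 1) abort("m must be in (0, 1]", class = "ncmtools_parameter_error")
  if (depth < 1) abort("depth must be >= 1", class = "ncmtools_parameter_error")
}

#' Sample neutral local communities (stationary sampler)
#'
#' Draws each sample's composition from the stationary law of Sloan's
#' neutral model — Dirichlet with concentration `N * m * p` — and then reads
#' as multinomial(depth, composition). This decouples the biological
#' community size `N` from sequencing depth. Marginally, each taxon's
#' relative abundance follows Beta(Nm p, Nm (1 - p)), the occupancy-
#' abundance law the NCM fit assumes.
#'
#' @param meta Metacommunity tibble from [make_metacommunity()] (or a bare
#'   probability vector).
#' @param N Local community size (individuals).
#' @param m Migration probability in (0, 1].
#' @param n_samples Number of local communities to draw.
#' @param depth Reads per sample.
#' @param seed Optional integer seed.
#' @return Count table tibble (taxa x samples).
#' @export
simulate_neutral_samples <- function(meta, N = 1e4, m = 0.2, n_samples = 21,
                                     depth = 1e4, seed = NULL) {
  mp <- meta_probs(meta)
  check_sim_config(N, m, depth)
  S <- length(mp$p)
  alpha <- N * m * mp$p
  counts <- with_seed_or_current(seed, {
    g <- matrix(rgamma(S * n_samples, shape = alpha), nrow = S)
    tot <- colSums(g)
    # guard against total underflow at extreme Nm; fall back to a point mass
    for (j in which(tot == 0)) {
      g[sample.int(S, 1, prob = mp$p), j] <- 1
      tot[j] <- 1
    }
    comp <- sweep(g, 2, tot, "/")
    vapply(seq_len(n_samples), function(j) rmultinom(1, depth, comp[, j])[, 1],
           numeric(S))
  })
  dimnames(counts) <- list(mp$ids, sprintf("S%02d", seq_len(n_samples)))
  count_table(counts)
}

#' Simulate neutral drift explicitly (Hubbell death-birth-immigration)
#'
#' Individual-based oracle for [simulate_neutral_samples()]: one community
#' of `N` individuals is initialised as multinomial(N, p); at each step a
#' uniformly chosen individual dies and is replaced, with probability `m`,
#' by an immigrant drawn from the metacommunity, otherwise by a copy of one
#' of the other `N - 1` residents. A generation is `N` steps. After a 50-
#' generation burn-in, `n_samples` evenly spaced snapshots are turned into
#' reads by multinomial(depth, composition).
#'
#' This is O(generations x N) and intended as a slow reference, not the
#' routine generator.
#'
#' @inheritParams simulate_neutral_samples
#' @param generations Total chain length in generations; snapshots are taken
#'   over the stretch after the first 50. If `generations < 50` the output
#'   carries attribute `burn_in_ok = FALSE` and a warning is raised.
#' @return Count table tibble with attributes `community` (latent taxon-by-
#'   snapshot individual counts) and `burn_in_ok`.
#' @export
simulate_neutral_dynamic <- function(meta, N = 500, m = 0.1, generations = 200,
                                     n_samples = 21, depth = 1e4, seed = NULL) {
  mp <- meta_probs(meta)
  check_sim_config(N, m, depth)
  N <- as.integer(N)
  S <- length(mp$p)
  burn <- 50L
  burn_in_ok <- generations >= burn
  if (!burn_in_ok) {
    warn(sprintf("only %d generations; %d needed for burn-in", generations, burn))
    burn <- 0L
  }
  steps_total <- as.integer(generations) * N
  snap_at <- unique(round(seq(burn * N + 1, steps_total, length.out = n_samples)))
  if (length(snap_at) < n_samples) snap_at <- rep(snap_at, length.out = n_samples)

  res <- with_seed_or_current(seed, {
    comm <- sample.int(S, N, replace = TRUE, prob = mp$p)  # taxon of each individual
    idx_death <- sample.int(N, steps_total, replace = TRUE)
    is_imm <- runif(steps_total) < m
    imm_taxon <- sample.int(S, steps_total, replace = TRUE, prob = mp$p)
    par_raw <- sample.int(N - 1L, steps_total, replace = TRUE)
    snaps <- matrix(0L, nrow = S, ncol = length(snap_at))
    k <- 1L
    next_snap <- snap_at[1L]
    for (t in seq_len(steps_total)) {
      i <- idx_death[t]
      if (is_imm[t]) {
        comm[i] <- imm_taxon[t]
      } else {
        j <- par_raw[t]
        if (j >= i) j <- j + 1L  # parent drawn uniformly from the other N - 1
        comm[i] <- comm[j]
      }
      if (t == next_snap) {
        snaps[, k] <- tabulate(comm, nbins = S)
        k <- k + 1L
        next_snap <- if (k <= length(snap_at)) snap_at[k] else NA_integer_
      }
    }
    reads <- vapply(seq_len(ncol(snaps)),
                    function(j) rmultinom(1, depth, snaps[, j] / N)[, 1],
                    numeric(S))
    list(snaps = snaps, reads = reads)
  })
  reads <- res$reads[, seq_len(n_samples), drop = FALSE]
  dimnames(reads) <- list(mp$ids, sprintf("S%02d", seq_len(n_samples)))
  out <- count_table(reads)
  attr(out, "community") <- res$snaps
  attr(out, "burn_in_ok") <- burn_in_ok
  out
}

#' Sample environmentally filtered (non-neutral) communities
#'
#' Gaussian niche model: each taxon receives an environmental optimum drawn
#' uniformly over the gradient's range, and its sampling weight in sample j
#' is `p_i * exp(-filter_strength * (o_i - g_j)^2)`, renormalised; reads are
#' multinomial(depth, weights). `filter_strength = 0` reduces exactly to
#' multinomial(depth, p) — the neutral sampler's no-drift limit.
#'
#' @inheritParams simulate_neutral_samples
#' @param gradient Numeric vector, one environmental value per sample.
#' @param filter_strength Non-negative niche-filtering intensity (inverse
#'   squared niche width on the gradient's scale).
#' @return List with `table` (count table tibble), `env` (tibble sample_id,
#'   gradient) and `optima` (tibble taxon_id, optimum).
#' @export
simulate_filtered_samples <- function(meta, gradient, filter_strength = 5,
                                      depth = 1e4, seed = NULL) {
  mp <- meta_probs(meta)
  if (filter_strength < 0) {
    abort("filter_strength must be >= 0", class = "ncmtools_parameter_error")
  }
  if (depth < 1) abort("depth must be >= 1", class = "ncmtools_parameter_error")
  n_samples <- length(gradient)
  S <- length(mp$p)
  counts <- with_seed_or_current(seed, {
    optima <- runif(S, min(gradient), max(gradient))
    w <- outer(optima, gradient, function(o, g) exp(-filter_strength * (o - g)^2))
    w <- w * mp$p
    w <- sweep(w, 2, colSums(w), "/")
    cnt <- vapply(seq_len(n_samples), function(j) rmultinom(1, depth, w[, j])[, 1],
                  numeric(S))
    list(cnt = cnt, optima = optima)
  })
  mat <- counts$cnt
  dimnames(mat) <- list(mp$ids, sprintf("S%02d", seq_len(n_samples)))
  list(table = count_table(mat),
       env = tibble::tibble(sample_id = colnames(mat), gradient = gradient),
       optima = tibble::tibble(taxon_id = mp$ids, optimum = counts$optima))
}

#' Simulate correlated physicochemical sample metadata
#'
#' Emulates a sediment survey design: samples cycle through seven site
#' codes with replicates, and eleven physicochemical variables (pH, WC, TC,
#' TSC, MBC, TN, AN, TP, AP, TK, AK) are monotone transforms of an
#' equicorrelated Gaussian latent field, so any pair of variables targets a
#' Pearson correlation near `env_corr` while honouring the range invariants
#' (pH in (0,14), WC in \[0,100\], concentrations positive).
#'
#' @param n_samples Number of samples.
#' @param env_corr Target latent correlation between variables, in \[0, 1).
#' @param seed Optional integer seed.
#' @param sites Site codes cycled over samples.
#' @param layer Layer label stored for every sample.
#' @return Metadata tibble: sample_id, site, layer, replicate + 11 variables.
#' @export
simulate_metadata <- function(n_samples = 21, env_corr = 0.5, seed = NULL,
                              sites = c("BYH", "ZYW", "LYH", "RYSD", "SW", "YQ", "JFD"),
                              layer = "0-20 cm") {
  if (env_corr < 0 || env_corr >= 1) {
    abort("env_corr must be in [0, 1)", class = "ncmtools_parameter_error")
  }
  site <- rep(sites, length.out = n_samples)
  replicate <- stats::ave(seq_len(n_samples), site, FUN = seq_along)
  z <- with_seed_or_current(seed, {
    common <- rnorm(n_samples)
    vapply(1:11, function(i) sqrt(env_corr) * common +
             sqrt(1 - env_corr) * rnorm(n_samples), numeric(n_samples))
  })
  z <- matrix(z, nrow = n_samples)
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    site = site, layer = layer, replicate = replicate,
    pH  = pmin(13.9, pmax(0.1, 7 + 0.8 * z[, 1])),
    WC  = 100 * stats::plogis(0.8 * z[, 2]),       # %
    TC  = exp(2.5 + 0.5 * z[, 3]),                 # g/kg
    TSC = exp(4.5 + 0.5 * z[, 4]),                 # mg/kg
    MBC = exp(5.3 + 0.5 * z[, 5]),                 # mg/kg
    TN  = exp(0.3 + 0.5 * z[, 6]),                 # g/kg
    AN  = exp(4.8 + 0.5 * z[, 7]),                 # mg/kg
    TP  = exp(-0.3 + 0.4 * z[, 8]),                # g/kg
    AP  = exp(3.2 + 0.5 * z[, 9]),                 # mg/kg
    TK  = exp(2.7 + 0.15 * z[, 10]),               # g/kg, typically > 10
    AK  = exp(5.1 + 0.4 * z[, 11])                 # mg/kg
  )
}

#' Assign synthetic phylum-level lineages to simulated taxa
#'
#' Utility for exercising rank aggregation and core-taxon analyses on
#' simulated tables: taxa are partitioned among `n_phyla` synthetic phyla
#' with lognormal phylum sizes (a few dominant phyla, many small ones).
#'
#' @param taxon_ids Character vector of taxon ids.
#' @param n_phyla Number of synthetic phyla.
#' @param seed Optional integer seed.
#' @return Taxonomy tibble as from [parse_lineage()].
#' @export
simulate_taxonomy <- function(taxon_ids, n_phyla = 8, seed = NULL) {
  phyla <- sprintf("Phylum%02d", seq_len(n_phyla))
  assign <- with_seed_or_current(seed, {
    w <- rlnorm(n_phyla, sdlog = 1)
    sample(phyla, length(taxon_ids), replace = TRUE, prob = w / sum(w))
  })
  parse_lineage(taxon_ids, paste0("d__Synthetica;p__", assign))
}
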