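#' Observed richness of one sample
#'
#' @param counts Non-negative numeric vector of counts.
#' @return Number of taxa with count > 0.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative",
                             class = "ncmtools_validation_error")
  sum(counts > 0)
}

#' Shannon diversity of one sample (natural log)
#'
#' `H = -sum(q log q)` over the sample's relative abundances q; bounded by
#' `log(richness)`.
#'
#' @param counts Non-negative numeric vector with positive sum.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative",
                             class = "ncmtools_validation_error")
  tot <- sum(counts)
  if (tot == 0) abort("Shannon index is undefined for an empty sample",
                      class = "ncmtools_domain_error")
  q <- counts[counts > 0] / tot
  -sum(q * log(q))
}

#' Alpha diversity per sample
#'
#' @param table Count table tibble.
#' @return Tibble with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  mat <- count_matrix(table)
  tibble::tibble(
    sample_id = colnames(mat),
    richness = apply(mat, 2, richness),
    shannon = apply(mat, 2, shannon)
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(j, k) = sum|x_ij - x_ik| / sum(x_ij + x_ik)`, computed with
#' vegan; symmetric with zero diagonal, bounded in \[0, 1\].
#'
#' @param table Count table tibble with at least two samples.
#' @return Square symmetric matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  mat <- count_matrix(table)
  if (ncol(mat) < 2) abort("need at least two samples",
                           class = "ncmtools_insufficient_data_error")
  totals <- colSums(mat)
  if (any(totals == 0)) {
    abort(paste0("Bray-Curtis is undefined for empty sample(s): ",
                 paste(colnames(mat)[totals == 0], collapse = ", ")),
          class = "ncmtools_division_error")
  }
  as.matrix(vegan::vegdist(t(mat), method = "bray"))
}

as_dist_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) abort("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-12) abort("distance matrix must be symmetric")
  D
}

#' Classical principal coordinates (metric scaling)
#'
#' Double-centres -D^2/2 and eigendecomposes it (via [stats::cmdscale()]);
#' axes with negative eigenvalues are truncated. Used as the NMDS starting
#' configuration and exported for direct use.
#'
#' @param D Square symmetric dissimilarity matrix.
#' @param k Number of axes, `k < nrow(D)`.
#' @return Tibble with `sample_id` and `PCo1..PCok` columns.
#' @export
pcoa <- function(D, k = 2) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (k >= n) abort("k must be smaller than the number of samples",
                    class = "ncmtools_parameter_error")
  coords <- cmdscale(stats::as.dist(D), k = k)
  if (ncol(coords) < k) {  # degenerate inputs can yield fewer positive axes
    coords <- cbind(coords, matrix(0, n, k - ncol(coords)))
  }
  colnames(coords) <- paste0("PCo", seq_len(k))
  ids <- rownames(D)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  dplyr::bind_cols(tibble::tibble(sample_id = ids),
                   tibble::as_tibble(coords, .name_repair = "minimal"))
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Global NMDS via vegan's monoMDS engine (monotone regression on
#' dissimilarity ranks, ties averaged), restarted from random
#' configurations plus a metric-scaling start; the lowest-stress solution
#' is returned. Stress-1 below 0.2 is conventionally a good fit; the
#' ordination is invariant to monotone transforms of the input
#' dissimilarities.
#'
#' @param D Square symmetric dissimilarity matrix.
#' @param k Number of ordination axes (default 2).
#' @param seed Optional integer seed (restarts are deterministic given it).
#' @param max_iter Maximum iterations per start.
#' @param n_restarts Number of random restarts.
#' @return Object of class `nmds_result`: `coordinates` (tibble, centred),
#'   `stress`, `converged`, `k`, `seed`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
nmds <- function(D, k = 2, seed = NULL, max_iter = 300, n_restarts = 4) {
  D <- as_dist_matrix(D)
  n <- nrow(D)
  if (n < 4) abort("NMDS needs at least 4 samples",
                   class = "ncmtools_insufficient_data_error")
  fit <- with_seed_or_current(seed, {
    suppressWarnings(vegan::metaMDS(
      stats::as.dist(D), k = k, try = n_restarts, trymax = max(n_restarts, 20),
      maxit = max_iter, trace = 0, autotransform = FALSE, wascores = FALSE,
      expand = FALSE
    ))
  })
  coords <- vegan::scores(fit, display = "sites")
  coords <- scale(coords, center = TRUE, scale = FALSE)
  colnames(coords) <- paste0("NMDS", seq_len(k))
  ids <- rownames(D)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample_id = ids),
        tibble::as_tibble(coords, .name_repair = "minimal")
      ),
      stress = fit$stress, converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged),
      k = k, seed = seed
    ),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress-1 = %.4f%s\n", x$k, x$stress,
              if (x$converged) "" else " (no convergent solution found)"))
  invisible(x)
}

#' @describeIn nmds Centred sample coordinates as a tibble.
#' @param x,object An `nmds_result`.
#' @param ... Unused.
#' @method tidy nmds_result
#' @export
tidy.nmds_result <- function(x, ...) x$coordinates

#' @describeIn nmds One-row summary (stress, convergence).
#' @method glance nmds_result
#' @export
glance.nmds_result <- function(x, ...) {
  tibble::tibble(stress = x$stress, converged = x$converged, k = x$k)
}

#' @describeIn nmds Ordination scatter plot annotated with the stress value.
#' @method autoplot nmds_result
#' @export
autoplot.nmds_result <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("NMDS, stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}
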