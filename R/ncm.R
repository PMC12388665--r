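#' Per-taxon mean relative abundance and occurrence frequency
#'
#' The two coordinates of the Sloan occupancy-abundance plot: `p` is the
#' mean across samples of a taxon's within-sample relative abundance, and
#' `f_obs` the fraction of samples in which it is detected at or above
#' `detection_count` reads. Taxa detected nowhere are excluded.
#'
#' @param table Count table tibble with at least two samples.
#' @param detection_count Minimum reads counting as presence (default 1).
#' @return Tibble with columns `taxon_id`, `p`, `f_obs`.
#' @export
occurrence_stats <- function(table, detection_count = 1) {
  mat <- count_matrix(table)
  if (ncol(mat) < 2) {
    abort("occurrence frequencies need at least two samples",
          class = "ncmtools_insufficient_data_error")
  }
  totals <- colSums(mat)
  if (any(totals == 0)) {
    abort(paste0("zero-sum sample(s): ",
                 paste(colnames(mat)[totals == 0], collapse = ", ")),
          class = "ncmtools_division_error")
  }
  rel <- sweep(mat, 2, totals, "/")
  out <- tibble::tibble(
    taxon_id = rownames(mat),
    p = unname(rowMeans(rel)),
    f_obs = unname(rowMeans(mat >= detection_count))
  )
  dplyr::filter(out, .data$f_obs > 0)
}

#' Predicted occurrence frequency under the Sloan neutral model
#'
#' Under neutral assembly a taxon's local relative abundance follows
#' Beta(Nm p, Nm (1 - p)); the probability of exceeding the detection
#' fraction x = d/N is therefore
#' `f = 1 - I_x(Nm p, Nm (1 - p))`,
#' with I the regularised incomplete beta function (beta CDF).
#'
#' @param p Metacommunity relative abundance(s), in (0, 1).
#' @param Nm Migration-dispersal magnitude N * m (> 0).
#' @param detection_fraction Detection limit as a fraction of community
#'   size, in (0, 1).
#' @return Predicted occurrence frequencies in (0, 1), vectorised over `p`.
#' @export
predicted_frequency <- function(p, Nm, detection_fraction) {
  if (any(p <= 0 | p >= 1)) {
    abort("p must lie strictly inside (0, 1)", class = "ncmtools_domain_error")
  }
  if (Nm <= 0) abort("Nm must be > 0", class = "ncmtools_domain_error")
  if (detection_fraction <= 0 || detection_fraction >= 1) {
    abort("detection_fraction must lie in (0, 1)", class = "ncmtools_domain_error")
  }
  1 - pbeta(detection_fraction, Nm * p, Nm * (1 - p))
}

#' Wilson score confidence interval for a proportion
#'
#' Closed-form score interval (the Hmisc `binconf` convention), used for
#' the 95% band around the neutral prediction.
#'
#' @param fraction Observed proportion(s) in \[0, 1\].
#' @param n_trials Number of trials (>= 1).
#' @param confidence Coverage level (default 0.95).
#' @return Tibble with columns `low`, `high`, one row per input fraction.
#' @export
wilson_interval <- function(fraction, n_trials, confidence = 0.95) {
  if (any(fraction < 0 | fraction > 1)) {
    abort("fraction must lie in [0, 1]", class = "ncmtools_domain_error")
  }
  if (n_trials < 1) abort("n_trials must be >= 1", class = "ncmtools_domain_error")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n <- n_trials
  centre <- (fraction + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(fraction * (1 - fraction) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  tibble::tibble(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Partition taxa against the neutral prediction band
#'
#' Adds a Wilson score band around each taxon's predicted frequency and
#' classifies it `above` (observed frequency exceeds the band — more
#' widespread than neutrality predicts), `below`, or `neutral`.
#'
#' @param records Tibble with columns `f_obs` and `f_pred` (e.g. the
#'   `records` of an [fit_ncm()] object).
#' @param n_samples Number of samples behind the frequencies.
#' @param confidence Band coverage (default 0.95).
#' @return `records` with added `ci_low`, `ci_high`, `partition` columns.
#' @export
classify_taxa <- function(records, n_samples, confidence = 0.95) {
  ci <- wilson_interval(records$f_pred, n_samples, confidence)
  dplyr::mutate(
    records,
    ci_low = ci$low,
    ci_high = ci$high,
    partition = factor(
      dplyr::case_when(
        .data$f_obs > .data$ci_high ~ "above",
        .data$f_obs < .data$ci_low ~ "below",
        TRUE ~ "neutral"
      ),
      levels = c("above", "neutral", "below")
    )
  )
}

#' Fit the Sloan neutral community model to occupancy-abundance pairs
#'
#' Lower-level entry point taking the plot coordinates directly; use
#' [fit_ncm()] for count tables. The single free parameter m is estimated
#' by least squares on the occurrence frequencies,
#' minimising `sum((f_obs - f_pred(p, N m, d/N))^2)` over m in (1e-6, 1]
#' with Brent's method on log m. R-squared is the coefficient of
#' determination 1 - SSR/SST.
#'
#' @param p Mean relative abundances in (0, 1).
#' @param f_obs Observed occurrence frequencies in (0, 1].
#' @param N Community size (mean reads per sample).
#' @param detection_count Reads treated as the detection limit d; the model
#'   uses the fraction d/N.
#' @param n_samples Number of samples behind `f_obs` (for the Wilson band);
#'   if `NA`, taxa are not partitioned.
#' @param taxon_id Optional taxon labels.
#' @return An object of class `ncm_fit`; see [fit_ncm()].
#' @export
fit_ncm_curve <- function(p, f_obs, N, detection_count = 1, n_samples = NA,
                          taxon_id = NULL) {
  stopifnot(length(p) == length(f_obs))
  if (length(p) < 10) {
    warn(sprintf("only %d taxa available for the NCM fit; estimates will be unstable",
                 length(p)))
  }
  x <- detection_count / N
  sst <- sum((f_obs - mean(f_obs))^2)
  if (sst == 0) {
    abort("all occurrence frequencies are identical; R-squared is undefined",
          class = "ncmtools_undefined_r2_error")
  }
  obj <- function(logm) {
    sum((f_obs - predicted_frequency(p, N * exp(logm), x))^2)
  }
  opt <- optimize(obj, interval = c(log(1e-6), 0), tol = 1e-10)
  m <- exp(opt$minimum)
  ssr <- opt$objective
  f_pred <- predicted_frequency(p, N * m, x)
  records <- tibble::tibble(
    taxon_id = if (is.null(taxon_id)) sprintf("tax%04d", seq_along(p)) else taxon_id,
    p = p, f_obs = f_obs, f_pred = f_pred
  )
  partition_counts <- NULL
  if (!is.na(n_samples)) {
    records <- classify_taxa(records, n_samples)
    partition_counts <- table(records$partition)
    partition_counts <- setNames(as.integer(partition_counts), names(partition_counts))
  }
  structure(
    list(m = m, N = N, Nm = N * m, r_squared = 1 - ssr / sst,
         detection_limit = detection_count, n_taxa = length(p),
         n_samples = n_samples, records = records,
         partition_counts = partition_counts, ssr = ssr, sst = sst),
    class = "ncm_fit"
  )
}

#' Fit the Sloan neutral community model to a count table
#'
#' Computes per-taxon mean relative abundance and occurrence frequency,
#' sets the community size N to the mean column sum (rounded), and fits the
#' migration parameter m of the neutral occupancy-abundance curve
#' `f = 1 - I_{d/N}(Nm p, Nm (1 - p))` by bounded least squares. Taxa are
#' partitioned against a 95% Wilson band around the prediction.
#'
#' High R-squared indicates assembly dominated by stochastic processes
#' (drift plus migration); low R-squared indicates deterministic forces
#' such as environmental filtering.
#'
#' @param table Count table tibble.
#' @param detection_count Minimum reads counting as presence (default 1).
#' @return Object of class `ncm_fit` with elements `m`, `N`, `Nm`,
#'   `r_squared`, `detection_limit`, `n_taxa`, `records` (per-taxon tibble
#'   with prediction, band and partition) and `partition_counts`. Supports
#'   [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
#' @examples
#' meta <- make_metacommunity(100, seed = 1)
#' tab <- simulate_neutral_samples(meta, N = 1000, m = 0.5, n_samples = 12,
#'                                 depth = 2000, seed = 2)
#' fit <- fit_ncm(tab)
#' glance(fit)
fit_ncm <- function(table, detection_count = 1) {
  mat <- count_matrix(table)
  stats <- occurrence_stats(table, detection_count)
  N <- round(mean(colSums(mat)))
  fit_ncm_curve(stats$p, stats$f_obs, N = N, detection_count = detection_count,
                n_samples = ncol(mat), taxon_id = stats$taxon_id)
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  taxa: %d   samples: %s   N (mean reads): %g\n",
              x$n_taxa, ifelse(is.na(x$n_samples), "?", x$n_samples), x$N))
  cat(sprintf("  m = %.6g   Nm = %.6g   R-squared = %.4f\n", x$m, x$Nm, x$r_squared))
  if (!is.null(x$partition_counts)) {
    cat(sprintf("  partition: above %d / neutral %d / below %d\n",
                x$partition_counts[["above"]], x$partition_counts[["neutral"]],
                x$partition_counts[["below"]]))
  }
  invisible(x)
}

#' @describeIn fit_ncm One-row model summary (m, N, Nm, R-squared, counts).
#' @param x,object An `ncm_fit` object.
#' @param ... Unused.
#' @method glance ncm_fit
#' @export
glance.ncm_fit <- function(x, ...) {
  pc <- x$partition_counts
  tibble::tibble(
    m = x$m, N = x$N, Nm = x$Nm, r_squared = x$r_squared,
    detection_limit = x$detection_limit, n_taxa = x$n_taxa,
    n_above = if (is.null(pc)) NA_integer_ else pc[["above"]],
    n_neutral = if (is.null(pc)) NA_integer_ else pc[["neutral"]],
    n_below = if (is.null(pc)) NA_integer_ else pc[["below"]]
  )
}

#' @describeIn fit_ncm Per-taxon records (p, f_obs, f_pred, band, partition).
#' @method tidy ncm_fit
#' @export
tidy.ncm_fit <- function(x, ...) x$records

#' @describeIn fit_ncm Occupancy-abundance scatter with the fitted neutral
#'   curve and its 95% band, on a log10 abundance axis.
#' @method autoplot ncm_fit
#' @export
autoplot.ncm_fit <- function(object, ...) {
  grid_p <- exp(seq(log(max(min(object$records$p), 1e-9)),
                    log(max(object$records$p)), length.out = 200))
  band <- wilson_interval(
    predicted_frequency(grid_p, object$Nm, object$detection_limit / object$N),
    ifelse(is.na(object$n_samples), object$n_taxa, object$n_samples)
  )
  curve_df <- tibble::tibble(
    p = grid_p,
    f_pred = predicted_frequency(grid_p, object$Nm, object$detection_limit / object$N),
    low = band$low, high = band$high
  )
  ggplot2::ggplot(object$records, ggplot2::aes(x = .data$p, y = .data$f_obs)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$partition), alpha = 0.7) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(y = .data$f_pred)) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(y = .data$low), linetype = 2) +
    ggplot2::geom_line(data = curve_df, ggplot2::aes(y = .data$high), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(above = "#2166ac", neutral = "#7f7f7f", below = "#b2182b"),
      drop = FALSE
    ) +
    ggplot2::labs(
      x = "mean relative abundance", y = "occurrence frequency",
      colour = NULL,
      title = sprintf("Neutral model: Nm = %.1f, R² = %.3f",
                      object$Nm, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
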