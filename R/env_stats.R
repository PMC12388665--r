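upper_vec <- function(D) D[upper.tri(D)]

align_dist <- function(Dx, Dy, name = "Dy") {
  Dx <- as_dist_matrix(Dx)
  Dy <- as_dist_matrix(Dy)
  if (nrow(Dx) != nrow(Dy)) {
    abort("distance matrices have different sizes", class = "ncmtools_alignment_error")
  }
  if (!is.null(rownames(Dx)) && !is.null(rownames(Dy))) {
    if (!setequal(rownames(Dx), rownames(Dy))) {
      abort(paste0("sample ids of ", name, " do not match"),
            class = "ncmtools_alignment_error")
    }
    Dy <- Dy[rownames(Dx), rownames(Dx)]
  }
  list(Dx = Dx, Dy = Dy)
}

# All n! permutations of 1..n as rows (n <= 8).
all_permutations <- function(n) {
  if (n > 8) abort("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' Mantel test between two distance matrices
#'
#' Correlates the n(n-1)/2 upper-triangle entries and assesses significance
#' by jointly permuting the rows and columns of `Dy`. The p-value is
#' one-tailed (greater), `(1 + #permuted r >= observed r) / (1 + n_perm)`,
#' the vegan/linkET convention. With `n_perm = "all"` every permutation is
#' enumerated (small n only) and the p-value is exact.
#'
#' @param Dx,Dy Square symmetric distance matrices over the same samples
#'   (matching dimnames are aligned; mismatched ids error).
#' @param n_perm Number of random permutations (default 999), or `"all"`.
#' @param seed Optional integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble: `statistic` (Mantel r), `p_value`, `n_perm`,
#'   `method`.
#' @export
mantel <- function(Dx, Dy, n_perm = 999, seed = NULL,
                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  al <- align_dist(Dx, Dy)
  n <- nrow(al$Dx)
  if (n < 4) abort("Mantel test needs at least 4 samples",
                   class = "ncmtools_insufficient_data_error")
  x <- upper_vec(al$Dx)
  if (method == "spearman") x <- rank(x)
  xs <- (x - mean(x)) / sd(x)
  ut <- upper.tri(al$Dx)
  r_of <- function(Dyp) {
    y <- Dyp[ut]
    if (method == "spearman") y <- rank(y)
    sum(xs * (y - mean(y))) / (sd(y) * (length(y) - 1))
  }
  r_obs <- r_of(al$Dy)
  if (identical(n_perm, "all")) {
    perms <- all_permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(i) {
      pm <- perms[i, ]
      r_of(al$Dy[pm, pm])
    }, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)  # includes the identity permutation
    n_used <- nrow(perms) - 1L
  } else {
    r_perm <- with_seed_or_current(seed, {
      vapply(seq_len(n_perm), function(i) {
        pm <- sample.int(n)
        r_of(al$Dy[pm, pm])
      }, numeric(1))
    })
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  tibble::tibble(statistic = r_obs, p_value = p, n_perm = n_used, method = method)
}

#' Partial Mantel test controlling a third matrix
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`
#' of the upper-triangle vectors; the permutation null permutes `Dy`
#' (recomputing `r_xy` and `r_yz`; `r_xz` is fixed), one-tailed greater.
#'
#' @inheritParams mantel
#' @param Dz Control distance matrix.
#' @return One-row tibble as [mantel()].
#' @export
partial_mantel <- function(Dx, Dy, Dz, n_perm = 999, seed = NULL,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  al <- align_dist(Dx, Dy)
  alz <- align_dist(al$Dx, Dz, "Dz")
  n <- nrow(al$Dx)
  prep <- function(D) {
    v <- upper_vec(D)
    if (method == "spearman") v <- rank(v)
    v
  }
  x <- prep(al$Dx); z <- prep(alz$Dy)
  r_xz <- cor(x, z)
  if (abs(r_xz) >= 1 - 1e-12) {
    abort("control matrix is perfectly correlated with Dx",
          class = "ncmtools_degenerate_control_error")
  }
  partial_r <- function(Dyp) {
    y <- prep(Dyp)
    r_xy <- cor(x, y); r_yz <- cor(y, z)
    num <- r_xy - r_xz * r_yz
    if (abs(r_yz) >= 1 - 1e-12) {
      # perfect control: the limit is 0 when the numerator vanishes too
      # (Dy identical to Dz); anything else is genuinely degenerate
      if (abs(num) < 1e-12) return(0)
      abort("control matrix is perfectly correlated with Dy",
            class = "ncmtools_degenerate_control_error")
    }
    num / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  }
  r_obs <- partial_r(al$Dy)
  r_perm <- with_seed_or_current(seed, {
    vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      partial_r(al$Dy[pm, pm])
    }, numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_perm)
  tibble::tibble(statistic = r_obs, p_value = p, n_perm = n_perm, method = method)
}

#' Euclidean distances on standardised environmental variables
#'
#' Each chosen variable is z-scored (sd with n-1); zero-variance variables
#' are dropped with a warning.
#'
#' @param metadata Metadata tibble with a `sample_id` column.
#' @param variables Character vector of numeric column names.
#' @return Square symmetric matrix with sample ids as dimnames.
#' @export
env_distance <- function(metadata, variables) {
  miss <- setdiff(variables, names(metadata))
  if (length(miss)) abort(paste0("unknown variable(s): ", paste(miss, collapse = ", ")),
                          class = "ncmtools_parameter_error")
  X <- as.matrix(metadata[, variables, drop = FALSE])
  if (!is.numeric(X)) abort("chosen variables must be numeric",
                            class = "ncmtools_parameter_error")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping zero-variance variable(s): ",
                paste(variables[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 0) abort("no variables with positive variance",
                          class = "ncmtools_parameter_error")
  Z <- scale(X)
  D <- as.matrix(dist(Z))
  ids <- if ("sample_id" %in% names(metadata)) metadata$sample_id else NULL
  if (!is.null(ids)) dimnames(D) <- list(ids, ids)
  D
}

#' Distance matrix from a single alpha-diversity vector
#'
#' Absolute pairwise differences of a per-sample statistic (Shannon,
#' richness, ...), the "diversity" response for Mantel panels.
#'
#' @param values Numeric vector, one value per sample.
#' @param sample_id Optional sample ids for dimnames.
#' @return Square symmetric matrix.
#' @export
diversity_distance <- function(values, sample_id = NULL) {
  D <- as.matrix(dist(values))
  if (!is.null(sample_id)) dimnames(D) <- list(sample_id, sample_id)
  D
}

#' Pearson correlation matrix of environmental variables
#'
#' @inheritParams env_distance
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   variables yield `NA` entries with a warning.
#' @export
pearson_matrix <- function(metadata, variables) {
  miss <- setdiff(variables, names(metadata))
  if (length(miss)) abort(paste0("unknown variable(s): ", paste(miss, collapse = ", ")),
                          class = "ncmtools_parameter_error")
  X <- as.matrix(metadata[, variables, drop = FALSE])
  if (nrow(X) < 3) abort("need at least 3 samples",
                         class = "ncmtools_insufficient_data_error")
  if (any(apply(X, 2, sd) == 0)) {
    warn("zero-variance variable(s): correlations undefined (NA)")
  }
  suppressWarnings(cor(X))
}

#' Mantel panel of community distances against environmental variables
#'
#' One Mantel test per variable (community dissimilarity vs the Euclidean
#' distance of the z-scored variable), with the significance bands used in
#' environment-microbe association panels: `p < 0.01`, `0.01 <= p < 0.05`,
#' `p >= 0.05`.
#'
#' @param D Community distance matrix.
#' @param metadata Metadata tibble.
#' @param variables Variables to test (default the 11 physicochemical ones
#'   present in the metadata).
#' @inheritParams mantel
#' @return Tibble: `variable`, `statistic`, `p_value`, `signif_band`.
#' @export
mantel_panel <- function(D, metadata, variables = NULL, n_perm = 999, seed = NULL,
                         method = "pearson") {
  if (is.null(variables)) {
    variables <- intersect(c("pH", "WC", "TC", "TSC", "MBC", "TN", "AN",
                             "TP", "AP", "TK", "AK"), names(metadata))
  }
  purrr::map_dfr(seq_along(variables), function(i) {
    res <- mantel(D, env_distance(metadata, variables[i]),
                  n_perm = n_perm, method = method,
                  seed = if (is.null(seed)) NULL else seed + i)
    dplyr::mutate(res, variable = variables[i], .before = 1)
  }) |>
    dplyr::mutate(signif_band = dplyr::case_when(
      .data$p_value < 0.01 ~ "p < 0.01",
      .data$p_value < 0.05 ~ "0.01 <= p < 0.05",
      TRUE ~ "p >= 0.05"
    ))
}

# Piepho-style insert-and-absorb compact letter display.
# distinct[i, j] TRUE means groups i and j differ significantly.
cld_insert_absorb <- function(distinct) {
  k <- nrow(distinct)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!distinct[i, j]) next
      for (ci in rev(seq_along(cols))) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1]] <- c2
        }
      }
      # absorb columns that are subsets of another column
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] <= cols[[b]]) && any(cols[[a]] < cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      # drop exact duplicates too
      sig <- vapply(cols, function(cc) paste(as.integer(cc), collapse = ""), "")
      keep <- keep & !duplicated(sig)
      cols <- cols[keep]
    }
  }
  # order columns by their first member so dominant groups get 'a'
  first <- vapply(cols, function(cc) which(cc)[1], numeric(1))
  cols <- cols[order(first)]
  letters_out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cc) cc[g], logical(1)))], collapse = "")
  }, "")
  letters_out
}

#' One-way ANOVA with LSD post hoc and compact letter display
#'
#' Fits a one-way ANOVA, runs Fisher's (unprotected) least-significant-
#' difference test — all pairwise t tests sharing the pooled error mean
#' square — and encodes the result as compact letters: two groups share a
#' letter exactly when their LSD comparison is non-significant at `alpha`.
#' Letters are assigned with groups ordered by decreasing mean, so the
#' highest-mean group carries "a".
#'
#' @param data Data frame.
#' @param value Column with the response (tidy-eval).
#' @param group Column with the grouping factor (tidy-eval).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `lsd_cld`: `anova` (one-row tibble: statistic,
#'   df, p_value, mse), `groups` (tibble: group, n, mean, letters) and
#'   `pairs` (tibble of pairwise comparisons). Supports [tidy()] and
#'   [glance()].
#' @export
anova_lsd_cld <- function(data, value, group, alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  ns <- table(g)
  if (length(ns) < 2) abort("need at least two groups",
                            class = "ncmtools_parameter_error")
  if (any(ns < 2)) {
    abort(paste0("group(s) with a single observation: ",
                 paste(names(ns)[ns < 2], collapse = ", ")),
          class = "ncmtools_parameter_error")
  }
  fit <- aov(v ~ g)
  tab <- anova(fit)
  mse <- tab[["Mean Sq"]][2]
  df_w <- tab[["Df"]][2]
  means <- tapply(v, g, mean)
  ord <- order(means, decreasing = TRUE)
  lev <- names(means)[ord]
  k <- length(lev)
  pairs <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k)) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::mutate(
      group1 = lev[.data$i], group2 = lev[.data$j],
      diff = as.numeric(means[.data$group1] - means[.data$group2]),
      se = as.numeric(sqrt(mse * (1 / ns[.data$group1] + 1 / ns[.data$group2]))),
      statistic = .data$diff / .data$se,
      p_value = 2 * pt(-abs(.data$statistic), df_w),
      significant = unname(.data$p_value < alpha)
    ) |>
    dplyr::select(-"i", -"j")
  distinct <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  for (r in seq_len(nrow(pairs))) {
    distinct[pairs$group1[r], pairs$group2[r]] <- pairs$significant[r]
    distinct[pairs$group2[r], pairs$group1[r]] <- pairs$significant[r]
  }
  letts <- cld_insert_absorb(distinct)
  structure(
    list(
      anova = tibble::tibble(
        statistic = tab[["F value"]][1], df_between = tab[["Df"]][1],
        df_within = df_w, p_value = tab[["Pr(>F)"]][1], mse = mse
      ),
      groups = tibble::tibble(
        group = lev, n = as.integer(ns[lev]), mean = as.numeric(means[lev]),
        letters = letts
      ),
      pairs = pairs, alpha = alpha
    ),
    class = "lsd_cld"
  )
}

#' @export
print.lsd_cld <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$statistic,
              x$anova$p_value))
  print(x$groups)
  invisible(x)
}

#' @describeIn anova_lsd_cld Group means with letters.
#' @param x,object An `lsd_cld` object.
#' @param ... Unused.
#' @method tidy lsd_cld
#' @export
tidy.lsd_cld <- function(x, ...) x$groups

#' @describeIn anova_lsd_cld One-row ANOVA summary.
#' @method glance lsd_cld
#' @export
glance.lsd_cld <- function(x, ...) x$anova
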