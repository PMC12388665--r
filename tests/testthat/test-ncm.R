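test_that("occurrence statistics match a brute-force recomputation", {
  tab <- count_table(matrix(c(1, 0, 0,
                              2, 5, 0,
                              3, 0, 4), nrow = 3, byrow = FALSE,
                            dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3"))))
  st <- occurrence_stats(tab)
  # taxon at proportions (0.1, 0.2, 0.3) across three samples -> p = 0.2, f = 1
  prop <- count_table(matrix(c(1, 9, 2, 8, 3, 7), nrow = 2,
                             dimnames = list(c("x", "y"), c("A", "B", "C"))))
  stp <- occurrence_stats(prop)
  expect_equal(stp$p[stp$taxon_id == "x"], mean(c(0.1, 0.2, 0.3)))
  expect_equal(stp$f_obs[stp$taxon_id == "x"], 1)

  # counts (0, 5, 0) -> f = 1/3
  sparse <- count_table(matrix(c(1, 1, 1, 0, 5, 0), nrow = 2, byrow = TRUE,
                               dimnames = list(c("k", "z"), c("A", "B", "C"))))
  expect_equal(occurrence_stats(sparse)$f_obs[2], 1 / 3)

  # independent loop-based oracle on a random fixture, exact equality
  rt <- random_table(n_taxa = 15, n_samples = 8, seed = 41)
  mat <- count_matrix(rt)
  st2 <- occurrence_stats(rt, detection_count = 2)
  for (i in seq_len(nrow(st2))) {
    row <- mat[st2$taxon_id[i], ]
    ps <- numeric(ncol(mat))
    for (j in seq_len(ncol(mat))) ps[j] <- row[j] / sum(mat[, j])
    expect_equal(st2$p[i], mean(ps), tolerance = 1e-14)
    expect_identical(st2$f_obs[i], mean(row >= 2))
  }
  expect_error(occurrence_stats(tab[, 1:2][, 1, drop = FALSE]),
               class = "ncmtools_format_error")
  expect_error(occurrence_stats(count_table(matrix(1:3, ncol = 1))),
               class = "ncmtools_insufficient_data_error")
})

test_that("predicted frequency agrees with quadrature and obeys its limits", {
  # numerical integration of the beta density over (x, 1)
  for (p in c(0.001, 0.01, 0.1, 0.3)) {
    for (Nm in c(10, 100, 1000)) {
      for (x in c(1e-4, 1e-3, 1e-2)) {
        quad <- stats::integrate(stats::dbeta, x, 1, shape1 = Nm * p,
                                 shape2 = Nm * (1 - p), rel.tol = 1e-13)$value
        expect_lt(abs(predicted_frequency(p, Nm, x) - quad), 1e-10)
      }
    }
  }
  # Nm -> 0: beta mass concentrates on {0, 1} with weight p at 1
  expect_lt(abs(predicted_frequency(0.3, 1e-4, 1e-4) - 0.3), 1e-3)
  # Nm -> infinity with p above the detection limit: always detected
  expect_gt(predicted_frequency(0.01, 1e7, 1e-4), 0.999)
  # nondecreasing in p (strict before the detected tail saturates)
  ps <- seq(0.001, 0.5, length.out = 50)
  fs <- predicted_frequency(ps, 200, 1e-3)
  expect_true(all(diff(fs) >= 0))
  expect_true(all(diff(fs[fs < 1 - 1e-12]) > 0))
  f1 <- predicted_frequency(0.01, 500, 1e-3)
  f2 <- predicted_frequency(0.01, 5000, 1e-3)
  expect_gt(f2, f1)
  expect_error(predicted_frequency(1.2, 100, 1e-3), class = "ncmtools_domain_error")
})

test_that("fitting noise-free model frequencies is self-consistent", {
  set.seed(101)
  p <- rlnorm(300, sdlog = 2); p <- p / sum(p)
  p <- pmin(pmax(p, 1e-8), 0.99)
  f <- predicted_frequency(p, 1500, 1e-4)
  fit <- fit_ncm_curve(p, f, N = 1e4, detection_count = 1)
  expect_lt(abs(fit$Nm - 1500), 1)
  expect_lt(abs(fit$r_squared - 1), 1e-9)
})

test_that("the least-squares objective has a single practical optimum", {
  # fitted m beats a dense grid of alternatives on random neutral tables
  for (s in 1:4) {
    meta <- make_metacommunity(120, 2, seed = s)
    tab <- simulate_neutral_samples(meta, 1e4, 0.15, 15, 5000, seed = 50 + s)
    st <- occurrence_stats(tab)
    N <- round(mean(colSums(count_matrix(tab))))
    fit <- fit_ncm(tab)
    sse <- function(m) sum((st$f_obs - predicted_frequency(st$p, N * m, 1 / N))^2)
    grid <- exp(seq(log(1e-6), 0, length.out = 400))
    expect_lte(sse(fit$m), min(vapply(grid, sse, numeric(1))) + 1e-10)
  }
})

test_that("fit errors are raised for degenerate inputs", {
  expect_error(suppressWarnings(fit_ncm_curve(c(0.1, 0.2, 0.3), c(0.5, 0.5, 0.5), N = 100)),
               class = "ncmtools_undefined_r2_error")
  expect_warning(fit_ncm_curve(seq(0.01, 0.05, length.out = 5),
                               seq(0.2, 0.9, length.out = 5), N = 100),
                 "unstable")
})

test_that("Wilson intervals match the closed form and shrink with n", {
  got <- wilson_interval(0.5, 10)
  expect_lt(abs(got$low - 0.2366), 5e-4)
  expect_lt(abs(got$high - 0.7634), 5e-4)
  expect_equal(wilson_interval(0, 25)$low, 0)
  widths <- vapply(c(5, 10, 50, 200, 1000),
                   function(n) { ci <- wilson_interval(0.3, n); ci$high - ci$low },
                   numeric(1))
  expect_true(all(diff(widths) < 0))
  # interval stays inside [0, 1] and brackets the fraction's centre
  ci <- wilson_interval(c(0, 0.2, 1), 7)
  expect_true(all(ci$low >= 0 & ci$high <= 1 & ci$low <= ci$high))
})

test_that("taxa partition correctly against the prediction band", {
  rec <- tibble::tibble(taxon_id = c("a", "b", "c"),
                        p = c(0.01, 0.02, 0.03),
                        f_obs = c(0.2, 1, 0.01),
                        f_pred = c(0.2, 0.2, 0.5))
  got <- classify_taxa(rec, n_samples = 21)
  expect_equal(as.character(got$partition), c("neutral", "above", "below"))
  expect_true(all(got$ci_low <= got$f_pred & got$f_pred <= got$ci_high))

  # under neutral simulation a clear majority of taxa fall inside the band
  fracs <- vapply(1:10, function(s) {
    meta <- make_metacommunity(300, 2, seed = s)
    tab <- simulate_neutral_samples(meta, 1e4, 0.2, 21, 1e4, seed = 400 + s)
    fit <- fit_ncm(tab)
    unname(fit$partition_counts[["neutral"]]) / fit$n_taxa
  }, numeric(1))
  expect_true(all(fracs > 0.70))
  expect_gt(mean(fracs), 0.75)
})

test_that("model fits on count tables expose tidy accessors", {
  meta <- make_metacommunity(150, 2, seed = 5)
  tab <- simulate_neutral_samples(meta, 1e4, 0.2, 21, 5000, seed = 6)
  fit <- fit_ncm(tab)
  expect_s3_class(fit, "ncm_fit")
  expect_equal(fit$Nm, fit$N * fit$m)
  expect_lte(fit$r_squared, 1)
  expect_equal(sum(fit$partition_counts), fit$n_taxa)
  g <- glance(fit)
  expect_equal(g$Nm, fit$Nm)
  td <- tidy(fit)
  expect_true(all(c("taxon_id", "p", "f_obs", "f_pred", "ci_low", "ci_high",
                    "partition") %in% names(td)))
  expect_s3_class(autoplot(fit), "ggplot")
})
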