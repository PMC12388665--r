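# Small builders shared across the suite; all fixtures are generated in code.

tiny_table <- function() {
  count_table(matrix(c(5, 3, 0,
                       2, 0, 7), nrow = 3,
                     dimnames = list(c("t1", "t2", "t3"), c("A", "B"))))
}

random_table <- function(n_taxa = 20, n_samples = 6, lambda = 15, seed = 1) {
  withr::with_seed(seed, {
    count_table(matrix(rpois(n_taxa * n_samples, lambda), nrow = n_taxa,
                       dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                                       sprintf("S%02d", seq_len(n_samples)))))
  })
}

# Euclidean distance matrix of random planar points (exactly 2-D embeddable).
planar_distance <- function(n = 5, seed = 42) {
  pts <- withr::with_seed(seed, matrix(runif(n * 2), ncol = 2))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
  D
}

random_distance <- function(n, seed) {
  pts <- withr::with_seed(seed, matrix(rnorm(n * 3), ncol = 3))
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(sprintf("S%02d", 1:n), sprintf("S%02d", 1:n))
  D
}
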