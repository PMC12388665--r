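#' Core taxa and Venn region counts across groups
#'
#' A taxon counts as present in a group when its group-level relative
#' abundance (summed counts over the group's samples divided by the group
#' total) exceeds `presence_threshold`. The core set is the intersection
#' over all groups; region counts enumerate every membership combination,
#' so they sum to the size of the union.
#'
#' @param tables Named list of count table tibbles, one per group. If
#'   `taxonomy` and `rank` are supplied each table is aggregated first.
#' @param rank Optional taxonomic rank for aggregation (default phylum when
#'   `taxonomy` is given).
#' @param taxonomy Optional taxonomy tibble (see [read_taxonomy()]).
#' @param presence_threshold Relative abundance above which a taxon is
#'   "present" (default 0, i.e. any reads).
#' @return List: `core` (character vector), `regions` (tibble `region`,
#'   `n_taxa`), `membership` (tibble taxon x group logical columns).
#' @export
core_taxa <- function(tables, rank = NULL, taxonomy = NULL, presence_threshold = 0) {
  if (length(tables) < 2) abort("need at least two groups",
                                class = "ncmtools_parameter_error")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("tables must be a named list", class = "ncmtools_parameter_error")
  }
  if (!is.null(taxonomy)) {
    if (is.null(rank)) rank <- "phylum"
    tables <- lapply(tables, aggregate_by_rank, taxonomy = taxonomy, rank = rank)
  }
  present <- lapply(tables, function(tab) {
    mat <- count_matrix(tab)
    tot <- sum(mat)
    if (tot == 0) abort("a group has no reads", class = "ncmtools_validation_error")
    rel <- rowSums(mat) / tot
    names(rel)[rel > presence_threshold]
  })
  universe <- sort(unique(unlist(present)))
  membership <- vapply(present, function(s) universe %in% s,
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, names(tables)))
  core <- universe[rowSums(membership) == ncol(membership)]
  combo <- unname(apply(membership, 1, function(row) {
    paste(colnames(membership)[row], collapse = "&")
  }))
  regions <- tibble::tibble(region = combo) |>
    dplyr::count(.data$region, name = "n_taxa") |>
    dplyr::arrange(dplyr::desc(.data$n_taxa))
  list(
    core = core,
    regions = regions,
    membership = dplyr::bind_cols(tibble::tibble(taxon = universe),
                                  tibble::as_tibble(membership, .name_repair = "minimal"))
  )
}

network_summary <- function(n_nodes, edges, degrees, density) {
  tibble::tibble(
    n_nodes = n_nodes, n_edges = nrow(edges), density = density,
    mean_degree = if (n_nodes > 0) sum(degrees$degree) / n_nodes else 0
  )
}

#' Bipartite sample-group / taxon network
#'
#' Draws an edge between a group and a taxon whenever the group-level
#' abundance passes `edge_threshold` (direction set by `edge_when`; the
#' comparison is exposed rather than fixed because distance-style criteria
#' vary between studies). Density uses the bipartite normalisation
#' `edges / (n_groups * n_taxa)`.
#'
#' @param abundance Groups-by-taxa numeric matrix (dimnames required), or a
#'   tibble whose first column holds group ids.
#' @param edge_threshold Threshold on the abundance/criterion value.
#' @param edge_when `"greater"` (value > threshold, default) or `"less"`.
#' @return List: `edges` (tibble group, taxon, value), `summary` (one-row
#'   tibble), `degrees` (tibble node, type, degree).
#' @export
bipartite_network <- function(abundance, edge_threshold, edge_when = c("greater", "less")) {
  edge_when <- match.arg(edge_when)
  if (is.data.frame(abundance)) {
    mat <- as.matrix(abundance[, -1, drop = FALSE])
    rownames(mat) <- abundance[[1]]
  } else {
    mat <- as.matrix(abundance)
  }
  if (any(mat < 0)) abort("abundances must be non-negative",
                          class = "ncmtools_validation_error")
  hit <- if (edge_when == "greater") mat > edge_threshold else mat < edge_threshold
  idx <- which(hit, arr.ind = TRUE)
  edges <- tibble::tibble(
    group = rownames(mat)[idx[, 1]],
    taxon = colnames(mat)[idx[, 2]],
    value = mat[idx]
  )
  deg_g <- rowSums(hit)
  deg_t <- colSums(hit)
  degrees <- dplyr::bind_rows(
    tibble::tibble(node = rownames(mat), type = "group", degree = as.numeric(deg_g)),
    tibble::tibble(node = colnames(mat), type = "taxon", degree = as.numeric(deg_t))
  )
  density <- nrow(edges) / (nrow(mat) * ncol(mat))
  list(edges = edges,
       summary = network_summary(nrow(mat) + ncol(mat), edges, degrees, density),
       degrees = degrees)
}

#' Correlation-based co-occurrence network of taxa
#'
#' Correlates taxa pairwise across samples on relative abundances (so the
#' Spearman variant is invariant to per-sample depth rescaling); an
#' undirected edge joins two taxa when `|r| >= r_min` and the t-
#' approximation p-value is `<= p_max`. Taxa detected in fewer than
#' `min_prevalence` samples are excluded first. Topology is summarised
#' with igraph.
#'
#' @param table Count table tibble with at least 5 samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param r_min Minimum absolute correlation (default 0.6).
#' @param p_max Maximum p-value (default 0.05).
#' @param adjust P-value adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, matching common practice; `"BH"` available).
#' @param min_prevalence Minimum number of samples with nonzero counts.
#' @return List: `edges` (tibble taxon1, taxon2, r, p_value), `summary`
#'   (one-row tibble with density `2E / (n (n-1))`), `degrees`, `graph`
#'   (igraph object over retained taxa).
#' @export
cooccurrence_network <- function(table, method = c("spearman", "pearson"),
                                 r_min = 0.6, p_max = 0.05, adjust = "none",
                                 min_prevalence = 3) {
  method <- match.arg(method)
  mat <- count_matrix(table)
  if (ncol(mat) < 5) abort("co-occurrence networks need at least 5 samples",
                           class = "ncmtools_insufficient_data_error")
  keep <- rowSums(mat > 0) >= min_prevalence
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) < 2) {
    warn("fewer than two taxa pass the prevalence filter; empty network")
    empty <- tibble::tibble(taxon1 = character(), taxon2 = character(),
                            r = numeric(), p_value = numeric())
    degrees <- tibble::tibble(node = rownames(mat), degree = numeric(nrow(mat)))
    return(list(edges = empty,
                summary = network_summary(nrow(mat), empty, degrees, 0),
                degrees = degrees, graph = igraph::make_empty_graph(nrow(mat))))
  }
  rel <- sweep(mat, 2, colSums(mat), "/")
  n <- ncol(rel)
  cmat <- suppressWarnings(cor(t(rel), method = method))
  tstat <- cmat * sqrt((n - 2) / pmax(1 - cmat^2, 1e-15))
  pmat <- 2 * pt(-abs(tstat), df = n - 2)
  ut <- which(upper.tri(cmat), arr.ind = TRUE)
  edges <- tibble::tibble(
    taxon1 = rownames(cmat)[ut[, 1]],
    taxon2 = rownames(cmat)[ut[, 2]],
    r = cmat[ut], p_value = pmat[ut]
  )
  edges$p_value <- stats::p.adjust(edges$p_value, method = adjust)
  edges <- dplyr::filter(edges, !is.na(.data$r),
                         abs(.data$r) >= r_min, .data$p_value <= p_max)
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon1", "taxon2")], directed = FALSE,
    vertices = data.frame(name = rownames(cmat))
  )
  if (nrow(edges) == 0) warn("no edges pass the thresholds; empty network")
  degrees <- tibble::tibble(node = igraph::V(g)$name,
                            degree = as.numeric(igraph::degree(g)))
  nn <- igraph::vcount(g)
  density <- if (nn > 1) 2 * nrow(edges) / (nn * (nn - 1)) else 0
  list(edges = edges,
       summary = network_summary(nn, edges, degrees, density),
       degrees = degrees, graph = g)
}
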