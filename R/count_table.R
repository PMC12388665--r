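#' Build a count table tibble from a taxa-by-samples matrix
#'
#' Count tables are the package's universal currency: a tibble whose first
#' column `taxon_id` holds unique taxon identifiers and whose remaining
#' columns are non-negative integer read counts, one column per sample.
#'
#' @param mat Numeric matrix, taxa in rows, samples in columns. Row and
#'   column names become `taxon_id` and sample columns; unnamed dimensions
#'   get `tax0001...` / `S01...` labels.
#' @return A count table tibble.
#' @export
#' @examples
#' count_table(matrix(0:5, nrow = 3, dimnames = list(letters[1:3], c("A", "B"))))
count_table <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("tax%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  out <- tibble::as_tibble(mat, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(taxon_id = rownames(mat)), out)
  validate_count_table(out)
  out
}

#' Convert a count table tibble back to a matrix
#'
#' @param table Count table tibble (first column taxon ids).
#' @return Integer-valued matrix with taxon ids as row names.
#' @export
count_matrix <- function(table) {
  validate_count_table(table)
  mat <- as.matrix(table[, -1, drop = FALSE])
  rownames(mat) <- table[[1]]
  storage.mode(mat) <- "double"
  mat
}

validate_count_table <- function(table, integer_only = TRUE) {
  if (!is.data.frame(table) || ncol(table) < 2) {
    abort("a count table needs a taxon id column plus at least one sample column",
          class = "ncmtools_format_error")
  }
  ids <- as.character(table[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate taxon ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "ncmtools_format_error")
  }
  samples <- names(table)[-1]
  if (anyDuplicated(samples)) {
    abort("duplicate sample ids in header", class = "ncmtools_format_error")
  }
  vals <- as.matrix(table[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals)) {
    abort("count cells must be numeric and non-missing",
          class = "ncmtools_validation_error")
  }
  if (any(vals < 0)) {
    abort("negative counts are not allowed", class = "ncmtools_validation_error")
  }
  if (integer_only && any(abs(vals - round(vals)) > 1e-8)) {
    abort("non-integer counts are not allowed", class = "ncmtools_validation_error")
  }
  invisible(table)
}

#' Read a taxa-by-samples count table
#'
#' TSV is the canonical on-disk format: first column taxon ids, header row
#' sample ids, tab-separated, UTF-8. BIOM files (JSON or HDF5 dialect) are
#' supported read-only through the biomformat package.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return A count table tibble.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
    return(count_table(mat))
  }
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  names(tab)[1] <- "taxon_id"
  for (j in seq_along(tab)[-1]) {
    num <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(num)) {
      abort(paste0("non-numeric count cell(s) in sample ", names(tab)[j]),
            class = "ncmtools_validation_error")
    }
    tab[[j]] <- num
  }
  validate_count_table(tab)
  tab
}

#' Write a count table to TSV
#'
#' @param table Count table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  validate_count_table(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Randomly subsamples each sample's reads without replacement down to
#' `depth`. Samples with fewer reads than `depth` are dropped with a warning
#' rather than padded, so retained columns stay comparable.
#'
#' @param table Count table tibble.
#' @param depth Target reads per sample; default is the minimum column sum.
#' @param seed Optional integer seed for reproducible subsampling.
#' @return Rarefied count table; every column sums exactly to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = NULL) {
  mat <- count_matrix(table)
  totals <- colSums(mat)
  if (is.null(depth)) depth <- min(totals)
  depth <- as.integer(depth)
  if (depth < 1) abort("depth must be >= 1")
  keep <- totals >= depth
  if (!any(keep)) {
    abort(sprintf("no sample reaches depth %d; maximum column sum is %d",
                  depth, max(totals)),
          class = "ncmtools_empty_table_error")
  }
  if (any(!keep)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth, paste(colnames(mat)[!keep], collapse = ", ")))
    mat <- mat[, keep, drop = FALSE]
  }
  sub <- with_seed_or_current(seed, {
    apply(mat, 2, function(col) {
      pool <- rep.int(seq_along(col), col)
      drawn <- if (length(pool) == depth) pool else sample(pool, depth)
      tabulate(drawn, nbins = length(col))
    })
  })
  rownames(sub) <- rownames(mat)
  count_table(sub)
}

#' Parse taxonomy lineage strings into ranked columns
#'
#' Accepts the greengenes/Silva prefix convention (`d__...;p__...;...`,
#' `k__` treated as domain) or bare semicolon-separated lineages assigned
#' positionally (domain, phylum, class, order, family, genus). Missing ranks
#' stay `NA`.
#'
#' @param taxon_id Character vector of taxon ids.
#' @param lineage Character vector of lineage strings.
#' @return Tibble with columns `taxon_id`, `domain` ... `genus`.
#' @export
parse_lineage <- function(taxon_id, lineage) {
  if (anyDuplicated(taxon_id)) {
    abort("duplicate taxon ids in taxonomy", class = "ncmtools_format_error")
  }
  prefix_of <- c(d = "domain", k = "domain", p = "phylum", c = "class",
                 o = "order", f = "family", g = "genus")
  rows <- lapply(lineage, function(s) {
    out <- setNames(rep(NA_character_, length(TAX_RANKS)), TAX_RANKS)
    if (is.na(s) || !nzchar(trimws(s))) return(out)
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts <- parts[nzchar(parts)]
    prefixed <- grepl("^[a-zA-Z]__", parts)
    if (any(prefixed)) {
      for (part in parts[prefixed]) {
        key <- tolower(substr(part, 1, 1))
        val <- sub("^[a-zA-Z]__", "", part)
        if (key %in% names(prefix_of) && nzchar(val)) out[prefix_of[[key]]] <- val
      }
    } else {
      n <- min(length(parts), length(TAX_RANKS))
      out[seq_len(n)] <- parts[seq_len(n)]
    }
    out
  })
  dplyr::bind_cols(tibble::tibble(taxon_id = as.character(taxon_id)),
                   tibble::as_tibble(do.call(rbind, rows)))
}

#' Read a two-column taxonomy TSV (taxon_id, lineage)
#'
#' @param path File path.
#' @return Tibble with `taxon_id` plus one column per rank.
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  if (ncol(tab) < 2) abort("taxonomy file needs two columns: taxon_id, lineage",
                           class = "ncmtools_format_error")
  parse_lineage(tab[[1]], tab[[2]])
}

#' Read a sample metadata TSV
#'
#' Requires columns `sample_id`, `site`, `layer`, `replicate`; any further
#' numeric columns are physicochemical variables (pH, WC, TC, TSC, MBC, TN,
#' AN, TP, AP, TK, AK). Range invariants (pH in (0,14), WC in \[0,100\],
#' concentrations non-negative) are enforced where those columns exist.
#'
#' @param path File path.
#' @return Metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  tab <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  need <- c("sample_id", "site", "layer", "replicate")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(paste0("metadata is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "ncmtools_format_error")
  }
  if (anyDuplicated(tab$sample_id)) {
    abort("duplicate sample_id in metadata", class = "ncmtools_format_error")
  }
  if ("pH" %in% names(tab) && any(tab$pH <= 0 | tab$pH >= 14, na.rm = TRUE)) {
    abort("pH out of (0, 14)", class = "ncmtools_validation_error")
  }
  if ("WC" %in% names(tab) && any(tab$WC < 0 | tab$WC > 100, na.rm = TRUE)) {
    abort("WC out of [0, 100]", class = "ncmtools_validation_error")
  }
  conc <- intersect(c("TC", "TSC", "MBC", "TN", "AN", "TP", "AP", "TK", "AK"),
                    names(tab))
  for (v in conc) {
    if (any(tab[[v]] < 0, na.rm = TRUE)) {
      abort(paste0(v, " has negative concentrations"),
            class = "ncmtools_validation_error")
    }
  }
  tab
}

#' Aggregate a count table to a taxonomic rank
#'
#' Sums counts of taxa sharing the same label at `rank`; taxa without a
#' mapping (or with `NA` at that rank) are pooled into `"Unassigned"`.
#' Column sums are conserved exactly.
#'
#' @param table Count table tibble.
#' @param taxonomy Tibble from [read_taxonomy()]/[parse_lineage()], or a
#'   two-column data frame (taxon_id, lineage) which is parsed on the fly.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Count table tibble keyed by rank labels.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank = "phylum") {
  if (!is.character(rank) || length(rank) != 1 || !rank %in% TAX_RANKS) {
    abort(paste0("unknown rank; use one of: ", paste(TAX_RANKS, collapse = ", ")),
          class = "ncmtools_parameter_error")
  }
  mat <- count_matrix(table)
  if (!all(TAX_RANKS %in% names(taxonomy))) {
    taxonomy <- parse_lineage(taxonomy[[1]], taxonomy[[2]])
  }
  labels <- taxonomy[[rank]][match(rownames(mat), taxonomy$taxon_id)]
  labels[is.na(labels)] <- "Unassigned"
  agg <- rowsum(mat, group = labels)
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  count_table(agg)
}

#' Convert counts to within-sample relative abundances
#'
#' @param table Count table tibble.
#' @return Tibble of the same shape with each sample column summing to 1.
#' @export
relative_abundance <- function(table) {
  mat <- count_matrix(table)
  totals <- colSums(mat)
  if (any(totals == 0)) {
    abort(paste0("zero-sum sample(s): ",
                 paste(colnames(mat)[totals == 0], collapse = ", ")),
          class = "ncmtools_division_error")
  }
  rel <- sweep(mat, 2, totals, "/")
  out <- tibble::as_tibble(rel, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(taxon_id = rownames(mat)), out)
}
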