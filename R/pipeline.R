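#' Default configuration for the study-shaped analysis
#'
#' Describes a two-layer sediment survey: 7 sites x 3 replicates = 21
#' samples per layer, archaea simulated as a neutrally assembled community
#' (high Nm in the surface layer, lower at depth) and bacteria as an
#' environmentally filtered community whose niche gradient is the water-
#' content column of the simulated metadata (filtering stronger at depth).
#' Every stage seed is derived from the master seed by fixed offsets.
#'
#' @param seed Master seed (integer).
#' @param n_perm Permutations for the Mantel panel.
#' @return Nested configuration list for [run_full_analysis()].
#' @export
analysis_config <- function(seed = 1, n_perm = 199) {
  list(
    seed = as.integer(seed),
    design = list(
      sites = c("BYH", "ZYW", "LYH", "RYSD", "SW", "YQ", "JFD"),
      layers = c("0-20 cm", "20-40 cm"),
      replicates = 3
    ),
    simulation = list(
      S = 300, depth = 1e4, meta_sigma = 2, env_corr = 0.5, n_phyla = 8,
      organisms = list(
        archaea = list(mode = "neutral", N = 1e4,
                       m = c("0-20 cm" = 0.2, "20-40 cm" = 0.1)),
        bacteria = list(mode = "filtered",
                        filter_strength = c("0-20 cm" = 3, "20-40 cm" = 6),
                        gradient_variable = "WC")
      )
    ),
    detection_count = 1,
    mantel = list(n_perm = n_perm, variables = NULL),
    alpha = 0.05
  )
}

stage_abort <- function(stage, parent) {
  abort(paste0("stage '", stage, "' failed: ", conditionMessage(parent)),
        class = "ncmtools_stage_error", stage = stage)
}

#' Run the full community-assembly analysis
#'
#' Executes, per layer and organism group: simulation (or ingest of TSV
#' inputs) -> rarefaction -> alpha diversity with LSD letters by site ->
#' Bray-Curtis + NMDS -> neutral community model fit -> Mantel panel
#' against the physicochemical metadata (composition and Shannon-diversity
#' responses) -> core taxa at phylum rank across sites. Identical
#' configuration and seed give a byte-identical report (see
#' [write_report()]).
#'
#' @param config Configuration list from [analysis_config()], possibly
#'   modified, or a path to a YAML file with the same structure.
#' @return Object of class `assembly_report`: nested list with one entry
#'   per layer/organism plus provenance (seeds, configuration hash,
#'   package version).
#' @export
run_full_analysis <- function(config = analysis_config()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed
  des <- config$design
  sim <- config$simulation
  n_samples <- length(des$sites) * des$replicates
  layers <- des$layers
  organisms <- names(sim$organisms)

  report <- list(
    provenance = list(
      seed = seed,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("ncmtools")),
      organisms = organisms, layers = layers, n_samples = n_samples
    ),
    layers = list()
  )

  # one metacommunity per organism, shared across layers
  metacoms <- lapply(seq_along(organisms), function(oi) {
    make_metacommunity(sim$S, sim$meta_sigma, seed = seed + 17L * oi)
  })
  names(metacoms) <- organisms

  for (li in seq_along(layers)) {
    layer <- layers[li]
    metadata <- tryCatch(
      simulate_metadata(n_samples, sim$env_corr, seed = seed + 100L + li,
                        sites = des$sites, layer = layer),
      error = function(e) stage_abort("metadata", e)
    )
    layer_out <- list(metadata = metadata, organisms = list())
    for (oi in seq_along(organisms)) {
      org <- organisms[oi]
      spec_org <- sim$organisms[[org]]
      sim_seed <- seed + 1000L * li + 10L * oi
      tab <- tryCatch({
        if (identical(spec_org$mode, "neutral")) {
          simulate_neutral_samples(metacoms[[org]], N = spec_org$N,
                                   m = spec_org$m[[layer]],
                                   n_samples = n_samples, depth = sim$depth,
                                   seed = sim_seed)
        } else if (identical(spec_org$mode, "filtered")) {
          gvar <- spec_org$gradient_variable
          gradient <- as.numeric(scale(metadata[[gvar]]))
          simulate_filtered_samples(metacoms[[org]], gradient,
                                    filter_strength = spec_org$filter_strength[[layer]],
                                    depth = sim$depth, seed = sim_seed)$table
        } else {
          abort(paste0("unknown simulation mode: ", spec_org$mode))
        }
      }, error = function(e) stage_abort("simulate", e))

      tab <- tryCatch(rarefy(tab, seed = sim_seed + 1L),
                      error = function(e) stage_abort("rarefy", e))

      alpha <- tryCatch({
        a <- alpha_diversity(tab)
        a$site <- metadata$site[match(a$sample_id, metadata$sample_id)]
        cld <- anova_lsd_cld(a, "shannon", "site", alpha = config$alpha)
        list(table = a, cld = tidy(cld), anova = glance(cld))
      }, error = function(e) stage_abort("alpha_diversity", e))

      beta <- tryCatch({
        D <- bray_curtis(tab)
        ord <- nmds(D, k = 2, seed = seed + 7L + li + oi)
        list(D = D, nmds = ord)
      }, error = function(e) stage_abort("beta_diversity", e))

      fit <- tryCatch(fit_ncm(tab, detection_count = config$detection_count),
                      error = function(e) stage_abort("ncm", e))

      mantel_out <- tryCatch({
        if (is.null(metadata)) abort("metadata table is missing")
        comp <- mantel_panel(beta$D, metadata,
                             variables = config$mantel$variables,
                             n_perm = config$mantel$n_perm,
                             seed = seed + 5000L + 100L * li + oi)
        Ddiv <- diversity_distance(alpha$table$shannon, alpha$table$sample_id)
        div <- mantel_panel(Ddiv, metadata,
                            variables = config$mantel$variables,
                            n_perm = config$mantel$n_perm,
                            seed = seed + 6000L + 100L * li + oi)
        list(composition = comp, diversity = div)
      }, error = function(e) stage_abort("mantel", e))

      core <- tryCatch({
        taxonomy <- simulate_taxonomy(metacoms[[org]]$taxon_id,
                                      n_phyla = sim$n_phyla,
                                      seed = seed + 42L * oi)
        by_site <- split_by_site(tab, metadata)
        core_taxa(by_site, rank = "phylum", taxonomy = taxonomy)
      }, error = function(e) stage_abort("core_taxa", e))

      layer_out$organisms[[org]] <- list(
        ncm = glance(fit),
        ncm_records = fit$records,
        alpha = alpha$table, alpha_cld = alpha$cld, alpha_anova = alpha$anova,
        nmds = tidy(beta$nmds), nmds_stress = beta$nmds$stress,
        mantel_composition = mantel_out$composition,
        mantel_diversity = mantel_out$diversity,
        core_phyla = core$core, venn_regions = core$regions
      )
    }
    report$layers[[layer]] <- layer_out
  }
  structure(report, class = "assembly_report")
}

# Split a count table's sample columns by the metadata's site codes.
split_by_site <- function(table, metadata) {
  sites <- unique(metadata$site)
  out <- lapply(sites, function(s) {
    ids <- metadata$sample_id[metadata$site == s]
    table[, c(names(table)[1], intersect(names(table)[-1], ids))]
  })
  names(out) <- sites
  out
}

#' Serialise an analysis report to canonical JSON
#'
#' Fixed numeric precision (10 significant digits) and stable key order:
#' identical configurations and seeds give byte-identical files.
#'
#' @param report An `assembly_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  invisible(path)
}

#' Contrast neutral-model fits between sediment layers
#'
#' Tabulates per-organism R-squared and Nm for each layer plus their
#' differences (first layer minus second), the summary used to ask whether
#' stochastic influence weakens with depth.
#'
#' @param report An `assembly_report` holding one or two layers.
#' @return Tibble: organism, per-layer r_squared and Nm, `delta_r_squared`,
#'   `delta_nm`. Missing layers yield `NA`.
#' @export
compare_layers <- function(report) {
  layers <- names(report$layers)
  organisms <- report$provenance$organisms
  get_val <- function(layer, org, field) {
    if (!layer %in% layers) return(NA_real_)
    g <- report$layers[[layer]]$organisms[[org]]$ncm
    if (is.null(g)) NA_real_ else g[[field]]
  }
  l1 <- layers[1]
  l2 <- if (length(layers) >= 2) layers[2] else NA_character_
  purrr::map_dfr(organisms, function(org) {
    r1 <- get_val(l1, org, "r_squared")
    r2 <- if (is.na(l2)) NA_real_ else get_val(l2, org, "r_squared")
    n1 <- get_val(l1, org, "Nm")
    n2 <- if (is.na(l2)) NA_real_ else get_val(l2, org, "Nm")
    tibble::tibble(
      organism = org,
      r_squared_layer1 = r1, r_squared_layer2 = r2,
      delta_r_squared = r1 - r2,
      nm_layer1 = n1, nm_layer2 = n2, delta_nm = n1 - n2
    )
  })
}

#' @export
print.assembly_report <- function(x, ...) {
  cat("Community assembly report\n")
  cat(sprintf("  seed %d, %d layer(s), organisms: %s\n",
              x$provenance$seed, length(x$layers),
              paste(x$provenance$organisms, collapse = ", ")))
  print(compare_layers(x))
  invisible(x)
}
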