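#' Read and validate a pipeline run configuration
#'
#' A run configuration is a YAML file (or list) with a global `seed`, an
#' `out_dir`, either `simulate:` parameters (forwarded to [sim_config()])
#' or `inputs:` paths (`otu_<season>` TSVs plus `metadata`), optional
#' `stages:` toggles, and per-stage `params:`. Unknown keys are rejected;
#' every violation is reported in one aggregated error.
#'
#' @param path YAML file path (for [read_run_config()]).
#' @param config A named list (for [validate_run_config()]).
#' @return A validated config list of class `"run_config"`, defaults
#'   filled.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  known_top <- c("seed", "out_dir", "simulate", "inputs", "stages", "params")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) note("unknown key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    seed = 1L, out_dir = "riverassembly-run",
    simulate = NULL, inputs = NULL,
    stages = list(hails = TRUE, diversity = TRUE, assembly = TRUE,
                  network = TRUE, drivers = TRUE),
    params = list(rarefy_depth = NULL, anosim_permutations = 999L,
                  null_model_simulations = 2000L, null_model_burn_in = 10000L,
                  null_model_thin = 100L, network_threshold = 0.6,
                  network_q_cutoff = 0.05, network_permutations = 1000L,
                  network_min_prevalence = 0.5,
                  network_scheme = "per-reach-triplicate",
                  bioenv_max_subset = 4L, mantel_permutations = 999L)
  )
  cfg <- utils::modifyList(defaults, config[intersect(names(config), known_top)])
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    note("seed must be a single integer")
  }
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    note("one of 'simulate' or 'inputs' is required")
  }
  if (!is.null(cfg$inputs)) {
    if (is.null(cfg$inputs$metadata)) note("inputs$metadata path is required")
    if (!any(startsWith(names(cfg$inputs), "otu_"))) {
      note("inputs must name at least one otu_<season> table")
    }
  }
  unknown_p <- setdiff(names(cfg$params), names(defaults$params))
  if (length(unknown_p)) {
    note("unknown params key(s): ", paste(unknown_p, collapse = ", "))
  }
  for (k in c("anosim_permutations", "null_model_simulations",
              "network_permutations", "mantel_permutations",
              "bioenv_max_subset")) {
    v <- cfg$params[[k]]
    if (!is.null(v) && (!is.numeric(v) || v < 1)) {
      note(k, " must be a positive count, got ", v)
    }
  }
  if (!is.null(cfg$params$network_threshold) &&
      (cfg$params$network_threshold < 0 || cfg$params$network_threshold > 1)) {
    note("network_threshold must lie in [0, 1]")
  }
  unknown_s <- setdiff(names(cfg$stages), names(defaults$stages))
  if (length(unknown_s)) {
    note("unknown stages key(s): ", paste(unknown_s, collapse = ", "))
  }
  if (length(problems)) {
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  # normalise so a config round-trips through YAML unchanged
  for (k in c("simulate", "inputs")) {
    if (!k %in% names(cfg)) cfg[k] <- list(NULL)
  }
  if (!"rarefy_depth" %in% names(cfg$params)) {
    cfg$params["rarefy_depth"] <- list(NULL)
  }
  cfg$params <- cfg$params[c("rarefy_depth",
                             setdiff(names(cfg$params), "rarefy_depth"))]
  if (!is.null(cfg$simulate) && !is.null(cfg$simulate$seasons)) {
    cfg$simulate$seasons <- as.character(unlist(cfg$simulate$seasons))
  }
  cfg <- cfg[c("seed", "out_dir", "simulate", "inputs", "stages", "params")]
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# per-stage seeds derive deterministically from the global seed so adding a
# stage never perturbs another stage's RNG stream (kept below 2^31)
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order - data (simulate or read), HAILS,
#' diversity/ordination, assembly diagnostics, gradient networks, driver
#' attribution - writing TSV/JSON outputs per stage plus a machine-readable
#' `manifest.json` (package version, global and per-stage seeds, parameters,
#' input checksums). A stage failure aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config A `"run_config"` (from [read_run_config()] /
#'   [validate_run_config()]) or a path to a YAML config.
#' @return The manifest, invisibly (list).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "riverassembly",
    version = as.character(utils::packageVersion("riverassembly")),
    seed = config$seed,
    params = config$params,
    stages = list(),
    inputs = list()
  )
  p <- config$params
  stage <- "data"
  result <- tryCatch({
    # -- data ---------------------------------------------------------------
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- stage_seed(config$seed, "simulate")
      cfg <- do.call(sim_config, sim_args)
      bundle <- simulate_study(cfg, out_dir = file.path(out, "inputs"))
      tables <- bundle$tables
      metadata <- bundle$metadata
      manifest$inputs <- as.list(bundle$paths)
    } else {
      paths <- config$inputs
      metadata <- readr::read_tsv(paths$metadata,
                                  col_types = readr::cols(),
                                  progress = FALSE)
      tables <- list()
      for (k in names(paths)) {
        if (!startsWith(k, "otu_")) next
        if (!file.exists(paths[[k]])) {
          stop("missing input file: ", paths[[k]], call. = FALSE)
        }
        tables[[sub("^otu_", "", k)]] <- read_otu_table(paths[[k]])
      }
      manifest$inputs <- lapply(paths, function(pp) {
        list(path = pp, md5 = unname(tools::md5sum(pp)))
      })
    }
    if (!is.null(p$rarefy_depth)) {
      tables <- lapply(tables, rarefy, depth = p$rarefy_depth,
                       seed = stage_seed(config$seed, "rarefy"),
                       drop_shallow = TRUE)
    }
    manifest$stages$data <- list(seasons = names(tables),
                                 n_samples = vapply(tables, nrow, integer(1)))

    # -- hails --------------------------------------------------------------
    if (isTRUE(config$stages$hails)) {
      stage <- "hails"
      hl <- classify_hails(
        dplyr::left_join(hails_index(metadata),
                         metadata[c("sample_id", "reach")], by = "sample_id"),
        scheme = "reach-map"
      )
      readr::write_tsv(hl, file.path(out, "hails.tsv"), progress = FALSE)
      metadata <- dplyr::left_join(metadata,
                                   hl[c("sample_id", "hails", "level")],
                                   by = "sample_id")
      manifest$stages$hails <- list(file = "hails.tsv")
    }

    # -- diversity ----------------------------------------------------------
    if (isTRUE(config$stages$diversity)) {
      stage <- "diversity"
      sd_ <- stage_seed(config$seed, "diversity")
      for (s in names(tables)) {
        tb <- tables[[s]]
        readr::write_tsv(alpha_diversity(tb),
                         file.path(out, paste0("alpha_", s, ".tsv")),
                         progress = FALSE)
        bc <- bray_curtis(tb)
        utils::write.table(bc, file.path(out, paste0("braycurtis_", s, ".tsv")),
                           sep = "\t", quote = FALSE)
        ord <- pcoa_ord(bc)
        readr::write_tsv(ord$coordinates,
                         file.path(out, paste0("pcoa_", s, ".tsv")),
                         progress = FALSE)
        md_s <- metadata[match(tb$sample_id, metadata$sample_id), ]
        an <- anosim_test(bc, md_s$reach,
                          n_permutations = p$anosim_permutations, seed = sd_)
        jsonlite::write_json(as.list(an),
                             file.path(out, paste0("anosim_", s, ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
      manifest$stages$diversity <- list(seed = sd_)
    }

    # -- assembly -----------------------------------------------------------
    if (isTRUE(config$stages$assembly)) {
      stage <- "assembly"
      sd_ <- stage_seed(config$seed, "assembly")
      for (s in names(tables)) {
        tb <- tables[[s]]
        fit <- fit_ncm(tb)
        jsonlite::write_json(as.list(glance(fit)),
                             file.path(out, paste0("ncm_", s, ".json")),
                             auto_unbox = TRUE, digits = NA)
        readr::write_tsv(tidy(fit),
                         file.path(out, paste0("ncm_otus_", s, ".tsv")),
                         progress = FALSE)
        md_s <- metadata[match(tb$sample_id, metadata$sample_id), ]
        nulls <- lapply(unique(md_s$reach), function(r) {
          pres <- presence_matrix(tb[md_s$reach == r, ])
          dplyr::mutate(
            null_model_ses(pres, n_simulations = p$null_model_simulations,
                           burn_in = p$null_model_burn_in,
                           thin = p$null_model_thin, seed = sd_),
            reach = r, season = s, .before = 1)
        })
        readr::write_tsv(dplyr::bind_rows(nulls),
                         file.path(out, paste0("cscore_", s, ".tsv")),
                         progress = FALSE)
        nb <- niche_breadth(tb, groups = md_s$level)
        readr::write_tsv(nb$summary,
                         file.path(out, paste0("niche_breadth_", s, ".tsv")),
                         progress = FALSE)
      }
      manifest$stages$assembly <- list(seed = sd_)
    }

    # -- network ------------------------------------------------------------
    topo_by_season <- list()
    if (isTRUE(config$stages$network)) {
      stage <- "network"
      sd_ <- stage_seed(config$seed, "network")
      for (s in names(tables)) {
        nets <- networks_along_gradient(
          tables[[s]], metadata, scheme = p$network_scheme, seed = sd_,
          min_prevalence = p$network_min_prevalence,
          threshold = p$network_threshold, q_cutoff = p$network_q_cutoff,
          n_permutations = p$network_permutations
        )
        topo <- gradient_topology(nets, seed = sd_)
        topo_by_season[[s]] <- topo
        readr::write_tsv(topo, file.path(out, paste0("topology_", s, ".tsv")),
                         progress = FALSE)
        if (nrow(topo) >= 3 && stats::sd(topo$hails) > 0) {
          decay <- dplyr::bind_rows(
            stability_decay(topo, topo$hails, "NM"),
            stability_decay(topo, topo$hails, "M")
          )
        } else {
          warning("too few non-empty networks for the stability regression",
                  " in season ", s, call. = FALSE)
          decay <- tibble::tibble()
        }
        readr::write_tsv(decay,
                         file.path(out, paste0("stability_", s, ".tsv")),
                         progress = FALSE)
        edges <- dplyr::bind_rows(lapply(seq_len(nrow(nets)), function(i) {
          dplyr::mutate(nets$network[[i]]$edges, group = nets$group[i],
                        .before = 1)
        }))
        readr::write_tsv(edges, file.path(out, paste0("edges_", s, ".tsv")),
                         progress = FALSE)
      }
      manifest$stages$network <- list(seed = sd_)
    }

    # -- drivers ------------------------------------------------------------
    if (isTRUE(config$stages$drivers)) {
      stage <- "drivers"
      sd_ <- stage_seed(config$seed, "drivers")
      landuse_cols <- c("farmland", "forest", "grassland", "freshwater",
                        "urban", "other")
      chem_cols <- intersect(c("NO3_N", "Cl", "TP", "NH4_N", "TOC", "SO4",
                               "pH", "EC"), names(metadata))
      geo_cols <- intersect(c("river_length", "catchment_area",
                              "cumulative_dendritic_distance",
                              "mean_dendritic_stream_length"),
                            names(metadata))
      for (s in names(tables)) {
        tb <- tables[[s]]
        md_s <- metadata[match(tb$sample_id, metadata$sample_id), ]
        bc <- bray_curtis(tb)
        dd <- distance_decay(bc, md_s$river_length,
                             n_permutations = p$mantel_permutations,
                             seed = sd_)
        jsonlite::write_json(as.list(dd),
                             file.path(out, paste0("distance_decay_", s,
                                                   ".json")),
                             auto_unbox = TRUE, digits = NA)
        be <- list(
          land_use = bioenv_search(bc, md_s[landuse_cols],
                                   max_subset_size = p$bioenv_max_subset),
          chemistry = bioenv_search(bc, md_s[chem_cols],
                                    max_subset_size = p$bioenv_max_subset),
          geographic = bioenv_search(bc, md_s[geo_cols],
                                     max_subset_size = p$bioenv_max_subset)
        )
        be_tbl <- dplyr::bind_rows(lapply(names(be), function(b) {
          dplyr::mutate(utils::head(tidy(be[[b]]), 10), block = b,
                        .before = 1)
        }))
        readr::write_tsv(be_tbl, file.path(out, paste0("bioenv_", s, ".tsv")),
                         progress = FALSE)
        # the bioenv-selected subsets feed the VPA, keeping predictors < n
        best_vars <- lapply(be, function(b) {
          strsplit(b$best$variables, " \\+ ")[[1]]
        })
        vp <- varpart3(tb, md_s[best_vars$land_use],
                       md_s[best_vars$chemistry], md_s[best_vars$geographic])
        jsonlite::write_json(as.list(vp$fractions),
                             file.path(out, paste0("varpart_", s, ".json")),
                             auto_unbox = TRUE, digits = NA)
      }
      manifest$stages$drivers <- list(seed = sd_)
    }
    manifest
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(result, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result)
}
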