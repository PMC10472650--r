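#' Default pipeline configuration
#'
#' All stage parameters with their reference defaults: locus filters
#' `a = 5, b = 5000, c = 4`; the 11 x 17 clustering grid; species filters
#' (>= 100 SNPs, >= 3 samples over depth 8); 450 grid rotations with the
#' Mediterranean penalties of 100 years out / 1 year in; classification with
#' `K = 8`, perplexity 5, 5000 iterations; LCA ratio 0.67 with E-value cutoff
#' 1e-5.  Override any entry by passing a partial list (or a YAML file path)
#' to [run_pipeline()].
#'
#' @return nested list of stage parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    stages = c("filter", "cluster", "fst", "lagrangian", "partition",
               "classify"),
    filter = list(min_depth = 5, max_depth = 5000, min_present = 4),
    cluster = list(epsilon_set = c(4, 5, 6, 7, 8, 9, 10, 12, 15, 18, 20),
                   minpts_set = c(1:10, 20, 50, 100, 200, 300, 400, 500),
                   min_snps = 100, min_samples = 3, min_depth = 8),
    lagrangian = list(n_rotations = 450, lag_days = 5, cell_deg = 1,
                      med_out_years = 100, med_in_years = 1,
                      matrix = NULL),
    partition = list(min_stations = 4),
    classify = list(k = 8, perplexity = 5, max_iter = 5000),
    lca = list(r = 0.67, evalue_max = 1e-5, per_query_cap = 10)
  )
}

# overlay a partial configuration on the defaults
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full connectivity pipeline on one input set
#'
#' Executes the enabled stages in order — filter, cluster, fst, lagrangian,
#' partition, classify (and lca when hit tables are supplied) — writing every
#' artifact as TSV/JSON under `out_dir` and a manifest with parameters,
#' seeds, per-stage counts and artifact checksums.  A precomputed
#' min-symmetrized travel-time matrix may be injected through
#' `config$lagrangian$matrix` (a TSV path or matrix), in which case the
#' lagrangian stage is skipped.
#'
#' @param inputs either a directory containing `snp.tsv`, `stations.tsv`,
#'   `environment.tsv`, `trajectories.tsv` (as written by
#'   [simulate_dataset()]) or a list with elements `snp_table`, `stations`,
#'   `environment`, `trajectories`.
#' @param out_dir output run directory (created if needed).
#' @param config partial configuration list or YAML file path overriding
#'   [default_pipeline_config()].
#' @return invisibly, a list with the in-memory stage results (`filter`,
#'   `species`, `fst`, `travel`, `partition`, `classify`, `manifest`).
#' @export
run_pipeline <- function(inputs, out_dir, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = logf, append = TRUE)
    message(line)
  }

  if (is.character(inputs)) {
    need <- file.path(inputs, c("snp.tsv", "stations.tsv", "environment.tsv"))
    if (!all(file.exists(need))) {
      stop_input("missing input artifacts in ", inputs)
    }
    inputs <- list(
      snp_table = read_snp_table(file.path(inputs, "snp.tsv")),
      stations = read_tsv(file.path(inputs, "stations.tsv")),
      environment = read_tsv(file.path(inputs, "environment.tsv")),
      trajectories = if (file.exists(file.path(inputs, "trajectories.tsv"))) {
        read_tsv(file.path(inputs, "trajectories.tsv"))
      }
    )
  }
  stations <- inputs$stations
  basin_of_station <- stats::setNames(stations$basin, stations$station_id)
  counts <- list()
  results <- list()

  # -- filter ----------------------------------------------------------------
  tab <- inputs$snp_table
  counts$snps_input <- length(tab$locus_id)
  if ("filter" %in% cfg$stages) {
    fl <- filter_loci(tab, filter_params(cfg$filter$min_depth,
                                         cfg$filter$max_depth,
                                         cfg$filter$min_present))
    tab <- fl$table
    results$filter <- fl$report
    jsonlite::write_json(fl$report, file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE)
    write_snp_table(tab, file.path(out_dir, "snp_filtered.tsv"))
    say("filter: %d -> %d SNPs", fl$report$n_input, fl$report$n_retained)
  }
  counts$snps_filtered <- length(tab$locus_id)

  # -- cluster ---------------------------------------------------------------
  species <- list()
  if ("cluster" %in% cfg$stages) {
    del <- delineate_species(tab,
                             epsilon_set = cfg$cluster$epsilon_set,
                             minpts_set = cfg$cluster$minpts_set,
                             min_snps = cfg$cluster$min_snps,
                             min_samples = cfg$cluster$min_samples,
                             min_depth = cfg$cluster$min_depth)
    species <- del$species
    counts <- c(counts, del$log)
    membership <- do.call(rbind, lapply(species, function(sp) {
      data.frame(species_id = sp$species_id, locus_id = sp$snp_ids,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(membership)) {
      write_tsv(membership, file.path(out_dir, "species_membership.tsv"))
    }
    say("cluster: grid %d, %d clusters detected, %d species selected",
        del$log$grid_size, del$log$n_clusters_unique, del$log$n_species)
    results$species <- species
  }

  # -- fst -------------------------------------------------------------------
  fst_results <- list()
  if ("fst" %in% cfg$stages && length(species)) {
    for (sp in species) {
      res <- summarize_fst(sp)
      fst_results[[sp$species_id]] <- res
      write_tsv(data.frame(locus_id = sp$snp_ids,
                           fst = res$per_variant_global),
                file.path(out_dir, paste0(sp$species_id, "_fst.tsv")))
      pw <- as.data.frame(res$pairwise_median)
      pw <- cbind(population = rownames(pw), pw)
      write_tsv(pw, file.path(out_dir,
                              paste0(sp$species_id, "_pairwise_fst.tsv")))
    }
    basins <- aggregate_basins(fst_results, basin_of_station)
    bm <- as.data.frame(basins)
    write_tsv(cbind(basin = rownames(bm), bm),
              file.path(out_dir, "basin_fst.tsv"))
    say("fst: %d species summarized", length(fst_results))
    results$fst <- fst_results
    results$basins <- basins
  }

  # -- lagrangian ------------------------------------------------------------
  travel <- NULL
  if (!is.null(cfg$lagrangian$matrix)) {
    travel <- cfg$lagrangian$matrix
    if (is.character(travel)) {
      df <- read_tsv(travel)
      travel <- as.matrix(df[, -1, drop = FALSE])
      rownames(travel) <- df[[1]]
    }
    say("lagrangian: using injected travel time matrix")
  } else if ("lagrangian" %in% cfg$stages && !is.null(inputs$trajectories)) {
    raw <- travel_time_matrix(inputs$trajectories, stations,
                              n_rotations = cfg$lagrangian$n_rotations,
                              lag_days = cfg$lagrangian$lag_days,
                              cell_deg = cfg$lagrangian$cell_deg)
    adj <- apply_basin_adjustments(raw, basin_of_station,
                                   out_penalty_years = cfg$lagrangian$med_out_years,
                                   in_penalty_years = cfg$lagrangian$med_in_years)
    travel <- min_symmetrize(adj)
    for (nm in c("raw", "adj", "travel")) {
      m <- as.data.frame(get(nm))
      write_tsv(cbind(station = rownames(m), m),
                file.path(out_dir, paste0("travel_time_", nm, ".tsv")))
    }
    say("lagrangian: %d rotations, %d stations",
        cfg$lagrangian$n_rotations, nrow(stations))
  }
  results$travel <- travel

  # -- partition -------------------------------------------------------------
  partition <- NULL
  if ("partition" %in% cfg$stages && length(fst_results) && !is.null(travel)) {
    partition <- partition_all_taxa(fst_results, inputs$environment, travel,
                                    min_stations = cfg$partition$min_stations)
    if (!is.null(partition$proportions)) {
      pt <- as.data.frame(partition$proportions)
      write_tsv(cbind(species_id = rownames(pt), pt),
                file.path(out_dir, "variance_partition.tsv"))
    }
    jsonlite::write_json(
      lapply(partition$fits, function(f) {
        list(sigma2 = as.list(f$sigma2), residual = f$residual,
             mu = f$mu, converged = f$converged, n_iter = f$n_iter,
             loglik = f$loglik)
      }),
      file.path(out_dir, "variance_partition_fits.json"), auto_unbox = TRUE)
    say("partition: %d taxa fitted, %d excluded",
        length(partition$fits), length(partition$excluded))
    results$partition <- partition
  }

  # -- classify --------------------------------------------------------------
  if ("classify" %in% cfg$stages && !is.null(partition) &&
      !is.null(partition$proportions) &&
      nrow(partition$proportions) > 3 * cfg$classify$perplexity) {
    report <- classify_drivers(partition$proportions,
                               k = min(cfg$classify$k,
                                       nrow(partition$proportions)),
                               perplexity = cfg$classify$perplexity,
                               max_iter = cfg$classify$max_iter,
                               seed = cfg$seed)
    write_tsv(data.frame(species_id = names(report$labels),
                         cluster = report$labels,
                         tsne1 = report$embedding[, 1],
                         tsne2 = report$embedding[, 2]),
              file.path(out_dir, "driver_clusters.tsv"))
    jsonlite::write_json(report$drivers,
                         file.path(out_dir, "cluster_drivers.json"),
                         auto_unbox = TRUE)
    say("classify: %d clusters over %d taxa",
        length(unique(report$labels)), length(report$labels))
    results$classify <- report
  } else if ("classify" %in% cfg$stages) {
    say("classify: skipped (too few partitioned taxa)")
  }

  # -- manifest --------------------------------------------------------------
  artifacts <- setdiff(list.files(out_dir), c("run.log", "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("mvspop")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    counts = counts,
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(artifacts))))
  )
  names(manifest$checksums) <- sort(artifacts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  say("done: %d artifacts", length(artifacts))
  invisible(results)
}
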