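#' Simulation configuration for the synthetic pipeline inputs
#'
#' Bundles the study conditions used to generate a fully synthetic dataset
#' with planted ground truth: per-taxon loci counts, negative-binomial
#' coverage, Balding-Nichols allele-frequency divergence, and a fraction of
#' unattributed noise SNPs.
#'
#' Defaults are the package's reference study conditions: 5 taxa of 300 loci
#' each, mean depth of coverage 30x with dispersion 5 (strongly overdispersed,
#' as in shotgun metagenomic depth), 15 stations with 2 size-fraction samples
#' each, each taxon occurring at 5 stations (matching the 4-6 station
#' occurrence range typical of macro-scale plankton surveys), target F_ST
#' 0.2, and 10% noise SNPs.
#'
#' @param n_taxa number of planted taxa.
#' @param loci_per_taxon loci per taxon (recycled to `n_taxa`).
#' @param n_stations number of sampling stations.
#' @param samples_per_station samples (size fractions) per station.
#' @param stations_per_taxon number of consecutive stations occupied by each
#'   taxon (cyclic blocks), so neighbouring taxa overlap in range but keep
#'   distinct abundance profiles.
#' @param nb_dispersion negative-binomial dispersion of depth
#'   (variance = mean + mean^2/dispersion).
#' @param mean_abundance mean depth of coverage where a taxon is present.
#' @param fst_target Balding-Nichols divergence per taxon in \[0, 1)
#'   (recycled to `n_taxa`).
#' @param noise_snp_fraction fraction (of planted loci) of extra noise SNPs
#'   with unstructured abundance profiles.
#' @param seed integer master seed; a fixed seed makes every generator output
#'   byte-identical.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 5, loci_per_taxon = 300, n_stations = 15,
                              samples_per_station = 2, stations_per_taxon = 5,
                              nb_dispersion = 5, mean_abundance = 30,
                              fst_target = 0.2, noise_snp_fraction = 0.1,
                              seed = 1L) {
  counts <- c(n_taxa = n_taxa, n_stations = n_stations,
              samples_per_station = samples_per_station,
              stations_per_taxon = stations_per_taxon)
  if (any(counts < 1) || any(loci_per_taxon < 1)) {
    stop_param("all counts must be >= 1")
  }
  if (any(fst_target <= 0) || any(fst_target >= 1)) {
    stop_param("fst_target must lie in (0, 1)")
  }
  if (nb_dispersion <= 0) stop_param("nb_dispersion must be positive")
  if (any(mean_abundance <= 0)) stop_param("mean_abundance must be positive")
  if (noise_snp_fraction < 0 || noise_snp_fraction > 1) {
    stop_param("noise_snp_fraction must lie in [0, 1]")
  }
  structure(list(
    n_taxa = as.integer(n_taxa),
    loci_per_taxon = rep_len(as.integer(loci_per_taxon), n_taxa),
    n_stations = as.integer(n_stations),
    samples_per_station = as.integer(samples_per_station),
    stations_per_taxon = as.integer(stations_per_taxon),
    nb_dispersion = nb_dispersion,
    mean_abundance = mean_abundance,
    fst_target = rep_len(fst_target, n_taxa),
    noise_snp_fraction = noise_snp_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate population allele frequencies under the Balding-Nichols model
#'
#' For ancestral frequency p and divergence F, each population's frequency is
#' drawn independently per locus from Beta(p(1-F)/F, (1-p)(1-F)/F), whose
#' across-population variance is p(1-p)F — so F is the expected per-variant
#' F_ST of the planted truth.
#'
#' @param ancestral_freqs vector of ancestral frequencies in (0, 1), one per
#'   locus.
#' @param n_populations number of populations.
#' @param fst_target divergence F in (0, 1).
#' @param seed optional integer seed.
#' @return `n_populations` x `n_loci` matrix of frequencies.
#' @export
simulate_allele_frequencies <- function(ancestral_freqs, n_populations,
                                        fst_target, seed = NULL) {
  if (fst_target <= 0 || fst_target >= 1) {
    stop_param("fst_target must lie in (0, 1)")
  }
  if (any(ancestral_freqs <= 0) || any(ancestral_freqs >= 1)) {
    stop_param("ancestral frequencies must lie in (0, 1)")
  }
  n_loci <- length(ancestral_freqs)
  shape_scale <- (1 - fst_target) / fst_target
  a <- ancestral_freqs * shape_scale
  b <- (1 - ancestral_freqs) * shape_scale
  with_seed(seed, {
    matrix(stats::rbeta(n_populations * n_loci,
                        rep(a, each = n_populations),
                        rep(b, each = n_populations)),
           nrow = n_populations, ncol = n_loci)
  })
}

#' Simulate negative-binomial depth of coverage with per-taxon covariation
#'
#' All loci of one taxon share that taxon's per-sample abundance profile, so
#' their depths covary across samples — the signal the density clustering
#' stage recovers.  Depth of locus l (of taxon t) in sample s is drawn
#' NegBinom(mean = abundance\[t, s\], dispersion), with
#' variance = mean + mean^2/dispersion.
#'
#' @param abundance taxa x samples matrix of non-negative mean depths; a zero
#'   abundance yields depth 0 (taxon absent from the sample).
#' @param loci_per_taxon integer vector of loci counts per taxon (recycled).
#' @param nb_dispersion positive dispersion parameter.
#' @param seed optional integer seed.
#' @return loci x samples integer matrix of depths, with attribute
#'   `taxon_of_locus` giving each row's taxon index.
#' @export
simulate_coverage <- function(abundance, loci_per_taxon, nb_dispersion,
                              seed = NULL) {
  if (nb_dispersion <= 0) stop_param("nb_dispersion must be positive")
  abundance <- as.matrix(abundance)
  if (any(abundance < 0)) stop_param("abundances must be non-negative")
  n_taxa <- nrow(abundance)
  n_samples <- ncol(abundance)
  loci_per_taxon <- rep_len(as.integer(loci_per_taxon), n_taxa)
  taxon_of_locus <- rep(seq_len(n_taxa), loci_per_taxon)
  mu <- abundance[taxon_of_locus, , drop = FALSE]
  with_seed(seed, {
    depth <- matrix(stats::rnbinom(length(mu), size = nb_dispersion,
                                   mu = as.vector(mu)),
                    nrow = nrow(mu), ncol = n_samples,
                    dimnames = list(NULL, colnames(abundance)))
    attr(depth, "taxon_of_locus") <- taxon_of_locus
    depth
  })
}

#' Simulate allele read counts and assemble a SNP table
#'
#' The minor-allele read count of each locus x sample cell is Binomial(depth,
#' freq of the sample's population); the major count is the remainder, so the
#' two allele counts always sum to the observed depth.
#'
#' @param freqs populations x loci frequency matrix (row names are
#'   population/station ids).
#' @param depths loci x samples depth matrix (column names are sample ids).
#' @param station_of_sample named character vector sample -> population id;
#'   every sample must map to a row of `freqs`.
#' @param seed optional integer seed.
#' @param locus_ids optional locus identifiers (default `L1..Ln`).
#' @return a [snp_table()]; the alternate allele carries the simulated minor
#'   count.
#' @export
simulate_read_counts <- function(freqs, depths, station_of_sample, seed = NULL,
                                 locus_ids = NULL) {
  n_loci <- nrow(depths)
  n_samples <- ncol(depths)
  if (ncol(freqs) != n_loci) {
    stop_input("freqs loci dimension does not match depths")
  }
  sample_ids <- colnames(depths) %||% paste0("S", seq_len(n_samples))
  colnames(depths) <- sample_ids
  pops <- station_of_sample[sample_ids]
  if (anyNA(pops) || !all(pops %in% rownames(freqs))) {
    stop_input("every sample must map to a simulated population")
  }
  locus_ids <- locus_ids %||% paste0("L", seq_len(n_loci))
  with_seed(seed, {
    # probability of the minor allele per cell, in locus-major order
    p <- t(freqs[pops, , drop = FALSE])          # loci x samples
    minor <- matrix(stats::rbinom(n_loci * n_samples, size = as.vector(depths),
                                  prob = as.vector(p)),
                    nrow = n_loci, ncol = n_samples)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_loci, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    counts <- array(0L, dim = c(n_loci, n_samples, 2L))
    counts[, , 1L] <- depths - minor
    counts[, , 2L] <- minor
    snp_table(locus_ids, cbind(ref, alt), counts, sample_ids,
              station_of_sample)
  })
}

#' Simulate drifter trajectories in a toy ocean
#'
#' Fixed-step Euler advection by the ocean's velocity field plus an isotropic
#' Gaussian displacement of variance `2 * diffusion * step` per step, with
#' reflecting domain boundaries (positions are folded back inside, so drifters
#' always stay in the domain).  Roughly half the drifters are flagged drogued.
#'
#' @param ocean a [toy_ocean()].
#' @param n_drifters number of drifters, released uniformly over the domain.
#' @param duration_days trajectory length in days.
#' @param step_days Euler step in days (must divide the duration usefully).
#' @param seed optional integer seed.
#' @return data.frame with columns `id`, `time_days`, `lon`, `lat`, `drogued`.
#' @export
simulate_drifters <- function(ocean, n_drifters, duration_days, step_days = 1,
                              seed = NULL) {
  if (step_days <= 0) stop_param("step_days must be positive")
  if (duration_days < step_days) stop_param("duration must be >= step")
  n_steps <- floor(duration_days / step_days)
  with_seed(seed, {
    lon <- stats::runif(n_drifters, ocean$lon_range[1], ocean$lon_range[2])
    lat <- stats::runif(n_drifters, ocean$lat_range[1], ocean$lat_range[2])
    drogued <- as.integer(stats::runif(n_drifters) < 0.5)
    sd_step <- sqrt(2 * ocean$diffusion * step_days)
    lons <- matrix(NA_real_, n_steps + 1L, n_drifters)
    lats <- matrix(NA_real_, n_steps + 1L, n_drifters)
    lons[1L, ] <- lon
    lats[1L, ] <- lat
    for (k in seq_len(n_steps)) {
      vel <- ocean_velocity(ocean, lon, lat)
      lon <- lon + vel$u * step_days + stats::rnorm(n_drifters, 0, sd_step)
      lat <- lat + vel$v * step_days + stats::rnorm(n_drifters, 0, sd_step)
      lon <- reflect_into(lon, ocean$lon_range)
      lat <- reflect_into(lat, ocean$lat_range)
      lons[k + 1L, ] <- lon
      lats[k + 1L, ] <- lat
    }
    data.frame(
      id = rep(paste0("D", seq_len(n_drifters)), each = n_steps + 1L),
      time_days = rep(seq(0, by = step_days, length.out = n_steps + 1L),
                      times = n_drifters),
      lon = as.vector(lons),
      lat = as.vector(lats),
      drogued = rep(drogued, each = n_steps + 1L)
    )
  })
}

# fold positions back into [lo, hi] (reflecting boundary)
reflect_into <- function(x, range) {
  lo <- range[1]
  hi <- range[2]
  w <- hi - lo
  # map into a 2w-periodic sawtooth then reflect
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

#' Default environmental gradient specification
#'
#' Smooth, mutually distinct spatial gradients for the five World Ocean
#' Atlas style parameters: temperature decreasing with absolute latitude,
#' salinity increasing eastward, and the three nutrients along mixed
#' directions.  Units: degC for temperature, unitless salinity, umol/L for
#' nitrate, phosphate and silicate.
#'
#' @return named list of per-parameter specs
#'   (`base`, `lon_slope`, `lat_slope` on absolute latitude, `noise_sd`).
#' @export
default_gradients <- function() {
  list(
    temperature = list(base = 28, lon_slope = 0,     lat_slope = -0.35, noise_sd = 0.3),
    salinity    = list(base = 34, lon_slope = 0.12,  lat_slope = 0,     noise_sd = 0.1),
    nitrate     = list(base = 1,  lon_slope = 0.2,   lat_slope = 0.05,  noise_sd = 0.1),
    phosphate   = list(base = 0.1, lon_slope = 0.012, lat_slope = 0.002, noise_sd = 0.01),
    silicate    = list(base = 2,  lon_slope = -0.08, lat_slope = 0.15,  noise_sd = 0.15)
  )
}

#' Simulate per-station environmental measurements
#'
#' Each parameter is a smooth function of longitude and absolute latitude
#' plus Gaussian noise, one value per station.
#'
#' @param stations data.frame with columns `station_id`, `lon`, `lat`.
#' @param gradient_spec per-parameter spec as in [default_gradients()].
#' @param seed optional integer seed.
#' @return data.frame: `station_id` plus one column per parameter.
#' @export
simulate_environment <- function(stations, gradient_spec = default_gradients(),
                                 seed = NULL) {
  with_seed(seed, {
    out <- data.frame(station_id = stations$station_id,
                      stringsAsFactors = FALSE)
    for (nm in names(gradient_spec)) {
      g <- gradient_spec[[nm]]
      out[[nm]] <- g$base + g$lon_slope * stations$lon +
        g$lat_slope * abs(stations$lat) +
        stats::rnorm(nrow(stations), 0, g$noise_sd)
    }
    out
  })
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Composes the five generators into the pipeline's full input set: a SNP
#' table (planted taxa plus noise SNPs), station metadata with basin labels,
#' an environmental table, drifter trajectories, and a ground-truth list.
#' Taxa occupy cyclic blocks of consecutive stations with mean depth
#' `mean_abundance` there and zero elsewhere; noise SNPs get independent
#' random station supports.  Truth (taxon of each locus, per-taxon F target
#' and home stations) is returned separately — and written to a side file when
#' `dir` is given — never inside the pipeline inputs.
#'
#' @param config a [simulation_config()].
#' @param ocean a [toy_ocean()] providing domain, currents and basin labels.
#' @param n_drifters,duration_days drifter simulation size (defaults 300
#'   drifters for 120 days at a 1-day step).
#' @param dir optional output directory; when given, writes `snp.tsv`,
#'   `stations.tsv`, `environment.tsv`, `trajectories.tsv`, `samples.tsv` and
#'   `truth.json`.
#' @return list with elements `snp_table`, `stations`, `environment`,
#'   `trajectories`, `truth`.
#' @export
simulate_dataset <- function(config, ocean = toy_ocean(),
                             n_drifters = 300, duration_days = 120,
                             dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  n_st <- config$n_stations
  # stations along the domain's central latitude
  lon <- seq(ocean$lon_range[1], ocean$lon_range[2],
             length.out = n_st + 2L)[-c(1L, n_st + 2L)]
  lat <- rep(mean(ocean$lat_range), n_st)
  stations <- data.frame(
    station_id = sprintf("ST%02d", seq_len(n_st)),
    lon = lon, lat = lat,
    basin = ocean_basin(ocean, lon, lat),
    stringsAsFactors = FALSE
  )
  sample_ids <- as.vector(t(outer(stations$station_id,
                                  paste0("f", seq_len(config$samples_per_station)),
                                  paste, sep = ".")))
  station_of_sample <- stats::setNames(rep(stations$station_id,
                                           each = config$samples_per_station),
                                       sample_ids)

  # per-taxon home stations: cyclic blocks of consecutive stations, block
  # starts spread evenly so neighbouring taxa overlap in range but keep
  # distinct abundance profiles
  stride <- max(1L, round(n_st / config$n_taxa))
  homes <- lapply(seq_len(config$n_taxa), function(t) {
    start <- (t - 1L) * stride
    idx <- (start + seq_len(config$stations_per_taxon) - 1L) %% n_st + 1L
    stations$station_id[sort(unique(idx))]
  })
  abundance <- matrix(0, config$n_taxa, length(sample_ids),
                      dimnames = list(NULL, sample_ids))
  for (t in seq_len(config$n_taxa)) {
    abundance[t, station_of_sample %in% homes[[t]]] <- config$mean_abundance
  }

  depth <- simulate_coverage(abundance, config$loci_per_taxon,
                             config$nb_dispersion, seed = seed)
  taxon_of_locus <- attr(depth, "taxon_of_locus")

  # planted allele frequencies, one Balding-Nichols draw per taxon
  n_planted <- nrow(depth)
  freqs <- matrix(0.5, n_st, n_planted,
                  dimnames = list(stations$station_id, NULL))
  anc <- with_seed(seed + 1L, stats::runif(n_planted, 0.1, 0.5))
  col0 <- 0L
  for (t in seq_len(config$n_taxa)) {
    nl <- config$loci_per_taxon[t]
    freqs[, col0 + seq_len(nl)] <- simulate_allele_frequencies(
      anc[col0 + seq_len(nl)], n_st, config$fst_target[t],
      seed = seed + 100L + t)
    col0 <- col0 + nl
  }

  # noise SNPs: independent random supports and frequencies
  n_noise <- round(config$noise_snp_fraction * n_planted)
  if (n_noise > 0) {
    noise <- with_seed(seed + 2L, {
      nd <- matrix(0L, n_noise, length(sample_ids))
      for (i in seq_len(n_noise)) {
        sup <- sample(length(sample_ids), sample(2:6, 1L))
        nd[i, sup] <- stats::rnbinom(length(sup), size = config$nb_dispersion,
                                     mu = config$mean_abundance)
      }
      nf <- matrix(stats::runif(n_st * n_noise), n_st, n_noise)
      list(depth = nd, freqs = nf)
    })
    depth_all <- rbind(depth, noise$depth)
    freqs_all <- cbind(freqs, noise$freqs)
  } else {
    depth_all <- depth
    freqs_all <- freqs
  }
  colnames(depth_all) <- sample_ids

  tab <- simulate_read_counts(freqs_all, depth_all, station_of_sample,
                              seed = seed + 3L)
  environment_tab <- simulate_environment(stations, seed = seed + 4L)
  trajectories <- simulate_drifters(ocean, n_drifters, duration_days,
                                    step_days = 1, seed = seed + 5L)

  truth <- list(
    taxon_of_locus = stats::setNames(
      c(paste0("taxon", taxon_of_locus),
        rep("noise", nrow(depth_all) - n_planted)),
      tab$locus_id),
    fst_target = stats::setNames(config$fst_target,
                                 paste0("taxon", seq_len(config$n_taxa))),
    home_stations = stats::setNames(homes,
                                    paste0("taxon", seq_len(config$n_taxa)))
  )

  out <- list(snp_table = tab, stations = stations,
              environment = environment_tab, trajectories = trajectories,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_snp_table(tab, file.path(dir, "snp.tsv"))
    write_tsv(stations, file.path(dir, "stations.tsv"))
    write_tsv(environment_tab, file.path(dir, "environment.tsv"))
    write_tsv(trajectories, file.path(dir, "trajectories.tsv"))
    write_tsv(data.frame(sample_id = sample_ids,
                         station_id = station_of_sample[sample_ids]),
              file.path(dir, "samples.tsv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE)
  }
  out
}
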