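#' Configuration for the synthetic hierarchical landscape
#'
#' Defaults reproduce the nested survey design of the study system: 11 rocky
#' reef sites along an ~80 km coastline, 2-3 transects per site (27 in all),
#' one triplicate-bottle transect per site plus single bottles at the rest
#' (49 bottles), lognormal species-abundance structure with site-level species
#' sorting, multinomial read sampling at observed depths, and a visual-census
#' observation process with taxon-specific detectability.
#'
#' @param n_sites number of sites placed along the coastline.
#' @param transects_per_site integer vector, transects at each site (summing
#'   to 27 under the default design).
#' @param coastline_km coastline length over which sites are spread.
#' @param within_site_spread_m range (m) of transect jitter within a site.
#' @param pool_size regional taxon pool size.
#' @param sorting_strength theta in \[0, 1\]: 0 = all sites share one regional
#'   composition, 1 = fully site-sorted composition.
#' @param sort_scale log-abundance scale of the site-sorting field.
#' @param range_km range of the exponential spatial correlation of site
#'   composition (drives distance decay).
#' @param sad_sd lognormal standard deviation of the regional species
#'   abundance distribution.
#' @param transect_sd lognormal sd of transect-level abundance noise.
#' @param bottle_sd lognormal sd of technical noise among replicate bottles.
#' @param read_depth_range integer interval from which per-bottle sequencing
#'   depth is drawn uniformly.
#' @param detect_shape shape parameters of the Beta distribution from which
#'   per-taxon visual detectability is drawn.
#' @param uvc_density_scale expected total fish density per transect used in
#'   the detection model.
#' @param uvc_sd lognormal sd of biomass observation noise.
#' @param mass_sd lognormal sd of per-taxon body-mass factors.
#' @param site_overlap `"mixture"` (default; lognormal site fields) or
#'   `"disjoint"` (each site supported on its own taxon subset - the fully
#'   sorted limit used in tests).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_sites = 11,
                              transects_per_site = c(rep(3L, 5), rep(2L, 6)),
                              coastline_km = 80,
                              within_site_spread_m = c(20, 100),
                              pool_size = 80,
                              sorting_strength = 1,
                              sort_scale = 4,
                              range_km = 25,
                              sad_sd = 3,
                              transect_sd = 0.8,
                              bottle_sd = 0.4,
                              read_depth_range = c(1413L, 22013L),
                              detect_shape = c(0.7, 2),
                              uvc_density_scale = 400,
                              uvc_sd = 0.8,
                              mass_sd = 1.2,
                              site_overlap = c("mixture", "disjoint")) {
  site_overlap <- match.arg(site_overlap)
  if (length(transects_per_site) != n_sites) {
    stop("transects_per_site must have one entry per site")
  }
  if (any(transects_per_site < 1)) stop("each site needs at least 1 transect")
  if (sorting_strength < 0 || sorting_strength > 1) {
    stop("sorting_strength must lie in [0, 1]")
  }
  if (any(read_depth_range <= 0) || diff(read_depth_range) < 0) {
    stop("read_depth_range must be a positive, non-decreasing interval")
  }
  cfg <- list(n_sites = n_sites, transects_per_site = as.integer(transects_per_site),
              coastline_km = coastline_km,
              within_site_spread_m = within_site_spread_m,
              pool_size = pool_size, sorting_strength = sorting_strength,
              sort_scale = sort_scale, range_km = range_km, sad_sd = sad_sd,
              transect_sd = transect_sd, bottle_sd = bottle_sd,
              read_depth_range = as.integer(read_depth_range),
              detect_shape = detect_shape,
              uvc_density_scale = uvc_density_scale, uvc_sd = uvc_sd,
              mass_sd = mass_sd, site_overlap = site_overlap)
  class(cfg) <- "simulation_config"
  cfg
}

# coastline km -> decimal degrees at a fixed reference latitude, so that
# haversine distances on the 6371-km sphere recover the along-shore spacing
.ref_lat <- 34.0
.km_per_deg_lon <- function(lat) pi / 180 * 6371 * cos(lat * pi / 180)

.km_to_lon <- function(km) km / .km_per_deg_lon(.ref_lat)

#' Simulate a hierarchical sampling landscape
#'
#' Places sites evenly along a one-dimensional coastline, jitters transects
#' within sites, and draws a ground-truth composition for every transect:
#' site log-abundance is `mu + theta * sort_scale * Z` where `mu` is a shared
#' lognormal regional profile and `Z` a site-level Gaussian field with
#' exponential spatial correlation (range `range_km`), so composition decays
#' in similarity with distance; transect composition adds lognormal noise of
#' sd `transect_sd` and is renormalized.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; fixed seed gives an identical landscape.
#' @return a list with elements `design_edna` and `design_uvc` (both
#'   [sample_design()] tables), and `truth`: per-transect relative abundances
#'   (`p_transect`), site compositions (`p_site`), per-taxon detectability
#'   (`p_detect`) and body-mass factors (`mass`), the theta used, and the
#'   transect table with along-shore positions.
#' @export
simulate_landscape <- function(config = simulation_config(), seed = NULL) {
  with_seed(seed, {
    S <- config$pool_size
    theta <- config$sorting_strength
    site_pos <- seq(0, config$coastline_km, length.out = config$n_sites)

    # transect table: first transect of each site carries the bottle triplicate
    tr <- do.call(rbind, lapply(seq_len(config$n_sites), function(s) {
      nt <- config$transects_per_site[s]
      jit <- runif(nt, config$within_site_spread_m[1],
                   config$within_site_spread_m[2]) / 1000 *
        sample(c(-1, 1), nt, replace = TRUE)
      data.frame(site = s, transect = seq_len(nt),
                 pos_km = site_pos[s] + jit,
                 triplicate = seq_len(nt) == 1L)
    }))
    tr$transect_id <- sprintf("S%02d.T%d", tr$site, tr$transect)
    tr$site_id <- sprintf("S%02d", tr$site)

    mu <- rnorm(S, 0, config$sad_sd)
    if (config$site_overlap == "disjoint") {
      # fully sorted limit: each site supported on its own block of taxa
      block <- split(seq_len(S),
                     cut(seq_len(S), config$n_sites, labels = FALSE))
      la_site <- matrix(-Inf, config$n_sites, S)
      for (s in seq_len(config$n_sites)) la_site[s, block[[s]]] <- mu[block[[s]]]
    } else {
      Dsite <- abs(outer(site_pos, site_pos, "-"))
      L <- chol(exp(-Dsite / config$range_km) + diag(1e-8, config$n_sites))
      Z <- t(L) %*% matrix(rnorm(config$n_sites * S), config$n_sites, S)
      la_site <- outer(rep(1, config$n_sites), mu) + theta * config$sort_scale * Z
    }
    la_tr <- la_site[tr$site, , drop = FALSE] +
      matrix(rnorm(nrow(tr) * S, 0, config$transect_sd), nrow(tr), S)

    softmax_rows <- function(m) {
      e <- exp(m - apply(m, 1, max))
      e[!is.finite(e)] <- 0
      e / rowSums(e)
    }
    p_site <- softmax_rows(la_site)
    p_tr <- softmax_rows(la_tr)
    taxa <- sprintf("taxon_%03d", seq_len(S))
    colnames(p_site) <- colnames(p_tr) <- taxa
    rownames(p_tr) <- tr$transect_id

    p_detect <- rbeta(S, config$detect_shape[1], config$detect_shape[2])
    mass <- exp(rnorm(S, 0, config$mass_sd))
    names(p_detect) <- names(mass) <- taxa

    lon <- .km_to_lon(tr$pos_km)
    design_uvc <- sample_design(data.frame(
      sample_id = tr$transect_id, method = "UVC", site_id = tr$site_id,
      transect_id = tr$transect_id, replicate_id = "",
      lat = .ref_lat, lon = lon, stringsAsFactors = FALSE))

    bot <- tr[rep(seq_len(nrow(tr)), ifelse(tr$triplicate, 3L, 1L)), ]
    bot$rep <- unlist(lapply(ifelse(tr$triplicate, 3L, 1L), seq_len))
    bot$sample_id <- sprintf("%s.B%d", bot$transect_id, bot$rep)
    design_edna <- sample_design(data.frame(
      sample_id = bot$sample_id, method = "eDNA", site_id = bot$site_id,
      transect_id = bot$transect_id, replicate_id = sprintf("B%d", bot$rep),
      lat = .ref_lat, lon = .km_to_lon(bot$pos_km), stringsAsFactors = FALSE))

    truth <- list(p_transect = p_tr, p_site = p_site, theta = theta,
                  transects = tr, p_detect = p_detect, mass = mass,
                  taxa = taxa)
    list(design_edna = design_edna, design_uvc = design_uvc, truth = truth)
  })
}

#' Simulate eDNA read counts for the bottle design
#'
#' Each bottle inherits its transect's true composition, perturbed by
#' lognormal technical noise (`bottle_sd`) and renormalized; sequencing depth
#' is drawn uniformly from `read_depth_range` and reads are multinomial.
#'
#' @param landscape result of [simulate_landscape()].
#' @param config the [simulation_config()] used to build the landscape.
#' @param seed integer seed.
#' @return a `community_matrix` (mode `"reads"`), one row per bottle.
#' @export
simulate_edna_reads <- function(landscape, config = simulation_config(),
                                seed = NULL) {
  with_seed(seed, {
    des <- landscape$design_edna
    p_tr <- landscape$truth$p_transect
    S <- ncol(p_tr)
    depth_seq <- seq(config$read_depth_range[1], config$read_depth_range[2])
    depths <- depth_seq[sample.int(length(depth_seq), nrow(des),
                                   replace = TRUE)]
    m <- matrix(0L, nrow(des), S,
                dimnames = list(des$sample_id, colnames(p_tr)))
    for (i in seq_len(nrow(des))) {
      p <- p_tr[des$transect_id[i], ]
      if (config$bottle_sd > 0) {
        p <- p * exp(rnorm(S, 0, config$bottle_sd))
        p <- p / sum(p)
      }
      m[i, ] <- rmultinom(1, depths[i], p)[, 1]
    }
    community_matrix(m, "reads")
  })
}

#' Simulate an underwater-visual-census survey
#'
#' Divers miss taxa: a taxon of local density `d` is detected with probability
#' `1 - (1 - p_detect)^d`, so cryptic taxa (low `p_detect`) are systematically
#' under-represented. Detected taxa receive biomass
#' `density * mass * lognormal(0, uvc_sd)`.
#'
#' @inheritParams simulate_edna_reads
#' @param p_detect optional per-taxon detectability override (defaults to the
#'   landscape's drawn values).
#' @return a `community_matrix` (mode `"biomass"`), one row per transect.
#' @export
simulate_uvc_survey <- function(landscape, config = simulation_config(),
                                seed = NULL, p_detect = NULL) {
  with_seed(seed, {
    des <- landscape$design_uvc
    p_tr <- landscape$truth$p_transect
    pd <- p_detect %||% landscape$truth$p_detect
    mass <- landscape$truth$mass
    S <- ncol(p_tr)
    m <- matrix(0, nrow(des), S,
                dimnames = list(des$sample_id, colnames(p_tr)))
    for (i in seq_len(nrow(des))) {
      dens <- p_tr[des$transect_id[i], ] * config$uvc_density_scale
      pdet <- 1 - (1 - pd)^dens
      det <- runif(S) < pdet
      if (any(det)) {
        noise <- if (config$uvc_sd > 0) exp(rnorm(sum(det), 0, config$uvc_sd)) else 1
        m[i, det] <- dens[det] * mass[det] * noise
      }
    }
    community_matrix(m, "biomass")
  })
}

#' Simulate a complete paired survey
#'
#' Convenience wrapper: landscape plus eDNA and UVC community matrices from a
#' single seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `design_edna`, `design_uvc`, `truth`, `edna` (reads) and
#'   `uvc` (biomass).
#' @export
simulate_study <- function(config = simulation_config(), seed = NULL) {
  with_seed(seed, {
    ls <- simulate_landscape(config)
    list(design_edna = ls$design_edna, design_uvc = ls$design_uvc,
         truth = ls$truth,
         edna = simulate_edna_reads(ls, config),
         uvc = simulate_uvc_survey(ls, config))
  })
}
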