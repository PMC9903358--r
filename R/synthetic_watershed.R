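#' Configuration for the synthetic watershed generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate a
#' Puget-Lowland-like study region: a dendritic network of ~1 km segments,
#' urban-gradient land cover with a dominant catchment-forest effect on the
#' biotic index, modest natural/artificial barrier densities, and national-
#' style 0-1 integrity indices built by mixing stressors. The default index
#' weights give forest condition zero weight, so the synthetic catchment
#' index is blind to the covariate that actually drives condition -- the
#' dilution mechanism that makes a national indicator insufficient
#' regionally and motivates substituting a regional one.
#'
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param n_catchments number of segments/catchments (>= 2; default 500).
#' @param n_sites number of monitored sites (default `min(177,
#'   n_catchments)`, one per sampled catchment).
#' @param length_meanlog,length_sdlog lognormal parameters of segment
#'   length in km (defaults give ~1.2 km median reaches).
#' @param barrier_intensity list with elements `mainstem` and `tributary`,
#'   each a named vector of expected barrier counts per km for
#'   `large_lake`, `small_lake`, `swamp_marsh`, `road_crossing`, `dam`.
#'   Large lakes are only ever placed on the mainstem.
#' @param beta named vector of true standardized effects of catchment/
#'   watershed covariates on the biotic index (forest-dominant by default).
#' @param intercept,response_scale the site linear predictor is
#'   `intercept + response_scale * Z beta` on the 0-100 B-IBI scale.
#' @param sigma_site SD of unexplained site-level variation (B-IBI points).
#' @param sigma_sample SD of within-site year-to-year sample noise.
#' @param samples_per_site integer vector of possible repeated-sample
#'   counts per site (default 3:8 yearly visits).
#' @param index_weights named stressor weights (summing to <= 1) used to
#'   build the synthetic integrity indices as `1 - sum(w * stressor)`;
#'   the `forest` weight defaults to 0.
#' @param disturbance_prob probability that a catchment is heavily
#'   disturbed (default 0.15), shifting its barren and forest-loss
#'   distributions upward; disturbance is independent of forest cover, so
#'   the indices stay blind to the forest gradient while still marking
#'   some catchments as low integrity.
#' @param p_good_logit_sd SD of logit-scale prediction error on the
#'   per-segment probability of good condition (default 1), representing
#'   that `p_good` is an imperfect model output rather than a function of
#'   the true drivers.
#' @return List of class `watershed_config`.
#' @export
watershed_config <- function(seed = 1L,
                             n_catchments = 500L,
                             n_sites = min(177L, n_catchments),
                             length_meanlog = log(1.2),
                             length_sdlog = 0.6,
                             barrier_intensity = list(
                               mainstem = c(large_lake = 0.02,
                                            small_lake = 0.05,
                                            swamp_marsh = 0.10,
                                            road_crossing = 0.40,
                                            dam = 0.01),
                               tributary = c(large_lake = 0,
                                             small_lake = 0.05,
                                             swamp_marsh = 0.10,
                                             road_crossing = 0.40,
                                             dam = 0.005)),
                             beta = c(pct_forest_cat = 0.62,
                                      pct_barren_ws = -0.17,
                                      pct_forest_loss_cat = -0.20,
                                      sn_deposition_cat = -0.15),
                             intercept = 54,
                             response_scale = 16,
                             sigma_site = 8,
                             sigma_sample = 5,
                             samples_per_site = 3:8,
                             index_weights = c(forest = 0,
                                               barren = 0.30,
                                               forest_loss = 0.40,
                                               deposition = 0.30),
                             disturbance_prob = 0.15,
                             p_good_logit_sd = 1) {
  stopifnot(n_catchments >= 2L, n_sites >= 1L, n_sites <= n_catchments,
            sigma_site > 0, sigma_sample > 0, response_scale > 0)
  for (side in c("mainstem", "tributary")) {
    iv <- barrier_intensity[[side]]
    if (is.null(iv) || any(iv < 0) ||
        !all(BARRIER_TYPES %in% names(iv))) {
      stop("barrier_intensity$", side,
           " must be a non-negative vector naming every barrier type")
    }
  }
  if (any(index_weights < 0) || sum(index_weights) > 1 + 1e-9) {
    stop("index_weights must be non-negative and sum to at most 1")
  }
  stopifnot(disturbance_prob >= 0, disturbance_prob <= 1,
            p_good_logit_sd >= 0)
  structure(list(seed = as.integer(seed), n_catchments = as.integer(n_catchments),
                 n_sites = as.integer(n_sites),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 barrier_intensity = barrier_intensity, beta = beta,
                 intercept = intercept, response_scale = response_scale,
                 sigma_site = sigma_site, sigma_sample = sigma_sample,
                 samples_per_site = samples_per_site,
                 index_weights = index_weights,
                 disturbance_prob = disturbance_prob,
                 p_good_logit_sd = p_good_logit_sd),
            class = "watershed_config")
}

#' Named simulation scenarios
#'
#' `smoke` is a 20-catchment / 10-site scenario for quick checks;
#' `kingcounty-analog` is the full default: 500 catchments, 177 sites,
#' forest-dominant effects and a forest-blind synthetic catchment index.
#'
#' @param name `"smoke"` or `"kingcounty-analog"`.
#' @param seed integer seed.
#' @param ... overrides passed to [watershed_config()].
#' @return A [watershed_config()].
#' @export
scenario_config <- function(name = c("kingcounty-analog", "smoke"),
                            seed = 1L, ...) {
  name <- match.arg(name)
  if (name == "smoke") {
    watershed_config(seed = seed, n_catchments = 20L, n_sites = 10L, ...)
  } else {
    watershed_config(seed = seed, ...)
  }
}

#' Simulate a dendritic stream network
#'
#' Grows a random recursive in-tree: segment i (i >= 2) drains into a
#' uniformly chosen earlier segment, giving a dendritic topology with one
#' outlet; lengths are lognormal; one local catchment per segment. The
#' mainstem is flagged by starting at the outlet and repeatedly following
#' the upstream neighbour whose subtree has the greatest total stream
#' length (ties to the earliest segment).
#'
#' @param config a [watershed_config()].
#' @return A [stream_network()].
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "watershed_config"))
  n <- config$n_catchments
  set.seed(config$seed)
  down <- c(NA_integer_,
            vapply(seq_len(n - 1L), function(i) sample.int(i, 1L),
                   integer(1)))
  len <- stats::rlnorm(n, config$length_meanlog, config$length_sdlog)

  # subtree total length; parents always precede children (index order)
  acc <- len
  for (i in seq.int(n, 2L)) acc[down[i]] <- acc[down[i]] + acc[i]

  up <- rep(list(integer(0)), n)
  for (i in seq.int(2L, n)) up[[down[i]]] <- c(up[[down[i]]], i)
  mainstem <- logical(n)
  j <- 1L # the outlet
  repeat {
    mainstem[j] <- TRUE
    kids <- up[[j]]
    if (length(kids) == 0L) break
    j <- kids[which.max(acc[kids])]
  }

  seg <- data.frame(
    segment_id = sprintf("s%04d", seq_len(n)),
    downstream_id = ifelse(is.na(down), NA_character_,
                           sprintf("s%04d", down)),
    length_km = len, mainstem = mainstem,
    catchment_id = sprintf("c%04d", seq_len(n)))
  stream_network(seg)
}

#' Simulate monitoring sites and barriers on a network
#'
#' Places one site per sampled catchment at a uniform offset along its
#' segment, and barriers of each type as independent Poisson processes with
#' the configured per-km intensity (mainstem and tributary intensities
#' differ; large lakes occur only on the mainstem).
#'
#' @param network a [stream_network()].
#' @param config a [watershed_config()].
#' @return List with `sites` (site_id, segment_id, offset_km,
#'   catchment_id) and `barriers` (barrier_id, barrier_type, segment_id,
#'   offset_km).
#' @export
simulate_sites_barriers <- function(network, config) {
  stopifnot(inherits(config, "watershed_config"))
  seg <- network$segments
  n <- nrow(seg)
  set.seed(config$seed + 1L)
  picked <- sort(sample.int(n, config$n_sites))
  sites <- data.frame(
    site_id = sprintf("site%04d", seq_along(picked)),
    segment_id = seg$segment_id[picked],
    offset_km = stats::runif(length(picked)) * seg$length_km[picked],
    catchment_id = seg$catchment_id[picked])

  rows <- list()
  for (ty in BARRIER_TYPES) {
    lam <- ifelse(seg$mainstem,
                  config$barrier_intensity$mainstem[[ty]],
                  config$barrier_intensity$tributary[[ty]]) * seg$length_km
    counts <- stats::rpois(n, lam)
    idx <- rep.int(seq_len(n), counts)
    if (length(idx) > 0L) {
      rows[[ty]] <- data.frame(
        barrier_type = ty, segment_id = seg$segment_id[idx],
        offset_km = stats::runif(length(idx)) * seg$length_km[idx])
    }
  }
  barriers <- if (length(rows) > 0L) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(barrier_type = character(0), segment_id = character(0),
               offset_km = numeric(0))
  }
  barriers <- cbind(barrier_id = sprintf("b%05d", seq_len(nrow(barriers))),
                    barriers)
  rownames(barriers) <- NULL
  list(sites = sites, barriers = barriers)
}

# length-weighted mean of a catchment value over the watershed
# (the catchment plus all upstream catchments)
.accumulate_watershed <- function(network, value) {
  seg <- network$segments
  n <- nrow(seg)
  down <- network$down
  acc_len <- seg$length_km
  acc_sum <- seg$length_km * value
  # random recursive trees index parents before children, but user networks
  # need a real topological order: process segments headward-first
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    d <- 0L
    while (!is.na(down[j])) {
      j <- down[j]
      d <- d + 1L
    }
    depth[i] <- d
  }
  for (i in order(depth, decreasing = TRUE)) {
    if (!is.na(down[i])) {
      acc_len[down[i]] <- acc_len[down[i]] + acc_len[i]
      acc_sum[down[i]] <- acc_sum[down[i]] + acc_sum[i]
    }
  }
  acc_sum / acc_len
}

#' Simulate landscape covariates, integrity indices, and B-IBI response
#'
#' Draws per-catchment covariates (percent forest, barren, forest loss, a
#' sulfur+nitrogen deposition analogue, two pure-noise decoys and one
#' urban-correlated non-causal decoy), accumulates watershed-scale versions
#' as length-weighted upstream means, builds synthetic 0-1 catchment and
#' watershed integrity indices as one minus a weighted stressor mix (forest
#' weight 0 by default), and generates the response: each site's latent
#' mean B-IBI is `intercept + response_scale * Z beta` plus site-level
#' Gaussian noise, observed through repeated yearly samples with their own
#' noise, all clipped to \[0, 100\]. Per-segment `p_good` (probability of
#' good biological condition) is a logistic transform of the same linear
#' predictor, so source quality is monotone in true condition.
#'
#' @param network a [stream_network()].
#' @param sites site table from [simulate_sites_barriers()].
#' @param config a [watershed_config()].
#' @return List: `covariates` (one row per site: identifiers, all
#'   covariates, `ici`, `iwi`, `mean_bibi`), `samples` (site_id, year,
#'   bibi_score), `catchments` (per-catchment covariates and indices),
#'   `reach_attributes` (segment_id, p_good), and `truth` (beta used,
#'   per-site linear predictor and latent class, clipped fraction, seed).
#' @export
simulate_covariates_response <- function(network, sites, config) {
  stopifnot(inherits(config, "watershed_config"))
  seg <- network$segments
  n <- nrow(seg)
  set.seed(config$seed + 2L)

  # a disturbed minority of catchments (independent of forest cover)
  # carries heavy barren/forest-loss stressor loads
  disturbed <- stats::runif(n) < config$disturbance_prob
  cat_tab <- data.frame(
    catchment_id = seg$catchment_id, segment_id = seg$segment_id,
    disturbed = disturbed,
    pct_forest_cat = 100 * stats::rbeta(n, 1.5, 1.2),
    pct_barren_cat = 100 * stats::rbeta(n, ifelse(disturbed, 4, 1.2),
                                        ifelse(disturbed, 3, 9)),
    pct_forest_loss_cat = 100 * stats::rbeta(n, ifelse(disturbed, 5, 1.5),
                                             ifelse(disturbed, 2, 10)),
    sn_deposition_cat = stats::rlnorm(n, 1.6, 0.35),
    decoy_noise_1 = stats::rnorm(n),
    decoy_noise_2 = stats::rnorm(n))
  zf <- as.numeric(scale(100 - cat_tab$pct_forest_cat))
  cat_tab$decoy_urban_cat <- 0.5 * zf + sqrt(1 - 0.25) * stats::rnorm(n)

  for (v in c("pct_forest", "pct_barren", "pct_forest_loss",
              "sn_deposition")) {
    cat_tab[[paste0(v, "_ws")]] <-
      .accumulate_watershed(network, cat_tab[[paste0(v, "_cat")]])
  }

  w <- config$index_weights
  stress_cat <- w[["forest"]] * (1 - cat_tab$pct_forest_cat / 100) +
    w[["barren"]] * cat_tab$pct_barren_cat / 100 +
    w[["forest_loss"]] * cat_tab$pct_forest_loss_cat / 100 +
    w[["deposition"]] * pmin(cat_tab$sn_deposition_cat / 15, 1)
  stress_ws <- w[["forest"]] * (1 - cat_tab$pct_forest_ws / 100) +
    w[["barren"]] * cat_tab$pct_barren_ws / 100 +
    w[["forest_loss"]] * cat_tab$pct_forest_loss_ws / 100 +
    w[["deposition"]] * pmin(cat_tab$sn_deposition_ws / 15, 1)
  cat_tab$ici <- pmin(pmax(1 - stress_cat, 0), 1)
  cat_tab$iwi <- pmin(pmax(1 - stress_ws, 0), 1)

  beta <- config$beta
  if (!all(names(beta) %in% names(cat_tab))) {
    stop("beta names must be covariate columns: ",
         paste(setdiff(names(beta), names(cat_tab)), collapse = ", "))
  }
  z_cols <- vapply(names(beta), function(v) {
    as.numeric(scale(cat_tab[[v]]))
  }, numeric(n))
  lp_seg <- config$intercept +
    config$response_scale * as.numeric(z_cols %*% beta)
  # p_good mimics an externally modeled probability: centred on a monotone
  # transform of the segment's linear predictor, with logit-scale error
  reach_attributes <- data.frame(
    segment_id = seg$segment_id,
    p_good = stats::plogis((lp_seg - 50) / 8 +
                             stats::rnorm(n, 0, config$p_good_logit_sd)))

  si <- match(sites$segment_id, seg$segment_id)
  lp_site <- lp_seg[si]
  latent <- lp_site + stats::rnorm(nrow(sites), 0, config$sigma_site)
  n_samp <- sample(config$samples_per_site, nrow(sites), replace = TRUE)
  samp_site <- rep.int(seq_len(nrow(sites)), n_samp)
  raw_scores <- latent[samp_site] +
    stats::rnorm(length(samp_site), 0, config$sigma_sample)
  scores <- pmin(pmax(raw_scores, 0), 100)
  samples <- data.frame(
    site_id = sites$site_id[samp_site],
    year = 2011L + unlist(lapply(n_samp, seq_len)),
    bibi_score = scores)
  mean_bibi <- as.numeric(tapply(scores, samples$site_id, mean))
  mean_bibi <- mean_bibi[match(sites$site_id,
                               sort(unique(samples$site_id)))]

  covariates <- cbind(sites["site_id"],
                      cat_tab[si, setdiff(names(cat_tab), "catchment_id")],
                      catchment_id = sites$catchment_id,
                      mean_bibi = mean_bibi)
  rownames(covariates) <- NULL

  truth <- list(
    beta = beta, site_id = sites$site_id, linear_predictor = lp_site,
    latent_mean = latent,
    latent_class = condition_class(pmin(pmax(lp_site, 0), 100)),
    clipped_fraction = mean(raw_scores != scores),
    seed = config$seed)

  list(covariates = covariates, samples = samples, catchments = cat_tab,
       reach_attributes = reach_attributes, truth = truth)
}

#' Run the full synthetic watershed generator
#'
#' Convenience wrapper: network, sites and barriers, covariates, indices
#' and response, all reproducible from `config$seed`.
#'
#' @param config a [watershed_config()].
#' @return List of class `synthetic_watershed`: `network`, `sites`,
#'   `barriers`, `covariates`, `samples`, `catchments`,
#'   `reach_attributes`, `truth`, `config`.
#' @export
simulate_watershed <- function(config = watershed_config()) {
  network <- simulate_network(config)
  sb <- simulate_sites_barriers(network, config)
  cv <- simulate_covariates_response(network, sb$sites, config)
  structure(c(list(network = network, sites = sb$sites,
                   barriers = sb$barriers, config = config), cv),
            class = "synthetic_watershed")
}

#' @export
print.synthetic_watershed <- function(x, ...) {
  cat("<synthetic_watershed> seed ", x$config$seed, ": ",
      nrow(x$network$segments), " segments, ", nrow(x$sites), " sites, ",
      nrow(x$barriers), " barriers, ", nrow(x$samples), " samples\n",
      sep = "")
  invisible(x)
}

#' Write a simulated watershed as the package's CSV dialects
#'
#' Emits `segments.csv`, `sites.csv`, `barriers.csv`,
#' `reach_attributes.csv`, `covariates.csv`, `samples.csv` and
#' `catchments.csv` into `dir`, in the formats the readers and the
#' command-line interface consume.
#'
#' @param sim a [simulate_watershed()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_watershed <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_watershed"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seg <- sim$network$segments
  seg$mainstem <- as.integer(seg$mainstem)
  seg$downstream_id[is.na(seg$downstream_id)] <- ""
  utils::write.csv(seg, file.path(dir, "segments.csv"), row.names = FALSE,
                   quote = FALSE)
  for (nm in c("sites", "barriers", "reach_attributes", "covariates",
               "samples", "catchments")) {
    utils::write.csv(sim[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
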