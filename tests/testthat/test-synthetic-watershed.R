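test_that("configuration validates its invariants", {
  expect_error(watershed_config(n_catchments = 1), "n_catchments")
  expect_error(watershed_config(sigma_site = 0), "sigma_site")
  expect_error(watershed_config(index_weights = c(forest = 0.5,
                                                  barren = 0.4,
                                                  forest_loss = 0.3,
                                                  deposition = 0)),
               "at most 1")
  bad <- watershed_config()
  expect_error(watershed_config(barrier_intensity = list(
    mainstem = c(large_lake = -1), tributary = bad$barrier_intensity$trib)),
    "non-negative")
  smoke <- scenario_config("smoke", seed = 2)
  expect_equal(smoke$n_catchments, 20L)
  expect_equal(scenario_config("kingcounty-analog")$n_catchments, 500L)
})

test_that("simulated networks are valid dendritic trees, reproducibly", {
  cfg <- watershed_config(seed = 30, n_catchments = 2, n_sites = 1)
  net <- simulate_network(cfg)
  expect_equal(nrow(net$segments), 2L)
  expect_equal(sum(is.na(net$down)), 1L)

  # passing the constructor IS the structural validation (cycles, ids,
  # mainstem contiguity); do it at scale
  big <- simulate_network(watershed_config(seed = 31, n_catchments = 500))
  expect_s3_class(big, "stream_network")
  expect_equal(anyDuplicated(big$segments$segment_id), 0L)
  # mainstem follows the larger subtree: it is one path outlet -> headwater
  expect_equal(sum(is.na(big$down[big$segments$mainstem])), 1L)

  n1 <- simulate_network(watershed_config(seed = 32))
  n2 <- simulate_network(watershed_config(seed = 32))
  expect_identical(n1$segments, n2$segments)
})

test_that("barrier placement follows the configured Poisson intensities", {
  cfg0 <- watershed_config(seed = 33, n_catchments = 50, n_sites = 5,
                           barrier_intensity = list(
                             mainstem = c(large_lake = 0, small_lake = 0,
                                          swamp_marsh = 0,
                                          road_crossing = 0, dam = 0),
                             tributary = c(large_lake = 0, small_lake = 0,
                                           swamp_marsh = 0,
                                           road_crossing = 0, dam = 0)))
  net <- simulate_network(cfg0)
  sb0 <- simulate_sites_barriers(net, cfg0)
  expect_equal(nrow(sb0$barriers), 0L)

  # intensity 0.5/km: total count within 3 sd of 0.5 * total length
  cfg <- watershed_config(seed = 34, n_catchments = 100, n_sites = 5,
                          barrier_intensity = list(
                            mainstem = c(large_lake = 0, small_lake = 0,
                                         swamp_marsh = 0,
                                         road_crossing = 0.5, dam = 0),
                            tributary = c(large_lake = 0, small_lake = 0,
                                          swamp_marsh = 0,
                                          road_crossing = 0.5, dam = 0)))
  net2 <- simulate_network(cfg)
  lambda <- 0.5 * sum(net2$segments$length_km)
  count <- nrow(simulate_sites_barriers(net2, cfg)$barriers)
  expect_lt(abs(count - lambda), 3 * sqrt(lambda))

  # large lakes are mainstem-only
  cfg2 <- watershed_config(seed = 35, n_catchments = 200)
  net3 <- simulate_network(cfg2)
  sb <- simulate_sites_barriers(net3, cfg2)
  ll <- sb$barriers[sb$barriers$barrier_type == "large_lake", ]
  ms <- net3$segments$segment_id[net3$segments$mainstem]
  expect_true(all(ll$segment_id %in% ms))
  # offsets are valid positions
  len <- net3$segments$length_km[match(sb$barriers$segment_id,
                                       net3$segments$segment_id)]
  expect_true(all(sb$barriers$offset_km >= 0 & sb$barriers$offset_km <= len))

  sb2 <- simulate_sites_barriers(net3, cfg2)
  expect_identical(sb, sb2)
})

test_that("covariates, indices and response honour the configuration", {
  cfg <- watershed_config(seed = 36, n_catchments = 500, n_sites = 200)
  sim <- simulate_watershed(cfg)
  cv <- sim$covariates
  ct <- sim$catchments
  expect_true(all(ct$pct_forest_cat >= 0 & ct$pct_forest_cat <= 100))
  expect_true(all(ct$ici >= 0 & ct$ici <= 1))
  expect_true(all(ct$iwi >= 0 & ct$iwi <= 1))
  expect_true(all(sim$reach_attributes$p_good > 0 &
                    sim$reach_attributes$p_good < 1))
  expect_true(all(sim$samples$bibi_score >= 0 &
                    sim$samples$bibi_score <= 100))
  # beta(1.5, 1.2) forest marginal: mean within 3 standard errors
  mu <- 100 * 1.5 / (1.5 + 1.2)
  s <- 100 * sqrt(1.5 * 1.2 / ((1.5 + 1.2)^2 * (1.5 + 1.2 + 1)))
  expect_lt(abs(mean(ct$pct_forest_cat) - mu), 3 * s / sqrt(500))
  # clipping to [0, 100] stays rare under the default effect sizes
  expect_lt(sim$truth$clipped_fraction, 0.05)
  # mean B-IBI equals the per-site sample mean
  m <- tapply(sim$samples$bibi_score, sim$samples$site_id, mean)
  expect_equal(as.numeric(m[cv$site_id]), cv$mean_bibi)

  # byte-identical reproduction from the same config
  sim2 <- simulate_watershed(cfg)
  expect_identical(sim$covariates, sim2$covariates)
  expect_identical(sim$samples, sim2$samples)
  expect_identical(sim$barriers, sim2$barriers)
})

test_that("watershed accumulation is a length-weighted upstream mean", {
  net <- stream_network(data.frame(
    segment_id = c("A", "B", "C"), downstream_id = c(NA, "A", "A"),
    length_km = c(2, 1, 3), mainstem = c(1, 0, 1),
    catchment_id = c("x", "y", "z")))
  v <- c(10, 40, 100) # A, B, C
  ws <- streamscape:::.accumulate_watershed(net, v)
  expect_equal(ws[2], 40) # headwater: watershed = own catchment
  expect_equal(ws[3], 100)
  expect_equal(ws[1], (2 * 10 + 1 * 40 + 3 * 100) / 6)
})

test_that("the noiseless limit pins down quadrant placements exactly", {
  cfg <- watershed_config(seed = 37, n_catchments = 300, n_sites = 150,
                          sigma_site = 1e-6, sigma_sample = 1e-6)
  sim <- simulate_watershed(cfg)
  cv <- sim$covariates
  cl <- classify_sites(cv, x = "ici", y = "iwi")
  # with no noise the observed condition equals the latent class
  expect_identical(as.character(cl$condition),
                   as.character(sim$truth$latent_class))
  # and quadrants are exactly those computed from the truth indicators
  expect_identical(as.character(cl$quadrant),
                   as.character(assign_quadrant(cv$ici, cv$iwi)))
})

test_that("doubling the noise weakens recovered t-statistics on average", {
  tmean <- function(sig) {
    mean(vapply(1:5, function(s) {
      cfg <- watershed_config(seed = 600 + s, n_catchments = 300,
                              n_sites = 300, sigma_site = sig)
      sim <- simulate_watershed(cfg)
      tab <- cbind(center_scale(sim$covariates["pct_forest_cat"]),
                   mean_bibi = sim$covariates$mean_bibi)
      ct <- summary(lm(mean_bibi ~ pct_forest_cat, data = tab))$coefficients
      ct["pct_forest_cat", "t value"]
    }, numeric(1)))
  }
  expect_gt(tmean(6), tmean(12))
})

test_that("round-tripping the CSV dialects preserves the simulation", {
  sim <- simulate_watershed(scenario_config("smoke", seed = 38))
  dir <- withr::local_tempdir()
  write_watershed(sim, dir)
  net <- read_segments(file.path(dir, "segments.csv"))
  expect_equal(net$segments$length_km, sim$network$segments$length_km)
  expect_identical(net$segments$mainstem, sim$network$segments$mainstem)
  b <- read_barriers(file.path(dir, "barriers.csv"))
  expect_equal(nrow(b), nrow(sim$barriers))
  ra <- read_reach_attributes(file.path(dir, "reach_attributes.csv"))
  expect_equal(ra$p_good, sim$reach_attributes$p_good, tolerance = 1e-12)
})
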