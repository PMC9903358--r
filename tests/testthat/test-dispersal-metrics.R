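straight_10km <- function() {
  stream_network(data.frame(
    segment_id = c("up", "dn"), downstream_id = c("dn", NA),
    length_km = c(5, 5), mainstem = c(1, 1),
    catchment_id = c("c1", "c2")))
}

test_that("inverse-distance barrier scores sum clamped reciprocal distances", {
  net <- straight_10km()
  site <- network_position("dn", 0) # barriers at 2 and 4 km upstream
  barriers <- data.frame(
    barrier_id = c("b1", "b2"), barrier_type = "road_crossing",
    segment_id = "dn", offset_km = c(2, 4))
  expect_equal(barrier_inverse_distance(net, site, barriers,
                                        "road_crossing", "upstream"),
               1 / 2 + 1 / 4)
  # no barriers of the requested type -> empty sum
  expect_equal(barrier_inverse_distance(net, site, barriers, "dam",
                                        "upstream"), 0)
  # co-located barrier is clamped before inversion
  at_site <- data.frame(barrier_id = "b", barrier_type = "dam",
                        segment_id = "dn", offset_km = 0)
  expect_equal(barrier_inverse_distance(net, site, at_site, "dam",
                                        "upstream",
                                        min_distance_km = 0.01), 100)
  expect_error(barrier_inverse_distance(net, site, at_site, "dam",
                                        "upstream", min_distance_km = 0),
               "positive")
  # boundary is inclusive
  at_radius <- data.frame(barrier_id = "b", barrier_type = "small_lake",
                          segment_id = "up", offset_km = 5)
  expect_equal(barrier_inverse_distance(net, site, at_radius, "small_lake",
                                        "upstream", radius_km = 10), 1 / 10)
})

test_that("barrier scores are additive and non-increasing with distance", {
  net <- straight_10km()
  site <- network_position("dn", 0)
  b1 <- data.frame(barrier_id = "x", barrier_type = "road_crossing",
                   segment_id = "dn", offset_km = 1.5)
  b2 <- data.frame(barrier_id = "y", barrier_type = "road_crossing",
                   segment_id = "dn", offset_km = 3.5)
  s1 <- barrier_inverse_distance(net, site, b1, "road_crossing", "upstream")
  s2 <- barrier_inverse_distance(net, site, b2, "road_crossing", "upstream")
  expect_equal(barrier_inverse_distance(net, site, rbind(b1, b2),
                                        "road_crossing", "upstream"),
               s1 + s2)
  ds <- vapply(seq(0.5, 4.5, by = 0.5), function(d) {
    b <- data.frame(barrier_id = "m", barrier_type = "dam",
                    segment_id = "dn", offset_km = d)
    barrier_inverse_distance(net, site, b, "dam", "upstream")
  }, numeric(1))
  expect_true(all(diff(ds) <= 1e-12))
})

test_that("off-mainstem barriers are excluded from the downstream pathway", {
  # site on headwater H; flow path H -> T (tributary) -> M (mainstem)
  net <- stream_network(data.frame(
    segment_id = c("M", "T", "H"), downstream_id = c(NA, "M", "T"),
    length_km = c(4, 1, 3), mainstem = c(1, 0, 0),
    catchment_id = c("a", "b", "c")))
  site <- network_position("H", 0.5)
  on_trib <- data.frame(barrier_id = "t", barrier_type = "small_lake",
                        segment_id = "T", offset_km = 0.5)
  on_main <- data.frame(barrier_id = "m", barrier_type = "small_lake",
                        segment_id = "M", offset_km = 3)
  expect_equal(barrier_inverse_distance(net, site, on_trib, "small_lake",
                                        "downstream"), 0)
  # distance: 0.5 down H + 1 through T + 1 into M = 2.5
  expect_equal(barrier_inverse_distance(net, site, on_main, "small_lake",
                                        "downstream"), 1 / 2.5)
})

test_that("habitat quantity follows the directional windows", {
  y <- y_network()
  expect_equal(habitat_quantity(y, network_position("A", 0), "upstream"),
               7.0)
  expect_equal(habitat_quantity(y, network_position("A", 1), "downstream"),
               1.0)
  net <- straight_10km()
  expect_equal(habitat_quantity(net, network_position("dn", 5),
                                "upstream"), 5.0)
  # upstream window over the full network is never shorter than along the
  # mainstem alone
  for (s in 1:5) {
    rn <- oracle_random_network(20, seed = 300 + s)
    seg <- rn$segments
    ms_only <- seg
    trib <- !seg$mainstem
    p <- network_position(seg$segment_id[seg$mainstem][1],
                          seg$length_km[seg$mainstem][1] / 2)
    full <- habitat_quantity(rn, p, "upstream", 6)
    ms_net <- stream_network(seg[seg$mainstem, , drop = FALSE])
    expect_gte(full + 1e-12,
               habitat_quantity(ms_net, p, "upstream", 6))
  }
})

test_that("source quality averages p_good per covered segment", {
  y <- y_network()
  attrs <- data.frame(segment_id = c("A", "B", "C"),
                      p_good = c(0.8, 0.6, 1.0))
  site <- network_position("A", 0)
  # window covers A, B, C
  expect_equal(source_quality(y, site, attrs, "upstream"),
               mean(c(0.8, 0.6, 1.0)))
  # radius 3 covers only the site's own segment
  expect_equal(source_quality(y, site, attrs[1, , drop = FALSE], "upstream",
                              radius_km = 3), 0.8)
  # two covered segments average without length weighting
  ab <- chain_ab()
  expect_equal(source_quality(ab, network_position("B", 0),
                              data.frame(segment_id = c("A", "B"),
                                         p_good = c(0.8, 0.6)),
                              "upstream", radius_km = 10), 0.7)
  expect_equal(source_quality(y, site,
                              transform(attrs, p_good = 1), "upstream"), 1)
  # duplicated attribute rows change nothing
  expect_equal(source_quality(y, site, rbind(attrs, attrs[1, ]),
                              "upstream"),
               source_quality(y, site, attrs, "upstream"))
  # missing attribute for a covered segment is a data error
  expect_error(source_quality(y, site, attrs[-2, ], "upstream"), "B")
  # window with no covered segment
  out <- stream_network(data.frame(
    segment_id = "O", downstream_id = NA, length_km = 2, mainstem = 1,
    catchment_id = "c"))
  expect_true(is.na(source_quality(out, network_position("O", 0),
                                   data.frame(segment_id = "O",
                                              p_good = 0.5),
                                   "downstream")))
  expect_error(source_quality(y, site,
                              transform(attrs, p_good = 2), "upstream"),
               "0, 1")
})

test_that("metrics match brute-force recomputation on random fixtures", {
  for (s in 1:10) {
    net <- oracle_random_network(sample(8:25, 1), seed = 400 + s)
    seg <- net$segments
    set.seed(500 + s)
    attrs <- data.frame(segment_id = seg$segment_id,
                        p_good = runif(nrow(seg)))
    nb <- 12
    bidx <- sample.int(nrow(seg), nb, replace = TRUE)
    barriers <- data.frame(
      barrier_id = paste0("b", seq_len(nb)),
      barrier_type = sample(c("road_crossing", "small_lake", "swamp_marsh"),
                            nb, replace = TRUE),
      segment_id = seg$segment_id[bidx],
      offset_km = runif(nb) * seg$length_km[bidx])
    for (p in random_positions_on(net, 3)) {
      for (dir in c("upstream", "downstream")) {
        expect_equal(habitat_quantity(net, p, dir, 5),
                     if (dir == "upstream")
                       oracle_upstream_cover(net, p, 5)$length
                     else oracle_downstream_cover(net, p, 5)$length,
                     tolerance = 1e-9)
        sq <- source_quality(net, p, attrs, dir, 5)
        osq <- oracle_source_quality(net, p, attrs, dir, 5)
        expect_equal(is.na(sq), is.na(osq))
        if (!is.na(sq)) expect_equal(sq, osq, tolerance = 1e-9)
        for (ty in c("road_crossing", "small_lake")) {
          expect_equal(
            barrier_inverse_distance(net, p, barriers, ty, dir, 5),
            oracle_barrier_sum(net, p, barriers, ty, dir, 5),
            tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("boxplot screening separates non-overlapping condition groups", {
  counts <- data.frame(
    site_id = paste0("s", 1:8),
    condition = rep(c("good", "poor"), each = 4),
    barrier_type = "road_crossing", direction = "upstream",
    radius_km = 5,
    count = c(0, 0, 0, 1, 3, 4, 5, 6))
  rep_ <- screen_barrier_types(counts)
  expect_equal(nrow(rep_), 1L)
  # type-7 quartiles frozen from the 8 listed values
  expect_equal(rep_$q3_good, 0.25)
  expect_equal(rep_$q1_poor, 3.75)
  expect_equal(rep_$separation, 3.5)
  expect_true(rep_$retained)

  # identical distributions never separate
  same <- counts
  same$count <- rep(c(1, 2, 3, 4), 2)
  rep2 <- screen_barrier_types(same)
  expect_lte(rep2$separation, 0)
  expect_false(rep2$retained)

  # a small condition group is flagged, not retained
  small <- counts[c(1, 5:8), ]
  rep3 <- screen_barrier_types(small)
  expect_identical(rep3$status, "insufficient data")
  expect_false(rep3$retained)

  # retained if separation is positive at either screened radius
  two_radii <- rbind(counts, transform(same, radius_km = 1))
  rep4 <- screen_barrier_types(two_radii)
  expect_true(all(rep4$retained))
})

test_that("count_barriers and the metric table agree with direct scores", {
  net <- straight_10km()
  site <- network_position("dn", 1)
  barriers <- data.frame(
    barrier_id = c("a", "b", "c"),
    barrier_type = c("road_crossing", "road_crossing", "dam"),
    segment_id = c("dn", "up", "dn"), offset_km = c(3, 1, 0.5))
  cnt <- count_barriers(net, site, barriers, "upstream", 5)
  expect_equal(unname(cnt["road_crossing"]), 2L)
  expect_equal(unname(cnt["dam"]), 0L) # downstream of the site
  sites <- data.frame(site_id = "s1", segment_id = "dn", offset_km = 1)
  attrs <- data.frame(segment_id = c("up", "dn"), p_good = c(0.9, 0.3))
  m <- dispersal_metrics(net, sites, barriers, attrs)
  expect_equal(m$inv_road_crossing_up,
               barrier_inverse_distance(net, site, barriers,
                                        "road_crossing", "upstream"))
  expect_equal(m$habitat_km_down, 1)
  expect_equal(m$source_quality_down, 0.3)
})
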