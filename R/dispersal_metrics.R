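BARRIER_TYPES <- c("large_lake", "small_lake", "swamp_marsh",
                   "road_crossing", "dam")

.check_barriers <- function(network, barriers) {
  req <- c("barrier_id", "barrier_type", "segment_id", "offset_km")
  miss <- setdiff(req, names(barriers))
  if (length(miss) > 0L) {
    stop("barrier table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !barriers$barrier_type %in% BARRIER_TYPES
  if (any(bad)) {
    stop("unknown barrier type(s): ",
         paste(unique(barriers$barrier_type[bad]), collapse = ", "))
  }
  invisible(barriers)
}

#' Read barrier and reach-attribute tables
#'
#' `read_barriers()` expects the header
#' `barrier_id,barrier_type,segment_id,offset_km` where `barrier_type` is
#' one of `large_lake`, `small_lake`, `swamp_marsh`, `road_crossing`, `dam`
#' (size classes such as the >= 19 km2 large-lake cut are assigned upstream
#' of this package; barriers arrive pre-classified). `read_reach_attributes()`
#' expects `segment_id,p_good`, the predicted probability that each segment
#' is in good biological condition.
#'
#' @param path path to a CSV file.
#' @return A data.frame.
#' @export
read_barriers <- function(path) {
  b <- utils::read.csv(path, colClasses = c(
    barrier_id = "character", barrier_type = "character",
    segment_id = "character"), stringsAsFactors = FALSE)
  b
}

#' @rdname read_barriers
#' @export
read_reach_attributes <- function(path) {
  utils::read.csv(path, colClasses = c(segment_id = "character"),
                  stringsAsFactors = FALSE)
}

#' Inverse-distance barrier score for one site, type, and direction
#'
#' Sums `1 / d_i` over barriers of `barrier_type` whose along-network
#' distance `d_i` from the site, measured along the direction's dispersal
#' pathway, is at most `radius_km` (boundary inclusive). Nearer barriers
#' therefore weigh more; a site with no qualifying barriers scores 0.
#' Distances below `min_distance_km` are clamped to `min_distance_km`
#' before inversion so a barrier co-located with the site cannot produce an
#' infinite score.
#'
#' Eligibility follows the same pathway rule as [traversal_window()]:
#' upstream barriers may sit on any branch, downstream barriers only on
#' mainstem-flagged segments of the flow path, so an off-mainstem lake never
#' enters the downstream predictor.
#'
#' @param network a [stream_network()].
#' @param site a [network_position()].
#' @param barriers barrier data.frame (see [read_barriers()]).
#' @param barrier_type one of `large_lake`, `small_lake`, `swamp_marsh`,
#'   `road_crossing`, `dam`.
#' @param direction `"upstream"` or `"downstream"`.
#' @param radius_km search radius in km (default 5).
#' @param min_distance_km positive clamp applied before inversion
#'   (default 0.01 km).
#' @return Non-negative numeric score (sum of inverse kilometres).
#' @export
barrier_inverse_distance <- function(network, site, barriers, barrier_type,
                                     direction = c("upstream", "downstream"),
                                     radius_km = 5.0,
                                     min_distance_km = 0.01) {
  direction <- match.arg(direction)
  barrier_type <- match.arg(barrier_type, BARRIER_TYPES)
  if (!is.numeric(min_distance_km) || min_distance_km <= 0) {
    stop("min_distance_km must be positive")
  }
  .check_barriers(network, barriers)
  b <- barriers[barriers$barrier_type == barrier_type, , drop = FALSE]
  if (nrow(b) == 0L) return(0)
  .check_position(network, site)
  total <- 0
  for (k in seq_len(nrow(b))) {
    pos <- network_position(b$segment_id[k], b$offset_km[k])
    rel <- .flow_relation(network, site, pos)
    if (is.na(rel$rel)) next
    if (rel$rel != direction && rel$rel != "same-point") next
    if (rel$dist > radius_km + 1e-12) next
    if (direction == "downstream" &&
        !network$segments$mainstem[.seg_index(network, pos$segment_id)]) next
    total <- total + 1 / max(rel$dist, min_distance_km)
  }
  total
}

#' Quantity of dispersal habitat around a site
#'
#' Total stream length (km) covered by the site's [traversal_window()]:
#' upstream includes the mainstem and all tributaries (and so can exceed
#' `radius_km`), downstream includes the mainstem flow path only, truncated
#' at the outlet.
#'
#' @inheritParams barrier_inverse_distance
#' @return Covered stream length in km.
#' @export
habitat_quantity <- function(network, site,
                             direction = c("upstream", "downstream"),
                             radius_km = 5.0) {
  direction <- match.arg(direction)
  covered_length(traversal_window(network, site, direction, radius_km))
}

#' Quality of nearby source populations
#'
#' Unweighted mean of `p_good` (the predicted probability of good biological
#' condition) over every segment with a positive-length covered interval in
#' the site's directional window. Returns `NA` when the window covers no
#' segment beyond a zero-length set. Averaging is per segment, not
#' length-weighted: probabilities are segment-level attributes.
#'
#' @inheritParams barrier_inverse_distance
#' @param reach_attributes data.frame with `segment_id` and `p_good` in
#'   \[0, 1\].
#' @return Mean probability in \[0, 1\], or `NA`.
#' @export
source_quality <- function(network, site, reach_attributes,
                           direction = c("upstream", "downstream"),
                           radius_km = 5.0) {
  direction <- match.arg(direction)
  if (any(reach_attributes$p_good < 0 | reach_attributes$p_good > 1,
          na.rm = TRUE)) {
    stop("p_good must lie in [0, 1]")
  }
  win <- traversal_window(network, site, direction, radius_km)
  ids <- unique(win$covered$segment_id)
  if (length(ids) == 0L) return(NA_real_)
  p <- reach_attributes$p_good[match(ids, reach_attributes$segment_id)]
  if (anyNA(p)) {
    stop("missing p_good for covered segment(s): ",
         paste(ids[is.na(p)], collapse = ", "))
  }
  mean(p)
}

#' Count barriers of each type within a directional radius of a site
#'
#' Helper for the boxplot screening stage; eligibility follows the same
#' pathway rules as [barrier_inverse_distance()].
#'
#' @inheritParams barrier_inverse_distance
#' @return Named integer vector over all barrier types.
#' @export
count_barriers <- function(network, site, barriers,
                           direction = c("upstream", "downstream"),
                           radius_km = 5.0) {
  direction <- match.arg(direction)
  .check_barriers(network, barriers)
  counts <- stats::setNames(integer(length(BARRIER_TYPES)), BARRIER_TYPES)
  for (k in seq_len(nrow(barriers))) {
    pos <- network_position(barriers$segment_id[k], barriers$offset_km[k])
    rel <- .flow_relation(network, site, pos)
    if (is.na(rel$rel)) next
    if (rel$rel != direction && rel$rel != "same-point") next
    if (rel$dist > radius_km + 1e-12) next
    if (direction == "downstream" &&
        !network$segments$mainstem[.seg_index(network, pos$segment_id)]) next
    ty <- barriers$barrier_type[k]
    counts[ty] <- counts[ty] + 1L
  }
  counts
}

#' All dispersal-limitation metrics for a table of sites
#'
#' Computes, for each site and each direction, the inverse-distance score of
#' every barrier type, the habitat quantity, and (when `reach_attributes` is
#' supplied) the source quality, returning one wide row per site.
#'
#' @param network a [stream_network()].
#' @param sites data.frame with `site_id`, `segment_id`, `offset_km`.
#' @param barriers barrier data.frame, or `NULL` to skip barrier scores.
#' @param reach_attributes data.frame with `segment_id`, `p_good`, or
#'   `NULL` to skip source quality.
#' @param radius_km search radius in km (default 5).
#' @param min_distance_km clamp for inverse distances (default 0.01).
#' @return data.frame with one row per site; columns
#'   `inv_<type>_<dir>`, `habitat_km_<dir>`, `source_quality_<dir>` with
#'   `dir` in `up`/`down`.
#' @export
dispersal_metrics <- function(network, sites, barriers = NULL,
                              reach_attributes = NULL, radius_km = 5.0,
                              min_distance_km = 0.01) {
  dirs <- c(up = "upstream", down = "downstream")
  out <- data.frame(site_id = as.character(sites$site_id))
  for (d in names(dirs)) {
    direction <- dirs[[d]]
    if (!is.null(barriers)) {
      for (ty in BARRIER_TYPES) {
        col <- paste0("inv_", ty, "_", d)
        out[[col]] <- vapply(seq_len(nrow(sites)), function(r) {
          barrier_inverse_distance(
            network, network_position(sites$segment_id[r],
                                      sites$offset_km[r]),
            barriers, ty, direction, radius_km, min_distance_km)
        }, numeric(1))
      }
    }
    out[[paste0("habitat_km_", d)]] <- vapply(
      seq_len(nrow(sites)), function(r) {
        habitat_quantity(network,
                         network_position(sites$segment_id[r],
                                          sites$offset_km[r]),
                         direction, radius_km)
      }, numeric(1))
    if (!is.null(reach_attributes)) {
      out[[paste0("source_quality_", d)]] <- vapply(
        seq_len(nrow(sites)), function(r) {
          source_quality(network,
                         network_position(sites$segment_id[r],
                                          sites$offset_km[r]),
                         reach_attributes, direction, radius_km)
        }, numeric(1))
    }
  }
  out
}

#' Boxplot screening of barrier types against site condition
#'
#' For each combination of barrier type, direction and radius, compares the
#' distribution of per-site barrier counts between good- and poor-condition
#' sites using interquartile-range separation: the statistic is the lower
#' quartile of the group with the higher median minus the upper quartile of
#' the other group (when medians tie, the larger of the two orderings).
#' Positive separation means the two boxes do not overlap, i.e. the barrier
#' type discriminates condition classes. A type/direction is `retained` when
#' separation is positive at any screened radius. Quartiles use linear
#' interpolation between order statistics (`stats::quantile` type 7), the
#' project-wide percentile convention.
#'
#' @param counts data.frame with columns `site_id`, `condition` (`"good"`
#'   or `"poor"`), `barrier_type`, `direction`, `radius_km`, `count`.
#' @param min_group smallest usable condition group (default 4); smaller
#'   groups yield status `"insufficient data"` and are never retained.
#' @return data.frame with one row per (type, direction, radius): group
#'   sizes, group quartiles, `separation`, `status` and the pooled
#'   `retained` flag for the type/direction.
#' @export
screen_barrier_types <- function(counts, min_group = 4L) {
  req <- c("site_id", "condition", "barrier_type", "direction", "radius_km",
           "count")
  miss <- setdiff(req, names(counts))
  if (length(miss) > 0L) {
    stop("screening table is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!all(counts$condition %in% c("good", "poor"))) {
    stop("condition must be 'good' or 'poor'")
  }
  combos <- unique(counts[c("barrier_type", "direction", "radius_km")])
  combos <- combos[order(combos$barrier_type, combos$direction,
                         combos$radius_km), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    sel <- counts$barrier_type == combos$barrier_type[r] &
      counts$direction == combos$direction[r] &
      counts$radius_km == combos$radius_km[r]
    g <- counts$count[sel & counts$condition == "good"]
    p <- counts$count[sel & counts$condition == "poor"]
    out <- data.frame(
      barrier_type = combos$barrier_type[r],
      direction = combos$direction[r], radius_km = combos$radius_km[r],
      n_good = length(g), n_poor = length(p),
      q1_good = NA_real_, med_good = NA_real_, q3_good = NA_real_,
      q1_poor = NA_real_, med_poor = NA_real_, q3_poor = NA_real_,
      separation = NA_real_, status = "insufficient data")
    if (length(g) >= min_group && length(p) >= min_group) {
      qg <- stats::quantile(g, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      qp <- stats::quantile(p, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[c("q1_good", "med_good", "q3_good")] <- as.list(qg)
      out[c("q1_poor", "med_poor", "q3_poor")] <- as.list(qp)
      sep_pg <- qp[1] - qg[3] # poor box above good box
      sep_gp <- qg[1] - qp[3]
      out$separation <- if (qp[2] > qg[2]) sep_pg
        else if (qg[2] > qp[2]) sep_gp
        else max(sep_pg, sep_gp)
      out$status <- "screened"
    }
    out
  })
  res <- do.call(rbind, rows)
  key <- paste(res$barrier_type, res$direction)
  retained_by_key <- vapply(split(res, key), function(d) {
    any(d$status == "screened" & d$separation > 0)
  }, logical(1))
  res$retained <- unname(retained_by_key[key])
  rownames(res) <- NULL
  res
}
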