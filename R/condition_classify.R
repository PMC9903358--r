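#' Site mean B-IBI score
#'
#' Arithmetic mean of all repeated sample scores at a site; the mean is the
#' unit of analysis for regression and for site-level (map) classification.
#'
#' @param scores numeric vector of B-IBI sample scores on the 0-100 scale.
#' @return The mean score.
#' @export
site_mean_bibi <- function(scores) {
  if (length(scores) == 0L) stop("a site needs at least one sample")
  if (any(scores < 0 | scores > 100, na.rm = TRUE)) {
    stop("B-IBI scores must lie in [0, 100]")
  }
  mean(scores)
}

#' Condition class from a B-IBI score
#'
#' Western Washington thresholds by default: scores <= 49.98 are poor,
#' >= 73.73 good, otherwise fair. Other jurisdictions use different scoring
#' systems, so both cuts are arguments.
#'
#' @param score numeric vector of B-IBI scores in \[0, 100\].
#' @param poor_max upper bound of the poor class (default 49.98).
#' @param good_min lower bound of the good class (default 73.73).
#' @return Factor with levels `poor`, `fair`, `good`.
#' @export
condition_class <- function(score, poor_max = 49.98, good_min = 73.73) {
  stopifnot(poor_max < good_min)
  if (any(score < 0 | score > 100, na.rm = TRUE)) {
    stop("B-IBI scores must lie in [0, 100]")
  }
  factor(ifelse(score <= poor_max, "poor",
                ifelse(score >= good_min, "good", "fair")),
         levels = c("poor", "fair", "good"))
}

#' Scatterplot quadrant of a site's two scaled indicators
#'
#' The x-axis is the catchment-scale indicator, the y-axis the
#' watershed-scale indicator, both on \[0, 1\]; two perpendicular lines at
#' `threshold` split the plane into four quadrants. High/low follows
#' [classify_high_low()], including its tie rule at the threshold.
#'
#' @param x,y numeric vectors of scaled indicator values in \[0, 1\].
#' @param threshold split point (default 0.5).
#' @return Factor with levels `upper_right`, `upper_left`, `lower_left`,
#'   `lower_right`.
#' @export
assign_quadrant <- function(x, y, threshold = 0.5) {
  xh <- classify_high_low(x, threshold) == "high"
  yh <- classify_high_low(y, threshold) == "high"
  factor(ifelse(yh, ifelse(xh, "upper_right", "upper_left"),
                ifelse(xh, "lower_right", "lower_left")),
         levels = c("upper_right", "upper_left", "lower_left",
                    "lower_right"))
}

#' Performance label from condition class and quadrant
#'
#' A poor-condition site in the upper-right quadrant (high watershed and
#' catchment integrity) is `underperforming`: its landscape gives no reason
#' for the poor condition. A good-condition site in either lower quadrant
#' (low watershed integrity) is `overperforming`. All other combinations
#' are `expected`.
#'
#' @param condition factor/character, levels of [condition_class()].
#' @param quadrant factor/character, levels of [assign_quadrant()].
#' @return Factor with levels `expected`, `underperforming`,
#'   `overperforming`.
#' @export
performance_label <- function(condition, quadrant) {
  condition <- as.character(condition)
  quadrant <- as.character(quadrant)
  out <- rep("expected", length(condition))
  out[condition == "poor" & quadrant == "upper_right"] <- "underperforming"
  out[condition == "good" &
        quadrant %in% c("lower_left", "lower_right")] <- "overperforming"
  factor(out, levels = c("expected", "underperforming", "overperforming"))
}

#' Landscape integrity map class of a catchment
#'
#' Maps the (watershed, catchment) high/low pair to the map colour classes:
#' (high, high) light green, (high, low) dark green, (low, high) yellow,
#' (low, low) brown. The yellow/brown split of the two low-watershed cells
#' is a fixed package convention (the lower quadrants are managed alike).
#'
#' @param watershed_class,catchment_class factors/characters with values
#'   `high`/`low` (watershed = y-axis, catchment = x-axis).
#' @return Factor with levels `light_green`, `dark_green`, `yellow`,
#'   `brown`.
#' @export
map_class <- function(watershed_class, catchment_class) {
  w <- as.character(watershed_class) == "high"
  c_ <- as.character(catchment_class) == "high"
  factor(ifelse(w, ifelse(c_, "light_green", "dark_green"),
                ifelse(c_, "yellow", "brown")),
         levels = c("light_green", "dark_green", "yellow", "brown"))
}

#' Classify sites against two scaled landscape indicators
#'
#' One-stop classification: condition class from the mean B-IBI, quadrant
#' from the (catchment, watershed) indicator pair, performance label, and
#' landscape-map class.
#'
#' @param data data.frame with one row per site (or per sample).
#' @param x,y names of the columns holding the catchment-scale (x) and
#'   watershed-scale (y) scaled indicators, both in \[0, 1\].
#' @param bibi name of the column holding the (mean) B-IBI score.
#' @param threshold high/low split (default 0.5).
#' @param poor_max,good_min condition thresholds, see [condition_class()].
#' @return `data` with added columns `condition`, `x_class`, `y_class`,
#'   `quadrant`, `performance`, `map_class`.
#' @export
classify_sites <- function(data, x, y, bibi = "mean_bibi", threshold = 0.5,
                           poor_max = 49.98, good_min = 73.73) {
  for (col in c(x, y, bibi)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  out <- data
  out$condition <- condition_class(data[[bibi]], poor_max, good_min)
  out$x_class <- classify_high_low(data[[x]], threshold)
  out$y_class <- classify_high_low(data[[y]], threshold)
  out$quadrant <- assign_quadrant(data[[x]], data[[y]], threshold)
  out$performance <- performance_label(out$condition, out$quadrant)
  out$map_class <- map_class(out$y_class, out$x_class)
  out
}

#' Quadrant composition and 1:1-line summary
#'
#' Tabulates, per quadrant, the count and fraction of each condition class
#' (the scatterplot pie charts), and reports the fractions of points above
#' (`y > x`), below (`y < x`), and on the 1:1 line. Pass per-sample rows to
#' reproduce sample-based pies, or per-site rows for the map unit.
#'
#' @param classified data.frame as returned by [classify_sites()]; needs
#'   columns `quadrant`, `condition` and the scaled indicator columns.
#' @param x,y names of the scaled indicator columns used for the 1:1 line.
#' @return List with `composition` (quadrant, condition, n, fraction),
#'   `quadrant_totals` (quadrant, n, fraction of all points) and `line`
#'   (fractions above/below/on the 1:1 line).
#' @export
quadrant_composition <- function(classified, x, y) {
  if (nrow(classified) == 0L) stop("no classified rows supplied")
  tab <- as.data.frame(table(quadrant = classified$quadrant,
                             condition = classified$condition),
                       responseName = "n")
  totals <- stats::ave(tab$n, tab$quadrant, FUN = sum)
  tab$fraction <- ifelse(totals > 0, tab$n / totals, NA_real_)
  qt <- as.data.frame(table(quadrant = classified$quadrant),
                      responseName = "n")
  qt$fraction <- qt$n / nrow(classified)
  xv <- classified[[x]]
  yv <- classified[[y]]
  line <- c(above = mean(yv > xv), below = mean(yv < xv),
            on = mean(yv == xv))
  list(composition = tab, quadrant_totals = qt, line = line)
}
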