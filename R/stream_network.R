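#' Build a dendritic stream network from a segment table
#'
#' Validates a flat segment table and assembles the directed network all
#' dispersal metrics traverse. Each row is one stream segment (reach) with a
#' single receiving segment downstream (`NA`/empty for an outlet), so the
#' graph is a forest of in-trees: flow converges at confluences and never
#' diverges. The `mainstem` flag marks, for every outlet, the single headward
#' principal flow path; it is an input (taken from the hydrography), not
#' derived from drainage area.
#'
#' @param segments data.frame with columns `segment_id`, `downstream_id`
#'   (`NA` or `""` for an outlet), `length_km` (positive), `mainstem`
#'   (logical or 0/1) and `catchment_id`.
#' @return An object of class `stream_network` with components `segments`
#'   (the validated table), `down` (integer index of the receiving segment,
#'   `NA` at outlets) and `up` (list of integer indices of upstream
#'   neighbours).
#' @examples
#' seg <- data.frame(
#'   segment_id = c("A", "B", "C"), downstream_id = c("B", "C", NA),
#'   length_km = c(2, 3, 1), mainstem = c(1, 1, 1),
#'   catchment_id = c("cA", "cB", "cC"))
#' net <- stream_network(seg)
#' upstream_segments(net, "C")
#' @export
stream_network <- function(segments) {
  req <- c("segment_id", "downstream_id", "length_km", "mainstem",
           "catchment_id")
  miss <- setdiff(req, names(segments))
  if (length(miss) > 0L) {
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  }
  seg <- as.data.frame(segments)[req]
  seg$segment_id <- as.character(seg$segment_id)
  seg$downstream_id <- as.character(seg$downstream_id)
  seg$downstream_id[is.na(seg$downstream_id) | !nzchar(seg$downstream_id)] <-
    NA_character_
  seg$length_km <- as.numeric(seg$length_km)
  seg$mainstem <- as.logical(as.integer(as.logical(seg$mainstem)))
  seg$catchment_id <- as.character(seg$catchment_id)
  rownames(seg) <- NULL

  if (anyDuplicated(seg$segment_id)) {
    stop("duplicate segment_id: ",
         paste(unique(seg$segment_id[duplicated(seg$segment_id)]),
               collapse = ", "))
  }
  if (any(is.na(seg$length_km)) || any(seg$length_km <= 0)) {
    stop("all segment lengths must be positive")
  }
  if (any(is.na(seg$mainstem))) stop("mainstem flag must be 0/1 or logical")

  n <- nrow(seg)
  down <- match(seg$downstream_id, seg$segment_id)
  bad <- !is.na(seg$downstream_id) & is.na(down)
  if (any(bad)) {
    stop("downstream_id references missing segment(s): ",
         paste(seg$downstream_id[bad], collapse = ", "))
  }
  if (any(!is.na(down) & down == seq_len(n))) {
    stop("segment drains to itself: ",
         seg$segment_id[which(!is.na(down) & down == seq_len(n))[1]])
  }

  # cycle detection by chain-walking with colouring
  state <- integer(n) # 0 unseen, 1 on current walk, 2 settled
  for (i in seq_len(n)) {
    if (state[i] != 0L) next
    j <- i
    walk <- integer(0)
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      walk <- c(walk, j)
      j <- down[j]
    }
    if (!is.na(j) && state[j] == 1L) {
      stop("cycle detected involving segment ", seg$segment_id[j])
    }
    state[walk] <- 2L
  }

  up <- rep(list(integer(0)), n)
  has_down <- which(!is.na(down))
  for (i in has_down) up[[down[i]]] <- c(up[[down[i]]], i)

  .validate_mainstem(seg, down, up)

  structure(list(segments = seg, down = down, up = up),
            class = "stream_network")
}

# mainstem segments must form, per outlet, one simple headward path
.validate_mainstem <- function(seg, down, up) {
  n <- nrow(seg)
  outlets <- which(is.na(down))
  if (any(!seg$mainstem[outlets])) {
    stop("outlet segment(s) must be mainstem-flagged: ",
         paste(seg$segment_id[outlets[!seg$mainstem[outlets]]],
               collapse = ", "))
  }
  ms <- which(seg$mainstem)
  non_outlet_ms <- ms[!is.na(down[ms])]
  if (any(!seg$mainstem[down[non_outlet_ms]])) {
    bad <- non_outlet_ms[!seg$mainstem[down[non_outlet_ms]]][1]
    stop("mainstem is not contiguous at segment ", seg$segment_id[bad])
  }
  for (i in ms) {
    if (sum(seg$mainstem[up[[i]]]) > 1L) {
      stop("mainstem branches above segment ", seg$segment_id[i])
    }
  }
  invisible(TRUE)
}

#' Read a stream segment table from CSV
#'
#' Expects the header `segment_id,downstream_id,length_km,mainstem,
#' catchment_id`; an empty `downstream_id` marks an outlet and `mainstem` is
#' 0/1.
#'
#' @param path path to the CSV file.
#' @return A validated [stream_network()].
#' @export
read_segments <- function(path) {
  seg <- utils::read.csv(path, colClasses = c(
    segment_id = "character", downstream_id = "character"),
    stringsAsFactors = FALSE)
  stream_network(seg)
}

#' @export
print.stream_network <- function(x, ...) {
  n <- nrow(x$segments)
  cat("<stream_network> ", n, " segments, ",
      sum(is.na(x$down)), " outlet(s), ",
      sum(x$segments$mainstem), " mainstem, total ",
      round(sum(x$segments$length_km), 2), " km\n", sep = "")
  invisible(x)
}

#' Upstream neighbours of a segment
#'
#' @param network a [stream_network()].
#' @param segment_id segment identifier.
#' @return Character vector of segment ids draining directly into
#'   `segment_id`.
#' @export
upstream_segments <- function(network, segment_id) {
  i <- .seg_index(network, segment_id)
  network$segments$segment_id[network$up[[i]]]
}

#' A position on the stream network
#'
#' Positions locate sites and barriers on a segment as the along-stream
#' offset (km) from the segment's downstream end; the segment head is at
#' `offset_km = length_km`. All distances in the package are along-network,
#' never Euclidean.
#'
#' @param segment_id segment identifier.
#' @param offset_km distance in km from the segment's downstream end.
#' @return An object of class `network_position`.
#' @export
network_position <- function(segment_id, offset_km) {
  stopifnot(length(segment_id) == 1L, length(offset_km) == 1L)
  structure(list(segment_id = as.character(segment_id),
                 offset_km = as.numeric(offset_km)),
            class = "network_position")
}

#' @export
print.network_position <- function(x, ...) {
  cat("<position> segment ", x$segment_id, " @ ", x$offset_km, " km\n",
      sep = "")
  invisible(x)
}

.seg_index <- function(network, segment_id) {
  i <- match(segment_id, network$segments$segment_id)
  if (is.na(i)) stop("unknown segment: ", segment_id)
  i
}

.check_position <- function(network, pos) {
  if (!inherits(pos, "network_position")) {
    stop("expected a network_position")
  }
  i <- .seg_index(network, pos$segment_id)
  len <- network$segments$length_km[i]
  if (is.na(pos$offset_km) || pos$offset_km < 0 || pos$offset_km > len) {
    stop("offset ", pos$offset_km, " outside [0, ", len, "] on segment ",
         pos$segment_id)
  }
  i
}

# downstream chain from a position: segment indices visited (excluding the
# origin segment) with the distance from the position to each segment's
# upstream end (head)
.downstream_chain <- function(network, pos) {
  i <- .check_position(network, pos)
  idx <- integer(0)
  d_head <- numeric(0)
  d <- pos$offset_km # distance to the bottom of the origin segment
  j <- network$down[i]
  while (!is.na(j)) {
    idx <- c(idx, j)
    d_head <- c(d_head, d)
    d <- d + network$segments$length_km[j]
    j <- network$down[j]
  }
  list(idx = idx, d_head = d_head)
}

# flow relation of `target` relative to `origin`:
# list(rel = "same-point" | "upstream" | "downstream" | NA, dist = km or NA)
.flow_relation <- function(network, origin, target) {
  io <- .check_position(network, origin)
  it <- .check_position(network, target)
  if (io == it) {
    d <- target$offset_km - origin$offset_km
    rel <- if (d > 0) "upstream" else if (d < 0) "downstream" else "same-point"
    return(list(rel = rel, dist = abs(d)))
  }
  len <- network$segments$length_km
  ch <- .downstream_chain(network, origin)
  k <- match(it, ch$idx)
  if (!is.na(k)) {
    # target downstream of origin: enter at its head, walk down to offset
    return(list(rel = "downstream",
                dist = ch$d_head[k] + (len[it] - target$offset_km)))
  }
  ch <- .downstream_chain(network, target)
  k <- match(io, ch$idx)
  if (!is.na(k)) {
    return(list(rel = "upstream",
                dist = ch$d_head[k] + (len[io] - origin$offset_km)))
  }
  list(rel = NA_character_, dist = NA_real_)
}

#' Along-network distance between two flow-connected positions
#'
#' Returns the along-stream path length in kilometres when one position lies
#' purely upstream or purely downstream of the other, and `NA` when no
#' monotone flow path connects them (e.g. positions on sibling tributaries).
#'
#' @param network a [stream_network()].
#' @param origin,target [network_position()] objects.
#' @return Distance in km, or `NA` if the positions are not flow-connected.
#' @export
network_distance <- function(network, origin, target) {
  .flow_relation(network, origin, target)$dist
}

#' Directional traversal window around a site
#'
#' Collects the set of segment intervals reachable from `origin` within
#' `radius_km` along-network kilometres under the direction's pathway rule:
#'
#' * `upstream` (the downstream-dispersal pathway, drift/swimming/crawling):
#'   the window climbs from the site into the mainstem and every tributary,
#'   branching at confluences, so covered length can exceed `radius_km`.
#' * `downstream` (the upstream-flight pathway of adult insects): the window
#'   follows the unique flow path below the site, is truncated at the
#'   outlet, and covers only mainstem-flagged intervals -- flight is assumed
#'   to proceed up the principal channel only, never up a side tributary.
#'   Distance still accrues along non-mainstem portions of the flow path.
#'
#' The `radius_km` boundary is inclusive (`distance <= radius` is covered);
#' degenerate zero-length intervals are dropped.
#'
#' @param network a [stream_network()].
#' @param origin a [network_position()].
#' @param direction `"upstream"` or `"downstream"`.
#' @param radius_km positive search radius in km (default 5, the distance
#'   beyond which most stream insects do not disperse).
#' @return An object of class `traversal_window` with a `covered`
#'   data.frame: `segment_id`, `lo_km`, `hi_km` (offsets bounding the
#'   covered interval) and `entry_km` (network distance from the origin to
#'   the nearest point of the interval).
#' @export
traversal_window <- function(network, origin,
                             direction = c("upstream", "downstream"),
                             radius_km = 5.0) {
  direction <- match.arg(direction)
  i <- .check_position(network, origin)
  if (!is.numeric(radius_km) || length(radius_km) != 1L || radius_km <= 0) {
    stop("radius_km must be a positive number")
  }
  seg <- network$segments
  rows <- if (direction == "upstream") {
    .cover_upstream(network, i, origin$offset_km, radius_km)
  } else {
    .cover_downstream(network, i, origin$offset_km, radius_km)
  }
  covered <- if (length(rows) > 0L) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(segment_id = character(0), lo_km = numeric(0),
               hi_km = numeric(0), entry_km = numeric(0))
  }
  covered <- covered[covered$hi_km - covered$lo_km > 0, , drop = FALSE]
  rownames(covered) <- NULL
  structure(list(origin = origin, direction = direction,
                 radius_km = radius_km, covered = covered),
            class = "traversal_window")
}

.cover_upstream <- function(network, i, offset, radius) {
  seg <- network$segments
  rows <- list(data.frame(
    segment_id = seg$segment_id[i], lo_km = offset,
    hi_km = min(seg$length_km[i], offset + radius), entry_km = 0))
  # stack of (segment index, budget remaining at its downstream end,
  # distance from origin to its downstream end)
  head_budget <- radius - (seg$length_km[i] - offset)
  if (head_budget > 0) {
    stack <- lapply(network$up[[i]], function(u) {
      c(u, head_budget, radius - head_budget)
    })
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      u <- fr[1]
      budget <- fr[2]
      entry <- fr[3]
      len <- seg$length_km[u]
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = seg$segment_id[u], lo_km = 0,
        hi_km = min(len, budget), entry_km = entry)
      if (budget > len) {
        for (v in network$up[[u]]) {
          stack[[length(stack) + 1L]] <- c(v, budget - len, entry + len)
        }
      }
    }
  }
  rows
}

.cover_downstream <- function(network, i, offset, radius) {
  seg <- network$segments
  rows <- list()
  if (seg$mainstem[i]) {
    rows[[1L]] <- data.frame(
      segment_id = seg$segment_id[i], lo_km = max(0, offset - radius),
      hi_km = offset, entry_km = 0)
  }
  budget <- radius - offset # remaining below the origin segment's bottom
  j <- network$down[i]
  entry <- offset
  while (!is.na(j) && budget > 0) {
    len <- seg$length_km[j]
    if (seg$mainstem[j]) {
      rows[[length(rows) + 1L]] <- data.frame(
        segment_id = seg$segment_id[j], lo_km = len - min(len, budget),
        hi_km = len, entry_km = entry)
    }
    budget <- budget - len
    entry <- entry + len
    j <- network$down[j]
  }
  rows
}

#' Total covered stream length of a traversal window
#'
#' @param window a [traversal_window()].
#' @return Length in km.
#' @export
covered_length <- function(window) {
  stopifnot(inherits(window, "traversal_window"))
  sum(window$covered$hi_km - window$covered$lo_km)
}

#' @export
print.traversal_window <- function(x, ...) {
  cat("<traversal_window> ", x$direction, " from segment ",
      x$origin$segment_id, " @ ", x$origin$offset_km, " km, radius ",
      x$radius_km, " km: ", nrow(x$covered), " interval(s), ",
      round(covered_length(x), 3), " km covered\n", sep = "")
  invisible(x)
}

# is a position inside (inclusive) a window's covered set?
.position_in_window <- function(window, pos) {
  cov <- window$covered
  any(cov$segment_id == pos$segment_id &
        cov$lo_km - 1e-12 <= pos$offset_km &
        pos$offset_km <= cov$hi_km + 1e-12)
}
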