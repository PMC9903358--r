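# Independent brute-force oracles for traversal quantities. These climb
# parent pointers segment by segment (a different formulation from the
# package's budgeted recursion) and are only ever used on tiny networks.

# random dendritic fixture, independent of the package generator:
# uniform parent attachment, uniform lengths, mainstem by largest subtree
# *count* (any flagging that satisfies the single-headward-path rule works)
oracle_random_network <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_,
              vapply(seq_len(n - 1L), function(i) sample.int(i, 1L),
                     integer(1)))
  len <- round(stats::runif(n, 0.2, 3), 3)
  size <- rep(1L, n)
  if (n > 1L) for (i in n:2) size[parent[i]] <- size[parent[i]] + size[i]
  kids <- rep(list(integer(0)), n)
  if (n > 1L) for (i in 2:n) kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  mainstem <- logical(n)
  j <- 1L
  repeat {
    mainstem[j] <- TRUE
    if (length(kids[[j]]) == 0L) break
    j <- kids[[j]][which.max(size[kids[[j]]])]
  }
  streamscape::stream_network(data.frame(
    segment_id = paste0("t", seq_len(n)),
    downstream_id = ifelse(is.na(parent), NA, paste0("t", parent)),
    length_km = len, mainstem = mainstem,
    catchment_id = paste0("k", seq_len(n))))
}

# distance from the *bottom* of segment t down to origin position (i, off);
# NA if origin's segment is not on t's downstream chain
.oracle_drop_dist <- function(net, t, i, off) {
  seg <- net$segments
  d <- 0
  j <- net$down[t]
  while (!is.na(j)) {
    if (j == i) return(d + (seg$length_km[i] - off))
    d <- d + seg$length_km[j]
    j <- net$down[j]
  }
  NA_real_
}

# covered length (and covered-segment ids) of the upstream window
oracle_upstream_cover <- function(net, pos, r) {
  seg <- net$segments
  i <- match(pos$segment_id, seg$segment_id)
  lens <- numeric(nrow(seg))
  lens[i] <- min(seg$length_km[i] - pos$offset_km, r)
  for (t in seq_len(nrow(seg))) {
    if (t == i) next
    d <- .oracle_drop_dist(net, t, i, pos$offset_km)
    if (is.na(d)) next
    lens[t] <- min(seg$length_km[t], max(0, r - d))
  }
  list(length = sum(lens), segments = seg$segment_id[lens > 0])
}

oracle_downstream_cover <- function(net, pos, r) {
  seg <- net$segments
  i <- match(pos$segment_id, seg$segment_id)
  lens <- numeric(nrow(seg))
  if (seg$mainstem[i]) lens[i] <- min(pos$offset_km, r)
  d <- pos$offset_km
  j <- net$down[i]
  while (!is.na(j) && d < r) {
    if (seg$mainstem[j]) lens[j] <- min(seg$length_km[j], r - d)
    d <- d + seg$length_km[j]
    j <- net$down[j]
  }
  list(length = sum(lens), segments = seg$segment_id[lens > 0])
}

# orientation + distance of b relative to a by pure chain climbing
oracle_relation <- function(net, a, b) {
  seg <- net$segments
  ia <- match(a$segment_id, seg$segment_id)
  ib <- match(b$segment_id, seg$segment_id)
  if (ia == ib) {
    d <- b$offset_km - a$offset_km
    rel <- if (d > 0) "upstream" else if (d < 0) "downstream" else
      "same-point"
    return(list(rel = rel, dist = abs(d)))
  }
  d <- .oracle_drop_dist(net, ib, ia, a$offset_km)
  if (!is.na(d)) return(list(rel = "upstream", dist = d + b$offset_km))
  d <- .oracle_drop_dist(net, ia, ib, b$offset_km)
  if (!is.na(d)) return(list(rel = "downstream", dist = d + a$offset_km))
  list(rel = NA_character_, dist = NA_real_)
}

oracle_barrier_sum <- function(net, site, barriers, type, direction, r,
                               min_d = 0.01) {
  seg <- net$segments
  b <- barriers[barriers$barrier_type == type, , drop = FALSE]
  total <- 0
  for (k in seq_len(nrow(b))) {
    pos <- streamscape::network_position(b$segment_id[k], b$offset_km[k])
    rel <- oracle_relation(net, site, pos)
    if (is.na(rel$rel)) next
    if (!(rel$rel == direction || rel$rel == "same-point")) next
    if (rel$dist > r) next
    if (direction == "downstream" &&
        !seg$mainstem[match(pos$segment_id, seg$segment_id)]) next
    total <- total + 1 / max(rel$dist, min_d)
  }
  total
}

oracle_source_quality <- function(net, pos, attrs, direction, r) {
  cov <- if (direction == "upstream") oracle_upstream_cover(net, pos, r)
    else oracle_downstream_cover(net, pos, r)
  if (length(cov$segments) == 0L) return(NA_real_)
  mean(attrs$p_good[match(cov$segments, attrs$segment_id)])
}

# shared tiny fixtures
chain_ab <- function() {
  streamscape::stream_network(data.frame(
    segment_id = c("A", "B"), downstream_id = c("B", NA),
    length_km = c(2, 3), mainstem = c(1, 1),
    catchment_id = c("cA", "cB")))
}

# outlet A (3 km, mainstem) with tributaries B (4 km, mainstem continues)
# and C (2 km) joining at A's head
y_network <- function() {
  streamscape::stream_network(data.frame(
    segment_id = c("A", "B", "C"), downstream_id = c(NA, "A", "A"),
    length_km = c(3, 4, 2), mainstem = c(1, 1, 0),
    catchment_id = c("cA", "cB", "cC")))
}

random_positions_on <- function(net, k) {
  seg <- net$segments
  idx <- sample.int(nrow(seg), k, replace = TRUE)
  lapply(seq_len(k), function(j) {
    streamscape::network_position(seg$segment_id[idx[j]],
                                  stats::runif(1) * seg$length_km[idx[j]])
  })
}
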