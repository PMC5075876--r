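# Independent oracles used across the suite. Each reimplements the quantity
# it checks from first principles, by a different route than the package.

# ray-casting point-in-polygon (no boundary subtleties needed: fixtures avoid
# points exactly on edges)
pip_oracle <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((poly_y[i] > y) != (poly_y[j] > y)) {
        xint <- poly_x[i] + (y - poly_y[i]) / (poly_y[j] - poly_y[i]) *
          (poly_x[j] - poly_x[i])
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# neighbour lists by brute-force pairwise angular distance
neighbour_oracle <- function(array) {
  d <- attr(array, "inter_unit_angle")
  xy <- cbind(array$azimuth_deg, array$elevation_deg)
  dist <- as.matrix(stats::dist(xy))
  lapply(seq_len(nrow(array)), function(i)
    sort(as.integer(which(abs(dist[i, ] - d) < 1e-9 * d))))
}

# Mann-Whitney U by direct pair counting
u_pair_oracle <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# exact two-sided p by enumerating all labelings, U recomputed per labeling
# by pair counting (independent of the rank-sum route in the package)
mwu_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  u_obs <- u_pair_oracle(a, b)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    u_pair_oracle(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# a tiny deterministic dendrite-segment table
example_segments <- function() {
  data.frame(
    neuron = c("LGMD1", "LGMD1", "LGMD2", "LGMD2", "LGMD2"),
    region = c("distal", "proximal", "distal", "mid", "proximal"),
    diameter_um = c(2, 8, 1.5, 6, 9),
    length_um = c(30, 12, 25, 18, 10),
    area_um2 = c(NA, 310, NA, NA, 290),
    synapse_count = c(60, 24, 55, 40, 20)
  )
}

# hand-built records: `spec` is a data frame of directed TmA->TmA contact
# counts (pre, post, n); every synapse is dyadic onto `lgmd`
records_from_spec <- function(spec, lgmd = "LGMD2", span = 2L) {
  rows <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    data.frame(
      pre_id = rep(spec$pre[i], spec$n[i]),
      post_id_1 = spec$post[i],
      stringsAsFactors = FALSE
    )
  }))
  data.frame(
    synapse_id = sprintf("s%03d", seq_len(nrow(rows))),
    pre_id = rows$pre_id,
    pre_class = "TmA",
    post_id_1 = rows$post_id_1,
    post_class_1 = "TmA",
    post_id_2 = lgmd,
    post_class_2 = lgmd,
    bouton_id = paste0(rows$pre_id, "_b1"),
    section_span = span,
    thickness_nm = 70,
    stringsAsFactors = FALSE
  )
}

# movie from a raw 0/1 coverage matrix (units x time) on a given array
movie_from_frames <- function(frames, array) {
  structure(
    list(
      frames = frames,
      time_ms = seq_len(ncol(frames)),
      subtense_deg = rep(NA_real_, ncol(frames)),
      trajectory = structure(list(type = "manual"),
                             class = "object_trajectory"),
      array = array,
      coverage_rule = "centre"
    ),
    class = "stimulus_movie"
  )
}

reference_array <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lgmdnet::hex_array(250, 3.3)
    cache
  }
})
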