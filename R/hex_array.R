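# Hexagonal retinotopic array of P-units.
#
# Units live on an axial ("pointy-top") hexagonal lattice and are placed on a
# planar angular map: one lattice step between neighbouring unit centres spans
# exactly `inter_unit_angle` degrees. The patch is built ring by ring around a
# central unit so it is roughly circular; a partially filled outer ring is
# completed in deterministic clockwise order starting due up.

# axial step offsets shared by construction and neighbour lookup
.hex_steps <- cbind(
  q = c(1L, 1L, 0L, -1L, -1L, 0L),
  r = c(0L, -1L, -1L, 0L, 1L, 1L)
)

.hex_xy <- function(q, r, spacing) {
  cbind(
    az = spacing * (q + r / 2),
    el = spacing * (sqrt(3) / 2) * r
  )
}

#' Build a hexagonal array of P-units
#'
#' Constructs a roughly circular patch of retinotopic units on an axial
#' hexagonal lattice, centred at azimuth/elevation (0, 0). Units are added in
#' concentric rings around a central unit; the outermost ring is filled in
#' clockwise order starting due up, so any unit count gives a deterministic
#' layout. Neighbouring unit centres are separated by exactly
#' `inter_unit_angle` degrees on the planar angular map.
#'
#' @param n_units number of units (default 250, the simulated eye patch).
#' @param inter_unit_angle angular spacing between neighbouring unit centres,
#'   in degrees (default 3.3).
#' @return An object of class `hex_array`: a data frame with columns
#'   `unit_id`, `q`, `r`, `azimuth_deg`, `elevation_deg`, and attributes
#'   `inter_unit_angle` and `neighbours` (a list of integer neighbour ids per
#'   unit).
#' @examples
#' arr <- hex_array(7)
#' hex_neighbours(arr, 1L)   # the centre unit touches all six ring-1 units
#' @export
hex_array <- function(n_units = 250, inter_unit_angle = 3.3) {
  if (length(n_units) != 1L || is.na(n_units) || n_units < 1)
    stop("`n_units` must be a single integer >= 1", call. = FALSE)
  if (length(inter_unit_angle) != 1L || is.na(inter_unit_angle) ||
      inter_unit_angle <= 0)
    stop("`inter_unit_angle` must be a single positive number", call. = FALSE)
  n_units <- as.integer(n_units)

  q <- 0L
  r <- 0L
  ring <- 0L
  while (length(q) < n_units) {
    ring <- ring + 1L
    rq <- integer(0)
    rr <- integer(0)
    # walk the ring: start at `ring` steps in direction 5 (axial (-1, 1)),
    # then take `ring` steps in each of the six directions
    cq <- -ring
    cr <- ring
    for (side in c(1L, 2L, 3L, 4L, 5L, 6L)) {
      for (i in seq_len(ring)) {
        rq <- c(rq, cq)
        rr <- c(rr, cr)
        cq <- cq + .hex_steps[side, "q"]
        cr <- cr + .hex_steps[side, "r"]
      }
    }
    # order clockwise starting due up (bearing measured clockwise from +el)
    xy <- .hex_xy(rq, rr, inter_unit_angle)
    bearing <- atan2(xy[, "az"], xy[, "el"]) %% (2 * pi)
    ord <- order(bearing)
    q <- c(q, rq[ord])
    r <- c(r, rr[ord])
  }
  q <- q[seq_len(n_units)]
  r <- r[seq_len(n_units)]

  xy <- .hex_xy(q, r, inter_unit_angle)
  units <- data.frame(
    unit_id = seq_len(n_units),
    q = q,
    r = r,
    azimuth_deg = xy[, "az"],
    elevation_deg = xy[, "el"]
  )
  if (anyDuplicated(units[, c("q", "r")]))
    stop("internal error: duplicate axial coordinates", call. = FALSE)

  key <- paste(q, r)
  idx <- seq_len(n_units)
  names(idx) <- key
  neighbours <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    nb_key <- paste(q[i] + .hex_steps[, "q"], r[i] + .hex_steps[, "r"])
    hit <- idx[nb_key]
    neighbours[[i]] <- sort(unname(hit[!is.na(hit)]))
  }

  structure(
    units,
    inter_unit_angle = inter_unit_angle,
    neighbours = neighbours,
    class = c("hex_array", "data.frame")
  )
}

#' @export
print.hex_array <- function(x, ...) {
  cat(sprintf(
    "<hex_array> %d P-units, %.3g deg between neighbouring centres\n",
    nrow(x), attr(x, "inter_unit_angle")
  ))
  cat(sprintf(
    "  field: azimuth [%.1f, %.1f] deg, elevation [%.1f, %.1f] deg\n",
    min(x$azimuth_deg), max(x$azimuth_deg),
    min(x$elevation_deg), max(x$elevation_deg)
  ))
  invisible(x)
}

#' Neighbouring units of a P-unit
#'
#' Returns the ids of units exactly one lattice step away. Interior units have
#' six neighbours; units on the rim of the patch have fewer. The relation is
#' symmetric.
#'
#' @param array a [hex_array()].
#' @param unit_id a single unit id present in the array.
#' @return Integer vector of neighbour ids (possibly empty).
#' @export
hex_neighbours <- function(array, unit_id) {
  stopifnot(inherits(array, "hex_array"))
  if (length(unit_id) != 1L || is.na(unit_id) ||
      !(unit_id %in% array$unit_id))
    stop(sprintf("unknown unit id: %s", paste(unit_id, collapse = ",")),
         call. = FALSE)
  attr(array, "neighbours")[[as.integer(unit_id)]]
}

# adjacency matrix (dense 0/1); used by the network simulation
.hex_adjacency <- function(array) {
  n <- nrow(array)
  nb <- attr(array, "neighbours")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[nb[[i]], i] <- 1
  A
}

#' Rasterize an angular silhouette onto the array
#'
#' Marks each unit covered (1) or uncovered (0) by a polygon given in degrees
#' of azimuth/elevation. Two coverage rules are available: `"centre"` marks a
#' unit when its centre falls inside (or exactly on the boundary of) the
#' polygon; `"fraction"` marks a unit when at least half of a fixed 13-point
#' stencil spanning its hexagonal cell falls inside. Degenerate polygons
#' (fewer than three vertices, or zero area) yield an all-zero frame.
#'
#' @param array a [hex_array()].
#' @param polygon_deg numeric matrix (or data frame) with two columns,
#'   azimuth and elevation in degrees, listing polygon vertices in order.
#' @param coverage_rule `"centre"` (default) or `"fraction"`.
#' @return Integer 0/1 vector of length `nrow(array)`.
#' @export
rasterize <- function(array, polygon_deg,
                      coverage_rule = c("centre", "fraction")) {
  stopifnot(inherits(array, "hex_array"))
  coverage_rule <- match.arg(coverage_rule)
  poly <- as.matrix(polygon_deg)
  n <- nrow(array)
  if (is.null(poly) || length(poly) == 0L || nrow(poly) < 3L)
    return(integer(n))
  if (ncol(poly) != 2L)
    stop("`polygon_deg` must have two columns (azimuth, elevation)",
         call. = FALSE)
  # shoelace area; a zero-area polygon covers nothing
  xs <- poly[, 1]; ys <- poly[, 2]
  area <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (area == 0) return(integer(n))

  if (coverage_rule == "centre") {
    inside <- pracma::inpolygon(array$azimuth_deg, array$elevation_deg,
                                xs, ys, boundary = TRUE)
    return(as.integer(inside))
  }

  # fraction rule: fixed stencil over each unit's hexagonal Voronoi cell
  # (circumradius spacing/sqrt(3), vertices midway between neighbour bearings)
  d <- attr(array, "inter_unit_angle")
  circ <- d / sqrt(3)
  vert_ang <- (seq(0, 5) * 60 + 30) * pi / 180 # cell vertices
  edge_ang <- (seq(0, 5) * 60) * pi / 180      # towards neighbours
  stencil <- rbind(
    c(0, 0),
    0.75 * circ * cbind(cos(vert_ang), sin(vert_ang)),
    0.75 * (d / 2) * cbind(cos(edge_ang), sin(edge_ang))
  )
  covered <- vapply(seq_len(n), function(i) {
    px <- array$azimuth_deg[i] + stencil[, 1]
    py <- array$elevation_deg[i] + stencil[, 2]
    frac <- mean(pracma::inpolygon(px, py, xs, ys, boundary = TRUE))
    frac >= 0.5
  }, logical(1))
  as.integer(covered)
}

#' Write / read a hex array as delimited text
#'
#' Exports the unit table (`unit_id, q, r, azimuth_deg, elevation_deg`) as a
#' tab-separated file; `read_hex_array()` rebuilds the array (including the
#' neighbour topology) from such a file.
#'
#' @param array a [hex_array()].
#' @param path file path.
#' @return `write_hex_array()` returns `path` invisibly; `read_hex_array()`
#'   returns a `hex_array`.
#' @export
write_hex_array <- function(array, path) {
  stopifnot(inherits(array, "hex_array"))
  df <- as.data.frame(array)
  attr(df, "inter_unit_angle") <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# inter_unit_angle=%.17g", attr(array, "inter_unit_angle")),
             con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hex_array
#' @export
read_hex_array <- function(path) {
  first <- readLines(path, n = 1L)
  spacing <- as.numeric(sub("# inter_unit_angle=", "", first, fixed = TRUE))
  if (is.na(spacing))
    stop("not a hex array file: missing inter_unit_angle header", call. = FALSE)
  df <- utils::read.delim(path, skip = 1L)
  arr <- hex_array(nrow(df), spacing)
  # the builder is deterministic, but honour the stored coordinates
  if (!isTRUE(all.equal(as.data.frame(arr)[, c("q", "r")], df[, c("q", "r")],
                        check.attributes = FALSE)))
    stop("stored unit layout does not match the deterministic builder",
         call. = FALSE)
  arr
}
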