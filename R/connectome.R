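# Quantification of EM synapse-record and dendrite-segment tables.
#
# Synapse records are one row per synapse: presynaptic cell id and class,
# up to two postsynaptic partners (dyadic synapses post onto a neighbouring
# TmA and an LGMD simultaneously), the bouton the synapse sits on, and the
# number of serial sections its active zone (az) extends through.

.cell_classes <- c("TmA", "LGMD1", "LGMD2", "GABA")

#' Active-zone length from a serial-section span
#'
#' Az length is measured by the number of sections the az extends through,
#' times the section thickness.
#'
#' @param section_span number of serial sections (>= 1).
#' @param thickness_nm section thickness in nm (default 70).
#' @return Length in nm.
#' @examples
#' az_length(2)  # 140 nm
#' @export
az_length <- function(section_span, thickness_nm = 70) {
  if (any(section_span < 1))
    stop("`section_span` must be >= 1", call. = FALSE)
  if (any(thickness_nm <= 0))
    stop("`thickness_nm` must be positive", call. = FALSE)
  section_span * thickness_nm
}

#' Synapse density per unit membrane area
#'
#' Synapses per square micron over an open cylinder of the given diameter and
#' length (`count / (pi * diameter * length)`). Measured surface areas, when
#' available, should be preferred by dividing directly.
#'
#' @param count synapse count.
#' @param diameter_um dendrite diameter, um.
#' @param length_um dendrite length, um.
#' @return Synapses per um^2.
#' @export
surface_density <- function(count, diameter_um, length_um) {
  if (any(diameter_um <= 0) || any(length_um <= 0))
    stop("dendrite geometry must be positive", call. = FALSE)
  if (any(count < 0)) stop("`count` must be >= 0", call. = FALSE)
  count / (pi * diameter_um * length_um)
}

#' Synapse density per unit dendrite length
#'
#' @param count synapse count.
#' @param length_um dendrite length, um.
#' @return Synapses per um.
#' @examples
#' linear_density(116, 16.8)  # 6.9 synapses/um
#' @export
linear_density <- function(count, length_um) {
  if (any(length_um <= 0)) stop("`length_um` must be positive", call. = FALSE)
  if (any(count < 0)) stop("`count` must be >= 0", call. = FALSE)
  count / length_um
}

#' Per-facet share of a whole-neuron total
#'
#' Divides a total (synapse count or membrane area) by the number of
#' ommatidial facets. Counts are reported to the nearest integer, areas to one
#' decimal, matching the conventions used for whole-eye comparisons.
#'
#' @param total total count or area.
#' @param n_facets number of facets (default 8134, the adult eye).
#' @param type `"count"` or `"area"`; controls the reporting precision.
#' @return Per-facet value (rounded per `type`).
#' @examples
#' per_facet(131000, type = "count")  # 16 synapses per facet
#' @export
per_facet <- function(total, n_facets = 8134, type = c("count", "area")) {
  type <- match.arg(type)
  if (n_facets < 1) stop("`n_facets` must be >= 1", call. = FALSE)
  x <- total / n_facets
  if (type == "count") round(x) else round(x, 1)
}

#' Mean synapse length per unit membrane area
#'
#' Product of a synapse surface density and a mean az length, i.e. the um of
#' active zone packed into each um^2 of dendritic membrane. Using the maximum
#' density across sampled regions gives an upper bound.
#'
#' @param density_per_um2 synapse density, per um^2.
#' @param mean_len_um mean az length, um.
#' @return um of az per um^2.
#' @export
mean_syn_len_per_area <- function(density_per_um2, mean_len_um) {
  if (any(density_per_um2 < 0) || any(mean_len_um < 0))
    stop("inputs must be >= 0", call. = FALSE)
  density_per_um2 * mean_len_um
}

# ---- synapse record tables ---------------------------------------------

.record_cols <- c("synapse_id", "pre_id", "pre_class", "post_id_1",
                  "post_class_1", "post_id_2", "post_class_2", "bouton_id",
                  "section_span", "thickness_nm")

.validate_records <- function(records) {
  missing <- setdiff(.record_cols, names(records))
  if (length(missing))
    stop("synapse records lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(records) && any(records$section_span < 1))
    stop("invalid record: section span must be >= 1", call. = FALSE)
  if (nrow(records) && any(is.na(records$post_id_1)))
    stop("invalid record: at least one postsynaptic partner required",
         call. = FALSE)
  cls <- c(records$pre_class, records$post_class_1,
           records$post_class_2[!is.na(records$post_class_2)])
  if (length(cls) && !all(cls %in% .cell_classes))
    stop("cell classes must be one of: ", paste(.cell_classes, collapse = ", "),
         call. = FALSE)
  invisible(records)
}

# directed TmA->TmA contacts in a record table (one row per synapse)
.tma_tma_edges <- function(records) {
  is_tt <- records$pre_class == "TmA" &
    (records$post_class_1 == "TmA" |
       (!is.na(records$post_class_2) & records$post_class_2 == "TmA"))
  rec <- records[is_tt, , drop = FALSE]
  if (!nrow(rec)) return(data.frame(pre = character(0), post = character(0)))
  post <- ifelse(rec$post_class_1 == "TmA", rec$post_id_1, rec$post_id_2)
  data.frame(pre = as.character(rec$pre_id), post = as.character(post),
             stringsAsFactors = FALSE)
}

#' Fraction of reciprocated TmA-to-TmA synapses
#'
#' A TmA-to-TmA synapse counts as reciprocal when at least one synapse exists
#' between the same pair of cells in the opposite direction.
#'
#' @param records a synapse-record table (see [read_synapse_records()]).
#' @return Fraction in 0..1.
#' @export
reciprocity_fraction <- function(records) {
  .validate_records(records)
  e <- .tma_tma_edges(records)
  if (!nrow(e))
    stop("no TmA->TmA synapses: reciprocity undefined", call. = FALSE)
  fwd <- paste(e$pre, e$post, sep = "\r")
  rev <- paste(e$post, e$pre, sep = "\r")
  mean(fwd %in% rev)
}

#' Build a bouton graph from synapse records
#'
#' Collects the TmA axons, their terminal boutons, and the TmA-TmA / TmA-LGMD
#' multigraph implied by a record table. A bouton inventory (data frame
#' `bouton_id`, `tma_id`) may be supplied; otherwise boutons are inferred from
#' the records. TmAs with more than 5 boutons are kept with a warning (axons
#' divide into 2-5 terminals).
#'
#' @param records a synapse-record table.
#' @param boutons optional bouton inventory.
#' @return A `bouton_graph`: list with `tma_ids`, `boutons`, `records`.
#' @export
bouton_graph <- function(records, boutons = NULL) {
  .validate_records(records)
  pre_tma <- unique(as.character(records$pre_id[records$pre_class == "TmA"]))
  post_tma <- unique(c(
    as.character(records$post_id_1[records$post_class_1 == "TmA"]),
    as.character(records$post_id_2[!is.na(records$post_class_2) &
                                     records$post_class_2 == "TmA"])
  ))
  tma_ids <- sort(unique(c(pre_tma, post_tma)))
  if (is.null(boutons)) {
    keep <- records$pre_class == "TmA"
    boutons <- unique(data.frame(
      bouton_id = as.character(records$bouton_id[keep]),
      tma_id = as.character(records$pre_id[keep]),
      stringsAsFactors = FALSE
    ))
  }
  per_tma <- table(boutons$tma_id)
  if (length(per_tma) && any(per_tma > 5))
    warning("some TmAs carry more than 5 boutons", call. = FALSE)
  structure(list(tma_ids = tma_ids, boutons = boutons, records = records),
            class = "bouton_graph")
}

#' Connectivity summary of a bouton graph
#'
#' Per-TmA distinct-partner counts, synapses per connected TmA pair, and
#' output synapses per bouton, with their medians and maxima. The per-TmA
#' connectivity product is (max partners) x (max synapses per connection).
#' Empty summaries (no TmA-TmA contacts, or no synapses on the inventoried
#' boutons) yield medians of 0.
#'
#' @param graph a [bouton_graph()].
#' @return List with `partners_per_tma`, `synapses_per_pair`,
#'   `synapses_per_bouton` (named vectors), their `median_*` and `max_*`
#'   summaries, and `connectivity_product`.
#' @export
connectivity_stats <- function(graph) {
  stopifnot(inherits(graph, "bouton_graph"))
  e <- .tma_tma_edges(graph$records)
  med0 <- function(x) if (length(x)) stats::median(x) else 0
  max0 <- function(x) if (length(x)) max(x) else 0

  if (nrow(e)) {
    pair_key <- ifelse(e$pre < e$post, paste(e$pre, e$post, sep = "\r"),
                       paste(e$post, e$pre, sep = "\r"))
    syn_per_pair <- c(table(pair_key))
    partner_sets <- unique(data.frame(a = c(e$pre, e$post),
                                      b = c(e$post, e$pre)))
    partners <- c(table(factor(partner_sets$a, levels = graph$tma_ids)))
  } else {
    syn_per_pair <- integer(0)
    partners <- if (length(graph$tma_ids))
      stats::setNames(integer(length(graph$tma_ids)), graph$tma_ids)
    else integer(0)
  }

  out_syn <- graph$records[graph$records$pre_class == "TmA", , drop = FALSE]
  syn_per_bouton <- c(table(factor(as.character(out_syn$bouton_id),
                                   levels = unique(graph$boutons$bouton_id))))

  list(
    partners_per_tma = partners,
    synapses_per_pair = syn_per_pair,
    synapses_per_bouton = syn_per_bouton,
    median_partners = med0(partners),
    median_synapses_per_pair = med0(syn_per_pair),
    median_synapses_per_bouton = med0(syn_per_bouton),
    max_partners = max0(partners),
    max_synapses_per_pair = max0(syn_per_pair),
    connectivity_product = max0(partners) * max0(syn_per_pair)
  )
}

#' Mann-Whitney U test with midrank ties
#'
#' U statistic of the first sample (number of (a, b) pairs with a > b, ties
#' counting one half) computed from midranks. The two-sided p-value is exact
#' by enumeration of all labelings when `n1 + n2 <= exact_limit`, otherwise a
#' normal approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (nonempty).
#' @param exact_limit enumeration threshold on `n1 + n2` (default 16).
#' @return List with `U`, `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b, exact_limit = 16) {
  if (!length(a) || !length(b))
    stop("both samples must be nonempty", call. = FALSE)
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  if (n1 + n2 <= exact_limit) {
    combos <- utils::combn(n1 + n2, n1)
    base <- n1 * (n1 + 1) / 2
    us <- colSums(matrix(rk[combos], nrow = n1)) - base
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }

  N <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) # all values tied: no evidence of a shift
    return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

# ---- dendrite segments, growth scaling, totals --------------------------

.segment_cols <- c("neuron", "region", "diameter_um", "length_um",
                   "area_um2", "synapse_count")

.validate_segments <- function(segments) {
  missing <- setdiff(c("neuron", "diameter_um", "length_um"), names(segments))
  if (length(missing))
    stop("segment table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(segments)) {
    if (any(is.na(segments$neuron)) ||
        !all(segments$neuron %in% c("LGMD1", "LGMD2")))
      stop("every segment must be labelled LGMD1 or LGMD2", call. = FALSE)
    if (any(segments$diameter_um <= 0) || any(segments$length_um <= 0))
      stop("segment geometry must be positive", call. = FALSE)
  }
  if (is.null(segments$area_um2)) segments$area_um2 <- NA_real_
  # open-cylinder area where no measured area is given
  miss <- is.na(segments$area_um2)
  segments$area_um2[miss] <-
    pi * segments$diameter_um[miss] * segments$length_um[miss]
  segments
}

#' Growth model for last-instar to adult extrapolation
#'
#' At the final moult facets are added at the anterior eye margin and new
#' dendritic segments are added to the finest distal dendrites. The model
#' scales segments below a per-neuron diameter threshold by `1 + fraction`.
#'
#' @param fraction growth fraction (default 0.11, the fractional increase in
#'   facet number between last instar and adult).
#' @param thresholds_um named diameter thresholds below which segments grow
#'   (defaults: LGMD1 < 5 um, LGMD2 < 7 um).
#' @param adult_facets facet count of the adult eye (default 8134).
#' @param facets_added facets added at the final moult (default 806).
#' @return A `growth_model` list.
#' @export
growth_model <- function(fraction = 0.11,
                         thresholds_um = c(LGMD1 = 5, LGMD2 = 7),
                         adult_facets = 8134, facets_added = 806) {
  if (fraction < 0) stop("`fraction` must be >= 0", call. = FALSE)
  if (any(thresholds_um <= 0)) stop("thresholds must be positive", call. = FALSE)
  structure(list(fraction = fraction, thresholds_um = thresholds_um,
                 adult_facets = adult_facets, facets_added = facets_added),
            class = "growth_model")
}

#' Apply dendritic growth scaling
#'
#' Scales the length and area of every segment whose diameter lies below its
#' neuron's threshold by `1 + fraction`; other segments are unchanged. Returns
#' adult totals per neuron.
#'
#' @param segments a dendrite-segment table (columns `neuron`, `diameter_um`,
#'   `length_um`, optionally `area_um2`).
#' @param model a [growth_model()].
#' @return List with `segments` (scaled table) and `totals` (data frame
#'   `neuron`, `total_length_um`, `total_area_um2`).
#' @export
grow_dendrites <- function(segments, model = growth_model()) {
  stopifnot(inherits(model, "growth_model"))
  segments <- .validate_segments(segments)
  thr <- model$thresholds_um[segments$neuron]
  if (anyNA(thr))
    stop("no growth threshold for neuron: ",
         paste(setdiff(unique(segments$neuron), names(model$thresholds_um)),
               collapse = ", "), call. = FALSE)
  scale <- ifelse(segments$diameter_um < thr, 1 + model$fraction, 1)
  segments$length_um <- segments$length_um * scale
  segments$area_um2 <- segments$area_um2 * scale
  totals <- do.call(rbind, lapply(split(segments, segments$neuron), function(s)
    data.frame(neuron = s$neuron[1],
               total_length_um = sum(s$length_um),
               total_area_um2 = sum(s$area_um2))))
  rownames(totals) <- NULL
  list(segments = segments, totals = totals)
}

#' Total synapse number from densities by diameter class
#'
#' Multiplies each segment's membrane area by the synapse density of its
#' diameter class and sums. Every segment must fall into a class of its
#' neuron's mapping.
#'
#' @param segments a dendrite-segment table.
#' @param densities data frame with columns `neuron`, `diameter_min_um`,
#'   `diameter_max_um` (half-open class `[min, max)`), `density_per_um2`.
#' @return List with `total` (raw) and `total_rounded` (nearest thousand, the
#'   reporting convention for whole-neuron totals).
#' @export
total_synapses <- function(segments, densities) {
  segments <- .validate_segments(segments)
  need <- c("neuron", "diameter_min_um", "diameter_max_um", "density_per_um2")
  if (!all(need %in% names(densities)))
    stop("`densities` needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(segments)) return(list(total = 0, total_rounded = 0))
  dens <- vapply(seq_len(nrow(segments)), function(i) {
    hit <- densities$neuron == segments$neuron[i] &
      densities$diameter_min_um <= segments$diameter_um[i] &
      segments$diameter_um[i] < densities$diameter_max_um
    if (!any(hit))
      stop(sprintf("no density class covers %s segment of diameter %g um",
                   segments$neuron[i], segments$diameter_um[i]), call. = FALSE)
    densities$density_per_um2[which(hit)[1L]]
  }, numeric(1))
  total <- sum(segments$area_um2 * dens)
  list(total = total, total_rounded = round(total, -3))
}

# ---- delimited-text readers/writers -------------------------------------

#' Read / write synapse-record and dendrite-segment tables
#'
#' Tab-separated tables with a header row. Synapse records carry
#' `synapse_id, pre_id, pre_class, post_id_1, post_class_1, post_id_2,
#' post_class_2, bouton_id, section_span, thickness_nm`; dendrite segments
#' carry `neuron, region, diameter_um, length_um, area_um2, synapse_count`.
#'
#' @param path file path.
#' @param records,segments tables to write.
#' @return The table (readers) or `path` invisibly (writers).
#' @export
read_synapse_records <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  .validate_records(rec)
}

#' @rdname read_synapse_records
#' @export
write_synapse_records <- function(records, path) {
  .validate_records(records)
  utils::write.table(records[, .record_cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_synapse_records
#' @export
read_dendrite_segments <- function(path) {
  .validate_segments(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_synapse_records
#' @export
write_dendrite_segments <- function(segments, path) {
  segments <- .validate_segments(segments)
  keep <- intersect(.segment_cols, names(segments))
  utils::write.table(segments[, keep], path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
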