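# Seeded generator of synapse-record tables with the statistical structure of
# TmA terminal connectivity: axons with 2-5 boutons, a median of one output
# synapse per bouton, a median of two synapses per connected TmA pair (max 7),
# up to six TmA partners per TmA, fully reciprocal TmA-TmA contacts each
# dyadic onto an LGMD, and active-zone section spans tuned to the observed
# mean az lengths (107 nm for LGMD 1 volumes, 155 nm for LGMD 2 at 70 nm
# sections).

# truncated geometric on {min..max}: pmf proportional to (1-p)^(k-min)
.rtrunc_geom <- function(n, p, min, max) {
  k <- min:max
  pmf <- (1 - p)^(k - min)
  sample(k, n, replace = TRUE, prob = pmf / sum(pmf))
}

#' Parameters of the synthetic connectome generator
#'
#' Distribution families are configurable because only medians, ranges and
#' means are known for the real tissue: boutons per TmA are uniform on
#' `bouton_range`; partners per TmA and synapses per connected pair are
#' truncated geometric with success probabilities chosen so the medians are 2;
#' az section spans are 1 + Poisson with class-specific rates matching the
#' target mean az lengths.
#'
#' @param n_tma number of TmA axons in the volume (default 87).
#' @param lgmd LGMD class of the volume, `"LGMD1"` or `"LGMD2"`; sets the
#'   default az span rate and whether GABAergic microcircuitry is emitted.
#' @param bouton_range boutons per TmA, inclusive integer range (default 2-5).
#' @param partner_p,partner_max truncated-geometric parameter and cap for
#'   distinct TmA partners per TmA (defaults give median 2, max 6).
#' @param pair_p,pair_max truncated-geometric parameter and cap for synapses
#'   per connected TmA pair (defaults give median 2, max 7).
#' @param reciprocity probability that a connected pair is wired reciprocally
#'   (default 1: every TmA-TmA synapse has a reverse partner).
#' @param az_span_rate Poisson rate of extra sections beyond the first; the
#'   default depends on `lgmd`: 107/70 - 1 for LGMD 1, 155/70 - 1 for LGMD 2,
#'   so mean az length matches the class target.
#' @param thickness_nm section thickness (default 70).
#' @param gaba_fraction fraction of TmAs that additionally exchange synapses
#'   with GABAergic processes (default 0.15 for LGMD 2 volumes, 0 for LGMD 1).
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_tma = 87,
                         lgmd = c("LGMD2", "LGMD1"),
                         bouton_range = c(2L, 5L),
                         partner_p = 0.35, partner_max = 6L,
                         pair_p = 0.45, pair_max = 7L,
                         reciprocity = 1.0,
                         az_span_rate = NULL,
                         thickness_nm = 70,
                         gaba_fraction = NULL) {
  lgmd <- match.arg(lgmd)
  if (n_tma < 1) stop("`n_tma` must be >= 1", call. = FALSE)
  if (reciprocity < 0 || reciprocity > 1)
    stop("`reciprocity` must be in [0, 1]", call. = FALSE)
  if (partner_max > 6L || pair_max > 7L || bouton_range[2] > 5L)
    stop("distribution bounds exceed the anatomical limits (6 partners, 7 synapses/pair, 5 boutons)",
         call. = FALSE)
  if (bouton_range[1] < 1L || partner_max < 1L || pair_max < 1L)
    stop("infeasible distribution bounds", call. = FALSE)
  if (is.null(az_span_rate))
    az_span_rate <- if (lgmd == "LGMD1") 107 / 70 - 1 else 155 / 70 - 1
  if (is.null(gaba_fraction))
    gaba_fraction <- if (lgmd == "LGMD2") 0.15 else 0
  structure(list(
    n_tma = as.integer(n_tma), lgmd = lgmd,
    bouton_range = as.integer(bouton_range),
    partner_p = partner_p, partner_max = as.integer(partner_max),
    pair_p = pair_p, pair_max = as.integer(pair_max),
    reciprocity = reciprocity,
    az_span_rate = az_span_rate,
    thickness_nm = thickness_nm,
    gaba_fraction = gaba_fraction
  ), class = "synth_params")
}

#' Generate a synthetic connectome volume
#'
#' Draws a TmA partner graph, splits each connected pair's synapses over the
#' two directions (reciprocal pairs carry at least one synapse each way), and
#' emits one dyadic record per synapse: the presynaptic TmA releases onto the
#' partner TmA and onto the volume's LGMD simultaneously. Boutons with no
#' TmA-TmA contact emit a single plain TmA-to-LGMD synapse, so every terminal
#' contributes output. Fully reproducible for a given seed.
#'
#' @param params a [synth_params()].
#' @param seed integer seed (required; all randomness flows from it).
#' @return List with `records` (synapse table), `graph` (a [bouton_graph()]),
#'   and `truth` (realized medians, maxima, mean az length, reciprocity).
#' @export
generate_connectome <- function(params = synth_params(), seed) {
  stopifnot(inherits(params, "synth_params"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- params$n_tma
  tma_ids <- sprintf("TmA%03d", seq_len(n))
  n_bout <- sample(seq(params$bouton_range[1], params$bouton_range[2]),
                   n, replace = TRUE)
  boutons <- data.frame(
    bouton_id = unlist(lapply(seq_len(n), function(i)
      sprintf("%s_b%d", tma_ids[i], seq_len(n_bout[i])))),
    tma_id = rep(tma_ids, n_bout),
    stringsAsFactors = FALSE
  )

  # partner graph: draw target degrees, then greedily pair TmAs
  deg_target <- if (n > 1)
    .rtrunc_geom(n, params$partner_p, 1L, min(params$partner_max, n - 1L))
  else integer(0)
  pairs <- matrix(character(0), ncol = 2)
  if (n > 1) {
    deg <- integer(n)
    order_ids <- sample.int(n)
    for (i in order_ids) {
      want <- deg_target[i] - deg[i]
      if (want <= 0) next
      cand <- setdiff(which(deg < deg_target), i)
      cand <- cand[!vapply(cand, function(j)
        any(pairs[, 1] == tma_ids[min(i, j)] &
              pairs[, 2] == tma_ids[max(i, j)]), logical(1))]
      if (!length(cand)) next
      take <- utils::head(cand[order(deg[cand], stats::runif(length(cand)))],
                          want)
      for (j in take) {
        pairs <- rbind(pairs, c(tma_ids[min(i, j)], tma_ids[max(i, j)]))
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
  }

  lgmd_id <- params$lgmd
  rec <- list()
  add <- function(pre, post1, class1, bouton, span) {
    rec[[length(rec) + 1L]] <<- data.frame(
      pre_id = pre, pre_class = "TmA",
      post_id_1 = post1, post_class_1 = class1,
      post_id_2 = if (class1 == "TmA") lgmd_id else NA_character_,
      post_class_2 = if (class1 == "TmA") params$lgmd else NA_character_,
      bouton_id = bouton, section_span = span,
      stringsAsFactors = FALSE
    )
  }
  draw_span <- function(k) 1L + stats::rpois(k, params$az_span_rate)
  bout_of <- split(boutons$bouton_id, boutons$tma_id)

  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      m <- .rtrunc_geom(1L, params$pair_p, 1L, params$pair_max)
      recip <- stats::runif(1) < params$reciprocity
      if (recip && m < 2L) m <- 2L
      fwd <- if (recip) ceiling(m / 2) else m
      bwd <- m - fwd
      # reciprocal contacts share a bouton pairing: one bouton per side
      ba <- sample(bout_of[[a]], 1L)
      bb <- sample(bout_of[[b]], 1L)
      for (i in seq_len(fwd)) add(a, b, "TmA", ba, draw_span(1L))
      for (i in seq_len(bwd)) add(b, a, "TmA", bb, draw_span(1L))
    }
  }

  # boutons without a TmA-TmA contact still synapse onto the LGMD
  used <- if (length(rec)) unique(do.call(rbind, rec)$bouton_id) else character(0)
  idle <- setdiff(boutons$bouton_id, used)
  for (bid in idle) {
    add(boutons$tma_id[boutons$bouton_id == bid], lgmd_id, params$lgmd,
        bid, draw_span(1L))
  }

  # GABAergic microcircuits (LGMD 2 volumes): TmA -> GABA and GABA -> TmA
  if (params$gaba_fraction > 0 && n >= 1) {
    n_g <- max(1L, round(params$gaba_fraction * n))
    g_tma <- sample(tma_ids, n_g)
    for (gi in seq_len(n_g)) {
      gid <- sprintf("G%02d", gi)
      tid <- g_tma[gi]
      bid <- sample(bout_of[[tid]], 1L)
      add(tid, gid, "GABA", bid, draw_span(1L))
      rec[[length(rec) + 1L]] <- data.frame(
        pre_id = gid, pre_class = "GABA",
        post_id_1 = tid, post_class_1 = "TmA",
        post_id_2 = NA_character_, post_class_2 = NA_character_,
        bouton_id = sprintf("%s_b1", gid), section_span = draw_span(1L),
        stringsAsFactors = FALSE
      )
    }
  }

  records <- do.call(rbind, rec)
  records$thickness_nm <- params$thickness_nm
  records$synapse_id <- sprintf("syn%05d", seq_len(nrow(records)))
  records <- records[, .record_cols]
  graph <- bouton_graph(records, boutons)
  stats <- connectivity_stats(graph)
  tma_rec <- records[records$pre_class == "TmA", ]
  truth <- list(
    seed = seed,
    lgmd = params$lgmd,
    n_tma = n,
    median_partners = stats$median_partners,
    median_synapses_per_pair = stats$median_synapses_per_pair,
    median_synapses_per_bouton = stats$median_synapses_per_bouton,
    max_partners = stats$max_partners,
    max_synapses_per_pair = stats$max_synapses_per_pair,
    mean_az_length_nm = mean(az_length(tma_rec$section_span,
                                       tma_rec$thickness_nm)),
    reciprocity = if (nrow(.tma_tma_edges(records)))
      reciprocity_fraction(records) else NA_real_
  )
  list(records = records, graph = graph, truth = truth)
}

#' Degrade a record table the way block-face imaging would
#'
#' Serial block-face imaging misses very short active zones: azs are only
#' detected when they persist through two or more block faces. `degrade()`
#' simulates that censoring (dropping span-1 records) plus optional random
#' record loss.
#'
#' @param records a synapse-record table.
#' @param drop_single_section drop records whose az spans one section.
#' @param record_loss_rate fraction of remaining records lost at random.
#' @param seed integer seed (required when `record_loss_rate > 0`).
#' @return The censored record table.
#' @export
degrade_records <- function(records, drop_single_section = FALSE,
                            record_loss_rate = 0, seed = NULL) {
  .validate_records(records)
  if (record_loss_rate < 0 || record_loss_rate > 1)
    stop("`record_loss_rate` must be in [0, 1]", call. = FALSE)
  out <- records
  if (drop_single_section)
    out <- out[out$section_span >= 2L, , drop = FALSE]
  if (record_loss_rate > 0) {
    if (is.null(seed))
      stop("`seed` is required when records are lost at random", call. = FALSE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    keep <- stats::runif(nrow(out)) >= record_loss_rate
    out <- out[keep, , drop = FALSE]
  }
  out
}
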