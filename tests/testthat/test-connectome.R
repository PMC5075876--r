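test_that("active-zone length is span times section thickness", {
  expect_equal(az_length(1, 70), 70)
  expect_equal(az_length(2, 70), 140)
  expect_error(az_length(0), "span")
  expect_error(az_length(2, 0), "thickness")
})

test_that("mean az length of a synthetic cohort matches its generator", {
  gen <- generate_connectome(synth_params(n_tma = 87, lgmd = "LGMD2"),
                             seed = 11)
  tma <- gen$records[gen$records$pre_class == "TmA", ]
  m <- mean(az_length(tma$section_span, tma$thickness_nm))
  expect_equal(m, gen$truth$mean_az_length_nm)
  expect_equal(m, 155, tolerance = 0.12) # generator target for LGMD 2
})

test_that("surface and linear densities follow the cylinder formulas", {
  expect_equal(surface_density(0, 5, 10), 0)
  expect_equal(surface_density(100, 5, 6.3), 100 / (pi * 5 * 6.3))
  expect_equal(surface_density(100, 5, 6.3), 1.0105, tolerance = 1e-4)
  expect_equal(surface_density(100, 10, 6.3),
               surface_density(100, 5, 6.3) / 2)
  expect_error(surface_density(10, 0, 5), "positive")

  expect_equal(linear_density(0, 16.8), 0)
  expect_equal(round(linear_density(235, 16.8), 2), 13.99)
  expect_error(linear_density(10, 0), "positive")

  # consistency: linear = surface x pi x diameter for cylinder-derived areas
  expect_equal(linear_density(116, 16.8),
               surface_density(116, 5, 16.8) * pi * 5)
})

test_that("per-facet and mean-synapse-length metrics reproduce arithmetic", {
  expect_equal(per_facet(0, 8134, "count"), 0)
  expect_equal(per_facet(1e5, 100, "count"), 1000)
  expect_equal(per_facet(123.45 * 100, 100, "area"), 123.4)
  expect_equal(mean_syn_len_per_area(0, 0.155), 0)
  expect_equal(mean_syn_len_per_area(2, 0.1), 0.2)
  expect_error(mean_syn_len_per_area(-1, 0.1), ">= 0")
})

test_that("reciprocity fraction counts directed contacts with a reverse", {
  one_way <- records_from_spec(data.frame(pre = "A", post = "B", n = 1))
  expect_equal(reciprocity_fraction(one_way), 0)

  both <- records_from_spec(data.frame(pre = c("A", "B"), post = c("B", "A"),
                                       n = c(2, 1)))
  expect_equal(reciprocity_fraction(both), 1)

  mixed <- records_from_spec(data.frame(pre = c("A", "B", "A"),
                                        post = c("B", "A", "C"),
                                        n = c(1, 1, 2)))
  expect_equal(reciprocity_fraction(mixed), 0.5)

  lgmd_only <- records_from_spec(data.frame(pre = "A", post = "B", n = 1))
  lgmd_only$post_class_1 <- "LGMD2"
  lgmd_only$post_id_1 <- "LGMD2"
  lgmd_only$post_id_2 <- NA
  lgmd_only$post_class_2 <- NA
  expect_error(reciprocity_fraction(lgmd_only), "undefined")
})

test_that("connectivity statistics match a brute-force edge-list recount", {
  spec <- data.frame(
    pre = c("A", "B", "A", "C", "C", "D"),
    post = c("B", "A", "C", "A", "D", "C"),
    n = c(3, 2, 1, 1, 2, 2)
  )
  g <- bouton_graph(records_from_spec(spec))
  st <- connectivity_stats(g)

  # oracle: recount from the raw directed contact list
  contacts <- spec[rep(seq_len(nrow(spec)), spec$n), c("pre", "post")]
  upair <- apply(contacts, 1, function(r) paste(sort(r), collapse = "|"))
  syn_per_pair <- table(upair)
  partner_of <- function(id)
    length(unique(c(contacts$post[contacts$pre == id],
                    contacts$pre[contacts$post == id])))
  partners <- vapply(c("A", "B", "C", "D"), partner_of, numeric(1))

  expect_equal(st$median_synapses_per_pair, median(as.numeric(syn_per_pair)))
  expect_equal(st$median_partners, median(partners))
  expect_equal(st$max_partners, max(partners))
  expect_equal(st$max_synapses_per_pair, max(as.numeric(syn_per_pair)))
  expect_equal(st$connectivity_product,
               max(partners) * max(as.numeric(syn_per_pair)))
})

test_that("connectivity statistics are invariant under TmA relabelling", {
  gen <- generate_connectome(synth_params(n_tma = 30), seed = 5)
  st <- connectivity_stats(gen$graph)
  rec <- gen$records
  ids <- gen$graph$tma_ids
  set.seed(99)
  relabel <- stats::setNames(sample(sprintf("X%02d", seq_along(ids))), ids)
  swap <- function(x) ifelse(x %in% names(relabel), relabel[x], x)
  rec$pre_id <- swap(rec$pre_id)
  rec$post_id_1 <- swap(rec$post_id_1)
  rec$post_id_2 <- swap(rec$post_id_2)
  rec$bouton_id <- paste0(swap(sub("_b.*", "", rec$bouton_id)), "_",
                          sub(".*_", "", rec$bouton_id))
  st2 <- connectivity_stats(bouton_graph(rec))
  for (f in c("median_partners", "median_synapses_per_pair",
              "max_partners", "max_synapses_per_pair",
              "connectivity_product"))
    expect_equal(st2[[f]], st[[f]], info = f)
})

test_that("a TmA with no partners yields zero medians", {
  rec <- records_from_spec(data.frame(pre = "A", post = "B", n = 1))
  rec$post_id_1 <- "LGMD2"
  rec$post_class_1 <- "LGMD2"
  rec$post_id_2 <- NA
  rec$post_class_2 <- NA
  inventory <- data.frame(bouton_id = paste0("A_b", 1:4), tma_id = "A")
  st <- connectivity_stats(bouton_graph(rec, inventory))
  expect_equal(st$median_partners, 0)
  expect_equal(st$median_synapses_per_pair, 0)
  expect_equal(st$median_synapses_per_bouton, 0) # 1 synapse over 4 boutons
  expect_equal(st$connectivity_product, 0)
})

test_that("Mann-Whitney U follows hand rankings and symmetry", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$U, 0)
  x <- c(2, 3, 3, 5)
  expect_equal(mann_whitney_u(x, x)$U, length(x)^2 / 2)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("exact Mann-Whitney p agrees with full enumeration over labelings", {
  set.seed(42)
  for (rep in 1:25) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    a <- sample(1:5, n1, replace = TRUE) # heavy ties on purpose
    b <- sample(1:5, n2, replace = TRUE)
    res <- mann_whitney_u(a, b)
    expect_equal(res$method, "exact")
    expect_equal(res$U, u_pair_oracle(a, b))
    expect_equal(res$p_value, mwu_enum_oracle(a, b))
  }
})

test_that("large-sample Mann-Whitney matches the standard normal test", {
  set.seed(7)
  a <- rnorm(30)
  b <- rnorm(35, 0.6)
  res <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$method, "normal")
  expect_equal(res$U, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("growth scaling matches a row-by-row oracle and is monotone", {
  seg <- example_segments()
  m0 <- growth_model(fraction = 0)
  base <- grow_dendrites(seg, m0)$totals
  expect_equal(sum(base$total_length_um), sum(seg$length_um)) # identity

  m11 <- growth_model(fraction = 0.11)
  grown <- grow_dendrites(seg, m11)
  # oracle: scale each row by hand
  thr <- c(LGMD1 = 5, LGMD2 = 7)
  fac <- ifelse(seg$diameter_um < thr[seg$neuron], 1.11, 1)
  area <- ifelse(is.na(seg$area_um2),
                 pi * seg$diameter_um * seg$length_um, seg$area_um2)
  for (nr in c("LGMD1", "LGMD2")) {
    i <- seg$neuron == nr
    j <- grown$totals$neuron == nr
    expect_equal(grown$totals$total_length_um[j],
                 sum(seg$length_um[i] * fac[i]))
    expect_equal(grown$totals$total_area_um2[j], sum(area[i] * fac[i]))
  }
  expect_true(all(grown$totals$total_length_um >= base$total_length_um))

  allfine <- data.frame(neuron = "LGMD1", region = "d",
                        diameter_um = c(1, 2), length_um = c(10, 20))
  tot <- grow_dendrites(allfine, m11)$totals
  expect_equal(tot$total_length_um, 30 * 1.11)

  bad <- data.frame(neuron = "LGMD3", region = "d", diameter_um = 1,
                    length_um = 1)
  expect_error(grow_dendrites(bad, m11), "LGMD1 or LGMD2")
})

test_that("total synapse extrapolation multiplies area by class density", {
  seg <- data.frame(neuron = "LGMD1", region = "d",
                    diameter_um = c(2, 2), length_um = c(10, 5),
                    area_um2 = c(100, 50))
  one <- data.frame(neuron = "LGMD1", diameter_min_um = 0,
                    diameter_max_um = 10, density_per_um2 = 3)
  expect_equal(total_synapses(seg, one)$total, 3 * 150)

  two <- data.frame(neuron = c("LGMD1", "LGMD1"),
                    diameter_min_um = c(0, 5), diameter_max_um = c(5, 20),
                    density_per_um2 = c(3, 1))
  seg2 <- data.frame(neuron = "LGMD1", region = "d",
                     diameter_um = c(2, 8), length_um = c(1, 1),
                     area_um2 = c(100, 200))
  expect_equal(total_synapses(seg2, two)$total, 3 * 100 + 1 * 200)
  expect_equal(total_synapses(seg2[0, ], two)$total, 0)

  gap <- data.frame(neuron = "LGMD1", diameter_min_um = 0,
                    diameter_max_um = 5, density_per_um2 = 3)
  expect_error(total_synapses(seg2, gap), "no density class")
})

test_that("record and segment tables round-trip through TSV", {
  gen <- generate_connectome(synth_params(n_tma = 12), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_synapse_records(gen$records, path)
  back <- read_synapse_records(path)
  expect_equal(back, gen$records, ignore_attr = TRUE)

  segp <- withr::local_tempfile(fileext = ".tsv")
  seg <- example_segments()
  write_dendrite_segments(seg, segp)
  back2 <- read_dendrite_segments(segp)
  expect_equal(back2$diameter_um, seg$diameter_um)
  expect_false(anyNA(back2$area_um2)) # cylinder fallback applied
})
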