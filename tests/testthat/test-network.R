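test_that("P-unit pulses fire exactly at coverage transitions", {
  arr <- hex_array(7)
  static <- movie_from_frames(matrix(1L, 7, 20), arr)
  expect_true(all(p_unit_pulses(static) == 0L))

  frames <- matrix(0L, 7, 15)
  frames[3, 5:8] <- 1L # covered at t = 5, uncovered at t = 9
  pulses <- p_unit_pulses(movie_from_frames(frames, arr))
  expect_identical(which(pulses[3, ] == 1L), c(5L, 9L))
  expect_true(all(pulses[-3, ] == 0L))
  onset <- p_unit_pulses(movie_from_frames(frames, arr), polarity = "onset")
  expect_identical(which(onset[3, ] == 1L), 5L)
})

test_that("translation pulse count equals the frame-difference oracle", {
  arr <- reference_array()
  mv <- render_stimulus(make_translation(), arr)
  pulses <- p_unit_pulses(mv)
  oracle <- sum(abs(mv$frames[, -1] - mv$frames[, -ncol(mv$frames)]))
  expect_equal(sum(pulses), oracle)
  expect_gt(oracle, 0)
})

test_that("an all-zero movie is a fixed point of the dynamics", {
  arr <- hex_array(19)
  mv <- movie_from_frames(matrix(0L, 19, 30), arr)
  res <- run_network(mv, network_params())
  expect_true(all(res$output_instant == 0))
  expect_true(all(res$output_integrated == 0))
})

test_that("a single isolated pulse activates one unit after E_delay", {
  arr <- hex_array(19)
  frames <- matrix(0L, 19, 20)
  frames[1, 6:20] <- 1L # pulse at t = 6
  mv <- movie_from_frames(frames, arr)
  res <- run_network(mv, network_params(enable_L = FALSE, enable_S = FALSE,
                                        E_delay_ms = 1))
  expect_equal(which(res$output_instant > 0), 7L)
  expect_equal(res$output_instant[7], 1)
})

test_that("simultaneous neighbour pulses are inhibited by exactly gain/6", {
  arr <- hex_array(19)
  u <- 1L
  v <- hex_neighbours(arr, u)[1]
  frames <- matrix(0L, 19, 20)
  frames[c(u, v), 6:20] <- 1L # both pulse at t = 6
  mv <- movie_from_frames(frames, arr)
  # excitation and inhibition arrive together two steps later
  p_off <- network_params(E_delay_ms = 2, L_delay_ms = 2,
                          enable_L = FALSE, enable_S = FALSE)
  p_on <- network_params(E_delay_ms = 2, L_delay_ms = 2,
                         enable_L = TRUE, enable_S = FALSE)
  off <- run_network(mv, p_off)
  on <- run_network(mv, p_on)
  expect_equal(off$output_instant[8], 2)
  expect_equal(on$output_instant[8], 2 * (1 - 2.0 / 6))
})

test_that("inhibition is dispatched only to existing neighbours at gain/6 each", {
  arr <- hex_array(7)
  corner <- 2L # ring-1 unit: three neighbours
  nbs <- hex_neighbours(arr, corner)
  expect_length(nbs, 3L)
  frames <- matrix(0L, 7, 25)
  frames[corner, 4:25] <- 1L          # pulse at t = 4
  probe <- setdiff(seq_len(7), corner)
  frames[probe, 6:25] <- 1L           # probes pulse at t = 6
  mv <- movie_from_frames(frames, arr)
  p <- network_params(E_delay_ms = 2, L_delay_ms = 4,
                      enable_L = TRUE, enable_S = FALSE)
  res <- run_network(mv, p) # probe excitation and corner inhibition meet at t = 8
  base <- run_network(mv, network_params(E_delay_ms = 2, L_delay_ms = 4,
                                         enable_L = FALSE, enable_S = FALSE))
  drop <- base$output_instant[8] - res$output_instant[8]
  expect_equal(drop, length(nbs) * 2.0 / 6, tolerance = 1e-12)
})

test_that("repeated runs are bit-identical", {
  arr <- reference_array()
  mv <- render_stimulus(make_loom(), arr)
  r1 <- run_network(mv, network_params())
  r2 <- run_network(mv, network_params())
  expect_identical(r1$output_integrated, r2$output_integrated)
  expect_identical(r1$output_instant, r2$output_instant)
})

test_that("inhibition only ever reduces the integrated output", {
  arr <- reference_array()
  movies <- list(
    loom = render_stimulus(make_loom(), arr),
    near_miss = render_stimulus(make_near_miss(), arr),
    translation = render_stimulus(make_translation(), arr)
  )
  for (mv in movies) {
    bat <- condition_battery(mv)
    tol <- 1e-9
    expect_true(all(bat$L$output_integrated <=
                      bat$none$output_integrated + tol))
    expect_true(all(bat$S$output_integrated <=
                      bat$none$output_integrated + tol))
    expect_true(all(bat$LS$output_integrated <= bat$L$output_integrated + tol))
    expect_true(all(bat$LS$output_integrated <= bat$S$output_integrated + tol))
  }
})

test_that("divergence time and suppression index follow their definitions", {
  a <- c(rep(1, 20), rep(2, 10))
  expect_true(is.na(divergence_time(a, a)))
  b <- a
  b[12:30] <- b[12:30] + 0.5
  expect_equal(divergence_time(a, b, epsilon = 0.01), 12)
  expect_error(divergence_time(numeric(0), numeric(0)), "nonempty")

  arr <- hex_array(19)
  frames <- matrix(0L, 19, 15)
  frames[1, 5:15] <- 1L
  mv <- movie_from_frames(frames, arr)
  res <- run_network(mv, network_params(enable_L = FALSE, enable_S = FALSE))
  expect_equal(suppression_index(res, res), 0)
  zero <- res
  zero$output_integrated[] <- 0
  expect_equal(suppression_index(res, zero), 1)
  expect_error(suppression_index(zero, res), "zero")
})

test_that("zero persistence means no self-inhibition at all", {
  arr <- reference_array()
  mv <- render_stimulus(make_translation(), arr)
  base <- run_network(mv, network_params(enable_L = FALSE, enable_S = FALSE))
  s0 <- run_network(mv, network_params(enable_L = FALSE, enable_S = TRUE,
                                       S_persistence_ms = 0))
  expect_equal(suppression_index(base, s0), 0)
  expect_error(persistence_sweep(mv, persistences_ms = integer(0)), "nonempty")
})
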