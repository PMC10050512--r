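# Synthetic traces with known structure serve as ground truth throughout.

test_that("object traces average member columns on the activity scale", {
  co <- generate_collection("orthogonal_fixed", n_objects = 2, sizes = 10,
                            L = 5, M = 5, seed = 1)
  nt <- 60
  z <- matrix(0, nt, 25)
  z[, co$objects[[1]]] <- 5                       # all features active
  z[, co$objects[[2]][1:7]] <- 5                  # 70% of features active
  rec <- synthetic_recording(list(WM = z, L1 = z, L2 = z, L3 = z), co)
  tr <- object_traces(rec, "L3")
  expect_equal(unique(tr$traces[, 1]), 5)
  expect_equal(unique(tr$traces[, 2]), 3.5)
  z0 <- matrix(0, nt, 25)
  rec0 <- synthetic_recording(list(WM = z0, L1 = z0, L2 = z0, L3 = z0), co)
  expect_true(all(object_traces(rec0, "L1")$traces == 0))
})

test_that("dominant_frequency finds pure tones and flags arrhythmic traces", {
  t <- seq(0, 3, by = 1e-3)
  expect_equal(dominant_frequency(sin(2 * pi * 10 * t), 1000, c(2, 12)), 10,
               tolerance = 0.05)
  two <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
  expect_equal(dominant_frequency(two, 1000, c(2, 12)), 5, tolerance = 0.1)
  expect_equal(dominant_frequency(two, 1000, c(15, 100)), 40, tolerance = 0.05)
  expect_true(is.na(dominant_frequency(rep(1, 3000), 1000, c(2, 12))))
  expect_error(dominant_frequency(sin(t[1:100]), 1000, c(2, 12)), "periods")
})

# brute-force event scan used as the oracle for the event detector
brute_events <- function(traces, time, high = 4, low = 1) {
  lapply(seq_len(ncol(traces)), function(k) {
    others_ok <- apply(traces[, -k, drop = FALSE], 1, max) < low
    n <- 0; state <- FALSE
    for (i in seq_along(time)) {
      if (!state && traces[i, k] >= high && others_ok[i]) { state <- TRUE; n <- n + 1 }
      if (state && traces[i, k] < low) state <- FALSE
    }
    n
  })
}

test_that("recognition events match a brute-force scan on synthetic bursts", {
  set.seed(4)
  nt <- 1500
  n_obj <- 3
  tr <- matrix(0, nt, n_obj)
  # 4 clean disjoint bursts per object, round-robin every 125 ms
  slot <- 0
  for (b in 1:4) for (k in 1:n_obj) {
    at <- 40 + slot * 120
    tr[at:(at + 25), k] <- 4.6
    slot <- slot + 1
  }
  time <- seq(0, by = 1e-3, length.out = nt)
  ev <- detect_recognitions(tr, time)
  expect_equal(tabulate(ev$object, 3), rep(4L, 3))
  expect_equal(tabulate(ev$object, 3),
               as.integer(unlist(brute_events(tr, time))))
  expect_true(all(ev$offset > ev$onset))
  expect_true(all(ev$peak >= 4))
  # fully overlapping bursts of two objects violate exclusivity: no events
  both <- cbind(tr[, 1], tr[, 1], tr[, 3] * 0)
  expect_identical(nrow(detect_recognitions(both, time)), 0L)
})

test_that("success classification is robust to the exact thresholds", {
  set.seed(5)
  nt <- 1500
  tr <- matrix(0.2, nt, 2)
  for (b in 0:3) {
    tr[(100 + b * 300):(140 + b * 300), 1] <- 4.8
    tr[(250 + b * 300):(290 + b * 300), 2] <- 4.8
  }
  time <- seq(0, by = 1e-3, length.out = nt)
  for (high in c(3.5, 4, 4.5)) for (low in c(0.5, 1, 1.5)) {
    ev <- detect_recognitions(tr, time, high = high, low = low)
    expect_identical(tabulate(ev$object, 2), c(4L, 4L))
  }
})

test_that("sequence decoding orders events within gate cycles", {
  co <- generate_collection("orthogonal_fixed", n_objects = 3, sizes = 5,
                            L = 5, M = 5, seed = 2)
  nt <- 400
  z3 <- matrix(0, nt, 25)
  gate <- rep(FALSE, nt)
  # two cycles, each replaying 1 -> 2 -> 3
  for (cyc in c(0, 200)) {
    gate[(cyc + 50):(cyc + 150)] <- TRUE
    for (k in 1:3)
      z3[(cyc + 50 + 30 * (k - 1)):(cyc + 70 + 30 * (k - 1)),
         co$objects[[k]]] <- 5
  }
  z0 <- matrix(0, nt, 25)
  rec <- synthetic_recording(list(WM = z0, L1 = z0, L2 = z0, L3 = z3), co,
                             gate = gate)
  dec <- decode_sequence(rec)
  expect_length(dec, 2)
  expect_identical(dec[[1]], c(1L, 2L, 3L))
  expect_identical(dec[[2]], c(1L, 2L, 3L))
  # an empty cycle decodes to an empty list
  gate2 <- gate; z_empty <- z3 * 0
  rec2 <- synthetic_recording(list(WM = z0, L1 = z0, L2 = z0, L3 = z_empty),
                              co, gate = gate2)
  expect_true(all(lengths(decode_sequence(rec2)) == 0))
})

test_that("phase estimates agree with an independent least-squares fit", {
  co <- generate_collection("orthogonal_fixed", n_objects = 2, sizes = 5,
                            L = 5, M = 5, seed = 3)
  nt <- 1800
  z3 <- matrix(0, nt, 25)
  gate <- rep(FALSE, nt)
  # three "cue epochs" of two cycles each; object 2's burst onset moves
  # earlier in the cycle by a fixed 30 ms per epoch
  onsets_frac <- c()
  for (e in 0:2) for (c2 in 0:1) {
    base <- 600 * e + 300 * c2 + 50
    gate[base:(base + 200)] <- TRUE
    lag <- 120 - 30 * e
    z3[(base + lag):(base + lag + 20), co$objects[[2]]] <- 5
    onsets_frac <- c(onsets_frac, lag / 200)
  }
  z0 <- matrix(0, nt, 25)
  rec <- synthetic_recording(list(WM = z0, L1 = z0, L2 = z0, L3 = z3), co,
                             gate = gate)
  rec$events <- data.frame(time = c(0, 0.6, 1.2))
  pp <- phase_precession_stat(rec, object = 2)
  oracle <- unname(coef(lm(tapply(onsets_frac, rep(1:3, each = 2), mean)
                           ~ c(1, 2, 3)))[2])
  expect_equal(pp$slope, oracle, tolerance = 0.05)
  expect_lt(pp$slope, 0)
  # a single cue epoch yields no slope
  rec$events <- data.frame(time = 0)
  expect_true(is.na(phase_precession_stat(rec, object = 2)$slope))
})

test_that("spontaneous burst decoding and transition classification", {
  seqs <- list(c(1L, 2L, 3L), c(6L, 7L), c(3L, 7L), c(2L, 5L))
  cl <- classify_transitions(seqs, list(1:5, 6:10))
  expect_identical(cl$within, 3L)    # 1-2, 2-3, 6-7
  expect_identical(cl$concat, 1L)    # 3-7 jumps across lists
  expect_identical(cl$illegal, 1L)   # 2-5: same list but not consecutive
  cl0 <- classify_transitions(list(1L), list(1:5))
  expect_true(is.na(cl0$legal))
})

test_that("an empty battery is vacuously successful", {
  row <- table2_battery(0, n_trials = 3)
  expect_equal(row$pct_success_2x, 100)
  expect_true(is.na(row$gamma_frequency))
})
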