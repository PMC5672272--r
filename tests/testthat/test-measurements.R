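test_that("read_plates round-trips a well-formed CSV and validates structure", {
  sim <- simulate_plates(n_plates = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(sim$plates, path)
  plates <- read_plates(path)
  expect_equal(dplyr::n_distinct(plates$plate_id), 5)
  expect_equal(nrow(plates), 5 * 22)
  counts <- dplyr::count(plates, plate_id, pair_id)
  expect_true(all(counts$n == 2))
  expect_true(all(plates$long_arm_um >= plates$short_arm_um))
})

test_that("read_plates normalises arm orientation and moves the satellite flag", {
  df <- plates_from_arms(
    short = matrix(c(3, 1), 1), long = matrix(c(2, 2), 1),
    satellite_arm = c("short", "none")
  )
  plates <- read_plates(df)
  p1 <- plates[plates$pair_id == 1, ]
  expect_equal(p1$short_arm_um, c(2, 2))
  expect_equal(p1$long_arm_um, c(3, 3))
  expect_equal(p1$satellite_arm, c("long", "long"))
})

test_that("read_plates rejects bad rows with informative errors", {
  df <- plates_from_arms(matrix(c(1, 2), 1), matrix(c(2, 3), 1))
  zero <- dplyr::mutate(df, short_arm_um = dplyr::if_else(dplyr::row_number() == 3, 0, short_arm_um))
  expect_error(read_plates(zero), "row 3", class = "karyometry_validation_error")

  odd <- df[-1, ]
  expect_error(read_plates(odd), "pair 1 has 1 homolog in plate P1",
               class = "karyometry_validation_error")

  expect_error(read_plates(dplyr::select(df, -plate_id)), "plate_id",
               class = "karyometry_schema_error")
})

test_that("relative lengths are forced by the definition", {
  eq <- plates_from_arms(matrix(rep(1, 11), 1), matrix(rep(1.5, 11), 1))
  rl <- relative_lengths(eq)
  expect_equal(rl$rl_total, rep(100 / 11, 11))

  three <- plates_from_arms(matrix(c(0.8, 1.2, 2), 1), matrix(c(1.2, 1.8, 3), 1))
  expect_equal(relative_lengths(three)$rl_total, c(20, 30, 50))
})

test_that("relative lengths sum to 100 per plate for random inputs", {
  set.seed(42)
  for (rep in 1:5) {
    short <- matrix(stats::runif(33, 0.5, 3), nrow = 3)
    long <- short * matrix(stats::runif(33, 1, 3), nrow = 3)
    rl <- relative_lengths(plates_from_arms(short, long))
    sums <- tapply(rl$rl_total, rl$plate_id, sum)
    expect_equal(as.numeric(sums), rep(100, 3))
    arm_sums <- tapply(rl$rl_short + rl$rl_long, rl$plate_id, sum)
    expect_equal(as.numeric(arm_sums), rep(100, 3))
  }
})

test_that("aggregation uses sample SDs and orders pairs by decreasing size", {
  single <- plates_from_arms(matrix(c(1, 2), 1), matrix(c(2, 3), 1))
  k1 <- aggregate_karyotype(single)
  expect_true(all(k1$pairs$rl_total_sd == 0))
  expect_true(all(k1$pairs$ar_sd == 0))

  # two plates built so pair 1's rl_total is 12.0 and 13.0
  short <- matrix(c(4, 44, 4.55, 45.5), 2, byrow = TRUE)
  long <- matrix(c(8, 44, 8.45, 41.5), 2, byrow = TRUE)
  rl <- relative_lengths(plates_from_arms(short, long))
  expect_equal(rl$rl_total[rl$pair_id == 1], c(12, 13))
  k2 <- aggregate_karyotype(plates_from_arms(short, long))
  big <- k2$pairs[k2$pairs$source_pair_id == 1, ]
  expect_equal(big$rl_total_mean, 12.5)
  expect_equal(big$rl_total_sd, sqrt(0.5), tolerance = 1e-12)

  expect_true(all(diff(k2$pairs$rl_total_mean) <= 0))
  expect_equal(k2$pairs$pair_id, seq_len(nrow(k2$pairs)))
})

test_that("aggregated karyotype satisfies haploid normalisation and CI consistency", {
  sim <- simulate_plates(seed = 11)
  k <- aggregate_karyotype(sim$plates)
  expect_equal(sum(k$pairs$rl_total_mean), 100, tolerance = 0.05)
  expect_equal(k$pairs$ci_mean, 100 / (1 + k$pairs$ar_mean), tolerance = 0.5)
  expect_equal(k$two_n, 22)
})

test_that("aggregation recovers generator truth at 2% noise", {
  truth <- canavalia_karyotypes("gladiata")
  sim <- simulate_plates(noise_cv = 0.02, n_plates = 5, seed = 5)
  k <- aggregate_karyotype(sim$plates)
  got <- k$pairs[order(k$pairs$source_pair_id), ]
  expect_true(all(abs(got$rl_total_mean - truth$rl_total_mean) < 0.2))
})

test_that("aggregation rejects inconsistent pair sets across plates", {
  a <- plates_from_arms(matrix(c(1, 2), 1), matrix(c(2, 3), 1), plate_ids = "P1")
  b <- plates_from_arms(matrix(c(1, 2, 3), 1), matrix(c(2, 3, 4), 1), plate_ids = "P2")
  expect_error(aggregate_karyotype(dplyr::bind_rows(a, b)),
               "same set of pair_ids", class = "karyometry_validation_error")
})

test_that("TCL selects the most condensed plates and uses sample SD", {
  one <- plates_from_arms(matrix(c(0.8, 1.2, 2), 1), matrix(c(1.2, 1.8, 3), 1))
  t1 <- total_complement_length(one)
  expect_equal(t1$tcl_mean, 10)
  expect_equal(t1$tcl_sd, 0)

  # three plates with TCL 40, 41, 39; condensation rank orders them 39, 40, 41
  short <- matrix(c(20, 20.5, 19.5), 3)
  long <- matrix(c(20, 20.5, 19.5), 3)
  plates <- plates_from_arms(short, long)
  plates$condensation_rank <- c(3L, 1L, 2L)[match(plates$plate_id, c("P1", "P2", "P3"))]
  # ranks: P3 (39) is rank 2, P2 (41) rank 1, P1 (40) rank 3
  t3 <- total_complement_length(plates, k = 3)
  expect_equal(t3$tcl_mean, 40)
  expect_equal(t3$tcl_sd, 1)

  t2 <- total_complement_length(plates, k = 2)
  expect_equal(t2$tcl_mean, mean(c(41, 39)))
  expect_equal(t2$tcl_sd, stats::sd(c(41, 39))) # ranks 1-2 only, not all plates

  expect_error(total_complement_length(plates, k = 0), class = "karyometry_argument_error")
  expect_warning(
    total_complement_length(dplyr::select(plates, -condensation_rank), k = 2),
    "condensation_rank"
  )
})

test_that("RL, AR, CI are scale-invariant and TCL scales linearly", {
  set.seed(7)
  short <- matrix(stats::runif(22, 0.5, 2), 2)
  long <- short * matrix(stats::runif(22, 1, 2), 2)
  base <- aggregate_karyotype(plates_from_arms(short, long))
  scaled <- aggregate_karyotype(plates_from_arms(short * 3.7, long * 3.7))
  expect_equal(scaled$pairs$rl_total_mean, base$pairs$rl_total_mean)
  expect_equal(scaled$pairs$ar_mean, base$pairs$ar_mean)
  expect_equal(scaled$pairs$ci_mean, base$pairs$ci_mean)
  expect_equal(scaled$tcl_mean, 3.7 * base$tcl_mean)
})

test_that("duplicating the plate list shrinks the sample SD", {
  set.seed(8)
  short <- matrix(stats::runif(33, 0.5, 2), 3)
  long <- short * matrix(stats::runif(33, 1, 2), 3)
  plates <- plates_from_arms(short, long)
  doubled <- plates_from_arms(rbind(short, short), rbind(long, long))
  k1 <- aggregate_karyotype(plates)
  k2 <- aggregate_karyotype(doubled)
  expect_true(all(k2$pairs$rl_total_sd < k1$pairs$rl_total_sd))

  same <- plates_from_arms(short[c(1, 1, 1), ], long[c(1, 1, 1), ])
  expect_true(all(aggregate_karyotype(same)$pairs$rl_total_sd == 0))
})
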