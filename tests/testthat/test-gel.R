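test_that("ladder calibration inverts the generating model exactly", {
  truth <- migration_model(100, 40)
  lad <- synthetic_ladder(c(10000, 5000, 2000, 1000, 500), model = truth)
  fit <- fit_migration_model(lad)
  expect_equal(fit$a, 100, tolerance = 1e-10)
  expect_equal(fit$b, 40, tolerance = 1e-10)
  expect_lt(fit$rms, 1e-10)
})

test_that("calibration from a noisy ladder recovers the slope within 5%", {
  truth <- migration_model(220, 40)
  lad <- synthetic_ladder(c(10000, 1000, 100), model = truth,
                          noise_sd = 0.1, seed = 33)
  fit <- fit_migration_model(lad)
  expect_lt(abs(fit$b - 40) / 40, 0.05)
  expect_gt(fit$rms, 0)
})

test_that("degenerate ladders are rejected", {
  expect_error(fit_migration_model(tibble::tibble(size_bp = c(1000, 500),
                                                  distance_mm = c(10, 20))),
               class = "phagerflp_input_error")
  expect_error(fit_migration_model(tibble::tibble(size_bp = c(1000, 500, 200),
                                                  distance_mm = c(10, 30, 20))),
               class = "phagerflp_input_error")
})

test_that("larger fragments migrate strictly less far", {
  m <- migration_model(220, 40)
  sizes <- withr::with_seed(4, sort(round(10^runif(20, 2, 5.2))))
  expect_true(all(diff(predict(m, sizes)) <= 0))
  expect_true(all(diff(predict(m, unique(sizes))) < 0))
})

test_that("a noiseless lane has one band per well-separated fragment at d(s)", {
  m <- migration_model(100, 40)
  frags <- c(9000, 4000, 1500, 600)
  lane <- render_lane(frags, m, detection = c(100, 50000))
  expect_equal(nrow(lane), 4L)
  expect_equal(lane$distance_mm, sort(predict(m, frags)))
  expect_true(all(lane$multiplicity == 1L))
})

test_that("bands closer than the resolution limit merge with summed multiplicity", {
  m <- migration_model(100, 40)
  # |d(3000) - d(3010)| = 40*log10(3010/3000) ~= 0.058 mm < 0.5 mm
  expect_lt(abs(diff(predict(m, c(3000, 3010)))), 0.5)
  lane <- render_lane(c(3000, 3010, 9000), m)
  expect_equal(nrow(lane), 2L)
  expect_equal(sort(lane$multiplicity), c(1L, 2L))
})

test_that("fragments outside the detection window leave no band", {
  m <- migration_model(220, 40)
  lane <- render_lane(c(80, 5000), m, detection = c(100, 50000))
  expect_equal(nrow(lane), 1L)
  inferred <- infer_band_sizes(lane, m)
  expect_equal(inferred$size_bp, 5000)
})

test_that("noiseless render -> infer round trip recovers sizes to the bp", {
  m <- migration_model(220, 40)
  frags <- frag_split(31280)
  lane <- infer_band_sizes(render_lane(frags, m, detection = c(1, 2e5)), m)
  expect_equal(sort(lane$size_bp), sort(frags), tolerance = 0)
  expect_equal(estimate_genome_size(lane, m), 31280)
})

test_that("noisy round trip stays within 3% of truth across seeds", {
  m <- migration_model(220, 40)
  frags <- c(12000, 6000, 3000, 1500, 700)
  rel_err <- unlist(lapply(1:100, function(s) {
    lane <- infer_band_sizes(
      render_lane(frags, m, noise_sd = 0.2, seed = s, detection = c(1, 2e5)), m)
    abs(sort(lane$size_bp) - sort(frags)) / sort(frags)
  }))
  expect_lt(stats::quantile(rel_err, 0.95), 0.03)
})

test_that("genome-size estimation follows lane arithmetic", {
  m <- migration_model(220, 40)
  # full genome round trip at a published-scale size
  g <- random_genome_with_fragments(frag_split(31280), seed = 8, id = "q")
  dig <- digest_genomes(g)
  lane <- render_lane(dig, m, detection = c(1, 2e5))
  expect_equal(estimate_genome_size(lane, m), 31280)
  # a 400 bp fragment below detection biases the estimate low by exactly 400
  frags <- c(frag_split(31280 - 400, props = c(0.4, 0.3, 0.2, 0.1)), 400)
  lane2 <- render_lane(frags, m, detection = c(500, 2e5))
  expect_equal(estimate_genome_size(lane2, m), sum(frags) - 400)
  expect_lte(estimate_genome_size(lane2, m), sum(frags))
  # a single uncut band estimates its own size
  lane3 <- render_lane(20000, m, detection = c(1, 2e5))
  expect_equal(estimate_genome_size(lane3, m), 20000)
})

test_that("non-physical band positions are rejected", {
  m <- migration_model(100, 40)
  lane <- tibble::tibble(lane_id = "x", band_index = 1L, distance_mm = 101,
                         size_bp = NA_real_, multiplicity = 1L)
  expect_error(infer_band_sizes(lane, m), class = "phagerflp_input_error")
  expect_error(estimate_genome_size(lane[0, ], m), class = "phagerflp_input_error")
})

test_that("rendering with noise is deterministic given the seed", {
  m <- migration_model(220, 40)
  l1 <- render_lane(c(5000, 2000, 800), m, noise_sd = 0.3, seed = 77)
  l2 <- render_lane(c(5000, 2000, 800), m, noise_sd = 0.3, seed = 77)
  expect_identical(tibble::as_tibble(l1), tibble::as_tibble(l2))
  expect_error(render_lane(c(5000), m, noise_sd = 0.3),
               class = "phagerflp_input_error")
})
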