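test_that("random genomes are reproducible and honour the GC fraction", {
  g1 <- random_genome(10000, 0.5, seed = 1)
  g2 <- random_genome(10000, 0.5, seed = 1)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq, random_genome(10000, 0.5, seed = 2)$seq))

  g <- random_genome(40000, gc = 0.37, seed = 3)
  gc_obs <- sum(strsplit(g$seq, "")[[1]] %in% c("G", "C")) / 40000
  expect_lt(abs(gc_obs - 0.37), 0.01)   # ~4 binomial SDs at n = 40000

  tiny <- random_genome(1, seed = 4)
  expect_equal(nchar(tiny$seq), 1L)
  expect_error(random_genome(0, seed = 1), class = "phagerflp_input_error")
  expect_error(random_genome(100, gc = 1, seed = 1), class = "phagerflp_input_error")
})

test_that("planted-fragment genomes digest to exactly the requested lengths", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      frags <- sort(sample(200:5000, sample(3:6, 1)), decreasing = TRUE)
      g <- random_genome_with_fragments(frags, seed = rep)
      d <- digest_genomes(g)
      expect_equal(d$length_bp, frags)
    }
  })
})

test_that("evolution on a tree follows the substitution model", {
  root <- random_genome(5000, seed = 5, id = "root")
  frozen <- evolve_on_tree(root, "((A:0,B:0):0,C:0);", seed = 6)
  expect_true(all(frozen$seq == root$seq))

  # one branch of length 0.01: differing sites ~ Binomial(L, 1 - e^-0.01)
  big <- random_genome(100000, seed = 7, id = "root")
  leaf <- evolve_on_tree(big, "(A:0.01);", seed = 8)
  ndiff <- sum(strsplit(big$seq, "")[[1]] != strsplit(leaf$seq, "")[[1]])
  p <- 1 - exp(-0.01)
  expect_lt(abs(ndiff - 1e5 * p), 3 * sqrt(1e5 * p * (1 - p)))

  # determinism and length conservation
  leaf2 <- evolve_on_tree(big, "(A:0.01);", seed = 8)
  expect_identical(leaf$seq, leaf2$seq)
  expect_equal(nchar(leaf$seq), 100000L)
})

test_that("sister leaves share more restriction sites than distant ones", {
  nwk <- "((A1:0.002,A2:0.002):0.05,B:0.052);"
  shared <- function(x, y) length(intersect(x, y))
  sis <- num <- 0
  for (s in 1:20) {
    root <- random_genome(30000, seed = 1000 + s, id = "root")
    leaves <- evolve_on_tree(root, nwk, seed = 2000 + s)
    sites <- lapply(leaves$id, function(id) {
      find_cut_sites(leaves[leaves$id == id, ])$cut_pos
    })
    names(sites) <- leaves$id
    sis <- sis + shared(sites$A1, sites$A2)
    num <- num + shared(sites$A1, sites$B)
  }
  expect_gt(sis, num)
})

test_that("challenge simulation reproduces exact means at zero noise", {
  obs <- simulate_challenge(3.05e9, effect_fraction = 0.85, cv = 0,
                            n_replicates = 3, seed = 1)
  m <- tapply(obs$value, obs$condition, mean)
  expect_equal(percent_reduction(m[["control"]], m[["phage"]]), 85)
  expect_equal(unique(obs$value[obs$condition == "control"]), 3.05e9)
})

test_that("challenge simulation has the requested structure and noise", {
  obs <- simulate_challenge(1e6, effect_fraction = 0.5, cv = 0.1,
                            n_replicates = 5, seed = 42, measure = "pfu_per_g",
                            timepoint = "tf")
  expect_equal(nrow(obs), 10L)
  expect_setequal(unique(obs$condition), c("control", "phage"))
  expect_true(all(obs$value > 0))
  expect_equal(unique(obs$measure), "pfu_per_g")
  obs2 <- simulate_challenge(1e6, 0.5, 0.1, 5, seed = 42, measure = "pfu_per_g",
                             timepoint = "tf")
  expect_identical(obs, obs2)
  # lognormal mean is calibrated: across many replicates the sample mean
  # approaches the requested control mean
  many <- simulate_challenge(1e6, 0.5, 0.2, n_replicates = 2000, seed = 9)
  expect_lt(abs(mean(many$value[many$condition == "control"]) / 1e6 - 1), 0.02)

  expect_error(simulate_challenge(1e6, 1, 0.1, seed = 1), class = "phagerflp_input_error")
  expect_error(simulate_challenge(1e6, -0.1, 0.1, seed = 1), class = "phagerflp_input_error")
  expect_error(simulate_challenge(1e6, 0.5, 0.1, n_replicates = 2, seed = 1),
               class = "phagerflp_input_error")
  expect_error(simulate_challenge(0, 0.5, 0.1, seed = 1), class = "phagerflp_input_error")
})

test_that("a realistic effect is detected in nearly all simulated assays", {
  hits <- sum(vapply(1:200, function(s) {
    obs <- simulate_challenge(3e9, effect_fraction = 0.85, cv = 0.1,
                              n_replicates = 3, seed = s)
    two_sample_t(obs$value[obs$condition == "control"],
                 obs$value[obs$condition == "phage"])$significant
  }, NA))
  expect_gte(hits, 0.95 * 200)
})

test_that("the two-clade truth tree is well formed", {
  skip_if_not_installed("ape")
  phy <- ape::read.tree(text = two_clade_tree(3, 0.002, 0.05))
  expect_equal(sort(phy$tip.label), c("A1", "A2", "A3", "B1", "B2", "B3"))
  expect_equal(sum(phy$edge.length), 6 * 0.002 + 2 * 0.05)
})
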