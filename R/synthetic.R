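#' Generate a random genome sequence
#'
#' i.i.d. bases with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#' Deterministic for a given seed. The default GC fraction of 0.37 is typical
#' of enterococci and their phages.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc GC fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param id Sequence label.
#' @param topology Passed to [genome_tbl()].
#' @return A one-row genome tibble.
#' @examples
#' random_genome(1000, seed = 1)
#' @export
random_genome <- function(length, gc = 0.37, seed = NULL, id = "synthetic1",
                          topology = "linear") {
  if (length < 1) abort_input("`length` must be >= 1")
  if (gc <= 0 || gc >= 1) abort_input("`gc` must lie strictly between 0 and 1")
  seq <- with_seed_(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  genome_tbl(id, seq, topology)
}

#' Generate a genome with prescribed restriction-fragment lengths
#'
#' Builds a random linear genome whose digest with `enzyme` yields exactly
#' the requested fragment lengths: spurious recognition sites arising by
#' chance are scrubbed by point mutation, then sites are planted so the cuts
#' fall at the cumulative fragment boundaries. Useful for constructing gel
#' calibration/round-trip fixtures of known composition.
#'
#' @param fragment_lengths Integer vector of desired fragment lengths (bp),
#'   each comfortably longer than the recognition site.
#' @inheritParams random_genome
#' @param enzyme A [restriction_enzyme()].
#' @return A one-row genome tibble (linear).
#' @export
random_genome_with_fragments <- function(fragment_lengths, enzyme = hindiii(),
                                         gc = 0.37, seed = NULL, id = "planted1") {
  fragment_lengths <- as.integer(fragment_lengths)
  k <- nchar(enzyme$recognition)
  if (any(fragment_lengths < k + 1)) {
    abort_input("each fragment must be longer than the recognition site")
  }
  L <- sum(fragment_lengths)
  cuts <- cumsum(fragment_lengths)[-length(fragment_lengths)]
  site_starts <- cuts - enzyme$cut_offset        # 0-based starts of planted sites
  planted <- unlist(lapply(site_starts, function(s) seq(s + 1, s + k))) # 1-based
  with_seed_(seed, {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    for (s in site_starts) {
      chars[(s + 1):(s + k)] <- strsplit(enzyme$recognition, "")[[1]]
    }
    # mutate away chance occurrences (outside the planted windows) until clean
    repeat {
      seq <- paste(chars, collapse = "")
      hits <- cut_sites_one(seq, enzyme, "linear")
      spurious <- setdiff(hits, cuts)
      if (length(spurious) == 0) break
      for (cutpos in spurious) {
        idx <- setdiff(seq(cutpos - enzyme$cut_offset + 1,
                           cutpos - enzyme$cut_offset + k), planted)
        i <- idx[1]
        chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
      }
    }
    genome_tbl(id, seq)
  })
}

#' Evolve a root genome along a tree by point substitutions
#'
#' Jukes-Cantor-style evolution: along each branch of length `l` (expected
#' substitutions per site), every site mutates independently with probability
#' `1 - exp(-l)`, to a base drawn uniformly from the three alternatives. No
#' indels are introduced, so all leaf genomes retain the root length and
#' their digest profiles stay directly comparable. Deterministic per seed.
#'
#' @param root A one-row genome tibble (ACGT only) providing the ancestral
#'   sequence.
#' @param tree An `ape::phylo` object or a Newick string with branch lengths;
#'   tip labels become the leaf genome ids.
#' @param seed Integer seed.
#' @return A genome tibble with one row per tip, topology inherited from the
#'   root.
#' @export
evolve_on_tree <- function(root, tree, seed = NULL) {
  root <- validate_genomes(root)
  if (nrow(root) != 1) abort_input("`root` must be a single genome")
  if (grepl("[^ACGT]", root$seq)) abort_input("root sequence must be unambiguous ACGT")
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) abort_input("`tree` must be a phylo object or Newick string")
  if (is.null(tree$edge.length)) abort_input("`tree` must carry branch lengths")
  if (any(tree$edge.length < 0)) abort_input("branch lengths must be >= 0")
  bases <- c("A", "C", "G", "T")
  x0 <- match(strsplit(root$seq, "")[[1]], bases)
  L <- length(x0)
  ntip <- length(tree$tip.label)
  rootnode <- ntip + 1L
  phy <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[rootnode]] <- x0
  with_seed_(seed, {
    for (e in seq_len(nrow(phy$edge))) {
      parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
      p <- 1 - exp(-phy$edge.length[e])
      x <- seqs[[parent]]
      hit <- which(stats::runif(L) < p)
      if (length(hit)) {
        # uniform choice among the three other bases
        shift <- sample.int(3, length(hit), replace = TRUE)
        x[hit] <- ((x[hit] - 1L + shift) %% 4L) + 1L
      }
      seqs[[child]] <- x
    }
  })
  genome_tbl(
    id = tree$tip.label,
    seq = vapply(seq_len(ntip), function(i) paste(bases[seqs[[i]]], collapse = ""), ""),
    topology = root$topology
  )
}

#' A balanced two-clade tree in Newick form
#'
#' Two star-shaped clades of `n_per_clade` tips each (labels `A1..`, `B1..`),
#' short within-clade branches and a longer stem separating the clades: the
#' ground-truth topology used to score end-to-end recovery by the RFLP
#' pipeline.
#'
#' @param n_per_clade Tips per clade (>= 2).
#' @param within Branch length tip-to-clade (expected substitutions/site).
#' @param between Stem length clade-to-root, each side.
#' @return A Newick string.
#' @examples
#' two_clade_tree()
#' @export
two_clade_tree <- function(n_per_clade = 3, within = 0.002, between = 0.05) {
  if (n_per_clade < 2) abort_input("`n_per_clade` must be >= 2")
  clade <- function(prefix) {
    tips <- paste0(prefix, seq_len(n_per_clade), ":", format(within, scientific = FALSE))
    paste0("(", paste(tips, collapse = ","), "):", format(between, scientific = FALSE))
  }
  paste0("(", clade("A"), ",", clade("B"), ");")
}

#' Simulate a phage-challenge dataset
#'
#' Control replicates are lognormal with the requested mean and coefficient
#' of variation (the standard noise model for plate counts); treated
#' replicates share the CV with mean `control_mean * (1 - effect_fraction)`.
#' `cv = 0` produces exact means. Deterministic per seed.
#'
#' @param control_mean Mean of the control group (> 0).
#' @param effect_fraction Fractional reduction in the treated group, in
#'   `[0, 1)`.
#' @param cv Coefficient of variation (>= 0).
#' @param n_replicates Replicates per group (>= 3, matching the study
#'   convention of at least three independent results).
#' @param seed Integer seed.
#' @param measure Measurement label, e.g. `"cfu_per_ml"`, `"pfu_per_g"`,
#'   `"tyramine_mM"`.
#' @param timepoint Timepoint label (`"t0"`, `"t15"`, `"tf"`, ...).
#' @return A challenge-observation tibble: `condition` (control/phage),
#'   `timepoint`, `replicate`, `measure`, `value`.
#' @examples
#' simulate_challenge(3.05e9, effect_fraction = 0.85, cv = 0.1, seed = 1)
#' @export
simulate_challenge <- function(control_mean, effect_fraction, cv = 0.1,
                               n_replicates = 3, seed = NULL,
                               measure = "cfu_per_ml", timepoint = "t15") {
  if (control_mean <= 0) abort_input("`control_mean` must be positive")
  if (effect_fraction < 0 || effect_fraction >= 1) {
    abort_input("`effect_fraction` must lie in [0, 1)")
  }
  if (cv < 0) abort_input("`cv` must be >= 0")
  if (n_replicates < 3) abort_input("at least 3 replicates per group are required")
  draw <- function(mu, n) {
    if (cv == 0) return(rep(mu, n))
    sdlog <- sqrt(log1p(cv^2))
    stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  }
  with_seed_(seed, {
    ctrl <- draw(control_mean, n_replicates)
    trt <- draw(control_mean * (1 - effect_fraction), n_replicates)
    tibble::tibble(
      condition = rep(c("control", "phage"), each = n_replicates),
      timepoint = timepoint,
      replicate = rep(seq_len(n_replicates), 2),
      measure = measure,
      value = c(ctrl, trt)
    )
  })
}

#' A synthetic size ladder
#'
#' Rung distances generated from a known migration model, optionally with
#' Gaussian positional noise — the calibration input for
#' [fit_migration_model()].
#'
#' @param sizes Rung sizes in bp (default: a conventional 1 kb-type ladder).
#' @param model A [migration_model()] (the generating truth).
#' @param noise_sd Gaussian noise SD on distances (mm).
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @return Tibble with columns `size_bp`, `distance_mm`.
#' @export
synthetic_ladder <- function(sizes = c(10000, 8000, 6000, 5000, 4000, 3000,
                                       2000, 1500, 1000, 500),
                             model = migration_model(220, 40),
                             noise_sd = 0, seed = NULL) {
  d <- predict(model, sizes)
  if (noise_sd > 0) d <- with_seed_(seed, d + stats::rnorm(length(d), 0, noise_sd))
  tibble::tibble(size_bp = as.numeric(sizes), distance_mm = d)
}
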