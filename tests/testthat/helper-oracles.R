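# Independent oracles: deliberately naive implementations used only to check
# the package's algorithms, never the other way round.

# all-offsets substring scan for restriction sites, 0-based cut positions
oracle_sites <- function(seq, recognition = "AAGCTT", cut_offset = 1L,
                         topology = "linear") {
  seq <- toupper(seq)
  L <- nchar(seq)
  k <- nchar(recognition)
  scan <- if (topology == "circular") paste0(seq, substr(seq, 1, k - 1)) else seq
  starts <- integer(0)
  if (nchar(scan) >= k) {
    for (s in 0:(nchar(scan) - k)) {
      if (substr(scan, s + 1, s + k) == recognition) starts <- c(starts, s)
    }
  }
  cuts <- starts + cut_offset
  if (topology == "circular") cuts <- cuts %% L
  sort(unique(cuts))
}

# brute-force maximum-cardinality one-to-one band matching
oracle_max_matching <- function(p, q, tol) {
  p <- sort(p, decreasing = TRUE)
  q <- sort(q, decreasing = TRUE)
  if (length(p) == 0 || length(q) == 0) return(0L)
  compat <- outer(p, q, function(a, b) abs(a - b) <= tol * (a + b) / 2)
  rec <- function(i, used) {
    if (i > length(p)) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(compat[i, ])) {
      if (!used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(q)))
}

# random band profile on a gel-realistic size range, with occasional
# near-coincident sizes to stress the tolerance window
random_profile <- function(n, near = NULL) {
  sizes <- round(10^stats::runif(n, 2, 4.7))
  if (!is.null(near) && length(near) > 0) {
    extra <- round(near * (1 + stats::runif(length(near), -0.02, 0.02)))
    sizes <- c(extra, sizes)[seq_len(n)]
  }
  pmax(sizes, 50)
}

# random sequence over an alphabet that can include ambiguity codes
random_seq <- function(len, ambiguity = FALSE) {
  alph <- if (ambiguity) c("A", "C", "G", "T", "N", "R", "Y") else c("A", "C", "G", "T")
  prob <- if (ambiguity) c(rep(0.23, 4), 0.04, 0.02, 0.02) else rep(0.25, 4)
  paste(sample(alph, len, replace = TRUE, prob = prob), collapse = "")
}

# plant `recognition` into a sequence at random offsets so site-finding tests
# actually see hits
plant_sites <- function(seq, n_sites, recognition = "AAGCTT") {
  chars <- strsplit(seq, "")[[1]]
  k <- nchar(recognition)
  if (n_sites > 0 && length(chars) >= k) {
    starts <- sample(seq_len(length(chars) - k + 1), n_sites)
    for (s in starts) chars[s:(s + k - 1)] <- strsplit(recognition, "")[[1]]
  }
  paste(chars, collapse = "")
}

# random ultrametric matrix built by agglomerating leaves at increasing
# heights (independent of the package's UPGMA)
random_ultrametric <- function(n) {
  labels <- paste0("t", seq_len(n))
  groups <- as.list(labels)
  M <- matrix(0, n, n, dimnames = list(labels, labels))
  h <- 0
  while (length(groups) > 1) {
    h <- h + stats::runif(1, 0.05, 0.3)
    ij <- sort(sample(length(groups), 2))
    for (a in groups[[ij[1]]]) for (b in groups[[ij[2]]]) {
      M[a, b] <- M[b, a] <- 2 * h
    }
    groups[[ij[1]]] <- c(groups[[ij[1]]], groups[[ij[2]]])
    groups[[ij[2]]] <- NULL
  }
  M
}

# root-to-leaf path lengths of an upgma_tree, from the tidy() edge table
leaf_path_lengths <- function(tree) {
  td <- tidy(tree)
  depth <- function(node) {
    len <- 0
    while (!is.na(td$parent[td$node == node])) {
      len <- len + td$branch_length[td$node == node]
      node <- td$parent[td$node == node]
    }
    len
  }
  vapply(td$node[td$is_leaf], depth, 0)
}

# fixed log-spaced split of a genome length into well-separated fragments
frag_split <- function(L, props = c(0.35, 0.25, 0.17, 0.11, 0.07, 0.05)) {
  f <- floor(props * L)
  f[1] <- f[1] + (L - sum(f))
  f
}
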