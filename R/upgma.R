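#' UPGMA dendrogram from a distance matrix
#'
#' Classic UPGMA (unweighted pair-group method with arithmetic mean):
#' repeatedly merge the closest pair of clusters; the distance from a merged
#' cluster AB to any other cluster C is the size-weighted mean
#' `(|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)`, and the merge node sits at
#' height `d_min / 2`. Ties are broken on the lexicographically smallest pair
#' of cluster labels (each cluster represented by its smallest leaf label),
#' making the construction deterministic across platforms. The result is a
#' rooted binary ultrametric tree: every root-to-leaf path length equals the
#' root height.
#'
#' @param D A symmetric distance matrix with labelled rows/columns, a
#'   [band_distance_matrix()] result, or a `stats::dist`.
#' @return An object of class `upgma_tree`. Use [to_newick()],
#'   [cophenetic_matrix()], [root_split()], `tidy()`, `glance()`,
#'   `autoplot()`.
#' @examples
#' D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(D))
#' @export
upgma <- function(D) {
  M <- as_dist_matrix(D)
  labels <- rownames(M)
  n <- nrow(M)
  clusters <- lapply(labels, function(lab) {
    list(node = list(label = lab, height = 0, children = NULL),
         size = 1L, min_label = lab)
  })
  Dm <- M
  while (length(clusters) > 1) {
    m <- length(clusters)
    off <- Dm
    off[!upper.tri(off)] <- Inf
    dmin <- min(off)
    cand <- which(off == dmin, arr.ind = TRUE)
    # deterministic tie-break: smallest (label_i, label_j) pair, labels sorted
    keys <- apply(cand, 1, function(ij) {
      labs <- sort(c(clusters[[ij[1]]]$min_label, clusters[[ij[2]]]$min_label))
      paste(labs, collapse = "\r")
    })
    pick <- cand[order(keys, method = "radix")[1], ]
    i <- pick[1]; j <- pick[2]
    ci <- clusters[[i]]; cj <- clusters[[j]]
    # smaller subtree-min-label goes first among the children
    kids <- if (ci$min_label <= cj$min_label) list(ci, cj) else list(cj, ci)
    merged <- list(
      node = list(label = NULL, height = dmin / 2,
                  children = list(kids[[1]]$node, kids[[2]]$node)),
      size = ci$size + cj$size,
      min_label = min(ci$min_label, cj$min_label)
    )
    newd <- (ci$size * Dm[i, ] + cj$size * Dm[j, ]) / (ci$size + cj$size)
    Dm[i, ] <- newd
    Dm[, i] <- newd
    Dm[i, i] <- 0
    keep <- setdiff(seq_len(m), j)
    Dm <- Dm[keep, keep, drop = FALSE]
    clusters[[i]] <- merged
    clusters[[j]] <- NULL
  }
  structure(list(root = clusters[[1]]$node, labels = labels, method = "upgma"),
            class = "upgma_tree")
}

as_dist_matrix <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (inherits(D, "band_dist")) D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort_input("`D` must be a square matrix")
  if (nrow(D) < 2) abort_input("at least 2 taxa are required")
  if (any(D < 0)) abort_input("distances must be non-negative")
  if (max(abs(D - t(D))) > 1e-8 || any(abs(diag(D)) > 1e-12)) {
    abort_input("`D` must be symmetric with a zero diagonal")
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (anyDuplicated(rownames(D))) abort_input("duplicate labels in distance matrix")
  storage.mode(D) <- "double"
  D
}

tree_leaves <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, tree_leaves))
}

#' Cophenetic distances of a dendrogram
#'
#' Entry (i, j) is twice the height of the lowest common ancestor of leaves i
#' and j; for an ultrametric tree this is the tree distance between them. If
#' the input matrix to [upgma()] was itself ultrametric, the cophenetic
#' matrix reproduces it exactly.
#'
#' @param tree An `upgma_tree`.
#' @return A symmetric labelled matrix.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  labels <- tree$labels
  C <- matrix(0, length(labels), length(labels), dimnames = list(labels, labels))
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    l1 <- tree_leaves(node$children[[1]])
    l2 <- tree_leaves(node$children[[2]])
    C[l1, l2] <<- 2 * node$height
    C[l2, l1] <<- 2 * node$height
    lapply(node$children, walk)
    invisible()
  }
  walk(tree$root)
  C
}

#' The two leaf sets under the root
#'
#' Convenience accessor for topology checks (e.g. did the dendrogram recover
#' a known two-clade split).
#'
#' @param tree An `upgma_tree`.
#' @return List of two character vectors of leaf labels.
#' @export
root_split <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  lapply(tree$root$children, function(ch) sort(tree_leaves(ch)))
}

newick_quote <- function(label) {
  if (grepl("[][():;,' \t]", label)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Serialize a dendrogram as Newick
#'
#' Branch lengths with 6 decimals; labels containing Newick metacharacters
#' are single-quoted; the string is terminated by ";".
#'
#' @param tree An `upgma_tree`.
#' @return A Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  fmt <- function(node, parent_height) {
    bl <- sprintf("%.6f", parent_height - node$height)
    if (is.null(node$children)) {
      paste0(newick_quote(node$label), ":", bl)
    } else {
      inner <- paste(vapply(node$children, fmt, "", parent_height = node$height),
                     collapse = ",")
      paste0("(", inner, "):", bl)
    }
  }
  root <- tree$root
  if (is.null(root$children)) return(paste0(newick_quote(root$label), ";"))
  inner <- paste(vapply(root$children, fmt, "", parent_height = root$height),
                 collapse = ",")
  paste0("(", inner, ");")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<UPGMA dendrogram> %d leaves, root height %.6g\n",
              length(x$labels), x$root$height))
  cat(to_newick(x), "\n")
  invisible(x)
}

#' @param x An `upgma_tree`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per node (`node`, `parent`,
#'   `label`, `height`, `branch_length`, `is_leaf`); `glance()`: a one-row
#'   tibble (`n_leaves`, `root_height`).
#' @rdname upgma
#' @method tidy upgma_tree
#' @export
tidy.upgma_tree <- function(x, ...) {
  rows <- list()
  counter <- 0L
  emit <- function(node, parent_id, parent_height) {
    counter <<- counter + 1L
    id <- counter
    lab <- if (is.null(node$label)) NA_character_ else node$label
    bl <- if (is.na(parent_id)) NA_real_ else parent_height - node$height
    h <- node$height
    leaf <- is.null(node$children)
    rows[[id]] <<- tibble::tibble(
      node = id, parent = parent_id, label = lab,
      height = h, branch_length = bl, is_leaf = leaf
    )
    for (ch in node$children) emit(ch, id, node$height)
  }
  emit(x$root, NA_integer_, NA_real_)
  purrr::list_rbind(rows)
}

#' @rdname upgma
#' @method glance upgma_tree
#' @export
glance.upgma_tree <- function(x, ...) {
  tibble::tibble(n_leaves = length(x$labels), root_height = x$root$height)
}

#' @param object An `upgma_tree`.
#' @rdname upgma
#' @method autoplot upgma_tree
#' @export
autoplot.upgma_tree <- function(object, ...) {
  segs <- list()
  lab <- list()
  build <- function(node) {
    if (is.null(node$children)) {
      x <- { leaf_i <<- leaf_i + 1; leaf_i }
      lab[[length(lab) + 1]] <<- tibble::tibble(x = x, y = 0, label = node$label)
      return(x)
    }
    cx <- vapply(node$children, build, 0)
    ch <- vapply(node$children, function(n) n$height, 0)
    x <- mean(cx)
    segs[[length(segs) + 1]] <<- tibble::tibble(
      x = c(cx, min(cx)), xend = c(cx, max(cx)),
      y = c(ch, node$height), yend = c(node$height, node$height, node$height)
    )
    x
  }
  leaf_i <- 0
  build(object$root)
  segs <- purrr::list_rbind(segs)
  lab <- purrr::list_rbind(lab)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "distance (1 - band-sharing similarity)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}
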