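#' Locate restriction cut positions in genomes
#'
#' Scans each genome for exact occurrences of the enzyme's recognition
#' sequence and returns the 0-based cut coordinates. Matching is conservative:
#' a genome position carrying an ambiguity code (including N) never matches an
#' unambiguous recognition base, so sites running through ambiguous stretches
#' are dropped rather than expanded. Palindromic recognition sequences are
#' scanned on one strand only. For circular genomes, sites spanning the
#' origin are detected and cut coordinates are reported modulo genome length.
#'
#' @param genomes A genome tibble (see [genome_tbl()]).
#' @param enzyme A [restriction_enzyme()]; defaults to HindIII.
#'
#' @return A tibble with columns `genome_id` and `cut_pos` (0-based, strictly
#'   increasing within a genome). Genomes with no site contribute no rows.
#' @examples
#' find_cut_sites(genome_tbl("g", "NNAAGCTTNN"))
#' @export
find_cut_sites <- function(genomes, enzyme = hindiii()) {
  genomes <- validate_genomes(genomes)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  purrr::pmap(genomes, function(id, seq, topology, ...) {
    tibble::tibble(genome_id = id, cut_pos = cut_sites_one(seq, enzyme, topology))
  }) |>
    purrr::list_rbind()
}

# 0-based cut positions for one sequence; Biostrings does the exact matching
# (fixed = TRUE: IUPAC ambiguity letters only match themselves, so AAGCTT
# never matches through an N), overlapping occurrences included
cut_sites_one <- function(seq, enzyme, topology) {
  L <- nchar(seq)
  k <- nchar(enzyme$recognition)
  scan_seq <- seq
  if (topology == "circular" && L > 1) {
    scan_seq <- paste0(seq, substr(seq, 1, min(k - 1L, L)))
  }
  m <- Biostrings::matchPattern(enzyme$recognition, Biostrings::DNAString(scan_seq),
                                fixed = TRUE)
  starts0 <- Biostrings::start(m) - 1L
  cuts <- starts0 + enzyme$cut_offset
  if (topology == "circular") cuts <- cuts %% L
  sort(unique(as.integer(cuts)))
}

#' Digest genomes into restriction-fragment profiles
#'
#' A linear genome with k interior cut sites yields k+1 fragments (terminal
#' fragments included); a circular genome with k >= 1 sites yields k fragments.
#' A genome without any site yields one full-length fragment, flagged uncut.
#' Fragment lengths always sum to the genome length.
#'
#' @inheritParams find_cut_sites
#' @return A tibble with one row per fragment: `genome_id`, `enzyme`, `rank`
#'   (1 = largest), `length_bp`, `topology_used`, `uncut`.
#' @examples
#' digest_genomes(genome_tbl("g", "NNAAGCTTNN"))
#' @export
digest_genomes <- function(genomes, enzyme = hindiii()) {
  genomes <- validate_genomes(genomes)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  purrr::pmap(genomes, function(id, seq, topology, ...) {
    L <- nchar(seq)
    cuts <- cut_sites_one(seq, enzyme, topology)
    if (topology == "linear") {
      bounds <- unique(c(0L, cuts[cuts > 0L & cuts < L], L))
      frags <- diff(bounds)
    } else if (length(cuts) == 0L) {
      frags <- L
    } else {
      frags <- diff(c(cuts, cuts[1] + L))
    }
    frags <- sort(as.integer(frags), decreasing = TRUE)
    tibble::tibble(
      genome_id = id,
      enzyme = enzyme$name,
      rank = seq_along(frags),
      length_bp = frags,
      topology_used = topology,
      uncut = length(cuts) == 0L
    )
  }) |>
    purrr::list_rbind()
}

#' Total length of a digest profile
#'
#' Sums fragment lengths. Equals the source genome length when fragments are
#' exact (virtual digest); for gel-inferred fragments it is the genome-size
#' estimate.
#'
#' @param profile Either a numeric vector of fragment lengths, or a digest
#'   tibble as returned by [digest_genomes()] (possibly several genomes).
#' @return For a numeric vector, a single number. For a digest tibble, a
#'   tibble with columns `genome_id` and `total_bp`.
#' @examples
#' total_length(c(7, 3))
#' @export
total_length <- function(profile) {
  if (is.numeric(profile)) {
    if (length(profile) == 0) abort_input("empty fragment list")
    return(sum(profile))
  }
  if (!is.data.frame(profile) || !all(c("genome_id", "length_bp") %in% names(profile))) {
    abort_input("`profile` must be a fragment-length vector or a digest tibble")
  }
  if (nrow(profile) == 0) abort_input("empty fragment list")
  profile |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(total_bp = sum(.data$length_bp), .groups = "drop")
}
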