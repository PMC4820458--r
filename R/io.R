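#' Read genomes from a FASTA file
#'
#' Accepts wrapped or single-line records and CRLF line endings; sequences
#' are uppercased and validated against the IUPAC alphabet. Structural
#' problems (sequence data before any header, headerless/empty records) are
#' reported with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @param topology Topology assigned to every record (default linear;
#'   virion-packaged phage DNA is linear).
#' @return A genome tibble (see [genome_tbl()]), records in file order.
#' @export
read_fasta <- function(path, topology = "linear") {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- nzchar(trimws(lines))
  if (!any(keep)) abort_input(paste0(path, ": empty FASTA file"))
  first <- which(keep)[1]
  if (!startsWith(lines[first], ">")) {
    abort_input(sprintf("%s: line %d: sequence data before any '>' header", path, first))
  }
  hdr <- which(startsWith(lines, ">"))
  ends <- c(hdr[-1] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    body <- lines[seq(hdr[i] + 1L, max(hdr[i], ends[i]))]
    if (hdr[i] == ends[i] || !any(nzchar(trimws(body)))) {
      abort_input(sprintf("%s: line %d: record '%s' has no sequence", path, hdr[i],
                          sub("^>\\s*", "", lines[hdr[i]])))
    }
  }
  # assemble records from the scanned lines; genome_tbl() validation then
  # names the offending record and offset on any illegal character
  is_hdr <- startsWith(lines, ">")
  rec <- cumsum(is_hdr)
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[is_hdr]))
  seqs <- vapply(split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(ids))),
                 paste, "", collapse = "")
  genome_tbl(ids, gsub("\\s", "", seqs), topology)
}

#' Write genomes to a FASTA file
#'
#' @param genomes A genome tibble.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70) {
  genomes <- validate_genomes(genomes)
  dss <- Biostrings::BStringSet(stats::setNames(genomes$seq, genomes$id))
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

#' Read and write long band-profile tables
#'
#' The interchange format is one row per band: `id`, `size_bp`.
#'
#' @param path TSV path.
#' @return `read_band_profiles()`: a tibble with columns `id`, `size_bp`.
#' @export
read_band_profiles <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), size_bp = readr::col_double()
  ))
  if (!all(c("id", "size_bp") %in% names(tab))) {
    abort_input("profile TSV needs columns id, size_bp")
  }
  if (any(tab$size_bp <= 0)) abort_input("band sizes must be positive")
  tab
}

#' @param profiles A long band-profile tibble (`id`, `size_bp`).
#' @rdname read_band_profiles
#' @export
write_band_profiles <- function(profiles, path) {
  readr::write_tsv(profiles[c("id", "size_bp")], path)
  invisible(path)
}

#' Write a digest table as TSV
#'
#' Columns `genome_id`, `enzyme`, `rank`, `length_bp` (one row per fragment,
#' rank 1 = largest).
#'
#' @param digest A digest tibble from [digest_genomes()].
#' @param path Output path.
#' @export
write_digest_tsv <- function(digest, path) {
  readr::write_tsv(digest[c("genome_id", "enzyme", "rank", "length_bp")], path)
  invisible(path)
}

#' Write a gel lane as TSV
#'
#' Distances are reported rounded to 0.01 mm and sizes to integer bp (the
#' in-memory lane keeps full precision).
#'
#' @param lane A `gel_lane` tibble.
#' @param path Output path.
#' @export
write_lane_tsv <- function(lane, path) {
  out <- tibble::as_tibble(lane)[c("lane_id", "band_index", "distance_mm",
                                   "size_bp", "multiplicity")]
  out$distance_mm <- round(out$distance_mm, 2)
  out$size_bp <- round(out$size_bp)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a distance matrix as square CSV
#'
#' Header row and first column carry the labels; the lower triangle is
#' redundant but emitted for readability. Distances at 4 decimals.
#'
#' @param D A `band_dist` or labelled symmetric matrix.
#' @param path Output path.
#' @export
write_distance_csv <- function(D, path) {
  m <- round(unclass(as_dist_matrix(D)), 4)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a host-range table
#'
#' TSV with columns `strain`, `origin`, `susceptible` ("+"/"-" or logical).
#' The packaged fixture `host_range_q69.tsv` holds the 27-strain panel of a
#' published Enterococcus faecalis phage host-range screen.
#'
#' @param path TSV path.
#' @return Tibble with `susceptible` as logical.
#' @export
read_host_range <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("strain", "origin", "susceptible") %in% names(tab))) {
    abort_input("host-range TSV needs columns strain, origin, susceptible")
  }
  tab$susceptible <- tab$susceptible %in% c("+", "true", "TRUE", "yes")
  tab
}

#' The packaged phage reference panel
#'
#' Metadata for 17 published Enterococcus faecalis phage genome records
#' (family, origin, lifestyle, genome size, NCBI accession). The genome-size
#' column (16,945-147,589 bp) defines the realistic length range the
#' synthetic generator emulates; the sequences themselves are not shipped.
#'
#' @return A tibble with columns `phage`, `family`, `origin`, `lifestyle`,
#'   `genome_size_bp`, `accession`.
#' @export
phage_panel <- function() {
  readr::read_tsv(system.file("extdata", "phage_panel.tsv", package = "phagerflp"),
                  col_types = readr::cols(
                    genome_size_bp = readr::col_integer(),
                    .default = readr::col_character()
                  ))
}

#' Write a Newick tree file
#'
#' @param tree An `upgma_tree` (or a ready Newick string).
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  nwk <- if (is.character(tree)) tree else to_newick(tree)
  writeLines(nwk, path)
  invisible(path)
}
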