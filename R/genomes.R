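# IUPAC nucleotide alphabet accepted in genome sequences (DNA, no gaps)
IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

#' Build a genome table
#'
#' Genomes are plain tibbles with one row per sequence and columns `id`,
#' `seq` and `topology`. Sequences are uppercased and validated against the
#' IUPAC nucleotide alphabet (ACGT plus ambiguity codes and N).
#'
#' @param id Character vector of unique sequence labels.
#' @param seq Character vector of nucleotide sequences (case-insensitive).
#' @param topology `"linear"` (default) or `"circular"`, recycled to length.
#'   Packaged phage DNA extracted from virions is linear, hence the default;
#'   replicative genome records may be circular.
#'
#' @return A tibble with columns `id`, `seq`, `topology`.
#' @examples
#' genome_tbl("phi1", "aagcttacgt")
#' @export
genome_tbl <- function(id, seq, topology = "linear") {
  if (length(id) != length(seq)) abort_input("`id` and `seq` must have the same length")
  if (length(id) == 0) abort_input("at least one genome is required")
  topology <- rep_len(topology, length(id))
  g <- tibble::tibble(
    id = as.character(id),
    seq = toupper(as.character(seq)),
    topology = as.character(topology)
  )
  validate_genomes(g)
}

validate_genomes <- function(g) {
  stopifnot(is.data.frame(g), all(c("id", "seq", "topology") %in% names(g)))
  if (anyDuplicated(g$id)) {
    abort_input(paste0("duplicate genome id(s): ",
                       paste(unique(g$id[duplicated(g$id)]), collapse = ", ")))
  }
  if (!all(g$topology %in% c("linear", "circular"))) {
    abort_input("`topology` must be \"linear\" or \"circular\"")
  }
  if (any(!nzchar(g$seq))) {
    abort_input(paste0("empty sequence for genome ", g$id[!nzchar(g$seq)][1]))
  }
  bad <- regexpr(sprintf("[^%s]", IUPAC_CHARS), g$seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort_input(sprintf(
      "genome %s contains non-IUPAC character '%s' at offset %d (1-based)",
      g$id[i], substr(g$seq[i], bad[i], bad[i]), bad[i]
    ))
  }
  g
}
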