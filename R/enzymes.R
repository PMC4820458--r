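#' Define a restriction enzyme
#'
#' @param name Enzyme name, e.g. `"HindIII"`.
#' @param recognition Recognition sequence; unambiguous ACGT only.
#' @param cut_offset 0-based position of the top-strand cut within the
#'   recognition site, in `0..nchar(recognition)`. HindIII (A^AGCTT) has
#'   `cut_offset = 1`.
#'
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' hindiii()
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  if (!nzchar(recognition) || grepl("[^ACGT]", recognition)) {
    abort_input("`recognition` must be a non-empty unambiguous ACGT string")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0 || cut_offset > nchar(recognition)) {
    abort_input("`cut_offset` must lie in 0..nchar(recognition)")
  }
  structure(
    list(name = as.character(name), recognition = recognition, cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<restriction enzyme> %s  %s\n", x$name, site))
  invisible(x)
}

#' @rdname restriction_enzyme
#' @export
hindiii <- function() restriction_enzyme("HindIII", "AAGCTT", 1L)

#' Read restriction-enzyme definitions from TSV
#'
#' Expects columns `name`, `recognition`, `cut_offset`.
#'
#' @param path Path to a tab-separated file.
#' @return A named list of [restriction_enzyme()] objects.
#' @export
read_enzymes <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    recognition = readr::col_character(),
    cut_offset = readr::col_integer()
  ))
  if (!all(c("name", "recognition", "cut_offset") %in% names(tab))) {
    abort_input("enzyme TSV needs columns name, recognition, cut_offset")
  }
  enz <- purrr::pmap(tab, function(name, recognition, cut_offset, ...) {
    restriction_enzyme(name, recognition, cut_offset)
  })
  stats::setNames(enz, tab$name)
}
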