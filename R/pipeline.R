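#' Configuration for the RFLP typing pipeline
#'
#' Bundles and validates every knob of the digest -> (optional gel) ->
#' band-comparison -> UPGMA pipeline.
#'
#' @param enzyme A [restriction_enzyme()]; default HindIII, the classic
#'   choice for phage genome fingerprinting.
#' @param topology Default genome topology when the input does not specify
#'   one (`"linear"` or `"circular"`).
#' @param tolerance Relative band-position tolerance for matching (default
#'   0.01, i.e. 1% on band molecular weight).
#' @param coefficient Band-sharing coefficient, `"dice"` or `"jaccard"`.
#' @param gel `NULL` to compare exact virtual-digest fragment sizes
#'   (default), or a list with elements `model` ([migration_model()]),
#'   `noise_sd`, `detection`, `resolution_mm` to pass every profile through a
#'   simulated gel and compare ladder-inferred sizes instead.
#' @param seed Integer seed for any stochastic stage.
#' @param out_dir Output directory for [run_pipeline()] artifacts; `NULL`
#'   disables file output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(enzyme = hindiii(), topology = "linear",
                            tolerance = 0.01, coefficient = c("dice", "jaccard"),
                            gel = NULL, seed = 1L, out_dir = NULL) {
  coefficient <- match.arg(coefficient)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (!topology %in% c("linear", "circular")) {
    abort_input("`topology` must be linear or circular")
  }
  if (tolerance < 0) abort_input("`tolerance` must be >= 0")
  if (!is.null(gel)) {
    if (!is.list(gel) || !inherits(gel$model, "migration_model")) {
      abort_input("`gel` must be a list with a migration_model in $model")
    }
    gel$noise_sd <- gel$noise_sd %||% 0
    gel$detection <- gel$detection %||% c(100, 50000)
    gel$resolution_mm <- gel$resolution_mm %||% 0.5
  }
  structure(list(enzyme = enzyme, topology = topology, tolerance = tolerance,
                 coefficient = coefficient, gel = gel, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full RFLP typing pipeline
#'
#' Virtual digestion of every genome, optional virtual-gel round trip
#' (render + size inference), band-profile distance matrix at the configured
#' tolerance, UPGMA dendrogram, Newick serialization. When
#' `config$out_dir` is set, writes `profiles.tsv`, `distances.csv`,
#' `tree.nwk` and `report.txt` (configuration echo, per-genome fragment
#' counts and fragment-length sums).
#'
#' @param genomes A genome tibble or a FASTA path; at least 2 genomes.
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with elements `digest` (fragment tibble),
#'   `profiles` (long band tibble), `distances` (`band_dist`), `tree`
#'   (`upgma_tree`), `newick` (string), `report` (character vector of log
#'   lines).
#' @examples
#' g <- dplyr::bind_rows(
#'   random_genome(20000, seed = 1, id = "phiA"),
#'   random_genome(20000, seed = 2, id = "phiB"),
#'   random_genome(20000, seed = 3, id = "phiC")
#' )
#' res <- run_pipeline(g, pipeline_config())
#' res$newick
#' @export
run_pipeline <- function(genomes, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(genomes)) {
    genomes <- tryCatch(read_fasta(genomes, topology = config$topology),
                        error = function(e) stop_stage("input", e))
  }
  genomes <- tryCatch(validate_genomes(genomes),
                      error = function(e) stop_stage("input", e))
  if (nrow(genomes) < 2) {
    abort_input("pipeline stage input: at least 2 genomes are needed to build a tree")
  }

  dig <- tryCatch(digest_genomes(genomes, config$enzyme),
                  error = function(e) stop_stage("digest", e))

  if (is.null(config$gel)) {
    profiles <- as_band_profiles(dig, source = "virtual_digest")
  } else {
    profiles <- tryCatch({
      lanes <- genomes$id |>
        purrr::imap(function(id, i) {
          lane <- render_lane(dig[dig$genome_id == id, ], config$gel$model,
                              noise_sd = config$gel$noise_sd,
                              detection = config$gel$detection,
                              resolution_mm = config$gel$resolution_mm,
                              seed = config$seed + i, lane_id = id)
          infer_band_sizes(lane, config$gel$model)
        })
      purrr::list_rbind(lanes) |> as_band_profiles(source = "gel_inferred")
    }, error = function(e) stop_stage("gel", e))
  }

  D <- tryCatch(band_distance_matrix(profiles, tol = config$tolerance,
                                     coefficient = config$coefficient),
                error = function(e) stop_stage("fingerprint", e))
  tree <- tryCatch(upgma(D), error = function(e) stop_stage("upgma", e))
  nwk <- to_newick(tree)

  counts <- dig |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(n_fragments = dplyr::n(), total_bp = sum(.data$length_bp),
                     .groups = "drop")
  report <- c(
    "phagerflp pipeline report",
    sprintf("enzyme: %s (%s, cut offset %d)", config$enzyme$name,
            config$enzyme$recognition, config$enzyme$cut_offset),
    sprintf("default topology: %s", config$topology),
    sprintf("tolerance: %.4g  coefficient: %s", config$tolerance, config$coefficient),
    sprintf("gel round-trip: %s", if (is.null(config$gel)) "no (exact fragment sizes)"
            else sprintf("yes (noise %.3g mm, window %g-%g bp)",
                         config$gel$noise_sd, config$gel$detection[1],
                         config$gel$detection[2])),
    sprintf("seed: %d", config$seed),
    "",
    sprintf("%-20s %12s %12s %10s", "genome", "fragments", "sum_bp", "topology"),
    sprintf("%-20s %12d %12d %10s", counts$genome_id, counts$n_fragments,
            counts$total_bp, genomes$topology[match(counts$genome_id, genomes$id)]),
    "",
    paste0("newick: ", nwk)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_digest_tsv(dig, file.path(config$out_dir, "profiles.tsv"))
    write_distance_csv(D, file.path(config$out_dir, "distances.csv"))
    write_newick(nwk, file.path(config$out_dir, "tree.nwk"))
    writeLines(report, file.path(config$out_dir, "report.txt"))
  }

  invisible(list(digest = dig, profiles = profiles, distances = D,
                 tree = tree, newick = nwk, report = report))
}

stop_stage <- function(stage, e) {
  rlang::abort(sprintf("pipeline stage %s: %s", stage, conditionMessage(e)),
               class = c("phagerflp_pipeline_error",
                         if (inherits(e, "phagerflp_input_error")) "phagerflp_input_error"))
}
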