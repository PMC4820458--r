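#' Log-linear gel migration model
#'
#' Migration distance of a DNA fragment in a conventional agarose gel is
#' modelled as `d(s) = a - b * log10(s)` with `b > 0`, a single log-linear
#' regime adequate for a 0.8% gel over roughly 0.5-25 kb. The model is
#' strictly decreasing in fragment size and invertible for s > 0.
#'
#' @param a Intercept (mm).
#' @param b Slope (mm per decade of bp); must be positive.
#' @param rms Root-mean-square residual of the calibration fit (mm), 0 for an
#'   exact model.
#' @return An object of class `migration_model`.
#' @examples
#' m <- migration_model(100, 40)
#' predict(m, size_bp = c(5000, 500))
#' @export
migration_model <- function(a, b, rms = 0) {
  if (!is.finite(a) || !is.finite(b) || b <= 0) {
    abort_input("`b` must be positive and both coefficients finite")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b), rms = as.numeric(rms)),
            class = "migration_model")
}

#' @export
print.migration_model <- function(x, ...) {
  cat(sprintf("<migration model> d(s) = %.4f - %.4f * log10(s)   (rms %.4g mm)\n",
              x$a, x$b, x$rms))
  invisible(x)
}

#' @param object A `migration_model`.
#' @param size_bp Fragment sizes in bp.
#' @param ... Unused.
#' @rdname migration_model
#' @export
predict.migration_model <- function(object, size_bp, ...) {
  if (any(size_bp <= 0)) abort_input("fragment sizes must be positive")
  object$a - object$b * log10(size_bp)
}

#' Calibrate a migration model from a size ladder
#'
#' Least-squares fit of migration distance against log10 size.
#'
#' @param ladder Tibble/data frame with columns `size_bp` and `distance_mm`;
#'   at least 3 rungs, sizes strictly decreasing as distances increase.
#' @return A [migration_model()] carrying the RMS residual of the fit.
#' @examples
#' lad <- tibble::tibble(size_bp = c(10000, 3000, 1000, 500),
#'                       distance_mm = 100 - 40 * log10(c(10000, 3000, 1000, 500)))
#' fit_migration_model(lad)
#' @export
fit_migration_model <- function(ladder) {
  if (!is.data.frame(ladder) || !all(c("size_bp", "distance_mm") %in% names(ladder))) {
    abort_input("`ladder` needs columns size_bp and distance_mm")
  }
  if (nrow(ladder) < 3) abort_input("a ladder needs at least 3 rungs")
  if (any(ladder$size_bp <= 0)) abort_input("ladder sizes must be positive")
  ord <- order(ladder$size_bp, decreasing = TRUE)
  d <- ladder$distance_mm[ord]
  s <- ladder$size_bp[ord]
  if (any(diff(s) >= 0) || any(diff(d) <= 0)) {
    abort_input("ladder must be monotone: strictly decreasing sizes, strictly increasing distances")
  }
  fit <- stats::lm(d ~ log10(s))
  migration_model(a = unname(stats::coef(fit)[1]),
                  b = -unname(stats::coef(fit)[2]),
                  rms = sqrt(mean(stats::resid(fit)^2)))
}

#' Render a digest profile as a virtual gel lane
#'
#' Each fragment inside the detection window becomes a band at its model
#' distance plus optional Gaussian noise (noise acts on distance, not size).
#' Fragments outside the window are dropped; bands closer together than the
#' resolution limit merge into a single band at their mean position with
#' summed multiplicity (co-migrating fragments). Deterministic for a given
#' seed.
#'
#' @param profile Numeric vector of fragment lengths (bp), or a digest tibble
#'   for a single genome (see [digest_genomes()]).
#' @param model A [migration_model()].
#' @param noise_sd Gaussian noise SD on migration distance (mm); 0 disables.
#' @param detection Length-2 numeric, (min bp, max bp) detection window.
#' @param resolution_mm Minimum separation of distinguishable bands (mm).
#' @param seed Integer seed, required when `noise_sd > 0`.
#' @param lane_id Lane label; defaults to the genome id when available.
#'
#' @return A `gel_lane` tibble with columns `lane_id`, `band_index`,
#'   `distance_mm` (ascending), `size_bp` (NA until [infer_band_sizes()]),
#'   `multiplicity`. The detection window is kept as an attribute.
#' @export
render_lane <- function(profile, model, noise_sd = 0,
                        detection = c(100, 50000), resolution_mm = 0.5,
                        seed = NULL, lane_id = NULL) {
  stopifnot(inherits(model, "migration_model"))
  if (noise_sd < 0) abort_input("`noise_sd` must be >= 0")
  if (is.data.frame(profile)) {
    ids <- unique(profile$genome_id)
    if (length(ids) != 1) abort_input("`profile` must contain a single genome; got multiple ids")
    if (is.null(lane_id)) lane_id <- ids
    sizes <- profile$length_bp
  } else {
    sizes <- as.numeric(profile)
    if (is.null(lane_id)) lane_id <- "lane1"
  }
  if (length(sizes) == 0) abort_input("empty fragment list")
  sizes <- sizes[sizes >= detection[1] & sizes <= detection[2]]
  if (length(sizes) == 0) {
    lane <- tibble::tibble(lane_id = character(), band_index = integer(),
                           distance_mm = numeric(), size_bp = numeric(),
                           multiplicity = integer())
    return(new_gel_lane(lane, detection))
  }
  d <- predict(model, sizes)
  if (noise_sd > 0) {
    d <- with_seed_(seed, d + stats::rnorm(length(d), 0, noise_sd))
  }
  d <- sort(d)
  # sequential single-linkage merge of bands closer than the resolution limit
  grp <- cumsum(c(1, diff(d) >= resolution_mm))
  merged <- tibble::tibble(distance_mm = d, grp = grp) |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(multiplicity = dplyr::n(),
                     distance_mm = mean(.data$distance_mm), .groups = "drop")
  lane <- tibble::tibble(
    lane_id = lane_id,
    band_index = seq_len(nrow(merged)),
    distance_mm = merged$distance_mm,
    size_bp = NA_real_,
    multiplicity = as.integer(merged$multiplicity)
  )
  new_gel_lane(lane, detection)
}

new_gel_lane <- function(lane, detection) {
  structure(lane, detection = as.numeric(detection),
            class = c("gel_lane", class(lane)))
}

#' Infer fragment sizes from band positions
#'
#' Inverts the migration model: `size = 10^((a - d)/b)`, rounded to the
#' nearest integer bp.
#'
#' @param lane A `gel_lane` tibble from [render_lane()] (or any tibble with a
#'   `distance_mm` column).
#' @param model The [migration_model()] used for the lane (or fitted from a
#'   ladder run on the same gel).
#' @return The lane tibble with `size_bp` filled in.
#' @export
infer_band_sizes <- function(lane, model) {
  stopifnot(inherits(model, "migration_model"))
  if (!is.data.frame(lane) || !"distance_mm" %in% names(lane)) {
    abort_input("`lane` needs a distance_mm column")
  }
  if (any(lane$distance_mm >= model$a)) {
    abort_input("band distance >= model intercept: non-physical position (< 1 bp)")
  }
  lane$size_bp <- round(10^((model$a - lane$distance_mm) / model$b))
  lane
}

#' Estimate genome size from a gel lane
#'
#' Sum of inferred band sizes weighted by band multiplicity. Fragments below
#' the detection window leave no band, so the estimate is biased low whenever
#' small fragments ran off the gel.
#'
#' @inheritParams infer_band_sizes
#' @return A single number (bp).
#' @export
estimate_genome_size <- function(lane, model) {
  if (!is.data.frame(lane) || nrow(lane) == 0) abort_input("empty lane")
  if (all(is.na(lane$size_bp))) lane <- infer_band_sizes(lane, model)
  sum(lane$size_bp * lane$multiplicity)
}

#' @param object,x A `gel_lane`.
#' @param ... Unused.
#' @method autoplot gel_lane
#' @export
autoplot.gel_lane <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lane_id)) +
    ggplot2::geom_tile(ggplot2::aes(y = .data$distance_mm,
                                    alpha = .data$multiplicity),
                       width = 0.6, height = 0.4, fill = "grey20") +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_alpha_continuous(range = c(0.6, 1), guide = "none") +
    ggplot2::labs(x = NULL, y = "migration distance (mm)") +
    ggplot2::theme_minimal()
}
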