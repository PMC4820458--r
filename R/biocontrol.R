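# molar mass of tyramine (C8H11NO), g/mol
TYRAMINE_MOLAR_MASS <- 137.179

#' Phage dose for a target multiplicity of infection
#'
#' MOI is the ratio of infecting phage particles (pfu) to host cells (cfu) at
#' inoculation, so the required titre is simply `moi * host_density`.
#'
#' @param moi Multiplicity of infection (dimensionless, > 0).
#' @param host_density Host concentration in cfu per ml (> 0).
#' @return Phage dose in pfu per ml.
#' @examples
#' moi_dose(0.1, 1e4) # the cheese-model inoculum: 1e3 pfu/ml
#' @export
moi_dose <- function(moi, host_density) {
  if (any(moi <= 0) || any(host_density <= 0)) {
    abort_input("`moi` and `host_density` must be positive")
  }
  moi * host_density
}

#' Percent reduction of a treated value relative to a control
#'
#' `100 * (1 - treated / control)`, in percent. Bounded above by 100
#' (attained only when the treated value is zero); negative when the treated
#' value exceeds the control.
#'
#' @param control Control value (> 0).
#' @param treated Treated value (>= 0).
#' @return Percent reduction.
#' @examples
#' percent_reduction(3.13, 0.46) # tyramine in cheese, ~85%
#' @export
percent_reduction <- function(control, treated) {
  if (any(control <= 0)) abort_input("`control` must be positive")
  if (any(treated < 0)) abort_input("`treated` must be non-negative")
  100 * (1 - treated / control)
}

#' Check a reported percent reduction against the underlying values
#'
#' Published reductions are sometimes rounded generously; this recomputes the
#' reduction from the raw control/treated values and flags a discrepancy when
#' the computed value differs from the reported one by more than
#' `tol_points` percentage points.
#'
#' @inheritParams percent_reduction
#' @param reported_percent The reduction claimed for the same pair of values.
#' @param tol_points Allowed gap in percentage points before flagging
#'   (default 1).
#' @return One-row tibble: `computed_percent`, `reported_percent`,
#'   `difference_points`, `consistent`.
#' @examples
#' # printed counts 3.05e9 vs 4.56e8 compute to 85.0%, not the reported 90%
#' reduction_consistency(3.05e9, 4.56e8, reported_percent = 90)
#' @export
reduction_consistency <- function(control, treated, reported_percent, tol_points = 1) {
  computed <- percent_reduction(control, treated)
  out <- tibble::tibble(
    computed_percent = computed,
    reported_percent = reported_percent,
    difference_points = computed - reported_percent,
    consistent = abs(computed - reported_percent) <= tol_points
  )
  if (any(!out$consistent)) {
    rlang::warn(sprintf(
      "reported reduction %.3g%% differs from computed %.3g%% by more than %g points",
      reported_percent[!out$consistent][1], computed[!out$consistent][1], tol_points
    ), class = "phagerflp_reduction_discrepancy")
  }
  out
}

#' Convert a tyramine concentration from mM to mg per kg
#'
#' Uses the tyramine molar mass of 137.179 g/mol and assumes 1 kg of cheese
#' corresponds to about 1 L of aqueous phase (unit density), the implicit
#' convention when food biogenic-amine levels measured in broth-equivalent mM
#' are expressed per kg of product.
#'
#' @param conc Concentration in mM (>= 0).
#' @return Concentration in mg per kg.
#' @examples
#' tyramine_mm_to_mgkg(3.13) # 429.4 mg/kg
#' @export
tyramine_mm_to_mgkg <- function(conc) {
  if (any(conc < 0)) abort_input("`conc` must be non-negative")
  conc * TYRAMINE_MOLAR_MASS
}

#' Summarise a host-range table
#'
#' Counts susceptible strains overall and per origin.
#'
#' @param records Tibble/data frame with columns `strain` (unique), `origin`
#'   and `susceptible` (logical, or "+"/"-" characters).
#' @return A tibble with one row per origin plus an `"overall"` row;
#'   columns `origin`, `n_susceptible`, `n_total`, `percent` (1 decimal).
#' @examples
#' hr <- read_host_range(system.file("extdata", "host_range_q69.tsv",
#'                                   package = "phagerflp"))
#' host_range_summary(hr)
#' @export
host_range_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_input("`records` must be a non-empty data frame")
  }
  if (!all(c("strain", "origin", "susceptible") %in% names(records))) {
    abort_input("`records` needs columns strain, origin, susceptible")
  }
  if (anyDuplicated(records$strain)) {
    abort_input(paste0("duplicate strain(s): ",
                       paste(unique(records$strain[duplicated(records$strain)]),
                             collapse = ", ")))
  }
  susc <- records$susceptible
  if (is.character(susc)) susc <- susc %in% c("+", "true", "TRUE", "yes")
  susc <- as.logical(susc)
  if (any(is.na(susc))) abort_input("`susceptible` must be logical or '+'/'-'")
  records$susceptible <- susc
  by_origin <- records |>
    dplyr::group_by(origin = .data$origin) |>
    dplyr::summarise(n_susceptible = sum(.data$susceptible),
                     n_total = dplyr::n(), .groups = "drop")
  overall <- tibble::tibble(origin = "overall",
                            n_susceptible = sum(susc),
                            n_total = length(susc))
  dplyr::bind_rows(by_origin, overall) |>
    dplyr::mutate(percent = round(100 * .data$n_susceptible / .data$n_total, 1))
}

#' qPCR standard curve
#'
#' A linear standard curve `Ct = intercept + slope * log10(N)` relating cycle
#' threshold to cell (template) number; `slope` must be negative (more
#' template, earlier threshold). A slope of -3.32 corresponds to 100%
#' amplification efficiency. The default coefficients are placeholders to be
#' replaced by a laboratory calibration.
#'
#' @param slope Ct change per decade of template (negative).
#' @param intercept Ct at one cell-equivalent.
#' @return An object of class `standard_curve`.
#' @export
standard_curve <- function(slope = -3.32, intercept = 40) {
  if (!is.finite(slope) || slope == 0) abort_input("`slope` must be non-zero")
  if (slope > 0) abort_input("`slope` must be negative (Ct falls as template rises)")
  structure(list(slope = as.numeric(slope), intercept = as.numeric(intercept)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<qPCR standard curve> Ct = %.4g %+.4g * log10(N)\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Cell numbers from qPCR cycle thresholds
#'
#' Inverts the standard curve: `N = 10^((ct - intercept) / slope)`.
#'
#' @param ct Cycle threshold value(s).
#' @param curve A [standard_curve()].
#' @return Cell-equivalents, in the units the curve was calibrated in
#'   (per g or per ml).
#' @examples
#' qpcr_cells(25, standard_curve(-3.32, 40))
#' @export
qpcr_cells <- function(ct, curve = standard_curve()) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Two-sample t-test on replicate values
#'
#' Pooled-variance (Student's) two-sided t-test by default, the test named in
#' classical biocontrol study designs; Welch's unequal-variance form is
#' available via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors of replicate values, each of length >= 2.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pool the variances (default TRUE = Student's test).
#' @return One-row tibble: `estimate_a`, `estimate_b`, `t`, `df`, `p_value`,
#'   `significant`, `method`.
#' @examples
#' two_sample_t(c(2.1, 2.0, 1.9), c(3.1, 3.0, 2.9))
#' @export
two_sample_t <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort_input("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) abort_input("zero pooled variance: degenerate (constant) input")
    tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
    method <- "Student's pooled t"
  } else {
    if (va + vb <= 0) abort_input("zero variance in both groups: degenerate input")
    se2 <- va / na + vb / nb
    tstat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    method <- "Welch's t"
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  tibble::tibble(
    estimate_a = mean(a), estimate_b = mean(b),
    t = tstat, df = df, p_value = p,
    significant = p < alpha, method = method
  )
}
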