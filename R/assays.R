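#' Serine consumption per million-cell increase
#'
#' `(amount_t0 - amount_t) / ((cells_t - cells_t0) / 1e6)`: the reduction of
#' serine in the culture well divided by the increase in viable cell number,
#' in micrograms per 10^6-cell increase. The formula presumes growth: wells
#' with no cell-number increase raise an error rather than returning a
#' negative or infinite value.
#'
#' @param amount_t0 Serine mass in the well at 0 h (ug).
#' @param amount_t Serine mass at the later timepoint (ug).
#' @param cells_t0,cells_t Viable cell counts at 0 h and at the timepoint.
#' @return Consumption in ug per 10^6-cell increase (vectorized).
#' @examples
#' serine_consumption(60, 40, 0.5e6, 1.5e6)  # 20
#' @export
serine_consumption <- function(amount_t0, amount_t, cells_t0, cells_t) {
  if (any(amount_t0 < 0) || any(amount_t < 0)) stop("amounts must be non-negative")
  if (any(cells_t0 <= 0) || any(cells_t <= 0)) stop("cell counts must be positive")
  if (any(cells_t <= cells_t0))
    stop("no cell-number increase: cells_t must exceed cells_t0")
  (amount_t0 - amount_t) / ((cells_t - cells_t0) / 1e6)
}

#' Convert a medium concentration to the serine amount in a well
#'
#' The assay mixes units (medium composition in mg/L, well volumes in mL,
#' consumption in ug); this helper keeps the conversion at the boundary:
#' mg/L equals ug/mL, so amount (ug) = concentration (mg/L) x volume (mL).
#'
#' @param conc_mg_per_l Concentration in mg/L (e.g. 30 for RPMI serine).
#' @param volume_ml Well medium volume in mL.
#' @return Amount in micrograms.
#' @examples
#' medium_amount_ug(30, 2)  # 60 ug
#' @export
medium_amount_ug <- function(conc_mg_per_l, volume_ml) {
  if (any(conc_mg_per_l < 0) || any(volume_ml < 0)) stop("inputs must be non-negative")
  conc_mg_per_l * volume_ml
}

#' ROS level per million cells
#'
#' Background-subtracted CM-H2DCFDA fluorescence divided by the cell count in
#' millions: `(f_stained - f_unstained) / cells_millions`. A stained reading
#' below the unstained background is physically unexpected; the (negative)
#' value is returned with a warning rather than suppressed.
#'
#' @param f_stained Fluorescence of the stained well (a.u.).
#' @param f_unstained Fluorescence of the unstained well (a.u.).
#' @param cells_millions Cell count divided by 10^6 (positive).
#' @return ROS level in a.u. per 10^6 cells (vectorized).
#' @examples
#' ros_level(5000, 500, 0.9)  # 5000
#' @export
ros_level <- function(f_stained, f_unstained, cells_millions) {
  if (any(cells_millions <= 0)) stop("cell count must be positive")
  diff <- f_stained - f_unstained
  if (any(diff < 0))
    warning("stained fluorescence below unstained background; negative ROS value returned")
  diff / cells_millions
}

#' Redox ratio of two metabolite pools
#'
#' Plain pool-size ratio (NADPH/NADP+ or GSH/GSSG), dimensionless; both pools
#' must be in the same (arbitrary) units.
#'
#' @param numerator_pool,denominator_pool Pool sizes; denominator must be
#'   strictly positive.
#' @return Dimensionless ratio (vectorized).
#' @examples
#' redox_ratio(10, 5)  # 2
#' @export
redox_ratio <- function(numerator_pool, denominator_pool) {
  if (any(numerator_pool < 0)) stop("numerator pool must be non-negative")
  if (any(denominator_pool <= 0)) stop("denominator pool must be strictly positive")
  numerator_pool / denominator_pool
}

#' Proliferation rate as the slope of a confluence time course
#'
#' Ordinary least-squares slope of percent confluence versus time, in percent
#' per hour, as reported by live-cell imaging systems.
#'
#' @param time_h Strictly increasing timepoints in hours (at least 3).
#' @param confluence Percent confluence at each timepoint.
#' @return Slope in percent per hour.
#' @examples
#' proliferation_slope(c(0, 24, 48), c(10, 20, 30))  # 10/24
#' @export
proliferation_slope <- function(time_h, confluence) {
  if (length(time_h) < 3L) stop("at least 3 timepoints are required")
  if (length(confluence) != length(time_h))
    stop("time_h and confluence must have equal lengths")
  if (any(diff(time_h) <= 0)) stop("timepoints must be strictly increasing")
  unname(stats::coef(stats::lm(confluence ~ time_h))[2L])
}

#' Relative proliferation versus untreated controls
#'
#' Each treated cell count divided by the mean count of the untreated control
#' wells (e.g. cells without H2O2).
#'
#' @param treated_counts Cell counts of treated wells.
#' @param control_counts Cell counts of untreated control wells (non-empty,
#'   positive mean).
#' @return Fractions, one per treated well.
#' @examples
#' relative_proliferation(50, c(100, 100))  # 0.5
#' @export
relative_proliferation <- function(treated_counts, control_counts) {
  if (!length(control_counts)) stop("empty control group")
  m <- mean(control_counts)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  if (any(treated_counts < 0)) stop("cell counts must be non-negative")
  treated_counts / m
}
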