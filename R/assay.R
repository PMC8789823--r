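# Deterministic quantification rules for split-luciferase (NanoBiT /
# HiBiT) and BRET plate-reader readouts. Time zero is the first
# post-ligand read; the pre-ligand baseline read is carried with the
# series.

#' Fold-change normalization of a luminescence series
#'
#' Divides every count by the pre-ligand baseline count (the series'
#' `baseline` attribute unless supplied explicitly).
#'
#' @param series data.frame `time_s, count` with attribute `baseline`,
#'   e.g. from [simulate_assay_series()].
#' @param baseline override the baseline count.
#' @return the series with `count` replaced by fold change; baseline
#'   attribute set to 1.
#' @export
fold_change <- function(series, baseline = attr(series, "baseline")) {
  if (is.null(baseline)) stop("series carries no baseline reading")
  if (baseline == 0) stop("zero baseline count")
  series$count <- series$count / baseline
  attr(series, "baseline") <- 1
  series
}

#' Average a normalized series over a quantification window
#'
#' Mean of the values whose times fall in `[window[1], window[2]]`
#' (inclusive). The conventional windows are 13-15 min after ligand
#' addition for NanoBiT kinetics and 27-30 min for the internalization
#' assay.
#'
#' @param series data.frame `time_s, count`.
#' @param window `c(start, end)` in seconds.
#' @return scalar response.
#' @export
window_quantify <- function(series, window = c(13, 15) * 60) {
  sel <- series$time_s >= window[1] & series$time_s <= window[2]
  if (!any(sel)) stop("no sample inside the quantification window")
  mean(series$count[sel])
}

#' Vehicle-normalized internalization response
#'
#' Surface-receptor quantification: the ligand series is divided by
#' the vehicle series at each time point, then averaged over the
#' window (27-30 min by default).
#'
#' @param ligand,vehicle data.frames `time_s, count` on the same time
#'   grid.
#' @param window quantification window (s).
#' @return scalar response.
#' @export
vehicle_normalized_response <- function(ligand, vehicle,
                                        window = c(27, 30) * 60) {
  if (!isTRUE(all.equal(ligand$time_s, vehicle$time_s)))
    stop("ligand and vehicle series must share the time grid")
  if (any(vehicle$count == 0)) stop("zero vehicle count")
  norm <- ligand
  norm$count <- ligand$count / vehicle$count
  window_quantify(norm, window)
}

#' BRET index
#'
#' `I_Venus / (I_NanoBiT + I_Venus)`, the acceptor fraction of the
#' total two-channel intensity; lies in `[0, 1]`, is invariant to a
#' common intensity scale and increases with energy transfer.
#'
#' @param i_nanobit donor-channel mean intensity (a.u.).
#' @param i_venus acceptor-channel mean intensity (a.u.).
#' @return BRET index (vectorized).
#' @export
bret_index <- function(i_nanobit, i_venus) {
  if (any(i_nanobit < 0) || any(i_venus < 0))
    stop("intensities must be >= 0")
  tot <- i_nanobit + i_venus
  if (any(tot == 0)) stop("zero total intensity")
  i_venus / tot
}

#' Per-cell BRET fold change
#'
#' Ratio of the BRET index after stimulation (around 14 min) to the
#' index before stimulation.
#'
#' @param before,after BRET indices (same length, per cell).
#' @return fold change per cell.
#' @export
bret_fold_change <- function(before, after) {
  if (any(before == 0)) stop("zero pre-stimulation BRET index")
  after / before
}
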