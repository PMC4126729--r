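# fixed slot order of the fingerprint feature vector
feature_slots <- function() {
  dirs <- c("horizontal", "vertical", "radial", "circumferential")
  c("fd_entire", "fd_roi", "lambda_entire", "lambda_roi",
    "alpha_width", "f_width", "asymmetry", "D0", "D1", "D2",
    as.vector(t(outer(dirs, c("mean", "var", "n_spikes", "spike1"),
                      paste, sep = "_"))))
}

#' Assemble the fingerprint feature vector
#'
#' Collects the per-image metrics from all analysis modules into one
#' fixed-order named numeric vector of length 26: whole-image and ROI
#' fractal dimension and lacunarity, multifractal summary (alpha and f
#' widths, asymmetry, D0, D1, D2), and per-direction profile moments
#' (density-weighted mean and variance of the scan coordinate, spike count,
#' first spike location). Metrics that were not computed stay `NA` in their
#' slot -- the vector length never changes -- so feature matrices from
#' different runs align column-wise for downstream classification.
#'
#' @param metrics Named list; recognized names are the slot names returned
#'   by `feature_slots()`, plus the convenience entries `fd_entire`/`fd_roi`
#'   (`fractal_fit`), `lambda_entire`/`lambda_roi` (`lacunarity_series`),
#'   `spectrum` (`spectrum_summary` or `mf_spectrum`) and `profiles` (named
#'   list of `directional_profile`s).
#' @param spike_prominence Passed to [find_spikes()] when profiles are given.
#' @return Named numeric vector of class `afp_features` with a `provenance`
#'   attribute recording which modules supplied which slots.
#' @export
build_feature_vector <- function(metrics, spike_prominence = 2) {
  if (length(metrics) == 0L) stopf("at least one metric must be present")
  v <- stats::setNames(rep(NA_real_, length(feature_slots())),
                       feature_slots())
  prov <- list()
  num <- function(x) if (inherits(x, "fractal_fit")) x$D_B else
    if (inherits(x, "lacunarity_series")) x$Lambda else as.numeric(x)
  for (nm in intersect(names(metrics), names(v))) {
    v[nm] <- num(metrics[[nm]])
    prov[[nm]] <- class(metrics[[nm]])[1L]
  }
  if (!is.null(metrics$spectrum)) {
    ss <- metrics$spectrum
    if (inherits(ss, "mf_spectrum")) ss <- spectrum_summary(ss)
    for (nm in c("alpha_width", "f_width", "asymmetry", "D0", "D1", "D2")) {
      v[nm] <- ss[[nm]]
      prov[[nm]] <- "spectrum_summary"
    }
  }
  if (!is.null(metrics$profiles)) {
    for (pr in metrics$profiles) {
      d <- attr(pr, "direction")
      wgt <- pr$density * pr$area_mm2 / 100  # probability mass per bin
      m1 <- sum(wgt * pr$mid)
      v[paste0(d, "_mean")] <- m1
      v[paste0(d, "_var")] <- sum(wgt * (pr$mid - m1)^2)
      sp <- find_spikes(pr, prominence = spike_prominence)
      v[paste0(d, "_n_spikes")] <- nrow(sp)
      v[paste0(d, "_spike1")] <- if (nrow(sp) > 0L) sp$coord[1L] else NA_real_
      prov[[d]] <- "directional_profile"
    }
  }
  structure(v, class = c("afp_features", "numeric"), provenance = prov)
}
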