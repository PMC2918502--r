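#' Spectral region boundaries
#'
#' Partition of 300--700 nm into the regions where the four avian single
#' cones are maximally sensitive. Defaults place the UV region below
#' 400 nm, SWS in 400--475, MWS in 475--575 (so "around 500 nm" is MWS)
#' and LWS above 575; intervals are \[lo, hi) except LWS which includes
#' 700. Fully configurable.
#'
#' @param uv,sws,mws,lws Length-2 numeric intervals; must be contiguous
#'   and cover \[300, 700\].
#' @return A `region_boundaries` object.
#' @export
region_boundaries <- function(uv = c(300, 400), sws = c(400, 475),
                              mws = c(475, 575), lws = c(575, 700)) {
  b <- list(UV = uv, SWS = sws, MWS = mws, LWS = lws)
  lims <- unlist(b)
  if (uv[1] != 300 || lws[2] != 700 ||
      uv[2] != sws[1] || sws[2] != mws[1] || mws[2] != lws[1] ||
      any(diff(lims) < 0))
    stop("region boundaries must be contiguous ascending intervals covering [300, 700]")
  structure(b, class = "region_boundaries")
}

.region_of <- function(wl, b) {
  ifelse(wl < b$UV[2], "UV",
         ifelse(wl < b$SWS[2], "SWS",
                ifelse(wl < b$MWS[2], "MWS", "LWS")))
}

#' Luminance of a grid spectrum
#'
#' Achromatic signal proxy for the avian double cone: the sum of
#' reflectance values at the 41 grid points from 500 to 700 nm inclusive.
#'
#' @param s Numeric 81-vector or 81 x n matrix.
#' @return Scalar (or length-n vector) luminance.
#' @export
luminance <- function(s) {
  .check_grid_values(s)
  sel <- grid_nm() >= 500
  if (is.matrix(s)) colSums(s[sel, , drop = FALSE]) else sum(s[sel])
}

#' Brightness of a grid spectrum
#'
#' Total area under the reflectance curve: the sum over all 81 grid
#' values. Always at least as large as [luminance()] for nonnegative
#' spectra, and `brightness(s) = luminance(s) + sum(s[grid < 500])`
#' exactly.
#'
#' @param s Numeric 81-vector or 81 x n matrix.
#' @return Scalar (or length-n vector) brightness.
#' @export
brightness <- function(s) {
  .check_grid_values(s)
  if (is.matrix(s)) colSums(s) else sum(s)
}

#' Signal-to-noise profile across replicate spectra of one egg
#'
#' Per-wavelength mean, sample standard deviation (n-1 denominator) and
#' their ratio across the replicate measurements of a single egg. Points
#' where the replicates agree exactly (sd = 0) have undefined SNR and are
#' masked.
#'
#' @param replicates An 81 x r matrix (r >= 2 replicate spectra), a list
#'   of 81-vectors, or a `spectra_set` whose spectra all share one egg.
#' @return A `snr_profile` data frame with columns `wavelength_nm`,
#'   `mean`, `sd`, `snr`, `undefined`.
#' @export
snr_profile <- function(replicates) {
  if (inherits(replicates, "spectra_set")) {
    egg <- unique(paste(replicates$meta$species, replicates$meta$clutch_id,
                        replicates$meta$egg_id))
    if (length(egg) != 1L)
      stop("snr_profile expects replicates of a single egg; got ",
           length(egg), " eggs")
    replicates <- replicates$R
  }
  if (is.list(replicates)) replicates <- do.call(cbind, replicates)
  replicates <- as.matrix(replicates)
  if (ncol(replicates) < 2L)
    stop("at least 2 replicate spectra are required for an SNR profile")
  .check_grid_values(replicates)
  m <- rowMeans(replicates)
  sd <- apply(replicates, 1, stats::sd)
  undef <- sd == 0
  snr <- ifelse(undef, NA_real_, m / sd)
  structure(
    data.frame(wavelength_nm = grid_nm(), mean = m, sd = sd, snr = snr,
               undefined = undef),
    class = c("snr_profile", "data.frame")
  )
}

#' Region of maximal reflectance
#'
#' Labels a spectrum by the spectral region (UV, SWS, MWS or LWS)
#' containing its global maximum. Ties are broken towards the longest
#' wavelength, so a constant spectrum is LWS. Invariant to positive
#' rescaling.
#'
#' @param s Numeric 81-vector or 81 x n matrix.
#' @param b A [region_boundaries()] object.
#' @return Character label(s) in `c("UV", "SWS", "MWS", "LWS")`.
#' @export
classify_max_region <- function(s, b = region_boundaries()) {
  .check_grid_values(s)
  g <- grid_nm()
  one <- function(v) {
    i <- max(which(v == max(v)))
    .region_of(g[i], b)
  }
  if (is.matrix(s)) apply(s, 2, one) else one(s)
}

#' Wavelength of maximal relative-spectral difference
#'
#' Grid wavelength where the two relative spectra differ most (ties
#' broken to the shortest wavelength). When the relative spectra are
#' identical the result is 300 nm with attribute `zero_difference = TRUE`.
#'
#' @param a,b Numeric 81-vectors.
#' @return Wavelength (nm) with attributes `max_difference` and
#'   `zero_difference`.
#' @export
max_difference_wavelength <- function(a, b) {
  d <- abs(relative_spectrum(a) - relative_spectrum(b))
  i <- which.max(d)
  structure(grid_nm()[i], max_difference = d[i],
            zero_difference = d[i] < 1e-12)
}

#' Fraction of maximal-difference wavelengths in an interval
#'
#' Summariser for collections of pairwise comparisons: the proportion of
#' wavelengths (as returned by [max_difference_wavelength()]) that fall in
#' \[lo, hi\].
#'
#' @param wavelengths Numeric vector of wavelengths (nm).
#' @param lo,hi Query interval bounds (inclusive).
#' @return Fraction in \[0, 1\].
#' @export
fraction_in_interval <- function(wavelengths, lo, hi) {
  mean(wavelengths >= lo & wavelengths <= hi)
}
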