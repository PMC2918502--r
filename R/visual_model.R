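#' Receptor spectral sensitivities for a tetrachromatic avian eye
#'
#' Builds the four single-cone sensitivity curves (UVS, SWS, MWS, LWS)
#' plus the double-cone curve on the canonical grid. In `"template"` mode
#' each curve is a visual-pigment nomogram alpha band of log-normal shape,
#' parameterised only by its wavelength of maximal absorbance:
#' \eqn{S(\lambda) = \exp(-\log(\lambda/\lambda_{max})^2 / (2 w^2))}.
#' In `"table"` mode a user-supplied CSV (columns `wavelength_nm`, `uvs`,
#' `sws`, `mws`, `lws`, `dbl`) is interpolated onto the grid, admitting
#' published sensitivity sets that include oil-droplet filtering. All
#' curves are normalised to unit area on the grid (sum x 5 nm = 1).
#'
#' @param mode `"template"` or `"table"`.
#' @param lambda_max Named numeric, template peak wavelengths (nm) for
#'   `uvs`, `sws`, `mws`, `lws`; defaults to the average UVS-type eye
#'   (370, 445, 508, 565).
#' @param dbl_max Double-cone peak wavelength (nm), default 565.
#' @param logwidth Log-normal width parameter `w`, default 0.07.
#' @param path CSV path for `"table"` mode.
#' @return A `receptor_sensitivities` object: the grid plus an 81 x 5
#'   curve matrix with columns `uvs`, `sws`, `mws`, `lws`, `dbl`.
#' @export
build_sensitivities <- function(mode = c("template", "table"),
                                lambda_max = c(uvs = 370, sws = 445,
                                               mws = 508, lws = 565),
                                dbl_max = 565, logwidth = 0.07, path = NULL) {
  mode <- match.arg(mode)
  g <- grid_nm()
  if (mode == "template") {
    if (any(lambda_max <= 300) || any(lambda_max >= 700))
      stop("template lambda_max values must lie in (300, 700) nm")
    peaks <- c(lambda_max[c("uvs", "sws", "mws", "lws")], dbl = dbl_max)
    curves <- vapply(peaks, function(lm)
      exp(-(log(g / lm))^2 / (2 * logwidth^2)), numeric(.N_GRID))
    colnames(curves) <- c("uvs", "sws", "mws", "lws", "dbl")
  } else {
    if (is.null(path)) stop("table mode requires a file path")
    d <- utils::read.csv(path)
    need <- c("wavelength_nm", "uvs", "sws", "mws", "lws", "dbl")
    if (!all(need %in% names(d)))
      stop("sensitivity table must have columns ", paste(need, collapse = ", "))
    if (is.unsorted(d$wavelength_nm, strictly = TRUE))
      stop("sensitivity table wavelength column must be strictly increasing")
    if (min(d$wavelength_nm) > 300 || max(d$wavelength_nm) < 700)
      stop("sensitivity table must cover 300-700 nm")
    curves <- vapply(c("uvs", "sws", "mws", "lws", "dbl"), function(cl)
      stats::approx(d$wavelength_nm, d[[cl]], xout = g, rule = 1)$y,
      numeric(.N_GRID))
    if (any(curves < 0)) stop("sensitivity curves must be nonnegative")
  }
  curves <- sweep(curves, 2, colSums(curves) * 5, "/")  # unit area (5 nm steps)
  structure(list(grid = g, curves = curves), class = "receptor_sensitivities")
}

#' Write receptor sensitivities as a CSV table
#' @param sens A `receptor_sensitivities` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivities <- function(sens, path) {
  utils::write.csv(data.frame(wavelength_nm = sens$grid, sens$curves),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flat (equal-energy) illuminant
#'
#' The package default: museum spectra are reflectance-only, so an
#' equal-energy illuminant leaves quantum-catch ratios driven entirely by
#' the reflectance shape.
#'
#' @param level Constant irradiance value (must be positive).
#' @return Numeric 81-vector.
#' @export
flat_illuminant <- function(level = 1) {
  if (level <= 0) stop("illuminant must be strictly positive")
  rep(level, .N_GRID)
}

#' Receptor-noise model
#'
#' Noise in each receptor channel follows the Weber fraction of the LWS
#' channel scaled by relative receptor densities:
#' \eqn{e_i = \omega_{LWS} \sqrt{n_{LWS}/n_i}}. Defaults are the
#' conventional values used in receptor-noise modelling: Weber fraction
#' 0.05 and relative densities 1:2:2:4 (UVS:SWS:MWS:LWS).
#'
#' @param weber_lws Weber fraction of the most abundant (LWS) cone.
#' @param densities Named positive numeric, relative cone densities for
#'   `uvs`, `sws`, `mws`, `lws`.
#' @return A `noise_model` object with the per-channel noise `e`.
#' @export
noise_model <- function(weber_lws = 0.05,
                        densities = c(uvs = 1, sws = 2, mws = 2, lws = 4)) {
  if (weber_lws <= 0) stop("weber_lws must be positive")
  densities <- densities[c("uvs", "sws", "mws", "lws")]
  if (anyNA(densities) || any(densities <= 0))
    stop("densities must be positive for uvs, sws, mws, lws")
  e <- weber_lws * sqrt(densities[["lws"]] / densities)
  names(e) <- names(densities)
  structure(list(weber_lws = weber_lws, densities = densities, e = e),
            class = "noise_model")
}

#' Quantum catches of a stimulus
#'
#' Receptor catch \eqn{q_i = \sum_k S_i(\lambda_k) R(\lambda_k)
#' I(\lambda_k)} over the 81 grid points, for the four single cones and
#' the double cone.
#'
#' @param s Numeric 81-vector (or 81 x n matrix) of reflectance.
#' @param sens A [build_sensitivities()] object.
#' @param ill Numeric 81-vector of irradiance (default flat).
#' @return For a vector: named catches `uvs`, `sws`, `mws`, `lws` with
#'   attribute `"double"` (double-cone catch). For a matrix: a 4 x n
#'   catch matrix with attribute `"double"` a length-n vector.
#' @export
quantum_catches <- function(s, sens, ill = flat_illuminant()) {
  .check_grid_values(s)
  if (length(ill) != .N_GRID || any(ill <= 0))
    stop("illuminant must be a strictly positive 81-vector")
  W <- sens$curves * ill  # 81 x 5
  if (is.matrix(s)) {
    q <- t(W) %*% s       # 5 x n
    if (any(q[1:4, ] <= 0))
      stop("zero quantum catch in a receptor channel; stimulus has no ",
           "energy where the receptor is sensitive")
    out <- q[1:4, , drop = FALSE]
    rownames(out) <- c("uvs", "sws", "mws", "lws")
    attr(out, "double") <- as.vector(q[5, ])
    return(out)
  }
  q <- as.vector(t(W) %*% s)
  names(q) <- c("uvs", "sws", "mws", "lws", "dbl")
  if (any(q[1:4] <= 0))
    stop("zero quantum catch in a receptor channel; stimulus has no ",
         "energy where the receptor is sensitive")
  structure(q[1:4], double = q[["dbl"]])
}

# Weighted-Helmert opponent axes: with f_i = ln q_i and weights
# w_i = 1/e_i^2, squared Euclidean distance between loci equals the
# closed-form tetrachromatic receptor-noise discriminability
# sum_i w_i (df_i - weighted mean df)^2. Axis order is fixed:
# X = LWS vs MWS, Y = SWS vs {MWS, LWS}, Z = UVS vs the rest (last),
# so Z is the UV-opponent axis and signs are reproducible.
.helmert_locus <- function(f, w) {
  wl <- w[["lws"]]; wm <- w[["mws"]]; ws <- w[["sws"]]; wu <- w[["uvs"]]
  fl <- f["lws", ]; fm <- f["mws", ]; fs <- f["sws", ]; fu <- f["uvs", ]
  s2 <- wl + wm; s3 <- s2 + ws; s4 <- s3 + wu
  X <- sqrt(wl * wm / s2) * (fl - fm)
  Y <- sqrt(ws * s2 / s3) * (fs - (wl * fl + wm * fm) / s2)
  Z <- sqrt(wu * s3 / s4) * (fu - (wl * fl + wm * fm + ws * fs) / s3)
  rbind(X = X, Y = Y, Z = Z)
}

#' Chromatic locus in receptor-noise-scaled opponent space
#'
#' Maps quantum catches to three opponent coordinates (X, Y, Z) in JND
#' units, built so that (i) equal catches map to the origin, (ii) scaling
#' the stimulus by any positive constant leaves the locus unchanged, and
#' (iii) the Euclidean distance between any two loci equals the
#' closed-form tetrachromatic receptor-noise discriminability of their
#' catch vectors. The axis convention is documented in the methods
#' vignette: X opposes LWS to MWS, Y opposes SWS to the longer-wave pair,
#' and Z (last) is the UV-opponent axis.
#'
#' @param q Catches from [quantum_catches()] (named 4-vector or 4 x n
#'   matrix, all positive).
#' @param noise A [noise_model()] object.
#' @return A named 3-vector (class `chromatic_locus`, with attribute
#'   `luminance_catch` when the catches carry a double-cone catch), or a
#'   3 x n matrix for matrix input.
#' @export
chromatic_locus <- function(q, noise = noise_model()) {
  w <- 1 / noise$e^2
  if (is.matrix(q)) {
    if (any(q <= 0)) stop("all quantum catches must be positive")
    out <- .helmert_locus(log(q), w)
    attr(out, "luminance_catch") <- attr(q, "double")
    return(out)
  }
  if (any(q <= 0)) stop("all quantum catches must be positive")
  f <- matrix(log(q[c("uvs", "sws", "mws", "lws")]), ncol = 1,
              dimnames = list(c("uvs", "sws", "mws", "lws"), NULL))
  out <- as.vector(.helmert_locus(f, w))
  names(out) <- c("X", "Y", "Z")
  structure(out, luminance_catch = attr(q, "double"),
            class = "chromatic_locus")
}

#' Perceptual distance between two chromatic loci
#'
#' Euclidean distance in (X, Y, Z); 1 unit is one just-noticeable
#' difference under the noise model that produced the loci.
#'
#' @param a,b Loci from [chromatic_locus()] (same noise model).
#' @return Nonnegative distance in JND.
#' @export
delta_e <- function(a, b) {
  sqrt(sum((as.numeric(a)[1:3] - as.numeric(b)[1:3])^2))
}

#' Compute chromatic loci for every spectrum in a set
#'
#' @param x A `spectra_set`.
#' @param sens Receptor sensitivities (default template eye).
#' @param ill Illuminant (default flat).
#' @param noise Noise model (default conventional values).
#' @return Data frame: hierarchy metadata plus `X`, `Y`, `Z` and the
#'   double-cone `luminance_catch` per spectrum.
#' @export
compute_loci <- function(x, sens = build_sensitivities(),
                         ill = flat_illuminant(), noise = noise_model()) {
  q <- quantum_catches(x$R, sens, ill)
  loc <- chromatic_locus(q, noise)
  data.frame(x$meta, X = loc["X", ], Y = loc["Y", ], Z = loc["Z", ],
             luminance_catch = attr(loc, "luminance_catch"),
             row.names = NULL)
}

#' Median locus and JND concentration of species
#'
#' Coordinate-wise median of the species-average loci, plus the fraction
#' of species having at least one individual locus within `radius` JND of
#' that median.
#'
#' @param loci Data frame with columns `species`, `X`, `Y`, `Z` (one row
#'   per individual locus).
#' @param radius JND radius, default 1.
#' @return List with `median` (named 3-vector), `fraction`, `n_species`.
#' @export
jnd_summary <- function(loci, radius = 1) {
  if (nrow(loci) == 0) stop("jnd_summary needs at least one locus")
  sp_mean <- do.call(rbind, lapply(split(loci[c("X", "Y", "Z")], loci$species),
                                   colMeans))
  med <- apply(sp_mean, 2, stats::median)
  d2 <- (loci$X - med["X"])^2 + (loci$Y - med["Y"])^2 + (loci$Z - med["Z"])^2
  within <- tapply(sqrt(d2) <= radius, loci$species, any)
  list(median = med, fraction = mean(within), n_species = nrow(sp_mean))
}
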