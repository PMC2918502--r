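#' Canonical wavelength grid
#'
#' All gridded spectra in the package live on a fixed 300--700 nm grid in
#' 5 nm steps (81 points, both endpoints included). Reflectance is percent
#' relative to a white diffuse standard.
#'
#' @return Numeric vector of 81 wavelengths (nm).
#' @export
grid_nm <- function() seq(300, 700, by = 5)

.N_GRID <- 81L

.check_grid_values <- function(x, what = "spectrum") {
  if (is.matrix(x)) {
    if (nrow(x) != .N_GRID)
      stop(what, " matrix must have ", .N_GRID, " rows (one per grid point)")
  } else if (length(x) != .N_GRID) {
    stop(what, " must have exactly ", .N_GRID, " values on the 300-700 nm, 5 nm grid")
  }
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

.hier_cols <- c("family", "species", "clutch_id", "egg_id", "replicate_idx")

#' Collection of gridded spectra with hierarchical metadata
#'
#' A `spectra_set` bundles a reflectance matrix (81 grid wavelengths by
#' n spectra, percent units) with one metadata row per spectrum carrying
#' the sampling hierarchy: family, species, clutch, egg, replicate (1-6)
#' and, optionally, the clutch collection year.
#'
#' @param R Numeric matrix, 81 x n, reflectance (percent) on [grid_nm()].
#' @param meta Data frame with n rows and columns `family`, `species`,
#'   `clutch_id`, `egg_id`, `replicate_idx` and optionally
#'   `collection_year`.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(R, meta) {
  R <- as.matrix(R)
  .check_grid_values(R, "reflectance")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != ncol(R))
    stop("meta must have one row per spectrum (", ncol(R), " columns in R, ",
         nrow(meta), " rows in meta)")
  missing_cols <- setdiff(.hier_cols, names(meta))
  if (length(missing_cols))
    stop("meta lacks hierarchy columns: ", paste(missing_cols, collapse = ", "))
  .validate_keys(meta)
  structure(list(grid = grid_nm(), R = R, meta = meta), class = "spectra_set")
}

.validate_keys <- function(meta) {
  for (cl in c("family", "species", "clutch_id", "egg_id")) {
    v <- meta[[cl]]
    if (anyNA(v) || any(!nzchar(as.character(v))))
      stop("hierarchy column '", cl, "' has missing values; ",
           "incomplete keys are rejected, not imputed")
  }
  ri <- meta$replicate_idx
  if (anyNA(ri) || any(ri != as.integer(ri)) || any(ri < 1L) || any(ri > 6L))
    stop("replicate_idx must be an integer in 1..6")
  invisible(meta)
}

#' @export
print.spectra_set <- function(x, ...) {
  m <- x$meta
  cat("spectra_set: ", ncol(x$R), " spectra on the 300-700 nm 5 nm grid\n",
      "  families: ", length(unique(m$family)),
      "  species: ", length(unique(m$species)),
      "  clutches: ", length(unique(paste(m$species, m$clutch_id))),
      "  eggs: ", length(unique(paste(m$species, m$clutch_id, m$egg_id))), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.spectra_set <- function(x) ncol(x$R)

# ---- raw spectra I/O -------------------------------------------------------

.default_schema <- c(
  wavelength_nm = "wavelength_nm", reflectance_pct = "reflectance_pct",
  family = "family", species = "species", clutch_id = "clutch_id",
  egg_id = "egg_id", replicate_idx = "replicate_idx",
  collection_year = "collection_year"
)

#' Read a long-format spectra table
#'
#' Reads a CSV with one row per (replicate spectrum, wavelength). Required
#' columns (renameable through `schema`): `wavelength_nm`,
#' `reflectance_pct`, `family`, `species`, `clutch_id`, `egg_id`,
#' `replicate_idx`; `collection_year` is optional. Negative reflectance
#' (instrument noise) is accepted on input.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector mapping canonical column names to
#'   the names used in the file; defaults to the canonical names.
#' @return A `raw_spectra` object: metadata data frame (one row per
#'   spectrum) plus a list of (wavelength, reflectance) tables sorted by
#'   wavelength. `length()` gives the number of spectra read.
#' @export
read_spectra_table <- function(path, schema = NULL) {
  sc <- .default_schema
  if (!is.null(schema)) sc[names(schema)] <- schema
  d <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- setdiff(names(sc), "collection_year")
  absent <- need[!(sc[need] %in% names(d))]
  if (length(absent))
    stop("spectra table schema error: missing column(s) ",
         paste(sprintf("'%s'", sc[absent]), collapse = ", "), " in ", path)
  num <- function(col) {
    x <- suppressWarnings(as.numeric(d[[sc[col]]]))
    bad <- which(is.na(x) & !(d[[sc[col]]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric ", col, " at data line ", bad[1] + 1L, " of ", path,
           " ('", d[[sc[col]]][bad[1]], "')")
    x
  }
  wl <- num("wavelength_nm")
  refl <- num("reflectance_pct")
  if (anyNA(wl) || anyNA(refl))
    stop("missing wavelength/reflectance values in ", path)
  if (!all(is.finite(refl))) stop("non-finite reflectance in ", path)
  meta_all <- data.frame(
    family = d[[sc["family"]]], species = d[[sc["species"]]],
    clutch_id = d[[sc["clutch_id"]]], egg_id = d[[sc["egg_id"]]],
    replicate_idx = suppressWarnings(as.integer(d[[sc["replicate_idx"]]])),
    stringsAsFactors = FALSE
  )
  if (sc["collection_year"] %in% names(d)) {
    meta_all$collection_year <- suppressWarnings(as.integer(d[[sc["collection_year"]]]))
  } else meta_all$collection_year <- NA_integer_
  key <- do.call(paste, c(meta_all[c("family", "species", "clutch_id",
                                     "egg_id", "replicate_idx")], sep = "\r"))
  if (anyDuplicated(paste(key, wl)))
    stop("duplicate (sample key, wavelength) rows in ", path)
  idx <- split(seq_along(key), key)
  meta <- meta_all[vapply(idx, `[`, 1L, 1L), , drop = FALSE]
  rownames(meta) <- NULL
  .validate_keys(meta)
  spectra <- lapply(idx, function(i) {
    o <- order(wl[i])
    data.frame(wavelength_nm = wl[i][o], reflectance_pct = refl[i][o])
  })
  names(spectra) <- NULL
  structure(list(meta = meta, spectra = spectra), class = "raw_spectra")
}

#' @export
length.raw_spectra <- function(x) length(x$spectra)

#' @export
print.raw_spectra <- function(x, ...) {
  cat("raw_spectra: ", length(x), " spectra (native instrument resolution)\n",
      sep = "")
  invisible(x)
}

#' Write spectra to the long CSV dialect
#'
#' Emits the exact dialect [read_spectra_table()] expects, so write/read
#' round-trips are value-identical.
#'
#' @param x A `raw_spectra` or `spectra_set` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(x, path) {
  if (inherits(x, "spectra_set")) {
    n <- ncol(x$R)
    rows <- data.frame(
      wavelength_nm = rep(x$grid, n),
      reflectance_pct = as.vector(x$R),
      x$meta[rep(seq_len(n), each = .N_GRID), , drop = FALSE],
      row.names = NULL
    )
  } else if (inherits(x, "raw_spectra")) {
    lens <- vapply(x$spectra, nrow, 1L)
    rows <- data.frame(
      wavelength_nm = unlist(lapply(x$spectra, `[[`, "wavelength_nm")),
      reflectance_pct = unlist(lapply(x$spectra, `[[`, "reflectance_pct")),
      x$meta[rep(seq_along(lens), lens), , drop = FALSE],
      row.names = NULL
    )
  } else stop("x must be a raw_spectra or spectra_set")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- resampling ------------------------------------------------------------

# Mean of the piecewise-linear interpolant of (wl, y) over [lo, hi].
# Exact for data that are linear across the window because every sample
# point inside the window is kept as a trapezoid knot.
.window_mean <- function(wl, y, lo, hi) {
  inner <- wl > lo & wl < hi
  knots <- c(lo, wl[inner], hi)
  vals <- stats::approx(wl, y, xout = knots, rule = 1)$y
  sum(diff(knots) * (vals[-1] + vals[-length(vals)]) / 2) / (hi - lo)
}

#' Resample raw spectra onto the canonical 5 nm grid
#'
#' Truncates to 300--700 nm and computes, at each grid point g, the
#' interpolated average of the raw curve: by default the mean of the
#' piecewise-linear interpolant over the window \[g-2.5, g+2.5\]
#' intersected with \[300, 700\] (edge windows shrink accordingly).
#' `method = "interpolate"` instead evaluates the interpolant at the grid
#' point itself. Negative raw reflectance is clipped to zero at this
#' stage, before any normalisation.
#'
#' @param raw A `raw_spectra` object, or a single spectrum given as a
#'   two-column data frame / list with `wavelength_nm`, `reflectance_pct`.
#' @param method `"window"` (default) or `"interpolate"`.
#' @return A `spectra_set` (for `raw_spectra` input) or a numeric
#'   81-vector (for a single spectrum).
#' @export
resample_to_grid <- function(raw, method = c("window", "interpolate")) {
  method <- match.arg(method)
  if (inherits(raw, "raw_spectra")) {
    R <- vapply(raw$spectra, function(s)
      .resample_one(s$wavelength_nm, s$reflectance_pct, method),
      numeric(.N_GRID))
    return(spectra_set(R, raw$meta))
  }
  .resample_one(raw$wavelength_nm, raw$reflectance_pct, method)
}

.resample_one <- function(wl, y, method) {
  if (is.unsorted(wl, strictly = TRUE)) {
    o <- order(wl)
    wl <- wl[o]; y <- y[o]
    if (anyDuplicated(wl)) stop("duplicate wavelengths in raw spectrum")
  }
  if (wl[1] > 300 || wl[length(wl)] < 700)
    stop(sprintf("raw spectrum covers %.1f-%.1f nm; full 300-700 nm coverage required",
                 wl[1], wl[length(wl)]))
  inside <- wl >= 300 & wl <= 700
  gaps <- diff(wl[inside])
  if (length(gaps) && max(gaps) > 5) {
    i <- which.max(gaps)
    stop(sprintf("coverage gap of %.2f nm between %.1f and %.1f nm (max allowed 5 nm)",
                 max(gaps), wl[inside][i], wl[inside][i + 1]))
  }
  g <- grid_nm()
  out <- if (method == "interpolate") {
    stats::approx(wl, y, xout = g, rule = 1)$y
  } else {
    vapply(g, function(gi)
      .window_mean(wl, y, max(gi - 2.5, 300), min(gi + 2.5, 700)), 0)
  }
  pmax(out, 0)
}

#' Treat already-gridded raw spectra as grid spectra
#'
#' Fast path for tables whose wavelengths are exactly the canonical grid
#' (e.g. files written by [write_dataset()]): values are taken as-is
#' (negatives clipped to zero), with no window averaging.
#'
#' @param raw A `raw_spectra` object whose every spectrum is sampled at
#'   exactly [grid_nm()].
#' @return A `spectra_set`.
#' @export
as_grid_spectra <- function(raw) {
  g <- grid_nm()
  R <- vapply(raw$spectra, function(s) {
    if (nrow(s) != .N_GRID || any(abs(s$wavelength_nm - g) > 1e-9))
      stop("spectrum is not sampled on the canonical grid; use resample_to_grid()")
    pmax(s$reflectance_pct, 0)
  }, numeric(.N_GRID))
  spectra_set(R, raw$meta)
}

#' Is a raw spectra collection already on the canonical grid?
#' @param raw A `raw_spectra` object.
#' @return Logical.
#' @export
is_on_grid <- function(raw) {
  g <- grid_nm()
  all(vapply(raw$spectra, function(s)
    nrow(s) == .N_GRID && all(abs(s$wavelength_nm - g) < 1e-9), TRUE))
}

# ---- spectral statistics ---------------------------------------------------

#' Relative spectrum (shape only)
#'
#' Divides each 5 nm grid value by the sum over the 81 grid values, so
#' proportions sum to one and the result is invariant to overall
#' intensity. Negative values (if any survived upstream clipping) are
#' clipped to zero first.
#'
#' @param s Numeric 81-vector, or an 81 x n matrix (column-wise).
#' @return Object of the same shape with columns summing to 1.
#' @export
relative_spectrum <- function(s) {
  .check_grid_values(s)
  if (is.matrix(s)) {
    s <- pmax(s, 0)
    tot <- colSums(s)
    if (any(tot <= 0)) stop("all-zero spectrum: relative spectrum undefined")
    return(sweep(s, 2, tot, "/"))
  }
  s <- pmax(s, 0)
  tot <- sum(s)
  if (tot <= 0) stop("all-zero spectrum: relative spectrum undefined")
  s / tot
}

#' Pointwise average of grid spectra
#'
#' @param spectra An 81 x n matrix, a list of 81-vectors, or a
#'   `spectra_set`.
#' @return Numeric 81-vector.
#' @export
average_spectrum <- function(spectra) {
  if (inherits(spectra, "spectra_set")) spectra <- spectra$R
  if (is.list(spectra)) spectra <- do.call(cbind, spectra)
  spectra <- as.matrix(spectra)
  if (ncol(spectra) == 0) stop("cannot average an empty set of spectra")
  .check_grid_values(spectra)
  rowMeans(spectra)
}

#' Absolute sum difference between two spectra
#'
#' A spectral-shape distance: both spectra are converted to
#' relative spectra, subtracted, and the absolute differences summed over
#' the 81 grid points. Symmetric, zero iff the relative spectra are equal,
#' and bounded by 2 (attained for disjoint support).
#'
#' @param a,b Numeric 81-vectors (grid spectra, any positive scaling).
#' @return Nonnegative scalar in \[0, 2\].
#' @export
abs_sum_difference <- function(a, b) {
  sum(abs(relative_spectrum(a) - relative_spectrum(b)))
}

#' Aggregate a spectra set up the sampling hierarchy
#'
#' Averages spectra pointwise within groups at the requested level:
#' `"egg"` averages replicates, `"clutch"` averages eggs, `"species"`
#' averages clutches, `"family"` averages species. Each step averages the
#' means of the level below (replicates -> egg -> clutch -> species ->
#' family), so unbalanced designs are weighted by group, not by spectrum.
#'
#' @param x A `spectra_set`.
#' @param level One of `"egg"`, `"clutch"`, `"species"`, `"family"`.
#' @return A `spectra_set` with one column per group; hierarchy columns
#'   below the chosen level are collapsed (replicate_idx set to 1).
#' @export
aggregate_spectra <- function(x, level = c("egg", "clutch", "species", "family")) {
  level <- match.arg(level)
  steps <- c("egg", "clutch", "species", "family")
  keep <- list(
    egg = c("family", "species", "clutch_id", "egg_id"),
    clutch = c("family", "species", "clutch_id"),
    species = c("family", "species"),
    family = "family"
  )
  for (st in steps[seq_len(match(level, steps))]) {
    cols <- keep[[st]]
    key <- do.call(paste, c(x$meta[cols], sep = "\r"))
    idx <- split(seq_along(key), key)
    R <- vapply(idx, function(i) rowMeans(x$R[, i, drop = FALSE]),
                numeric(.N_GRID))
    meta <- x$meta[vapply(idx, `[`, 1L, 1L), , drop = FALSE]
    for (cl in setdiff(c("species", "clutch_id", "egg_id"), cols))
      if (st == "family") meta[[cl]] <- meta$family
    if (!("clutch_id" %in% cols) && st != "family") meta$clutch_id <- meta[[cols[length(cols)]]]
    if (!("egg_id" %in% cols)) meta$egg_id <- meta$clutch_id
    meta$replicate_idx <- 1L
    if ("collection_year" %in% names(meta) && !("clutch_id" %in% cols))
      meta$collection_year <- NA_integer_
    rownames(meta) <- NULL
    x <- spectra_set(R, meta)
  }
  x
}
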