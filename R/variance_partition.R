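# Moment-based (Type I) nested random-effects ANOVA for fully nested,
# possibly unbalanced designs, solved through expected-mean-square
# coefficients: for grouping level l and component m >= l,
#   coef(l, m) = (T[l, m] - T[l-1, m]) / df_l,
#   T[l, m]   = sum over level-l cells c of
#               (sum over level-m cells within c of n^2) / n_c,
# with T[0, m] the same quantity over the whole sample. On balanced
# designs these reduce to the textbook products of subgroup sizes.

.nested_design <- function(groups) {
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  L <- ncol(groups)
  if (L < 1) stop("at least one grouping level is required")
  for (cl in names(groups))
    if (anyNA(groups[[cl]]) || any(!nzchar(as.character(groups[[cl]]))))
      stop("grouping level '", cl, "' has missing values")
  n <- nrow(groups)
  ids <- vector("list", L)
  key <- rep("", n)
  for (l in seq_len(L)) {
    key <- paste(key, as.character(groups[[l]]), sep = "\r")
    ids[[l]] <- match(key, unique(key))
  }
  counts <- lapply(ids, tabulate)
  # parent cell of each cell at level l (level 1 parent = grand)
  first_row <- lapply(ids, function(id) match(seq_len(max(id)), id))
  parents <- vector("list", L)
  for (l in seq_len(L))
    parents[[l]] <- if (l == 1) rep(1L, max(ids[[l]])) else ids[[l - 1]][first_row[[l]]]
  ncells <- vapply(ids, max, 1L)
  df <- c(ncells[1] - 1L, diff(ncells), n - ncells[L])
  # T matrix: rows l = 0..L (stratum boundaries), cols m = 1..L (components)
  Tm <- matrix(0, L + 1L, L)
  for (m in seq_len(L)) {
    n2 <- counts[[m]]^2
    Tm[1, m] <- sum(n2) / n
    for (l in seq_len(m)) {
      anc <- seq_len(ncells[m])
      p <- m
      while (p > l) { anc <- parents[[p]][anc]; p <- p - 1L }
      Tm[l + 1L, m] <- sum(rowsum(n2, anc) / counts[[l]])
    }
  }
  K <- matrix(0, L + 1L, L + 1L)  # EMS coefficients, strata x components
  for (l in seq_len(L)) {
    if (df[l] > 0)
      K[l, seq_len(L)] <- (Tm[l + 1L, ] - Tm[l, ]) / df[l]
  }
  K[, L + 1L] <- 1
  K[L + 1L, seq_len(L)] <- 0
  for (l in seq_len(L)) K[l, seq_len(l - 1L)] <- 0  # components above stratum absent
  list(ids = ids, counts = counts, df = df, K = K, n = n, L = L,
       levels = names(groups))
}

.varcomp_fit <- function(design, y) {
  L <- design$L
  means <- vector("list", L)
  for (l in seq_len(L))
    means[[l]] <- as.vector(rowsum(y, design$ids[[l]])) / design$counts[[l]]
  grand <- mean(y)
  SS <- numeric(L + 1L)
  for (l in seq_len(L)) {
    parent_mean <- if (l == 1) grand else {
      first_row <- match(seq_along(means[[l]]), design$ids[[l]])
      means[[l - 1]][design$ids[[l - 1]][first_row]]
    }
    SS[l] <- sum(design$counts[[l]] * (means[[l]] - parent_mean)^2)
  }
  SS[L + 1L] <- sum((y - means[[L]][design$ids[[L]]])^2)
  MS <- ifelse(design$df > 0, SS / design$df, NA_real_)
  comps <- numeric(L + 1L)
  comps[L + 1L] <- MS[L + 1L]
  for (l in rev(seq_len(L))) {
    if (design$df[l] <= 0)
      stop("no replication anywhere at level '", design$levels[l],
           "': its variance component is not estimable")
    comps[l] <- (MS[l] - sum(design$K[l, -l] * comps[-l])) / design$K[l, l]
  }
  list(SS = SS, MS = MS, components_raw = comps)
}

#' Nested random-effects variance components
#'
#' Hierarchical (Type I) nested ANOVA for a fully nested design, e.g.
#' replicate measurements within eggs within clutches within species
#' within families. Sums of squares come from nested group means;
#' expected-mean-square coefficients are computed for the (possibly
#' unbalanced) design; components are solved from the residual stratum
#' upwards; negative estimates are reported raw and truncated to zero
#' before percentages.
#'
#' @param x A formula like `value ~ family/species/clutch_id/egg_id`
#'   (outermost level first; the residual stratum is the replicate level),
#'   or a numeric vector of observations.
#' @param data Data frame holding the formula variables.
#' @param groups For the default method: data frame of grouping columns,
#'   outermost first.
#' @param ... Unused.
#' @return A `nested_varcomp` object: ANOVA table (df, SS, MS), EMS
#'   coefficient matrix, raw and truncated components, percentages
#'   (summing to 100 unless the data are constant, which is flagged
#'   `degenerate`).
#' @export
nested_varcomp <- function(x, ...) UseMethod("nested_varcomp")

#' @rdname nested_varcomp
#' @export
nested_varcomp.formula <- function(x, data, ...) {
  lhs <- x[[2]]
  y <- eval(lhs, data, environment(x))
  rhs <- all.vars(x[[3]])
  groups <- data[rhs]
  out <- nested_varcomp(y, groups)
  out$call <- match.call()
  out
}

#' @rdname nested_varcomp
#' @export
nested_varcomp.default <- function(x, groups, ...) {
  y <- as.numeric(x)
  if (anyNA(y)) stop("observations contain NA")
  design <- .nested_design(groups)
  if (any(design$df == 0)) {
    lv <- c(design$levels, "replicate")[which(design$df == 0)[1]]
    stop("no replication anywhere at level '", lv,
         "': its variance component is not estimable")
  }
  fit <- .varcomp_fit(design, y)
  .varcomp_result(design, fit, match.call())
}

.varcomp_result <- function(design, fit, call = NULL) {
  lev <- c(design$levels, "replicate")
  comps <- fit$components_raw
  trunc <- pmax(comps, 0)
  total <- sum(trunc)
  degenerate <- total <= 0
  pct <- if (degenerate) rep(0, length(trunc)) else 100 * trunc / total
  names(comps) <- names(trunc) <- names(pct) <- lev
  tab <- data.frame(level = lev, df = design$df, SS = fit$SS, MS = fit$MS,
                    component = comps, percent = pct, row.names = NULL)
  structure(list(table = tab, components_raw = comps, components = trunc,
                 percentages = pct, total = total, ems = design$K,
                 degenerate = degenerate, n = design$n, call = call),
            class = "nested_varcomp")
}

#' @export
print.nested_varcomp <- function(x, digits = 4, ...) {
  cat("Nested ANOVA variance components (", x$n, " observations)\n", sep = "")
  tab <- x$table
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$component <- signif(tab$component, digits)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  if (x$degenerate) cat("note: constant data; all components zero (degenerate)\n")
  invisible(x)
}

#' @export
summary.nested_varcomp <- function(object, ...) object

#' Per-wavelength variance partition of a spectra set
#'
#' Applies [nested_varcomp()] independently at each of the 81 grid
#' wavelengths of a spectra set, using the replicate / egg / clutch /
#' species / family hierarchy in the metadata. The design (group index
#' structure and EMS coefficients) is computed once and reused across
#' wavelengths.
#'
#' @param x A `spectra_set` with complete hierarchy metadata.
#' @return A `variance_profile` object: wavelengths, an 81 x 5 percentage
#'   matrix and an 81 x 5 raw-component matrix (columns family, species,
#'   clutch, egg, replicate).
#' @export
variance_profile <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  groups <- x$meta[c("family", "species", "clutch_id", "egg_id")]
  design <- .nested_design(groups)
  if (any(design$df == 0)) {
    lv <- c(design$levels, "replicate")[which(design$df == 0)[1]]
    stop("no replication anywhere at level '", lv, "'")
  }
  lev <- c("family", "species", "clutch", "egg", "replicate")
  pct <- raw <- matrix(NA_real_, .N_GRID, 5, dimnames = list(NULL, lev))
  for (k in seq_len(.N_GRID)) {
    fit <- .varcomp_fit(design, x$R[k, ])
    comps <- fit$components_raw
    tr <- pmax(comps, 0)
    tot <- sum(tr)
    raw[k, ] <- comps
    pct[k, ] <- if (tot > 0) 100 * tr / tot else 0
  }
  structure(list(grid = grid_nm(), percentages = pct, components_raw = raw,
                 n = design$n),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  cat("Per-wavelength nested variance partition (", x$n,
      " observations per wavelength)\n", sep = "")
  cat("mean percentages across 300-700 nm:\n")
  print(round(colMeans(x$percentages), 2))
  invisible(x)
}

#' @export
plot.variance_profile <- function(x, ...) {
  cum <- t(apply(x$percentages, 1, cumsum))
  graphics::matplot(x$grid, cum, type = "l", lty = 1, lwd = 2,
                    xlab = "wavelength (nm)",
                    ylab = "cumulative % of variance", ylim = c(0, 100), ...)
  graphics::legend("bottomright", colnames(x$percentages), lty = 1, lwd = 2,
                   col = seq_len(ncol(cum)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Export a variance profile as a data frame / CSV
#' @param x A `variance_profile`.
#' @param path Optional CSV path; when given the table is also written.
#' @return Data frame with wavelength, five raw components and five
#'   percentages.
#' @export
variance_profile_table <- function(x, path = NULL) {
  d <- data.frame(wavelength_nm = x$grid,
                  stats::setNames(as.data.frame(x$components_raw),
                                  paste0("vc_", colnames(x$components_raw))),
                  stats::setNames(as.data.frame(x$percentages),
                                  paste0("pct_", colnames(x$percentages))))
  if (!is.null(path)) utils::write.csv(d, path, row.names = FALSE)
  d
}
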