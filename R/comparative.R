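.rank_cols <- c("genus", "tribe", "subfamily", "family")

#' Validate a taxonomy table
#'
#' Checks the columns (`species`, `genus`, `tribe`, `subfamily`,
#' `family`), uniqueness of species, and rank nesting consistency (same
#' genus implies same tribe, same tribe implies same subfamily, ...).
#'
#' @param tax Data frame.
#' @return `tax`, invisibly, or an error.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("species", .rank_cols)
  miss <- setdiff(need, names(tax))
  if (length(miss)) stop("taxonomy lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tax$species)) stop("duplicate species in taxonomy")
  for (i in seq_len(length(.rank_cols) - 1)) {
    lo <- .rank_cols[i]; hi <- .rank_cols[i + 1]
    up <- tapply(tax[[hi]], tax[[lo]], function(v) length(unique(v)))
    if (any(up > 1))
      stop("taxonomy ranks not nested: ", lo, " '",
           names(up)[which(up > 1)[1]], "' spans multiple ", hi, " values")
  }
  invisible(tax)
}

#' Extract independent sister pairs from a taxonomy
#'
#' Pairs species at their shallowest shared rank, each species used at
#' most once: species are first paired within genera, leftovers within
#' tribes (necessarily across genera), then subfamilies, then families,
#' and finally across families. Within every group species are processed
#' in sorted label order, which makes the pairing deterministic.
#'
#' @param tax Taxonomy data frame (see [validate_taxonomy()]).
#' @param tree Optional `phylo`; currently unused (the pairing is
#'   taxonomic), accepted for interface compatibility.
#' @return Data frame with `species_a`, `species_b` and `level` (factor:
#'   congeneric, tribe, subfamily, family, between-family); unpaired
#'   species (at most one) in attribute `"unpaired"`.
#' @export
extract_sister_pairs <- function(tax, tree = NULL) {
  validate_taxonomy(tax)
  levels_out <- c("congeneric", "tribe", "subfamily", "family", "between-family")
  remaining <- sort(tax$species)
  rank_of <- function(sp, col) tax[[col]][match(sp, tax$species)]
  pairs <- list()
  for (k in seq_along(levels_out)) {
    if (length(remaining) < 2) break
    groups <- if (k <= 4) split(remaining, rank_of(remaining, .rank_cols[k]))
              else list(all = remaining)
    for (g in groups) {
      np <- length(g) %/% 2
      if (np == 0) next
      a <- g[seq_len(np) * 2 - 1]; b <- g[seq_len(np) * 2]
      pairs[[length(pairs) + 1]] <-
        data.frame(species_a = a, species_b = b, level = levels_out[k])
      remaining <- setdiff(remaining, c(a, b))
    }
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(species_a = character(), species_b = character(),
               level = character())
  out$level <- factor(out$level, levels = levels_out)
  out <- out[order(out$level, out$species_a), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unpaired") <- remaining
  out
}

#' Attach spectral differences to sister pairs
#'
#' Computes [abs_sum_difference()] between the species-average spectra of
#' each pair.
#'
#' @param pairs Data frame from [extract_sister_pairs()].
#' @param species_spectra 81 x n matrix of species-average spectra with
#'   species names as column names, or a `spectra_set` (aggregated to
#'   species level internally).
#' @return `pairs` with a `spectral_difference` column.
#' @export
pair_spectral_differences <- function(pairs, species_spectra) {
  if (inherits(species_spectra, "spectra_set")) {
    sp <- aggregate_spectra(species_spectra, "species")
    species_spectra <- sp$R
    colnames(species_spectra) <- sp$meta$species
  }
  miss <- setdiff(c(pairs$species_a, pairs$species_b), colnames(species_spectra))
  if (length(miss)) stop("no spectra for species: ", paste(miss, collapse = ", "))
  pairs$spectral_difference <- vapply(seq_len(nrow(pairs)), function(i)
    abs_sum_difference(species_spectra[, pairs$species_a[i]],
                       species_spectra[, pairs$species_b[i]]), 0)
  pairs
}

#' One-way ANOVA of spectral differences across taxonomic distance
#'
#' Tests whether sister-pair spectral differences vary with the taxonomic
#' level of the pair, with per-level box-plot summaries (n, median,
#' quartiles, mean, sd). Levels with fewer than 2 pairs are dropped with
#' a warning.
#'
#' @param pairs Data frame with `level` and `spectral_difference`.
#' @return List (class `sister_anova`): `F`, `df1`, `df2`, `p`,
#'   `by_level` summary data frame.
#' @export
sister_pair_anova <- function(pairs) {
  counts <- table(droplevels(factor(pairs$level)))
  drop <- names(counts)[counts < 2]
  if (length(drop)) {
    warning("dropping level(s) with a single pair: ", paste(drop, collapse = ", "))
    pairs <- pairs[!(as.character(pairs$level) %in% drop), , drop = FALSE]
  }
  pairs$level <- droplevels(factor(pairs$level))
  if (nlevels(pairs$level) < 2)
    stop("at least 2 taxonomic levels with >= 2 pairs are required")
  a <- if (stats::var(pairs$spectral_difference) == 0) {
    # constant response: define F = 0 rather than a 0/0 ratio
    data.frame(Df = c(nlevels(pairs$level) - 1L,
                      nrow(pairs) - nlevels(pairs$level)),
               `F value` = c(0, NA), `Pr(>F)` = c(1, NA),
               check.names = FALSE)
  } else {
    stats::anova(stats::lm(spectral_difference ~ level, data = pairs))
  }
  by_level <- do.call(rbind, lapply(split(pairs$spectral_difference, pairs$level),
    function(v) data.frame(n = length(v), median = stats::median(v),
                           q1 = unname(stats::quantile(v, 0.25)),
                           q3 = unname(stats::quantile(v, 0.75)),
                           mean = mean(v), sd = stats::sd(v))))
  by_level <- data.frame(level = rownames(by_level), by_level, row.names = NULL)
  structure(list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                 p = a$`Pr(>F)`[1], by_level = by_level),
            class = "sister_anova")
}

#' @export
print.sister_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of spectral difference by taxonomic level:\n  F_%d,%d = %.3f, P = %.3g\n",
              x$df1, x$df2, x$F, x$p))
  print(x$by_level, row.names = FALSE)
  invisible(x)
}

#' Build museum-storage clutch pairs
#'
#' For every species with clutches collected in at least two distinct
#' years, selects the two clutches separated by the largest time span and
#' computes the clutch-average luminance of each and the absolute sum
#' difference between the clutch-average relative spectra.
#'
#' @param x A `spectra_set` whose metadata carry `collection_year`.
#' @return Data frame (class `storage_pairs`): species, old/new clutch
#'   ids and years, `delta_years`, luminances, `delta_luminance`
#'   (new - old), `delta_spectral`.
#' @export
storage_pairs <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  cl <- aggregate_spectra(x, "clutch")
  m <- cl$meta
  if (!("collection_year" %in% names(m)) || all(is.na(m$collection_year)))
    stop("spectra metadata carry no collection years")
  rows <- list()
  for (sp in unique(m$species)) {
    i <- which(m$species == sp & !is.na(m$collection_year))
    if (length(i) < 2) next
    yr <- m$collection_year[i]
    if (max(yr) == min(yr)) next
    o <- i[order(yr, m$clutch_id[i])]
    old <- o[1]; new <- o[length(o)]
    rows[[length(rows) + 1]] <- data.frame(
      species = sp,
      clutch_old = m$clutch_id[old], clutch_new = m$clutch_id[new],
      year_old = m$collection_year[old], year_new = m$collection_year[new],
      delta_years = m$collection_year[new] - m$collection_year[old],
      lum_old = luminance(cl$R[, old]), lum_new = luminance(cl$R[, new]),
      delta_spectral = abs_sum_difference(cl$R[, old], cl$R[, new])
    )
  }
  if (!length(rows)) stop("no species with clutches from distinct years")
  out <- do.call(rbind, rows)
  out$delta_luminance <- out$lum_new - out$lum_old
  class(out) <- c("storage_pairs", "data.frame")
  out
}

#' Museum-storage effect tests
#'
#' (a) Paired t-test of newer- versus older-clutch luminance; (b)
#' ordinary least-squares regressions of the luminance difference and of
#' the spectral-shape difference on the natural log of the year gap, each
#' reported as estimate, standard error, t and two-sided p.
#'
#' @param pairs A [storage_pairs()] data frame (or any data frame with
#'   columns `lum_old`, `lum_new`, `delta_luminance`, `delta_spectral`,
#'   `delta_years`).
#' @param log_fn Transform applied to `delta_years` (default natural
#'   log).
#' @return List (class `storage_tests`): `t_test` (t, n, p),
#'   `luminance_fit` and `spectral_fit` (estimate, se, t, p, n).
#' @export
storage_effect_tests <- function(pairs, log_fn = log) {
  zero <- pairs$delta_years <= 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " pair(s) with zero year separation")
    pairs <- pairs[!zero, , drop = FALSE]
  }
  n <- nrow(pairs)
  if (n < 3) stop("at least 3 storage pairs are required")
  d <- pairs$lum_new - pairs$lum_old
  tt <- if (stats::sd(d) == 0) {
    list(statistic = c(t = if (mean(d) == 0) 0 else Inf * sign(mean(d))),
         p.value = if (mean(d) == 0) 1 else 0)
  } else stats::t.test(pairs$lum_new, pairs$lum_old, paired = TRUE)
  slope <- function(yv) {
    x <- log_fn(pairs$delta_years)
    if (stats::var(yv) == 0 || stats::var(x) == 0)
      return(list(estimate = 0, se = NA_real_, t = 0, p = 1, n = n))
    fit <- summary(stats::lm(yv ~ x))$coefficients
    list(estimate = fit[2, 1], se = fit[2, 2], t = fit[2, 3], p = fit[2, 4],
         n = n)
  }
  structure(list(
    t_test = list(t = unname(tt$statistic), n = n, p = tt$p.value),
    luminance_fit = slope(pairs$delta_luminance),
    spectral_fit = slope(pairs$delta_spectral)
  ), class = "storage_tests")
}

#' @export
print.storage_tests <- function(x, ...) {
  cat(sprintf("Paired t-test (newer vs older clutch luminance): t = %.2f, n = %d, P = %.3g\n",
              x$t_test$t, x$t_test$n, x$t_test$p))
  cat(sprintf("delta luminance ~ ln(delta years): %.4g +/- %.4g, t = %.2f, P = %.3g\n",
              x$luminance_fit$estimate, x$luminance_fit$se,
              x$luminance_fit$t, x$luminance_fit$p))
  cat(sprintf("delta spectral  ~ ln(delta years): %.4g +/- %.4g, t = %.2f, P = %.3g\n",
              x$spectral_fit$estimate, x$spectral_fit$se,
              x$spectral_fit$t, x$spectral_fit$p))
  invisible(x)
}

#' Sampling-bias randomization test
#'
#' Compares the median of a focal species set against the distribution of
#' medians of `n_draw` species drawn repeatedly without replacement from
#' a pool, with a 95% (2.5th-97.5th percentile) envelope.
#'
#' @param pool Numeric trait values for every species in the pool.
#' @param focal Numeric trait values of the focal subset.
#' @param n_draw Species per draw (default `length(focal)`).
#' @param reps Number of random draws (>= 100), default 1000.
#' @param seed Optional integer seed for reproducible draws.
#' @return List: `observed` median, `lower`, `upper`, `inside` verdict,
#'   and the vector of replicate `medians`.
#' @export
sampling_randomization <- function(pool, focal, n_draw = length(focal),
                                   reps = 1000, seed = NULL) {
  if (n_draw > length(pool)) stop("n_draw exceeds pool size")
  if (reps < 100) stop("reps must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  meds <- vapply(seq_len(reps), function(i)
    stats::median(sample(pool, n_draw, replace = FALSE)), 0)
  env <- stats::quantile(meds, c(0.025, 0.975), names = FALSE)
  obs <- stats::median(focal)
  list(observed = obs, lower = env[1], upper = env[2],
       inside = obs >= env[1] && obs <= env[2], medians = meds)
}

#' Maculation score repeatability between observers
#'
#' Eggs are scored 0 (immaculate), 1 (maculated with a dominant
#' background colour) or 2 (widespread maculation) by two observers.
#' Species scores are the mean over eggs and observers; repeatability is
#' the Pearson correlation of the per-species observer means.
#'
#' @param scores Data frame with columns `species`, `egg_id`, `score_a`,
#'   `score_b` (one row per egg; scores must be 0, 1 or 2).
#' @return List: `species_scores` data frame (species, mean_a, mean_b,
#'   score), `r`, `n`.
#' @export
maculation_repeatability <- function(scores) {
  for (cl in c("score_a", "score_b")) {
    v <- scores[[cl]]
    if (is.null(v)) stop("scores must have columns score_a and score_b")
    if (anyNA(v) || !all(v %in% c(0, 1, 2)))
      stop("egg-level ", cl, " values must be 0, 1 or 2")
  }
  agg <- do.call(rbind, lapply(split(scores, scores$species), function(d)
    data.frame(species = d$species[1], mean_a = mean(d$score_a),
               mean_b = mean(d$score_b))))
  agg$score <- (agg$mean_a + agg$mean_b) / 2
  rownames(agg) <- NULL
  r <- stats::cor(agg$mean_a, agg$mean_b)
  list(species_scores = agg, r = r, n = nrow(agg))
}
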