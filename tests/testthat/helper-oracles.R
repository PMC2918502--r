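# Independent oracles and fixture builders used across the suite.
# Oracles deliberately use direct loops / dense algebra, not the package's
# computational paths.

# Closed-form tetrachromatic receptor-noise discriminability (squared):
# numerator over receptor pairs, weighted by the squared noise product of
# the OTHER two receptors; denominator over receptor triples.
rnl_delta_s2 <- function(qa, qb, e) {
  ord <- c("uvs", "sws", "mws", "lws")
  f <- log(qa[ord]) - log(qb[ord])
  e <- e[ord]
  num <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    others <- setdiff(1:4, c(i, j))
    num <- num + (e[others[1]] * e[others[2]])^2 * (f[i] - f[j])^2
  }
  den <- 0
  cmb <- utils::combn(4, 3)
  for (k in seq_len(ncol(cmb))) den <- den + prod(e[cmb[, k]])^2
  unname(num / den)
}

# Dense multivariate-normal log-likelihood maximised over (mu, sigma2) by
# brute-force 2-D grid refinement; independent of the package's profiled
# Cholesky evaluation.
dense_profile_loglik <- function(y, V, tol = 1e-4) {
  n <- length(y)
  Vi <- solve(V)
  ld <- determinant(V, logarithm = TRUE)$modulus
  ll <- function(mu, s2) {
    r <- y - mu
    -0.5 * (n * log(2 * pi * s2) + ld + drop(t(r) %*% Vi %*% r) / s2)
  }
  mu_rng <- range(y) + c(-2, 2) * stats::sd(y)
  s2_rng <- c(1e-4, 10) * stats::var(y)
  best <- -Inf
  for (it in 1:6) {
    mus <- seq(mu_rng[1], mu_rng[2], length.out = 41)
    s2s <- exp(seq(log(s2_rng[1]), log(s2_rng[2]), length.out = 41))
    vals <- outer(mus, s2s, Vectorize(ll))
    k <- arrayInd(which.max(vals), dim(vals))
    best <- max(vals)
    mu_step <- diff(mu_rng) / 40
    mu_rng <- mus[k[1]] + c(-1, 1) * mu_step
    s2_rng <- s2s[k[2]] * exp(c(-1, 1) * diff(log(s2_rng)) / 40)
  }
  best
}

# A spectra_set with a fully crossed toy hierarchy and controllable
# per-spectrum values.
toy_spectra_set <- function(values, family, species, clutch, egg, replicate,
                            year = NA_integer_) {
  R <- vapply(values, function(v) rep(v, 81), numeric(81))
  spectra_set(R, data.frame(
    family = family, species = species, clutch_id = clutch, egg_id = egg,
    replicate_idx = replicate, collection_year = year
  ))
}

# Enumerate all ways to pair species and return the lexicographically
# best achievable level-count vector (shallowest levels maximised first).
best_pairing_counts <- function(tax) {
  levels_out <- c("congeneric", "tribe", "subfamily", "family", "between-family")
  pair_level <- function(a, b) {
    ra <- tax[tax$species == a, ]; rb <- tax[tax$species == b, ]
    if (ra$genus == rb$genus) "congeneric"
    else if (ra$tribe == rb$tribe) "tribe"
    else if (ra$subfamily == rb$subfamily) "subfamily"
    else if (ra$family == rb$family) "family"
    else "between-family"
  }
  best <- NULL
  recurse <- function(remaining, counts) {
    if (length(remaining) < 2) {
      if (is.null(best) || .lex_gt(counts, best)) best <<- counts
      return(invisible())
    }
    a <- remaining[1]
    for (b in remaining[-1]) {
      lv <- pair_level(a, b)
      cnt <- counts
      cnt[lv] <- cnt[lv] + 1
      recurse(setdiff(remaining, c(a, b)), cnt)
    }
    # option: leave a unpaired (only useful for odd leftovers)
    recurse(remaining[-1], counts)
  }
  counts0 <- stats::setNames(rep(0, 5), levels_out)
  recurse(sort(tax$species), counts0)
  best
}

.lex_gt <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}
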