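# Synthetic studies with known ground truth: phylogeny, taxonomy,
# pigment-based eggshell spectra with nested noise, collection years and
# two-observer maculation scores. Every pipeline stage has a recovery
# test against these generators.

#' Simulate a pure-birth (Yule) tree
#'
#' Iterative random tip splitting with exponential waiting times: starting
#' from a two-tip cherry, at each step every active lineage is extended by
#' an Exp(k * birth) waiting time (k = current number of tips) and one
#' uniformly chosen tip splits. A final waiting time keeps terminal
#' branches strictly positive. All tips are extended equally, so the tree
#' is ultrametric.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate, default 1.
#' @param labels Tip labels, default `t1..tn` (assigned left to right).
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth = 1, labels = paste0("t", seq_len(n_tips))) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  parent <- c(NA_integer_, 1L, 1L)
  blen <- c(0, 0, 0)
  children <- list(c(2L, 3L))
  active <- c(2L, 3L)
  while (length(active) < n_tips) {
    k <- length(active)
    blen[active] <- blen[active] + stats::rexp(1, k * birth)
    i <- active[sample.int(k, 1)]
    id1 <- length(parent) + 1L; id2 <- id1 + 1L
    parent[c(id1, id2)] <- i
    blen[c(id1, id2)] <- 0
    children[[i]] <- c(id1, id2)
    active <- c(active[active != i], id1, id2)
  }
  blen[active] <- blen[active] + stats::rexp(1, n_tips * birth)
  lab <- character(length(parent))
  lab[active] <- labels
  nwk <- function(v) {
    if (v <= length(children) && !is.null(children[[v]]) && length(children[[v]]) == 2) {
      inner <- paste(vapply(children[[v]], nwk, ""), collapse = ",")
      if (v == 1L) paste0("(", inner, ")") else
        sprintf("(%s):%.12g", inner, blen[v])
    } else sprintf("%s:%.12g", lab[v], blen[v])
  }
  ape::read.tree(text = paste0(nwk(1L), ";"))
}

#' Simulate trait values under a lambda-transformed Brownian model
#'
#' Draws tip values from a zero-mean multivariate normal with covariance
#' `sigma2 * C_lambda(tree)`, where `C_lambda` is the phylogenetic
#' covariance with off-diagonals multiplied by `lambda`, via the Cholesky
#' square root. `lambda = 1` is Brownian motion; `lambda = 0` gives
#' independent tips.
#'
#' @param tree A `phylo` with positive branch lengths.
#' @param sigma2 Brownian rate (> 0).
#' @param lambda Phylogenetic-signal multiplier in \[0, 1\].
#' @return Named numeric vector of tip values.
#' @export
simulate_traits <- function(tree, sigma2 = 1, lambda = 1) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  C <- .lambda_cov(phylo_covariance(tree), lambda)
  R <- tryCatch(chol(sigma2 * C),
                error = function(e) stop("transformed covariance is not positive definite"))
  y <- as.vector(t(R) %*% stats::rnorm(nrow(C)))
  names(y) <- rownames(C)
  y
}

#' Pigment absorbance and baseline parameters
#'
#' Defaults for the synthetic eggshell spectrum model: a smooth baseline
#' rising to ~70% reflectance at 700 nm; biliverdin absorbing in Gaussian
#' bands at 380 and 670 nm (leaving a blue-green window); protoporphyrin
#' with a strong band at 410 nm (Soret) and weaker bands at 540 and
#' 580 nm. Band centres/widths/weights are documented defaults, not fits
#' to literature curves; only the blue-green versus red-brown axis
#' matters for testing.
#'
#' @param baseline_max Reflectance approached at 700 nm (percent).
#' @param baseline_min Reflectance at 300 nm (percent).
#' @param bv_bands,pp_bands Data frames with `center`, `width`, `weight`.
#' @return List of parameters for [pigment_spectrum()].
#' @export
pigment_params <- function(baseline_max = 70, baseline_min = 8,
                           bv_bands = data.frame(center = c(380, 670),
                                                 width = c(35, 45),
                                                 weight = c(1, 0.7)),
                           pp_bands = data.frame(center = c(410, 540, 580),
                                                 width = c(30, 20, 20),
                                                 weight = c(1, 0.35, 0.35))) {
  list(baseline_max = baseline_max, baseline_min = baseline_min,
       bv_bands = bv_bands, pp_bands = pp_bands)
}

.bands_absorbance <- function(g, bands) {
  a <- numeric(length(g))
  for (i in seq_len(nrow(bands)))
    a <- a + bands$weight[i] * exp(-(g - bands$center[i])^2 / (2 * bands$width[i]^2))
  a
}

.pigment_baseline <- function(params) {
  g <- grid_nm()
  params$baseline_min +
    (params$baseline_max - params$baseline_min) * ((g - 300) / 400)^1.8
}

#' Synthetic eggshell reflectance from pigment concentrations
#'
#' Beer-Lambert-style model: `R(lambda) = baseline(lambda) *
#' exp(-c_bv * A_bv(lambda) - c_pp * A_pp(lambda))`. Zero concentrations
#' return the baseline (a pigment-free, long-wavelength-maximal shell);
#' high biliverdin produces a blue-green (MWS-maximal) shell; reflectance
#' is strictly decreasing in each concentration wherever the
#' corresponding absorbance is positive.
#'
#' @param biliverdin,protoporphyrin Nonnegative concentrations
#'   (dimensionless absorbance multipliers).
#' @param params From [pigment_params()].
#' @return Numeric 81-vector (grid spectrum, percent reflectance).
#' @export
pigment_spectrum <- function(biliverdin = 0, protoporphyrin = 0,
                             params = pigment_params()) {
  if (biliverdin < 0 || protoporphyrin < 0)
    stop("pigment concentrations must be nonnegative")
  g <- grid_nm()
  .pigment_baseline(params) *
    exp(-biliverdin * .bands_absorbance(g, params$bv_bands)
        - protoporphyrin * .bands_absorbance(g, params$pp_bands))
}

#' Simulate a balanced nested Gaussian design
#'
#' The scalar engine behind the variance-partition recovery tests: draws
#' independent Gaussian effects at each nested level (family, species,
#' clutch, egg) plus replicate noise, with the requested variance
#' components.
#'
#' @param n Named integer vector of sizes: `family` (number of families),
#'   `species` (per family), `clutch` (per species), `egg` (per clutch),
#'   `replicate` (per egg).
#' @param components Named numeric variances for `family`, `species`,
#'   `clutch`, `egg`, `replicate`.
#' @param mean Grand mean, default 0.
#' @return Data frame with `family`, `species`, `clutch_id`, `egg_id`,
#'   `replicate_idx`, `value`.
#' @export
simulate_nested_design <- function(n = c(family = 10, species = 5, clutch = 3,
                                         egg = 3, replicate = 6),
                                   components = c(family = 25, species = 12.5,
                                                  clutch = 12.5, egg = 25,
                                                  replicate = 25),
                                   mean = 0) {
  stopifnot(all(n >= 1), all(components >= 0))
  d <- expand.grid(replicate_idx = seq_len(n[["replicate"]]),
                   egg = seq_len(n[["egg"]]),
                   clutch = seq_len(n[["clutch"]]),
                   species = seq_len(n[["species"]]),
                   family = seq_len(n[["family"]]))
  fam <- sprintf("F%02d", d$family)
  sp <- paste0(fam, "_s", d$species)
  clu <- paste0(sp, "_c", d$clutch)
  egg <- paste0(clu, "_e", d$egg)
  eff <- function(key, v) {
    u <- unique(key)
    stats::rnorm(length(u), 0, sqrt(v))[match(key, u)]
  }
  value <- mean + eff(fam, components[["family"]]) +
    eff(sp, components[["species"]]) + eff(clu, components[["clutch"]]) +
    eff(egg, components[["egg"]]) +
    stats::rnorm(nrow(d), 0, sqrt(components[["replicate"]]))
  data.frame(family = fam, species = sp, clutch_id = paste0("c", d$clutch),
             egg_id = paste0("e", d$egg), replicate_idx = d$replicate_idx,
             value = value, stringsAsFactors = FALSE)
}

#' Simulate museum-storage clutch pairs with a known drift slope
#'
#' Fixture generator for the storage-effect regression: year gaps are
#' drawn uniformly, the spectral-shape difference follows
#' `intercept + slope * ln(delta_years) + noise`, and luminance
#' differences follow an (optional) slope of their own.
#'
#' @param n Number of species pairs (default 108).
#' @param slope Spectral drift per ln-year (default 0.004).
#' @param intercept Baseline spectral difference (default 0.02).
#' @param noise_sd Residual sd of the spectral difference (default 0.023).
#' @param lum_slope,lum_noise_sd Luminance drift per ln-year and residual
#'   sd (defaults 0 and 5).
#' @param year_range Range of year gaps, default 1 to 170.
#' @return A `storage_pairs`-shaped data frame usable with
#'   [storage_effect_tests()].
#' @export
simulate_storage_pairs <- function(n = 108, slope = 0.004, intercept = 0.02,
                                   noise_sd = 0.023, lum_slope = 0,
                                   lum_noise_sd = 5, year_range = c(1, 170)) {
  dy <- sample(seq(year_range[1], year_range[2]), n, replace = TRUE)
  x <- log(dy)
  lum_old <- stats::rnorm(n, 50, 10)
  dlum <- lum_slope * x + stats::rnorm(n, 0, lum_noise_sd)
  out <- data.frame(
    species = sprintf("sp%03d", seq_len(n)),
    clutch_old = "c1", clutch_new = "c2",
    year_old = 1900L - dy, year_new = 1900L,
    delta_years = dy, lum_old = lum_old, lum_new = lum_old + dlum,
    delta_spectral = intercept + slope * x + stats::rnorm(n, 0, noise_sd),
    delta_luminance = dlum
  )
  class(out) <- c("storage_pairs", "data.frame")
  out
}

#' Configuration for the full synthetic-study generator
#'
#' Defaults emulate the museum study design at a desk-friendly scale: 10
#' families x 5 species x 3 clutches x 3 eggs x 6 replicate spectra,
#' collection years 1825-2002, lambda = 0.7 phylogenetic signal in the
#' pigment traits, variance fractions (replicate 25%, egg 25%, clutch
#' 12.5%, species 12.5%, family 25%) for the flat intensity effects, and
#' a storage drift of 0.004 per ln-year.
#'
#' @param n_families,species_per_family,clutches_per_species,eggs_per_clutch,replicates_per_egg
#'   Design sizes (clutches and eggs capped at 5, replicates default 6).
#' @param variance_fractions Named nonnegative fractions for `replicate`,
#'   `egg`, `clutch`, `species`, `family`; must sum to at most 1.
#' @param effect_total_sd Total sd (percent reflectance) distributed over
#'   the five levels according to `variance_fractions`.
#' @param lambda_true Phylogenetic signal of the species pigment traits.
#' @param bv_range,pp_range Concentration ranges the logistic trait map
#'   squashes into (biliverdin, protoporphyrin).
#' @param pigment_logit_shift Named offsets (`bv`, `pp`) added to the
#'   standardised traits before the logistic squash. The defaults skew
#'   concentrations low, so most species are weakly pigmented
#'   (long-wavelength-maximal) with a blue-green minority, as in real
#'   collections.
#' @param year_range Collection-year range.
#' @param drift_coef Spectral drift per ln-year of specimen age.
#' @param macul_probs Species probabilities of maculation categories 0-2.
#' @param observer_agreement Probability an observer scores an egg at the
#'   species' true category.
#' @param macul_noise Replicate-noise inflation per maculation category
#'   (sd multiplier `1 + macul_noise * score`).
#' @param pigment Parameters from [pigment_params()].
#' @param seed Optional integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_families = 10, species_per_family = 5,
                             clutches_per_species = 3, eggs_per_clutch = 3,
                             replicates_per_egg = 6,
                             variance_fractions = c(replicate = 0.25,
                                                    egg = 0.25, clutch = 0.125,
                                                    species = 0.125,
                                                    family = 0.25),
                             effect_total_sd = 2, lambda_true = 0.7,
                             bv_range = c(0, 6), pp_range = c(0, 2),
                             pigment_logit_shift = c(bv = -2, pp = -1),
                             year_range = c(1825, 2002), drift_coef = 0.004,
                             macul_probs = c(0.37, 0.33, 0.30),
                             observer_agreement = 0.95, macul_noise = 0.5,
                             pigment = pigment_params(), seed = NULL) {
  counts <- c(n_families, species_per_family, clutches_per_species,
              eggs_per_clutch, replicates_per_egg)
  if (any(counts < 1)) stop("all design counts must be positive")
  if (clutches_per_species > 5 || eggs_per_clutch > 5)
    stop("at most 5 clutches per species and 5 eggs per clutch")
  vf <- variance_fractions[c("replicate", "egg", "clutch", "species", "family")]
  if (anyNA(vf) || any(vf < 0) || sum(vf) > 1 + 1e-12)
    stop("variance_fractions must be nonnegative, named, and sum to at most 1")
  structure(list(
    n_families = n_families, species_per_family = species_per_family,
    clutches_per_species = clutches_per_species,
    eggs_per_clutch = eggs_per_clutch,
    replicates_per_egg = replicates_per_egg, variance_fractions = vf,
    effect_total_sd = effect_total_sd, lambda_true = lambda_true,
    bv_range = bv_range, pp_range = pp_range,
    pigment_logit_shift = pigment_logit_shift, year_range = year_range,
    drift_coef = drift_coef, macul_probs = macul_probs,
    observer_agreement = observer_agreement, macul_noise = macul_noise,
    pigment = pigment, seed = seed
  ), class = "generator_config")
}

.family_tree <- function(cfg, family_names, species_names) {
  nf <- cfg$n_families; k <- cfg$species_per_family
  if (nf == 1) {
    tr <- if (k >= 2) simulate_tree(k, labels = species_names[[1]]) else
      stop("need at least 2 species in total")
    return(tr)
  }
  tree <- simulate_tree(nf, labels = family_names)
  if (k == 1) {
    tree$tip.label <- vapply(species_names, `[`, "", 1L)
    return(tree)
  }
  # graft species subtrees onto the family backbone by composing Newick
  # strings (robust for any backbone size); each subtree is rescaled to
  # 40% of its family's terminal branch so the result stays ultrametric
  nwk <- sub(";\\s*$", "", ape::write.tree(tree))
  for (f in seq_len(nf)) {
    tip <- which(tree$tip.label == family_names[f])
    tiplen <- tree$edge.length[tree$edge[, 2] == tip]
    sub <- simulate_tree(k, labels = species_names[[f]])
    target <- 0.4 * tiplen
    sub$edge.length <- sub$edge.length * target /
      max(ape::node.depth.edgelength(sub))
    snk <- sprintf("%s:%.12g", sub(";\\s*$", "", ape::write.tree(sub)),
                   tiplen - target)
    nwk <- sub(paste0(family_names[f], ":[0-9.eE+-]+"), snk, nwk)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

.squash <- function(z, range) range[1] + (range[2] - range[1]) * stats::plogis(z)

#' Generate a complete synthetic eggshell-colour study
#'
#' Builds a phylogeny with monophyletic families (a pure-birth family
#' backbone whose tips carry pure-birth species subtrees, rescaled to unit
#' depth), a nested taxonomy (genera of 2 species, tribes of 2 genera,
#' subfamilies of 2 tribes within each family), species pigment
#' concentrations driven by lambda-structured traits squashed
#' logistically into the configured ranges, nested spectra (flat additive
#' intensity effects at family/species/clutch/egg level sized by the
#' configured variance fractions, plus per-wavelength replicate noise,
#' clamped to \[0, baseline\]), clutch collection years with ln(age)
#' spectral drift, and two-observer maculation scores. The ground truth
#' (lambda, fractions, concentrations, drift) is stored alongside.
#'
#' @param cfg A [generator_config()].
#' @return An `eggshell_dataset`: `tree`, `taxonomy`, `spectra`
#'   (a `spectra_set`), `years`, `maculation`, `truth`, `config`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nf <- cfg$n_families; k <- cfg$species_per_family
  family_names <- sprintf("F%02d", seq_len(nf))
  species_names <- lapply(seq_len(nf), function(f)
    sprintf("%s_sp%d", family_names[f], seq_len(k)))
  tree <- .family_tree(cfg, family_names, species_names)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))

  taxonomy <- do.call(rbind, lapply(seq_len(nf), function(f) {
    i <- seq_len(k)
    data.frame(species = species_names[[f]],
               genus = sprintf("%s_g%d", family_names[f], (i + 1) %/% 2),
               tribe = sprintf("%s_t%d", family_names[f], (i + 3) %/% 4),
               subfamily = sprintf("%s_sf%d", family_names[f], (i + 7) %/% 8),
               family = family_names[f], stringsAsFactors = FALSE)
  }))
  validate_taxonomy(taxonomy)

  trait_bv <- simulate_traits(tree, 1, cfg$lambda_true)
  trait_pp <- simulate_traits(tree, 1, cfg$lambda_true)
  shift <- cfg$pigment_logit_shift %||% c(bv = 0, pp = 0)
  conc <- data.frame(species = names(trait_bv),
                     biliverdin = .squash(trait_bv + shift[["bv"]],
                                          cfg$bv_range),
                     protoporphyrin = .squash(trait_pp + shift[["pp"]],
                                              cfg$pp_range))
  base <- vapply(seq_len(nrow(conc)), function(i)
    pigment_spectrum(conc$biliverdin[i], conc$protoporphyrin[i], cfg$pigment),
    numeric(.N_GRID))
  colnames(base) <- conc$species
  baseline <- .pigment_baseline(cfg$pigment)

  s_lev <- cfg$effect_total_sd * sqrt(cfg$variance_fractions)
  fam_eff <- stats::setNames(stats::rnorm(nf, 0, s_lev[["family"]]), family_names)
  sp_eff <- stats::setNames(stats::rnorm(nf * k, 0, s_lev[["species"]]),
                            unlist(species_names))

  macul_cat <- stats::setNames(
    sample(0:2, nf * k, replace = TRUE, prob = cfg$macul_probs),
    unlist(species_names))

  nc <- cfg$clutches_per_species; ne <- cfg$eggs_per_clutch
  nr <- cfg$replicates_per_egg
  cols <- list(); meta_rows <- list(); years_rows <- list(); mac_rows <- list()
  for (sp in unlist(species_names)) {
    fam <- taxonomy$family[taxonomy$species == sp]
    sp_base <- base[, sp] + fam_eff[[fam]] + sp_eff[[sp]]
    rep_sd <- s_lev[["replicate"]] * (1 + cfg$macul_noise * macul_cat[[sp]])
    for (ci in seq_len(nc)) {
      year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), 1)
      age <- cfg$year_range[2] - year
      drift <- 1 + cfg$drift_coef * log1p(age) *
        exp(-(grid_nm() - 400)^2 / (2 * 50^2))
      cl_base <- sp_base * drift + stats::rnorm(1, 0, s_lev[["clutch"]])
      years_rows[[length(years_rows) + 1]] <-
        data.frame(species = sp, clutch_id = paste0("c", ci),
                   collection_year = year)
      for (ei in seq_len(ne)) {
        egg_base <- cl_base + stats::rnorm(1, 0, s_lev[["egg"]])
        sa <- .observer_score(macul_cat[[sp]], cfg$observer_agreement)
        sb <- .observer_score(macul_cat[[sp]], cfg$observer_agreement)
        mac_rows[[length(mac_rows) + 1]] <-
          data.frame(species = sp, clutch_id = paste0("c", ci),
                     egg_id = paste0("e", ei), score_a = sa, score_b = sb)
        for (ri in seq_len(nr)) {
          obs <- egg_base + stats::rnorm(.N_GRID, 0, rep_sd)
          cols[[length(cols) + 1]] <- pmin(pmax(obs, 0), baseline)
          meta_rows[[length(meta_rows) + 1]] <-
            data.frame(family = fam, species = sp, clutch_id = paste0("c", ci),
                       egg_id = paste0("e", ei), replicate_idx = ri,
                       collection_year = year)
        }
      }
    }
  }
  spectra <- spectra_set(do.call(cbind, cols), do.call(rbind, meta_rows))
  structure(list(
    tree = tree, taxonomy = taxonomy, spectra = spectra,
    years = do.call(rbind, years_rows), maculation = do.call(rbind, mac_rows),
    truth = list(lambda_true = cfg$lambda_true,
                 variance_fractions = cfg$variance_fractions,
                 effect_total_sd = cfg$effect_total_sd,
                 drift_coef = cfg$drift_coef, concentrations = conc,
                 maculation_categories = macul_cat, seed = cfg$seed),
    config = cfg
  ), class = "eggshell_dataset")
}

.observer_score <- function(true, agreement) {
  if (stats::runif(1) < agreement) return(true)
  max(0, min(2, true + sample(c(-1, 1), 1)))
}

#' @export
print.eggshell_dataset <- function(x, ...) {
  cat("Synthetic eggshell study: ", nrow(x$taxonomy), " species in ",
      length(unique(x$taxonomy$family)), " families; ",
      ncol(x$spectra$R), " spectra\n", sep = "")
  cat("  lambda_true = ", x$truth$lambda_true, ", drift = ",
      x$truth$drift_coef, " per ln-year\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to interchange files
#'
#' Emits `spectra.csv` (the long spectra dialect), `tree.nwk`,
#' `taxonomy.csv`, `clutch_years.csv`, `maculation.csv` and
#' `ground_truth.json`.
#'
#' @param ds An `eggshell_dataset`.
#' @param dir Output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(spectra = file.path(dir, "spectra.csv"),
         tree = file.path(dir, "tree.nwk"),
         taxonomy = file.path(dir, "taxonomy.csv"),
         years = file.path(dir, "clutch_years.csv"),
         maculation = file.path(dir, "maculation.csv"),
         truth = file.path(dir, "ground_truth.json"))
  write_spectra_table(ds$spectra, p[["spectra"]])
  write_newick_tree(ds$tree, p[["tree"]])
  utils::write.csv(ds$taxonomy, p[["taxonomy"]], row.names = FALSE)
  utils::write.csv(ds$years, p[["years"]], row.names = FALSE)
  utils::write.csv(ds$maculation, p[["maculation"]], row.names = FALSE)
  truth <- ds$truth
  truth$maculation_categories <- as.list(truth$maculation_categories)
  jsonlite::write_json(truth, p[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
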