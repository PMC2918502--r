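test_that("pure-birth tree simulation is reproducible and well-formed", {
  set.seed(50)
  cherry <- simulate_tree(2)
  expect_equal(ape::Ntip(cherry), 2L)
  expect_true(all(cherry$edge.length > 0))

  set.seed(51)
  a <- ape::write.tree(simulate_tree(20))
  set.seed(51)
  b <- ape::write.tree(simulate_tree(20))
  expect_identical(a, b)

  set.seed(52)
  depth <- function(n) max(ape::node.depth.edgelength(simulate_tree(n)))
  d_small <- mean(replicate(30, depth(5)))
  d_large <- mean(replicate(30, depth(60)))
  expect_gt(d_large, d_small)
  expect_true(ape::is.ultrametric(simulate_tree(15), tol = 1e-8))
})

test_that("lambda-transformed trait simulation has the intended covariance structure", {
  set.seed(53)
  tr <- simulate_tree(5)
  # lambda = 0: tips are independent across draws
  draws0 <- t(replicate(400, simulate_traits(tr, 1, 0)))
  C0 <- cov(draws0)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.25)
  expect_equal(mean(diag(C0)), mean(diag(phylo_covariance(tr))),
               tolerance = 0.2)

  # lambda = 1 on a long-stemmed cherry: the two tips are highly correlated
  cherry <- read_newick_tree(text = "(A:0.05,B:0.05):0;")
  cherry$root.edge <- NULL
  stem <- read_newick_tree(text = "((A:0.05,B:0.05):0.95,C:1);")
  draws1 <- t(replicate(400, simulate_traits(stem, 1, 1)))
  expect_gt(cor(draws1[, "A"], draws1[, "B"]), 0.8)

  expect_error(simulate_traits(tr, 0, 1), "positive")
  expect_error(simulate_traits(tr, 1, 1.2), "0, 1")
})

test_that("the pigment spectrum model produces the blue-green/red-brown axis", {
  base <- pigment_spectrum(0, 0)
  expect_equal(base, ovocolor:::.pigment_baseline(pigment_params()),
               tolerance = 1e-12)
  expect_equal(classify_max_region(base), "LWS")

  blue <- pigment_spectrum(6, 0)
  expect_equal(classify_max_region(blue), "MWS")
  peak <- grid_nm()[which.max(blue)]
  expect_gte(peak, 475); expect_lt(peak, 575)

  # reflectance strictly decreasing in each concentration where the
  # absorbance is positive (it is everywhere for Gaussian bands)
  s1 <- pigment_spectrum(1, 0.5)
  s2 <- pigment_spectrum(1.5, 0.5)
  s3 <- pigment_spectrum(1, 0.9)
  expect_true(all(s2 < s1))
  expect_true(all(s3 < s1))
  expect_error(pigment_spectrum(-1, 0), "nonnegative")
})

test_that("generated datasets are deterministic under a seed and pass reader validation", {
  cfg <- generator_config(n_families = 3, species_per_family = 2,
                          clutches_per_species = 2, eggs_per_clutch = 2,
                          replicates_per_egg = 2, seed = 54)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$spectra$R, d2$spectra$R)
  expect_identical(ape::write.tree(d1$tree), ape::write.tree(d2$tree))
  expect_identical(d1$years, d2$years)

  dir <- withr::local_tempdir()
  paths <- write_dataset(d1, dir)
  expect_true(all(file.exists(paths)))
  raw <- read_spectra_table(paths[["spectra"]])
  expect_length(raw, ncol(d1$spectra$R))
  expect_true(is_on_grid(raw))
  tr <- read_newick_tree(paths[["tree"]])
  expect_equal(sort(tr$tip.label), sort(d1$taxonomy$species))
  expect_silent(validate_taxonomy(read.csv(paths[["taxonomy"]])))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$lambda_true, 0.7)
})

test_that("generated spectra respect the nonnegativity and baseline bounds", {
  ds <- generate_dataset(generator_config(n_families = 3,
                                          species_per_family = 3,
                                          clutches_per_species = 2,
                                          eggs_per_clutch = 2,
                                          replicates_per_egg = 3, seed = 55))
  expect_true(all(ds$spectra$R >= 0))
  base <- ovocolor:::.pigment_baseline(ds$config$pigment)
  expect_true(all(ds$spectra$R <= base + 1e-9))
})

test_that("a generator with no between-level effects yields replicate-dominated variance", {
  cfg <- generator_config(
    n_families = 3, species_per_family = 3, clutches_per_species = 2,
    eggs_per_clutch = 2, replicates_per_egg = 4,
    variance_fractions = c(replicate = 1, egg = 0, clutch = 0, species = 0,
                           family = 0),
    bv_range = c(1, 1), pp_range = c(0.5, 0.5),  # no pigment variation
    drift_coef = 0, macul_noise = 0, seed = 56)
  ds <- generate_dataset(cfg)
  vp <- variance_profile(ds$spectra)
  expect_gt(mean(vp$percentages[, "replicate"]), 85)
})

test_that("realized variance fractions track the configured fractions", {
  # intensity-only regime: pigment and maculation effects silenced so the
  # additive level effects are the only variance sources
  set.seed(57)
  pct <- replicate(8, {
    cfg <- generator_config(
      n_families = 8, species_per_family = 4, clutches_per_species = 3,
      eggs_per_clutch = 3, replicates_per_egg = 6,
      bv_range = c(1, 1), pp_range = c(0.5, 0.5),
      drift_coef = 0, macul_noise = 0)
    ds <- generate_dataset(cfg)
    vp <- variance_profile(ds$spectra)
    colMeans(vp$percentages)
  })
  truth <- c(family = 25, species = 12.5, clutch = 12.5, egg = 25,
             replicate = 25)
  expect_lt(max(abs(rowMeans(pct) - truth[colnames(t(pct))])), 5)
})

test_that("immaculate eggs yield higher replicate SNR than maculated eggs", {
  set.seed(58)
  ds <- generate_dataset(generator_config(n_families = 6,
                                          species_per_family = 3,
                                          clutches_per_species = 1,
                                          eggs_per_clutch = 1,
                                          replicates_per_egg = 6,
                                          macul_noise = 1.5))
  cat0 <- ds$truth$maculation_categories
  m <- ds$spectra$meta
  snr_by_cat <- sapply(c(0, 2), function(k) {
    sp_k <- names(cat0)[cat0 == k]
    if (!length(sp_k)) return(NA_real_)
    mean(sapply(sp_k, function(sp) {
      reps <- ds$spectra$R[, m$species == sp, drop = FALSE]
      mean(snr_profile(reps)$snr, na.rm = TRUE)
    }))
  })
  skip_if(anyNA(snr_by_cat), "draw lacked one of the categories")
  expect_gt(snr_by_cat[1], snr_by_cat[2])
})

test_that("the end-to-end pipeline recovers the generator's phylogenetic signal", {
  # 200 species, pigment-driven chromatic signal with a small
  # non-phylogenetic intensity nuisance: the spectra -> loci -> species
  # means -> ML chain must not distort lambda. (Larger iid species-level
  # intensity effects attenuate lambda-hat, as ML should; see the methods
  # vignette.)
  set.seed(59)
  err <- replicate(5, {
    ds <- generate_dataset(generator_config(n_families = 40,
                                            species_per_family = 5,
                                            clutches_per_species = 1,
                                            eggs_per_clutch = 1,
                                            replicates_per_egg = 2,
                                            lambda_true = 0.7,
                                            effect_total_sd = 0.2,
                                            pigment_logit_shift = c(bv = 0,
                                                                    pp = 0)))
    loci <- compute_loci(ds$spectra)
    z <- tapply(loci$Z, loci$species, mean)
    fit_lambda(z, ds$tree)$lambda - 0.7
  })
  expect_lt(abs(mean(err)), 0.15)
})
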