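toy_taxonomy <- function(species, genus, tribe = genus, subfamily = tribe,
                         family = subfamily) {
  data.frame(species = species, genus = genus, tribe = tribe,
             subfamily = subfamily, family = family,
             stringsAsFactors = FALSE)
}

test_that("sister pairing is shallowest-first, deterministic, and never reuses a species", {
  tax <- toy_taxonomy(c("a1", "a2", "b1", "b2"),
                      genus = c("gA", "gA", "gB", "gB"), family = "F")
  p <- extract_sister_pairs(tax)
  expect_equal(nrow(p), 2L)
  expect_true(all(p$level == "congeneric"))
  expect_equal(sort(c(p$species_a, p$species_b)), sort(tax$species))

  # 7 species across 2 families; compare the level counts with an
  # exhaustive search maximising shallow pairs first
  tax7 <- data.frame(
    species = c("s1", "s2", "s3", "s4", "s5", "s6", "s7"),
    genus = c("g1", "g1", "g2", "g3", "g4", "g5", "g6"),
    tribe = c("t1", "t1", "t1", "t2", "t2", "t3", "t4"),
    subfamily = c("u1", "u1", "u1", "u1", "u1", "u2", "u3"),
    family = c("F1", "F1", "F1", "F1", "F1", "F1", "F2"))
  p7 <- extract_sister_pairs(tax7)
  counts <- table(p7$level)
  expect_equal(sum(counts), 3L)  # floor(7/2)
  expect_length(attr(p7, "unpaired"), 1L)
  oracle <- best_pairing_counts(tax7)
  expect_equal(as.numeric(counts), unname(oracle))
  # determinism
  expect_identical(p7, extract_sister_pairs(tax7[sample(7), ]))

  expect_error(validate_taxonomy(
    toy_taxonomy(c("x", "y"), genus = c("g", "g"), family = c("F1", "F2"))),
    "not nested")
})

test_that("pair counts always sum to floor(n/2) on generated taxonomies", {
  set.seed(40)
  for (i in 1:5) {
    ds <- generate_dataset(generator_config(
      n_families = sample(2:4, 1), species_per_family = sample(2:5, 1),
      clutches_per_species = 1, eggs_per_clutch = 1, replicates_per_egg = 1,
      seed = 40 + i))
    p <- extract_sister_pairs(ds$taxonomy)
    expect_equal(nrow(p), nrow(ds$taxonomy) %/% 2)
    expect_false(anyDuplicated(c(p$species_a, p$species_b)) > 0)
  }
})

test_that("the sister-pair ANOVA matches hand-computed mean squares", {
  # 3 groups of sizes 3/3/2 with known values
  pairs <- data.frame(
    level = factor(rep(c("congeneric", "tribe", "family"), c(3, 3, 2))),
    spectral_difference = c(1, 2, 3, 4, 5, 6, 7, 9))
  a <- sister_pair_anova(pairs)
  gm <- mean(pairs$spectral_difference)
  means <- tapply(pairs$spectral_difference, pairs$level, mean)
  ns <- tapply(pairs$spectral_difference, pairs$level, length)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((pairs$spectral_difference -
                 means[as.character(pairs$level)])^2)
  F_hand <- (ss_b / 2) / (ss_w / 5)
  expect_equal(a$F, F_hand, tolerance = 1e-12)
  expect_equal(c(a$df1, a$df2), c(2, 5))
  expect_equal(a$by_level$n, c(3, 2, 3))  # factor order: congeneric, family, tribe

  # all-equal differences: F defined as 0
  pairs$spectral_difference <- 2
  a0 <- sister_pair_anova(pairs)
  expect_equal(a0$F, 0)
  expect_equal(a0$p, 1)

  # single-pair levels are dropped with a warning
  pairs2 <- data.frame(level = factor(c("congeneric", "congeneric", "tribe",
                                        "tribe", "family")),
                       spectral_difference = c(1, 2, 3, 4, 99))
  expect_warning(a2 <- sister_pair_anova(pairs2), "single pair")
  expect_equal(c(a2$df1, a2$df2), c(1, 2))
})

test_that("storage pairs pick the widest year gap and feed the reported tests", {
  # one species, three clutches measured as constant spectra
  x <- toy_spectra_set(
    values = c(10, 20, 42),
    family = "F", species = "sp",
    clutch = c("c1", "c2", "c3"), egg = "e1", replicate = 1L,
    year = c(1850L, 1900L, 1990L))
  sp <- storage_pairs(x)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$clutch_old, "c1")
  expect_equal(sp$clutch_new, "c3")
  expect_equal(sp$delta_years, 140L)
  expect_equal(sp$delta_luminance, luminance(rep(42, 81)) - luminance(rep(10, 81)))
  expect_equal(sp$delta_spectral, 0)  # constant spectra share a shape

  # all-zero deltas: t = 0, slopes = 0
  z <- data.frame(lum_old = rep(5, 4), lum_new = rep(5, 4),
                  delta_luminance = 0, delta_spectral = 0,
                  delta_years = c(2, 5, 9, 30))
  tz <- storage_effect_tests(z)
  expect_equal(tz$t_test$t, 0)
  expect_equal(tz$spectral_fit$estimate, 0)

  # 4-point closed-form least squares
  d4 <- data.frame(lum_old = c(1, 1, 1, 1), lum_new = c(2, 3, 1, 5),
                   delta_years = c(exp(1), exp(2), exp(3), exp(4)))
  d4$delta_luminance <- d4$lum_new - d4$lum_old
  d4$delta_spectral <- c(0.01, 0.02, 0.02, 0.05)
  t4 <- storage_effect_tests(d4)
  x4 <- 1:4
  bhat <- cov(x4, d4$delta_spectral) / var(x4)
  expect_equal(t4$spectral_fit$estimate, bhat, tolerance = 1e-12)
  res <- d4$delta_spectral - (mean(d4$delta_spectral) + bhat * (x4 - mean(x4)))
  se <- sqrt(sum(res^2) / 2 / sum((x4 - mean(x4))^2))
  expect_equal(t4$spectral_fit$se, se, tolerance = 1e-12)

  d4$delta_years[1] <- 0
  expect_warning(storage_effect_tests(d4), "zero year separation")
})

test_that("the storage drift slope is recovered from the pair generator", {
  set.seed(41)
  est <- replicate(20, {
    p <- simulate_storage_pairs(n = 108, slope = 0.004)
    storage_effect_tests(p)$spectral_fit$estimate
  })
  expect_lt(abs(mean(est) - 0.004), 0.002)
})

test_that("sampling randomization is reproducible and matches exhaustive enumeration", {
  pool <- c(1, 3, 4, 7, 10, 15)
  r1 <- sampling_randomization(pool, focal = pool, n_draw = 3, reps = 2000,
                               seed = 99)
  r2 <- sampling_randomization(pool, focal = pool, n_draw = 3, reps = 2000,
                               seed = 99)
  expect_identical(r1$medians, r2$medians)
  expect_true(r1$inside)

  # all C(6,3) = 20 subsets
  all_meds <- apply(combn(6, 3), 2, function(i) median(pool[i]))
  expect_true(all(r1$medians %in% all_meds))
  expect_equal(sort(unique(r1$medians)), sort(unique(all_meds)))
  expect_gte(r1$lower, min(all_meds))
  expect_lte(r1$upper, max(all_meds))

  const <- sampling_randomization(rep(4, 10), focal = rep(4, 3), reps = 500,
                                  seed = 1)
  expect_equal(c(const$lower, const$upper), c(4, 4))
  expect_error(sampling_randomization(1:5, 1:2, n_draw = 9), "pool size")
  expect_error(sampling_randomization(1:5, 1:2, n_draw = 2, reps = 10),
               "at least 100")
})

test_that("maculation repeatability reproduces hand-computed correlations", {
  s <- data.frame(species = rep(c("a", "b", "c"), each = 2),
                  egg_id = rep(c("e1", "e2"), 3),
                  score_a = c(0, 0, 1, 1, 2, 2))
  s$score_b <- s$score_a
  r <- maculation_repeatability(s)
  expect_equal(r$r, 1)
  expect_equal(r$species_scores$score, c(0, 1, 2))

  s$score_b <- 2 - s$score_a
  expect_equal(maculation_repeatability(s)$r, -1)

  set.seed(42)
  s5 <- data.frame(species = rep(letters[1:5], each = 3),
                   egg_id = rep(c("e1", "e2", "e3"), 5),
                   score_a = sample(0:2, 15, replace = TRUE),
                   score_b = sample(0:2, 15, replace = TRUE))
  r5 <- maculation_repeatability(s5)
  ma <- tapply(s5$score_a, s5$species, mean)
  mb <- tapply(s5$score_b, s5$species, mean)
  r_hand <- sum((ma - mean(ma)) * (mb - mean(mb))) /
    sqrt(sum((ma - mean(ma))^2) * sum((mb - mean(mb))^2))
  expect_equal(r5$r, r_hand, tolerance = 1e-12)

  s5$score_a[1] <- 3
  expect_error(maculation_repeatability(s5), "0, 1 or 2")
})
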