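test_that("zero-noise configurations give identical replicates and are deterministic", {
  cfg <- quiet_config(seed = 11)
  tab <- generate_metabolite_table(cfg)
  expect_equal(nrow(tab), 4 * 2 * 3)
  conc <- as.matrix(tab[, cfg$metabolites])
  for (key in unique(paste(tab$cultivar, tab$vintage))) {
    rows <- conc[paste(tab$cultivar, tab$vintage) == key, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(v) diff(range(v)))), 0)
  }
  # determinism: identical seed => bit-identical tables
  cfg2 <- sim_config(seed = 42)
  expect_identical(generate_metabolite_table(cfg2), generate_metabolite_table(cfg2))
  t2 <- generate_metabolite_table(cfg2)
  expect_identical(generate_responses(t2, cfg2), generate_responses(t2, cfg2))
  fm <- generate_feature_matrix(t2, cfg2)
  expect_identical(fm$values, generate_feature_matrix(t2, cfg2)$values)
})

test_that("default cultivar means fall in the published concentration ranges", {
  cfg <- sim_config(seed = 5)
  m <- cfg$cultivar_means
  cls <- metabolite_class(colnames(m))
  ac_total <- rowSums(m[, cls == "anthocyanin", drop = FALSE])
  expect_true(all(ac_total >= 14 & ac_total <= 114))
  asc <- m[, cls == "ascorbic_acid"]
  expect_true(all(asc >= 7 & asc <= 15))
  hca <- rowSums(m[, cls == "hydroxycinnamic_acid", drop = FALSE])
  expect_true(all(hca <= 65))
  q <- rowSums(m[, cls == "quercetin", drop = FALSE])
  expect_true(all(q <= 7))
  expect_true(all(m >= 0))
})

test_that("replicate noise is mean-one: large-n sample means track configured means", {
  means <- matrix(c(50, 10), 1, 2, dimnames = list("cv01", c("a", "b")))
  cfg <- sim_config(n_cultivars = 1, n_vintages = 1, n_replicates = 10000,
                    cultivar_means = means, metabolites = c("a", "b"),
                    vintage_shift_sd = 0, replicate_cv = 0.1, seed = 8)
  tab <- generate_metabolite_table(cfg)
  expect_equal(mean(tab$a), 50, tolerance = 0.01)
  expect_equal(mean(tab$b), 10, tolerance = 0.01)
})

test_that("responses follow the additive + interaction model exactly at zero noise", {
  # 12 cultivars so the 7 metabolite columns are full rank at zero noise
  cfg <- quiet_config(n_cultivars = 12, seed = 3)
  tab <- generate_metabolite_table(cfg)
  # all coefficients zero -> intercept everywhere
  cfg0 <- quiet_config(n_cultivars = 12, seed = 3,
                       response_coefficients = setNames(rep(0, 7), cfg$metabolites),
                       response_intercept = 4.5)
  expect_equal(generate_responses(tab, cfg0)$teac, rep(4.5, nrow(tab)))
  # purely additive, zero noise -> OLS recovers beta to machine precision
  r <- generate_responses(tab, cfg)
  conc <- as.matrix(tab[, cfg$metabolites])
  fit <- lm(r$teac ~ conc)
  expect_equal(unname(coef(fit)[-1]), unname(cfg$response_coefficients),
               tolerance = 1e-9)
  # a positive interaction exceeds the additive prediction wherever both
  # partners are present
  cfgs <- quiet_config(n_cultivars = 12, seed = 3, synergy_terms = list(
    list(i = "cyanidin_3_rutinoside", j = "ascorbic_acid", weight = 0.01)))
  rs <- generate_responses(tab, cfgs)
  both <- conc[, "cyanidin_3_rutinoside"] > 0 & conc[, "ascorbic_acid"] > 0
  expect_true(all(rs$teac[both] > r$teac[both]))
  expect_equal(rs$teac[!both], r$teac[!both])
})

test_that("response coefficients must cover the table's metabolites", {
  cfg <- quiet_config(seed = 3)
  tab <- generate_metabolite_table(cfg)
  cfg$response_coefficients <- cfg$response_coefficients[-1]
  expect_error(generate_responses(tab, cfg), "coefficients missing")
})

test_that("feature expansion has exact isotope ratios and recoverable intensity factors", {
  means <- matrix(30, 1, 1, dimnames = list("cv01", "a"))
  cfg <- sim_config(n_cultivars = 1, n_vintages = 1, n_replicates = 6,
                    cultivar_means = means, metabolites = "a",
                    vintage_shift_sd = 0, replicate_cv = 0.2,
                    n_noise_features = 0, isotope_fraction = 0.1,
                    adduct_fraction = 0, feature_noise_cv = 0, seed = 2)
  fm <- generate_feature_matrix(generate_metabolite_table(cfg), cfg)
  expect_equal(ncol(fm$values), 2L)
  expect_equal(unname(fm$values[, 1] / fm$values[, 2]), rep(10, 6))

  # injected per-sample intensity factors are recovered by normalization
  # (most features uninformative and stable, as the method assumes)
  cfg2 <- sim_config(n_cultivars = 6, n_vintages = 2, n_replicates = 3,
                     replicate_cv = 0.1, intensity_factor_sd = 0.4,
                     n_noise_features = 300, noise_feature_cv = 0.02, seed = 9)
  fm2 <- generate_feature_matrix(generate_metabolite_table(cfg2), cfg2)
  nz <- median_fold_change_normalize(fm2)
  est <- nz$normalization_factors / median(nz$normalization_factors)
  truth <- fm2$intensity_factors / median(fm2$intensity_factors)
  expect_equal(unname(est), unname(truth), tolerance = 0.01)
})

test_that("noise features show no cultivar effect (one-way ANOVA F near 1)", {
  fstats <- c()
  for (s in 1:6) {
    cfg <- sim_config(n_cultivars = 6, n_vintages = 1, n_replicates = 4,
                      replicate_cv = 0.1, n_noise_features = 15, seed = s)
    tab <- generate_metabolite_table(cfg)
    fm <- generate_feature_matrix(tab, cfg)
    noise_cols <- grep("^N", colnames(fm$values))
    g <- factor(tab$cultivar)
    fstats <- c(fstats, vapply(noise_cols, function(j) {
      a <- anova(lm(log(fm$values[, j]) ~ g))
      a$`F value`[1]
    }, numeric(1)))
  }
  expect_gt(mean(fstats), 0.7)
  expect_lt(mean(fstats), 1.4)
})

test_that("cultivar structure dominates vintage structure in PCA of the features", {
  cfg <- sim_config(seed = 21)
  tab <- generate_metabolite_table(cfg)
  fm <- generate_feature_matrix(tab, cfg)
  nz <- median_fold_change_normalize(fm)
  mm <- log_mean_center(nz$values)
  pc <- pca_matrix(mm$X, 4)
  sil_cultivar <- mean_silhouette(pc$scores, tab$cultivar)
  sil_vintage <- mean_silhouette(pc$scores, tab$vintage)
  expect_gt(sil_cultivar, sil_vintage)
})

test_that("simulated plates invert through the calibration module", {
  curve <- fit_standard_curve(data.frame(concentration = seq(0, 1, 0.25),
                                         signal = 0.04 + 0.8 * seq(0, 1, 0.25)),
                              "trolox", 593)
  prot <- extraction_protocol()
  teac <- c(s1 = 12, s2 = 25, s3 = 0)
  plate <- simulate_assay_plate(teac, curve, prot, noise_sd = 0, seed = 4)
  for (id in names(teac)) {
    abs_ <- plate$absorbance[plate$sample_id == id]
    got <- teac_from_absorbance(abs_, curve, prot, sample_id = id)
    expect_equal(got$teac, unname(teac[id]), tolerance = 1e-10)
  }
  # zero TEAC -> absorbance equals the curve intercept
  expect_equal(plate$absorbance[plate$sample_id == "s3"], rep(0.04, 3))
  expect_error(simulate_assay_plate(c(a = -1), curve, prot), "non-negative")
})

test_that("noisy plate recovery is unbiased and matches delta-method error propagation", {
  curve <- fit_standard_curve(data.frame(concentration = seq(0, 1, 0.25),
                                         signal = 0.05 + 0.9 * seq(0, 1, 0.25)),
                              "trolox", 593)
  prot <- extraction_protocol()
  truth <- 18
  noise_sd <- 0.005
  est <- vapply(1:1000, function(s) {
    plate <- simulate_assay_plate(c(s1 = truth), curve, prot,
                                  n_wells = 3, noise_sd = noise_sd, seed = s)
    abs_ <- plate$absorbance[plate$well_type == "sample"]
    teac_from_absorbance(abs_, curve, prot)$teac
  }, numeric(1))
  expect_equal(mean(est), truth, tolerance = 0.01)
  scale <- prot$solvent_volumes * prot$dilution_factor
  expected_sd <- noise_sd / curve$slope * scale / sqrt(3)
  expect_equal(sd(est), expected_sd, tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cultivars = 0), "positive integer")
  expect_error(sim_config(replicate_cv = -1), ">= 0")
  expect_error(sim_config(n_cultivars = 3,
                          cultivar_means = matrix(1, 2, 7)), "one row per cultivar")
})
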