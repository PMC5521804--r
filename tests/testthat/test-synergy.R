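test_that("additive expectation is a weighted sum of component activities", {
  expect_equal(expected_additive_teac(data.frame()), 0)
  one <- data.frame(compound = "cyr", concentration = 2, unit_activity = 0.1)
  expect_equal(expected_additive_teac(one), 0.2)
  three <- data.frame(compound = c("a", "b", "c"),
                      concentration = c(2, 5, 1),
                      unit_activity = c(0.1, 0.02, 0.5))
  expect_equal(expected_additive_teac(three), 0.2 + 0.1 + 0.5)
  three$unit_activity[2] <- NA
  expect_error(expected_additive_teac(three), "schema error")
})

test_that("depletion assessment classifies exact cases correctly", {
  # exact additivity at zero spread
  a <- assess_depletion(tr(c(10, 10)), tr(c(7, 7)), tr(c(3, 3)), seed = 1)
  expect_equal(a$synergy_index, 0)
  expect_equal(a$classification, "additive")
  expect_equal(a$ci, c(0, 0))
  # loss twice the component: synergistic
  b <- assess_depletion(tr(c(10, 10.01, 9.99)), tr(c(4, 4.01, 3.99)),
                        tr(c(3, 3.01, 2.99)), seed = 1)
  expect_equal(b$synergy_index, 3, tolerance = 1e-6)
  expect_equal(b$classification, "synergistic")
  expect_equal(b$interaction_ratio, 2, tolerance = 1e-3)
  # loss below the component: antagonistic
  d <- assess_depletion(tr(c(10, 10.01, 9.99)), tr(c(9, 9.01, 8.99)),
                        tr(c(3, 3.01, 2.99)), seed = 1)
  expect_equal(d$classification, "antagonistic")
  expect_error(assess_depletion(tr(10), tr(c(7, 7)), tr(c(3, 3))),
               "insufficient replication")
})

test_that("bootstrap interval matches a high-replication brute-force recomputation", {
  full <- tr(c(9.5, 10, 10.5)); dep <- tr(c(6.5, 7, 7.5)); comp <- tr(c(2.5, 3, 3.5))
  a <- assess_depletion(full, dep, comp, n_boot = 200000, seed = 3)
  # independent recomputation of the same t-bootstrap definition
  set.seed(99)
  v <- c(var(c(9.5, 10, 10.5)), var(c(6.5, 7, 7.5)), var(c(2.5, 3, 3.5))) / 3
  se <- sqrt(sum(v))
  df <- sum(v)^2 / sum(v^2 / 2)
  draws <- (10 - 7 - 3) + se * rt(1e6, df)
  ci <- unname(quantile(draws, c(0.025, 0.975)))
  expect_equal(a$ci, ci, tolerance = 0.02)
  expect_equal(a$synergy_index, 0)
})

test_that("index antisymmetry under exchanging the full and depleted roles", {
  full <- tr(c(10, 10)); dep <- tr(c(6, 6)); comp <- tr(c(3, 3))
  fwd <- assess_depletion(full, dep, comp, seed = 1)
  rev <- assess_depletion(dep, full, comp, seed = 1)
  # (D - F) - C = -[(F - D) - C] - 2C; with the component's own activity
  # removed from both, the residual interaction terms are exact negatives
  expect_equal(fwd$synergy_index + rev$synergy_index, -2 * comp$teac)
  expect_equal(fwd$loss, -rev$loss)
})

test_that("bootstrap interval coverage is near nominal on additive truths", {
  set.seed(31)
  hits <- 0; n_sim <- 500
  for (i in seq_len(n_sim)) {
    f <- tr(rnorm(3, 10, 0.5)); d <- tr(rnorm(3, 7, 0.5)); c0 <- tr(rnorm(3, 3, 0.5))
    a <- assess_depletion(f, d, c0, n_boot = 2000, seed = i)
    if (a$ci[1] <= 0 && a$ci[2] >= 0) hits <- hits + 1
  }
  coverage <- hits / n_sim
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.995)
})

test_that("coverage fraction is the ratio of means with a bootstrap interval", {
  asp <- tr(c(7.5, 8, 8.5)); nat <- tr(c(7.5, 8, 8.5))
  expect_equal(coverage_fraction(asp, nat, seed = 1)$fraction, 1)
  half <- tr(c(3.75, 4, 4.25))
  cf <- coverage_fraction(half, nat, seed = 1)
  expect_equal(cf$fraction, 0.5)
  expect_true(cf$ci[1] < 0.5 && cf$ci[2] > 0.5)
  expect_error(coverage_fraction(asp, tr(c(0, 0, 0))), "domain error")
})

test_that("design validation enforces the depletion structure", {
  demo <- synthetic_depletion_panel(seed = 1)
  expect_silent(validate_designs(demo$designs))
  bad <- demo$designs
  # a depleted condition keeping one compound of its own class is invalid
  drop_row <- which(bad$design == "ST" & bad$condition == "depleted:quercetin")[1]
  bad$condition[bad$design == "ST" & bad$condition == "full" &
                  bad$compound == "chlorogenic_acid"] <- "depleted:quercetin"
  expect_error(validate_designs(bad), "design error")
  bad2 <- demo$designs
  bad2$concentration[1] <- -1
  expect_error(validate_designs(bad2), "concentrations must be > 0")
  bad3 <- demo$designs
  bad3$condition[1] <- "weird"
  expect_error(validate_designs(bad3), "unknown condition")
})

test_that("a noiseless depletion panel recovers the planted interactions exactly", {
  demo <- synthetic_depletion_panel(seed = 7, noise_sd = 0)
  panel <- run_depletion_panel(demo$designs, demo$plates, demo$curve,
                               demo$protocol, n_boot = 4000, seed = 11)
  merged <- merge(panel, demo$true_classes, by = c("design", "class"))
  expect_equal(merged$classification, merged$true_class)
  # synergy requires anthocyanins: the anthocyanin-free baseline is additive
  noac <- merged[merged$design == "ST_noAC", ]
  expect_true(all(noac$classification == "additive"))
  # a purely additive panel classifies everything additive
  add <- synthetic_depletion_panel(seed = 8, noise_sd = 0, synergy_weight = 0)
  panel2 <- run_depletion_panel(add$designs, add$plates, add$curve,
                                add$protocol, n_boot = 4000, seed = 12)
  expect_true(all(panel2$classification == "additive"))
})

test_that("planted synergies survive realistic plate noise", {
  hits <- 0; rows <- 0
  for (s in 1:5) {
    demo <- synthetic_depletion_panel(seed = s)
    panel <- run_depletion_panel(demo$designs, demo$plates, demo$curve,
                                 demo$protocol, n_boot = 2000, seed = 100 + s)
    merged <- merge(panel, demo$true_classes, by = c("design", "class"))
    syn <- merged[merged$true_class == "synergistic", ]
    expect_true(all(syn$classification == "synergistic"))
    hits <- hits + sum(merged$classification == merged$true_class)
    rows <- rows + nrow(merged)
  }
  expect_gte(hits / rows, 0.9)
})

test_that("missing triple members are reported by name", {
  demo <- synthetic_depletion_panel(seed = 2)
  plates <- demo$plates[!(demo$plates$design == "SA" &
                            demo$plates$condition == "isolated:quercetin"), ]
  expect_error(run_depletion_panel(demo$designs, plates, demo$curve,
                                   demo$protocol, n_boot = 100),
               "SA / quercetin.*isolated")
})
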