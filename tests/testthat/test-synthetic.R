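test_that("cohort specs validate planted effects", {
  expect_error(cohort_spec(groups = c(3, 2)), "named")
  expect_error(cohort_spec(band_power_effects = list(
    PD = list(gamma = list(channels = "Cz", factor = -1)))), "factor")
  expect_error(cohort_spec(band_power_effects = list(
    PD = list(gamma = list(channels = "NoSuch", factor = 2)))), "NoSuch")
  expect_error(cohort_spec(plv_effects = list(
    PD = list(beta = list(pairs = rbind(c("C3", "C4")), kappa = -2)))),
    "kappa")
})

test_that("generation is bit-reproducible from the seed", {
  spec <- cohort_spec(groups = c(HC = 2), fs = 128, duration_s = 4, seed = 81)
  r1 <- generate_cohort(spec)
  r2 <- generate_cohort(spec)
  expect_identical(r1[[1]]$data, r2[[1]]$data)
  expect_identical(r1[[2]]$data, r2[[2]]$data)
  # different seed, different data
  r3 <- generate_cohort(cohort_spec(groups = c(HC = 2), fs = 128,
                                    duration_s = 4, seed = 82))
  expect_gt(max(abs(r1[[1]]$data - r3[[1]]$data)), 0)
})

test_that("von Mises sampler has the right mean resultant length", {
  set.seed(83)
  for (kappa in c(0.5, 2, 10)) {
    th <- rvonmises(4000, kappa)
    r_hat <- Mod(mean(exp(1i * th)))
    r_exp <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_equal(r_hat, r_exp, tolerance = 0.05)
  }
  set.seed(84)
  th0 <- rvonmises(4000, 0)
  expect_lt(Mod(mean(exp(1i * th0))), 0.05)
})

test_that("kappa = 0 plants nothing: PLV at the independent-noise null", {
  spec0 <- cohort_spec(groups = c(HC = 1), fs = 128, duration_s = 30,
                       channels = c("C3", "C4", "Fz"),
                       plv_effects = list(HC = list(beta = list(
                         pairs = rbind(c("C3", "C4")), kappa = 0))),
                       seed = 85)
  rec <- generate_cohort(spec0)[[1]]
  plv <- compute_plv(segment_epochs(rec, 1), eeg_bands("beta"))
  target <- mean(plv$values[, "C3-C4", 1])
  others <- mean(plv$values[, c("C3-Fz", "C4-Fz"), 1])
  expect_lt(abs(target - others), 0.05)
})

test_that("recovered PLV rises monotonically with planted kappa", {
  kappas <- c(0, 1, 5, 50)
  got <- vapply(kappas, function(k) {
    spec <- cohort_spec(groups = c(HC = 1), fs = 128, duration_s = 60,
                        channels = c("C3", "C4"),
                        plv_effects = if (k > 0) list(HC = list(beta = list(
                          pairs = rbind(c("C3", "C4")), kappa = k)))
                        else list(),
                        seed = 86)
    rec <- generate_cohort(spec)[[1]]
    plv <- compute_plv(segment_epochs(rec, 1), eeg_bands("beta"))
    mean(plv$values[, 1, 1])
  }, numeric(1))
  expect_true(all(diff(got) > 0))
  # kappa = 50: strong coupling, near the asymptotic von Mises value
  expect_gte(got[4], 0.8)
  # expectation helper is monotone too
  expect_true(all(diff(vapply(kappas, plv_from_kappa, numeric(1))) >= 0))
})

test_that("a large planted coupling is confined to its pair", {
  co <- planted_cohort()
  grp <- vapply(co$plv, `[[`, character(1), "group")
  ip <- match("C3-C4", co$plv[[1]]$pair_index$name)
  target <- mean(vapply(co$plv[grp == "PD"],
                        function(f) mean(f$values[, ip, "beta"]), numeric(1)))
  others <- mean(vapply(co$plv[grp == "PD"],
                        function(f) mean(f$values[, -ip, "beta"]), numeric(1)))
  null_level <- mean(vapply(co$plv[grp == "HC"],
                            function(f) mean(f$values[, ip, "beta"]),
                            numeric(1)))
  expect_gte(target, 0.8)
  expect_lt(abs(others - null_level), 0.05)
})

test_that("a planted power factor is recovered as the expected ratio", {
  co <- planted_cohort()
  grp <- vapply(co$psd, `[[`, character(1), "group")
  iCz <- match("Cz", co$spec$channels)
  mean_gamma <- function(fs_) {
    rowMeans(vapply(fs_, function(f) colMeans(f$values[, , "gamma"]),
                    numeric(32)))
  }
  ratio <- mean_gamma(co$psd[grp == "PD"]) / mean_gamma(co$psd[grp == "HC"])
  expect_gte(ratio[iCz], 1.7)
  expect_lte(ratio[iCz], 2.3)
  # off-target channels stay near 1
  expect_lt(max(abs(ratio[-iCz] - 1)), 0.3)
})

test_that("planted_effect_report flags the planted units and only those", {
  co <- planted_cohort()
  rep_ <- planted_effect_report(co$spec, co$psd, co$plv)
  planted <- rep_[rep_$planted, ]
  expect_true(all(planted$flagged))
  # FDR-style tolerance: <= 10% false flags among non-planted units
  expect_lte(mean(rep_$flagged[!rep_$planted]), 0.10)
  # planted PSD ratio is inside its own confidence interval's neighbourhood
  cz <- rep_[rep_$planted & rep_$mode == "PSD", ]
  expect_gte(cz$observed, 1.7)
  expect_lte(cz$observed, 2.3)
  expect_error(planted_effect_report(co$spec, co$psd[1:3]),
               class = "mpeeg_validation_error")
})

test_that("null cohorts give CIs that cover unity for nearly all units", {
  spec <- cohort_spec(groups = c(HC = 5, PD = 5), fs = 128, duration_s = 20,
                      seed = 87)
  recs <- generate_cohort(spec)
  psd <- lapply(recs, function(r) compute_psd(segment_epochs(r, 1),
                                              eeg_bands(c("alpha", "gamma"))))
  rep_ <- planted_effect_report(spec, psd, NULL)
  covered <- rep_$ci_lo <= 1 & rep_$ci_hi >= 1
  expect_gte(mean(covered), 0.90)
})
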