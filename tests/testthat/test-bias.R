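test_that("transmission-fraction chain reproduces the closed forms", {
  expect_equal(fx_chain(1.27)$fx_r, sqrt(1.27) / (1 + sqrt(1.27)))
  expect_equal(round(100 * fx_chain(1.27)$fx_r, 1), 53.0)

  neutral <- fx_chain(1, c_rate = 0.01)
  expect_equal(neutral$fx_r, 0.5)
  expect_equal(neutral$fx_total, 0.5)
  expect_equal(neutral$b, 0)

  expect_equal(fx_chain(0)$fx_r, 0)
  expect_equal(fx_chain(4, convention = "linear")$fx_r, 0.8)

  # monotone increasing in the rate ratio for fixed c
  rr <- seq(0, 5, by = 0.25)
  fx <- fx_chain(rr, c_rate = 0.002)$fx_r
  expect_true(all(diff(fx) > 0))

  expect_error(fx_chain(-1), "rr")
  expect_error(fx_chain(1, c_rate = 2), "c_rate")
})

test_that("Li-Bulmer equilibrium has the right fixed points and limits", {
  expect_equal(li_bulmer_equilibrium(1, 1e4, 0), 0.5)
  # 2 Ne b = log(kappa) cancels the mutation bias exactly
  kappa <- 3
  ne <- 1e4
  expect_equal(li_bulmer_equilibrium(kappa, ne, log(kappa) / (2 * ne)), 0.5)
  expect_equal(li_bulmer_equilibrium(2, 1e8, 1e-3), 1)
  expect_lt(li_bulmer_equilibrium(2, 1e4, 0), 0.5)
  expect_error(li_bulmer_equilibrium(0, 1, 0), "kappa")
})

test_that("label swap inverts the pooled rate ratio exactly", {
  for (seed in 1:20) {
    s <- random_strata(n = sample(1:8, 1), seed = seed)
    rr <- cmh_rate_ratio(s)$rate_ratio
    rr_sw <- cmh_rate_ratio(swap_strata_labels(s))$rate_ratio
    expect_equal(rr * rr_sw, 1, tolerance = 1e-12)
  }
})

test_that("single-stratum pooling equals the plain 2x2 rate ratio", {
  s <- tibble::tibble(x_favored = 9, t_favored = 2e4,
                      x_disfavored = 4, t_disfavored = 3e4)
  rr <- cmh_rate_ratio(s)
  expect_equal(rr$rate_ratio, (9 / 2e4) / (4 / 3e4))
})

test_that("homogeneous strata pool to the common ratio and reversals cancel", {
  s2 <- tibble::tibble(x_favored = c(20, 10), t_favored = c(1e4, 1e4),
                       x_disfavored = c(10, 5), t_disfavored = c(1e4, 1e4))
  expect_equal(cmh_rate_ratio(s2)$rate_ratio, 2)

  rev <- tibble::tibble(x_favored = c(20, 10), t_favored = c(1e4, 1e4),
                        x_disfavored = c(10, 20), t_disfavored = c(1e4, 1e4))
  expect_equal(cmh_rate_ratio(rev)$rate_ratio, 1)

  # opposite orientations with equal weight cancel on the log scale
  rev_or <- dplyr::mutate(rev, orientation = c("RI", "RII"))
  expect_equal(cmh_rate_ratio(rev_or)$rate_ratio, 1)
})

test_that("single-orientation pooling matches the metafor MH estimator", {
  s <- tibble::tibble(
    x_favored = c(12, 30, 7, 21), t_favored = c(1e4, 3e4, 8e3, 2e4),
    x_disfavored = c(9, 22, 11, 15), t_disfavored = c(1.2e4, 2.5e4, 9e3, 2e4)
  )
  got <- cmh_rate_ratio(s)
  mh <- metafor::rma.mh(x1i = s$x_favored, t1i = s$t_favored,
                        x2i = s$x_disfavored, t2i = s$t_disfavored,
                        measure = "IRR")
  expect_equal(got$rate_ratio, exp(as.numeric(mh$beta)), tolerance = 1e-8)
})

test_that("zero favored counts yield a zero ratio with an exact upper bound", {
  s <- tibble::tibble(x_favored = 0, t_favored = 1e4,
                      x_disfavored = 25, t_disfavored = 1e4)
  expect_message(rr <- cmh_rate_ratio(s), "exact")
  expect_equal(rr$rate_ratio, 0)
  expect_equal(rr$ci_low, 0)
  expect_gt(rr$ci_high, 0)
  expect_lt(rr$p_value, 1e-6)
  expect_equal(fx_chain(rr$rate_ratio)$fx_r, 0)
})

test_that("per-site log rate ratios follow the count arithmetic", {
  map <- snp_map(c(100, 200, 300))
  mols <- dplyr::bind_rows(
    purrr::map(1:30, ~ mol_from_phases(map, c(1, 1, 2), reciprocal = "RI")),
    purrr::map(1:70, ~ mol_from_phases(map, c(1, 2, 2), reciprocal = "RI")),
    purrr::map(1:10, ~ mol_from_phases(map, c(2, 2, 1), reciprocal = "RII")),
    purrr::map(1:90, ~ mol_from_phases(map, c(2, 1, 1), reciprocal = "RII"))
  )
  ev <- call_events(mols, map)
  lr <- logrr_per_site(mols, ev, map)
  # at position 200 the h1 allele is carried by 30/100 RI and 10/100 RII
  row <- dplyr::filter(lr, position == 200,
                       allele == map$markers$allele_h1[2])
  expect_equal(row$logrr, log(3))
  # swapping the allele flips the sign
  row2 <- dplyr::filter(lr, position == 200,
                        allele == map$markers$allele_h2[2])
  expect_equal(row2$logrr, log((70 / 100) / (90 / 100)))
  expect_false(row$corrected)
})

test_that("standardized residual stars are calibrated on unbiased tables", {
  set.seed(5)
  map <- snp_map(seq(100, 2000, by = 100))
  n <- 400
  phases_ri <- purrr::map(1:n, ~ {
    j <- sample(19, 1)
    c(rep(1, j), rep(2, 20 - j))
  })
  phases_rii <- purrr::map(1:n, ~ {
    j <- sample(19, 1)
    c(rep(2, j), rep(1, 20 - j))
  })
  mols <- dplyr::bind_rows(
    purrr::map(phases_ri, mol_from_phases, map = map, reciprocal = "RI"),
    purrr::map(phases_rii, mol_from_phases, map = map, reciprocal = "RII")
  )
  ev <- call_events(mols, map)
  lr <- logrr_per_site(mols, ev, map)
  flagged <- mean(abs(lr$residual) > 1.96, na.rm = TRUE)
  expect_lt(flagged, 0.12)
})

test_that("pooled strata at a known ratio recover it within the interval", {
  set.seed(23)
  rr_true <- 1.27
  n_mol <- 1e4
  p <- rr_true / (1 + rr_true)
  s <- tibble::tibble(
    stratum = paste0("s", 1:20),
    orientation = rep(c("RI", "RII"), 10),
    x_favored = rbinom(20, n_mol / 20, p),
    t_favored = 1e5,
    x_disfavored = NA_integer_,
    t_disfavored = 1e5
  )
  s$x_disfavored <- as.integer(round(n_mol / 20)) - s$x_favored
  got <- cmh_rate_ratio(s)
  expect_gt(rr_true, got$ci_low)
  expect_lt(rr_true, got$ci_high)
})

test_that("strata built from crossovers contrast complementary reciprocal pairs", {
  map <- snp_map(c(100, 200, 300, 400))
  mols <- dplyr::bind_rows(
    purrr::map(1:12, ~ mol_from_phases(map, c(1, 1, 2, 2), reciprocal = "RI")),
    purrr::map(1:8, ~ mol_from_phases(map, c(2, 2, 1, 1), reciprocal = "RII"))
  )
  ev <- call_events(mols, map)
  assays <- tibble::tibble(donor_id = "d1", assay = "CO",
                           reciprocal = c("RI", "RII"),
                           amplifiable_genomes = c(1e4, 1e4))
  s <- build_strata(mols, ev, map, assays, "strong_weak", "CO")
  expect_equal(nrow(s), 1)
  # interval 200-300: RI retains (A weak at 200? no: h1 alternates G,A,G,A)
  # h1@200 = A (weak), h2@300 = A? h2 of G is A: pair (weak, weak) for RI
  expect_setequal(s$orientation, "RII")
  expect_equal(s$x_favored + s$x_disfavored, 20L)
})

test_that("simulated unbiased experiments give a rate ratio near one", {
  d <- donor_profile("d1", "Ht", correction_factor = 1)
  p <- sim_params(seed = 29, n_pools_co = 1000, co_rate = 2e-3, nco_rate = 0,
                  p_strong_transmission = 0.5,
                  p_long_transmission_short_heterology = 0.5,
                  p_short_transmission_long_heterology = 0.5,
                  p_complex_co = 0)
  ex <- simulate_experiment(d, p)
  ev <- call_events(ex$molecules, d$map)
  b <- estimate_transmission_bias(ex$molecules, ev, d$map, ex$assays,
                                  "strong_weak", "CO")
  expect_gt(b$ci_high, 1)
  expect_lt(b$ci_low, 1)
  expect_lt(abs(log(b$rate_ratio)), 0.2)
})

test_that("the deletion bias at the long heterology reproduces a zero NCO ratio", {
  # with the short allele always winning repair, no conversion ever gains
  # the long allele: RR = 0 with a tiny p-value, as in the printed table
  d <- donor_profile("d1", "Ht", correction_factor = 1)
  p <- sim_params(seed = 37, n_pools_nco = 2000, co_rate = 0, nco_rate = 2e-3,
                  tract_mean = 400)
  ex <- simulate_experiment(d, p)
  ev <- call_events(ex$molecules, d$map)
  central <- d$map$motif_position - 154
  b <- estimate_transmission_bias(ex$molecules, ev, d$map, ex$assays,
                                  "long_short", "NCO", markers = central,
                                  method = "exact")
  expect_equal(b$rate_ratio, 0)
  expect_equal(b$fx_r, 0)
  expect_lt(b$p_value, 1e-6)
})

test_that("NCO conversion strata recover the configured bias direction", {
  d <- donor_profile("d1", "Ht", correction_factor = 1)
  p <- sim_params(seed = 41, n_pools_nco = 4000, co_rate = 0, nco_rate = 2e-3,
                  p_strong_transmission = 0.65, tract_mean = 150,
                  p_complex_nco = 0)
  ex <- simulate_experiment(d, p)
  ev <- call_events(ex$molecules, d$map)
  b <- estimate_transmission_bias(ex$molecules, ev, d$map, ex$assays,
                                  "strong_weak", "NCO", convention = "linear")
  # true single-site odds 0.65/0.35 = 1.857; multi-site tracts blur it a bit
  expect_gt(b$rate_ratio, 1.5)
  expect_lt(b$rate_ratio, 2.3)
  expect_gt(b$fx_r, 0.58)
})
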