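test_that("frequencies reproduce the count-over-amplifiable-genomes arithmetic", {
  est <- estimate_frequency(4448, 3948418, 1, "CO")
  expect_equal(est$rate_per_amplifiable_genome, 4448 / 3948418)
  # 1.126e-3 per amplifiable genome at the printed precision
  expect_equal(est$rate_per_amplifiable_genome, 1.126e-3, tolerance = 1e-3)
  expect_equal(est$rate_per_meiosis, 2 * est$rate_per_amplifiable_genome)

  nco <- estimate_frequency(246, 360474, 1, "NCO")
  expect_equal(nco$meiosis_multiplier, 1)
  expect_equal(nco$rate_per_meiosis, nco$rate_per_amplifiable_genome)

  zero <- estimate_frequency(0, 1000, 0.2, "CO")
  expect_equal(zero$rate_per_amplifiable_genome, 0)
  expect_equal(zero$ci_low, 0)
  expect_gt(zero$ci_high, 0)

  expect_error(estimate_frequency(5, 0, 0.2, "CO"), "positive")
  expect_error(estimate_frequency(5, 100, 0, "CO"), "correction_factor")
})

test_that("exact Poisson interval matches brute-force test inversion", {
  # the 95% bounds are the rates whose exact Poisson tail probability is
  # exactly 2.5% for the observed count
  count <- 10
  denom <- 1000
  est <- estimate_frequency(count, denom, 1, "CO")
  lower <- uniroot(function(m) 1 - ppois(count - 1, m) - 0.025,
                   c(1e-6, count))$root
  upper <- uniroot(function(m) ppois(count, m) - 0.025,
                   c(count, 10 * count))$root
  expect_equal(est$ci_low, lower / denom, tolerance = 1e-6)
  expect_equal(est$ci_high, upper / denom, tolerance = 1e-6)
})

test_that("interval scale equivariance: doubling count and exposure narrows the CI", {
  a <- estimate_frequency(20, 1e4, 0.5, "CO")
  b <- estimate_frequency(40, 2e4, 0.5, "CO")
  expect_equal(a$rate_per_amplifiable_genome, b$rate_per_amplifiable_genome)
  expect_lt(b$ci_high - b$ci_low, a$ci_high - a$ci_low)
})

test_that("exact rate comparison matches its binomial and Poisson oracles", {
  same <- compare_groups(estimate_frequency(15, 1e4, 1, "CO"),
                         estimate_frequency(15, 1e4, 1, "CO"))
  expect_equal(same$rate_ratio, 1)
  expect_equal(same$p_value, 1)

  est1 <- estimate_frequency(20, 1e4, 1, "CO")
  est2 <- estimate_frequency(10, 1e4, 1, "CO")
  cmp <- compare_groups(est1, est2)
  expect_equal(cmp$p_value, binom.test(20, 30, 0.5)$p.value)
  # independent implementation of the same conditional construction
  pt <- poisson.test(c(20, 10), c(1e4, 1e4))
  expect_equal(cmp$p_value, pt$p.value)
  expect_equal(cmp$rate_ratio, unname(pt$estimate))
  expect_equal(c(cmp$ci_low, cmp$ci_high), as.numeric(pt$conf.int),
               tolerance = 1e-8)

  expect_warning(
    out <- compare_groups(estimate_frequency(0, 1e4, 1, "CO"),
                          estimate_frequency(0, 1e4, 1, "CO")),
    "undefined"
  )
  expect_true(is.na(out$rate_ratio))
})

test_that("cM/Mb conversion is plain arithmetic", {
  expect_equal(cm_per_mb(1e-3, 1000), 100)
  expect_equal(cm_per_mb(0, 5000), 0)
  expect_error(cm_per_mb(1e-3, 0), "positive")
})

test_that("simulated experiments recover the configured genetic map length", {
  d <- donor_profile("d1", "Ht", correction_factor = 1)
  p <- sim_params(seed = 3, n_pools_co = 1000, co_rate = 1.1e-3, nco_rate = 0)
  ex <- simulate_experiment(d, p)
  ev <- call_events(ex$molecules, d$map)
  n <- sum(ev$scorable)
  est <- estimate_frequency(n, 2e6, 1, "CO")
  span <- diff(range(d$map$markers$position))
  got <- cm_per_mb(est$rate_per_meiosis, span)
  want_lo <- cm_per_mb(2 * est$ci_low, span)
  want_hi <- cm_per_mb(2 * est$ci_high, span)
  truth <- cm_per_mb(2 * 1.1e-3, span)
  expect_gt(truth, want_lo)
  expect_lt(truth, want_hi)
  expect_equal(got, truth, tolerance = 0.1)
})

test_that("95% Poisson intervals cover the truth at the nominal rate", {
  set.seed(42)
  lambda <- 50
  denom <- 1e5
  hits <- purrr::map_lgl(rpois(2000, lambda), function(x) {
    est <- estimate_frequency(x, denom, 1, "CO")
    est$ci_low <= lambda / denom && lambda / denom <= est$ci_high
  })
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("complex-event rates use exact binomial intervals", {
  map <- snp_map(100 * (1:4))
  mols <- dplyr::bind_rows(
    purrr::map(1:984, ~ mol_from_phases(map, c(1, 1, 2, 2))),
    purrr::map(1:16, ~ mol_from_phases(map, c(1, 2, 1, 2)))
  )
  ev <- call_events(mols, map)
  assays <- tibble::tibble(donor_id = "d1", group = "Ht", assay = c("CO", "NCO"),
                           reciprocal = c("RI", "NRI"), n_pools = 1,
                           genomes_assayed = c(4e5, 4e5),
                           correction_factor = 0.25,
                           amplifiable_genomes = c(1e5, 1e5))
  cr <- complex_event_rates(ev, assays)
  prop <- dplyr::filter(cr, statistic == "CCO_per_CO")
  expect_equal(prop$estimate, 0.016)
  bt <- binom.test(16, 1000)
  expect_equal(c(prop$ci_low, prop$ci_high), as.numeric(bt$conf.int))

  # no complex crossovers: zero estimate with an exact upper bound
  ev0 <- call_events(dplyr::bind_rows(
    purrr::map(1:50, ~ mol_from_phases(map, c(1, 1, 2, 2)))
  ), map)
  cr0 <- complex_event_rates(ev0, assays)
  p0 <- dplyr::filter(cr0, statistic == "CCO_per_CO")
  expect_equal(p0$estimate, 0)
  expect_equal(p0$ci_low, 0)
  expect_gt(p0$ci_high, 0)
})

test_that("per-donor rate table mirrors counts and exposures", {
  d <- donor_profile("d1", "Ht")
  ex <- simulate_experiment(d, sim_params(seed = 13, n_pools_co = 100,
                                          n_pools_nco = 100))
  ev <- call_events(ex$molecules, d$map)
  tbl <- summarize_rates(ev, ex$assays)
  expect_setequal(unique(tbl$assay), c("CO", "NCO"))
  expect_equal(sum(tbl$event_count), sum(ev$scorable))
  expect_true(all(tbl$ci_low <= tbl$rate_per_amplifiable_genome + 1e-12))
  expect_true(all(tbl$rate_per_amplifiable_genome <= tbl$ci_high + 1e-12))
})
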