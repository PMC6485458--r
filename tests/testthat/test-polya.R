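test_that("run detection finds maximal runs with the length threshold", {
  r <- find_runs("CCAAAAAATT")
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end, r$length), c(3, 8, 6))

  expect_equal(nrow(find_runs("AAAAA")), 0)      # below threshold
  expect_equal(nrow(find_runs("")), 0)           # empty sequence
  expect_equal(nrow(find_runs("ccaaaaaatt")), 1) # case-insensitive
  expect_equal(nrow(find_runs("AAANAAAAAA", min_len = 6)), 1) # N breaks runs
  expect_equal(find_runs("AAANAAAAAA", min_len = 6)$start, 5)

  t_runs <- find_runs("GGTTTTTTTC", base = "T")
  expect_equal(c(t_runs$start, t_runs$end), c(3, 9))

  long <- find_runs(strrep("A", 30))
  expect_equal(long$length, 30)
  expect_equal(long$capped_length, 26)
})

test_that("rle scanner agrees with the quadratic regex oracle", {
  set.seed(101)
  for (i in 1:25) {
    s <- random_seq(20000, p_a = 0.35, with_n = TRUE)
    got <- find_runs(s)
    want <- regex_find_runs(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("poly-T runs equal poly-A runs on the reverse complement", {
  set.seed(11)
  s <- random_seq(5000, p_a = 0.35)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  t_runs <- find_runs(s, base = "T")
  a_runs <- find_runs(rc, base = "A")
  n <- nchar(s)
  expect_equal(sort(n - t_runs$end + 1), sort(a_runs$start))
  expect_equal(sort(n - t_runs$start + 1), sort(a_runs$end))
})

test_that("a 1-kb DSB interval yields a 2-kb hotspot zone and 2-kb flank zones", {
  zs <- build_zones(tibble::tibble(contig = "c1", start = 10000, end = 10999),
                    c(c1 = 50000))
  zl <- attr(zs, "zone_lengths")
  expect_equal(zl$total_bp[zl$zone == "hotspot"], 2000)
  for (k in 1:5) {
    expect_equal(zl$total_bp[zl$zone == paste0("flank", k)], 2000)
  }
  # conservation of the contig
  expect_equal(sum(zl$total_bp), 50000)
})

test_that("nearby hotspots truncate their shared flanks without overlap", {
  dsb <- tibble::tibble(contig = "c1", start = c(10000, 14000),
                        end = c(10999, 14999))
  zs <- build_zones(dsb, c(c1 = 60000))
  # zones are pairwise disjoint
  z <- dplyr::arrange(tibble::as_tibble(zs), start)
  expect_true(all(z$start[-1] > z$end[-nrow(z)]))
  # the 2-kb gap between padded hotspot zones is split between flank1 zones
  expect_equal(sum(attr(zs, "zone_lengths")$total_bp), 60000)
  f1 <- dplyr::filter(z, zone == "flank1")
  expect_equal(sum(f1$end - f1$start + 1), 2000 + 2000) # outer 2kb + split gap
})

test_that("hotspots at the contig edge are clipped", {
  zs <- build_zones(tibble::tibble(contig = "c1", start = 1, end = 400),
                    c(c1 = 10000))
  z <- tibble::as_tibble(zs)
  expect_true(all(z$start >= 1))
  expect_true(all(z$end <= 10000))
  hs <- dplyr::filter(z, zone == "hotspot")
  expect_equal(hs$start, 1)
  expect_equal(hs$end, 900)
})

test_that("malformed DSB intervals are rejected with their row numbers", {
  bad <- tibble::tibble(contig = "c1", start = c(100, 900), end = c(500, 200))
  expect_error(build_zones(bad, c(c1 = 1e4)), "row\\(s\\): 2")
  oob <- tibble::tibble(contig = "c1", start = 100, end = 2e4)
  expect_error(build_zones(oob, c(c1 = 1e4)), "out-of-bounds")
})

test_that("zone densities follow the counting arithmetic and conserve runs", {
  zs <- build_zones(tibble::tibble(contig = "c1", start = 10000, end = 10999),
                    c(c1 = 50000))
  runs <- tibble::tibble(
    contig = "c1",
    start = c(9700, 9800, 10200, 11000, 30000),
    end = c(9706, 9806, 10206, 11006, 30009),
    base = "A", length = c(7, 7, 7, 7, 10), capped_length = c(7, 7, 7, 7, 10)
  )
  zd <- zone_densities(runs, zs)
  hs <- dplyr::filter(zd$summary, zone == "hotspot")
  expect_equal(hs$n_runs, 4L)
  expect_equal(hs$run_density, 4 / 2000)
  expect_equal(sum(zd$summary$n_runs), nrow(runs))
  out <- dplyr::filter(zd$summary, zone == "outside")
  expect_equal(out$n_runs, 1L)
})

test_that("uniform runs give unit enrichment and planted runs twice that", {
  set.seed(5)
  n_hs <- 300
  dsb <- tibble::tibble(contig = "c1",
                        start = seq(20000, by = 20000, length.out = n_hs),
                        end = seq(20999, by = 20000, length.out = n_hs))
  zs <- build_zones(dsb, c(c1 = 20000 * n_hs + 30000))

  unif <- planted_runs(zs, rate_hotspot = 2e-3, rate_elsewhere = 2e-3)
  zd0 <- zone_densities(unif, zs)
  expect_lt(abs(zd0$enrichment$ratio[1] - 1), 0.1)
  expect_gt(enrichment_test(unif, zs)$p_value, 0.01)

  planted <- planted_runs(zs, rate_hotspot = 4e-3, rate_elsewhere = 2e-3)
  zd2 <- zone_densities(planted, zs)
  expect_lt(abs(zd2$enrichment$ratio[1] - 2), 0.2)
  kw <- enrichment_test(planted, zs)
  expect_lt(kw$p_value, 0.01)
  expect_equal(kw$n_hotspot_obs, n_hs)
})

test_that("rank test p-values agree with permutation references", {
  # exhaustive label permutation at n = 8: the chi-square p is only an
  # approximation this small, so agreement is coarse
  vals <- c(1.2, 3.4, 0.7, 2.2, 5.1, 4.4, 2.9, 0.3)
  grp <- rep(c("hotspot", "flank"), each = 4)
  kw <- kruskal.test(split(vals, grp))
  idx <- utils::combn(8, 4)
  stat_perm <- apply(idx, 2, function(ix) {
    g <- rep("flank", 8)
    g[ix] <- "hotspot"
    kruskal.test(split(vals, g))$statistic
  })
  p_perm <- mean(stat_perm >= kw$statistic - 1e-12)
  expect_lt(abs(kw$p.value - p_perm), 0.15)

  # at a moderate sample size the asymptotic and permutation p agree closely
  set.seed(71)
  vals2 <- c(rnorm(15, 1), rnorm(15, 1.6))
  grp2 <- rep(c("flank", "hotspot"), each = 15)
  kw2 <- kruskal.test(split(vals2, grp2))
  stat2 <- replicate(4000, {
    g <- sample(grp2)
    kruskal.test(split(vals2, g))$statistic
  })
  p_perm2 <- mean(stat2 >= kw2$statistic - 1e-12)
  expect_lt(abs(kw2$p.value - p_perm2), 0.03)
})

test_that("enrichment test requires observations in both groups", {
  # a zone set without flank zones leaves nothing to compare against
  zs <- build_zones(tibble::tibble(contig = "c1", start = 10000, end = 10999),
                    c(c1 = 50000), n_flanks = 0)
  runs <- tibble::tibble(contig = "c1", start = 10100L, end = 10106L,
                         base = "A", length = 7L, capped_length = 7L)
  expect_error(enrichment_test(runs, zs), "no observations")
})

test_that("renormalised length-class densities sum to one across zones", {
  set.seed(9)
  zs <- build_zones(tibble::tibble(contig = "c1", start = 10000, end = 10999),
                    c(c1 = 100000))
  runs <- planted_runs(zs, 3e-3, 1.5e-3)
  zd <- zone_densities(runs, zs, renormalize = TRUE)
  sums <- zd$by_length |>
    dplyr::group_by(capped_length) |>
    dplyr::summarise(s = sum(density_renorm))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})
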