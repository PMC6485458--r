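#' Simulation parameters for pooled sperm typing
#'
#' Bundles the generative parameters of the synthetic pooled-sperm-typing
#' experiment. Defaults reflect the magnitudes measured at the modelled
#' hotspot: crossover (CO) products at about 1.1e-3 and detectable
#' non-crossovers (NCO) at about 6.8e-4 per amplifiable genome per reciprocal
#' assay, a DSB zone centred 287 bp upstream of the PRDM9 motif with a 400-bp
#' spread, conversion tracts with a geometric length scale, and per-site
#' transmission biases: strong (G/C) over weak alleles at heteroduplex SNPs,
#' the long allele at a 1-unit poly-A heterology, and the short allele at a
#' long (10-unit) heterology.
#'
#' @param n_meioses_per_pool Sperm genomes aliquoted per reaction.
#' @param n_pools_co,n_pools_nco Number of reactions per reciprocal for the
#'   CO and NCO assays.
#' @param co_rate,nco_rate Events per amplifiable genome per reciprocal
#'   assay; their sum must not exceed 1.
#' @param dsb_center,dsb_sd Normal position model of the double-strand-break
#'   zone (bp); `dsb_sd` must be positive.
#' @param tract_mean Geometric mean conversion-tract length (bp).
#' @param p_strong_transmission Probability that the strong allele wins
#'   heteroduplex repair at a SNP.
#' @param p_long_transmission_short_heterology Probability that the long
#'   allele wins at an STR with short heterology (length difference of at
#'   most 2 units).
#' @param p_short_transmission_long_heterology Probability that the short
#'   allele wins at an STR with long heterology (difference above 2 units).
#' @param p_complex_co Probability that a CO acquires a discordant converted
#'   block separated from its breakpoint (complex CO).
#' @param p_complex_nco Probability that an NCO conversion tract skips one
#'   covered internal marker (complex conversion).
#' @param missing_rate Per-marker probability that a call is masked to
#'   missing, emulating uninformative or failed genotyping.
#' @param seed Integer seed recorded with the parameters;
#'   [simulate_experiment()] seeds from it so equal seeds give identical
#'   molecule tables.
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' sim_params(seed = 1)
#' @export
sim_params <- function(n_meioses_per_pool = 1000,
                       n_pools_co = 100,
                       n_pools_nco = 100,
                       co_rate = 1.1e-3,
                       nco_rate = 6.8e-4,
                       dsb_center = 6360770,
                       dsb_sd = 400,
                       tract_mean = 300,
                       p_strong_transmission = 0.53,
                       p_long_transmission_short_heterology = 0.583,
                       p_short_transmission_long_heterology = 1,
                       p_complex_co = 0.015,
                       p_complex_nco = 0.12,
                       missing_rate = 0,
                       seed = NULL) {
  check_number(co_rate, "co_rate", lower = 0)
  check_number(nco_rate, "nco_rate", lower = 0)
  if (co_rate + nco_rate > 1) {
    abort("co_rate + nco_rate must not exceed 1")
  }
  check_number(dsb_sd, "dsb_sd")
  if (dsb_sd <= 0) abort("dsb_sd must be positive")
  check_number(tract_mean, "tract_mean")
  if (tract_mean < 1) abort("tract_mean must be at least 1 bp")
  check_probability(p_strong_transmission, "p_strong_transmission")
  check_probability(p_long_transmission_short_heterology,
                    "p_long_transmission_short_heterology")
  check_probability(p_short_transmission_long_heterology,
                    "p_short_transmission_long_heterology")
  check_probability(p_complex_co, "p_complex_co")
  check_probability(p_complex_nco, "p_complex_nco")
  check_probability(missing_rate, "missing_rate")
  for (n in c(n_meioses_per_pool, n_pools_co, n_pools_nco)) {
    check_number(n, "pool sizes", lower = 1)
  }
  structure(
    list(
      n_meioses_per_pool = n_meioses_per_pool,
      n_pools_co = n_pools_co,
      n_pools_nco = n_pools_nco,
      co_rate = co_rate,
      nco_rate = nco_rate,
      dsb_center = dsb_center,
      dsb_sd = dsb_sd,
      tract_mean = tract_mean,
      p_strong_transmission = p_strong_transmission,
      p_long_transmission_short_heterology = p_long_transmission_short_heterology,
      p_short_transmission_long_heterology = p_short_transmission_long_heterology,
      p_complex_co = p_complex_co,
      p_complex_nco = p_complex_nco,
      missing_rate = missing_rate,
      seed = seed
    ),
    class = "sim_params"
  )
}

# Repair-win weight of one allele at a heteroduplex site.
# SNPs: strong allele wins with p_strong. STRs: the long allele wins with
# p_long at short heterologies (<= 2 repeat units), the short allele wins
# with p_short at long heterologies. Sites without a contrast weigh 1/2.
allele_weight <- function(markers, idx, homolog, params) {
  m <- markers[idx, ]
  if (!m$heterozygous) return(0.5)
  if (m$kind == "SNP") {
    cls <- if (homolog == 1) m$class_h1 else m$class_h2
    other <- if (homolog == 1) m$class_h2 else m$class_h1
    if (is.na(cls) || is.na(other) || cls == other) return(0.5)
    return(if (cls == "strong") params$p_strong_transmission
           else 1 - params$p_strong_transmission)
  }
  # STR
  len <- if (homolog == 1) m$length_h1 else m$length_h2
  other_len <- if (homolog == 1) m$length_h2 else m$length_h1
  if (len == other_len) return(0.5)
  delta <- abs(m$length_h1 - m$length_h2)
  if (delta <= 2) {
    p_long <- params$p_long_transmission_short_heterology
    if (len > other_len) p_long else 1 - p_long
  } else {
    p_short <- params$p_short_transmission_long_heterology
    if (len < other_len) p_short else 1 - p_short
  }
}

# Geometric tract length with the configured mean, at least 1 bp
draw_tract_length <- function(params) {
  rgeom(1, 1 / params$tract_mean) + 1
}

# Construct the transmitted haplotype of one CO product.
#
# The exchange interval is drawn from the inter-marker intervals with
# probability proportional to the Normal DSB mass they contain times the
# repair-win weights of the two retained alleles flanking the exchange:
# heteroduplex repair at the mismatches next to the resolution junction
# tilts where the realised phase switch lands. For reciprocal RI the
# retained flank alleles are h1 on the left and h2 on the right; RII is the
# mirror image. Returns a character vector of calls, one per marker.
co_interval_weights <- function(donor, params, reciprocal) {
  mk <- donor$map$markers
  k <- nrow(mk)
  pos <- mk$position
  lo <- pos[-k]
  hi <- pos[-1]
  pos_w <- pnorm(hi, params$dsb_center, params$dsb_sd) -
    pnorm(lo, params$dsb_center, params$dsb_sd)
  pos_w <- pmax(pos_w, 1e-12)
  left_hom <- if (reciprocal == "RI") 1 else 2
  right_hom <- if (reciprocal == "RI") 2 else 1
  bias_w <- vapply(seq_len(k - 1), function(j) {
    allele_weight(mk, j, left_hom, params) *
      allele_weight(mk, j + 1, right_hom, params)
  }, numeric(1))
  w <- pos_w * bias_w
  if (all(w == 0)) w <- pos_w
  w
}

simulate_co_calls <- function(donor, params, reciprocal, weights = NULL) {
  mk <- donor$map$markers
  k <- nrow(mk)
  w <- weights %||% co_interval_weights(donor, params, reciprocal)
  j <- sample.int(k - 1, 1, prob = w)

  calls <- if (reciprocal == "RI") {
    c(mk$allele_h1[seq_len(j)], mk$allele_h2[seq(j + 1, k)])
  } else {
    c(mk$allele_h2[seq_len(j)], mk$allele_h1[seq(j + 1, k)])
  }

  # complex CO: one internal marker beyond the exchange flips to the other
  # homologue, leaving a discordant block separated from the breakpoint
  if (runif(1) < params$p_complex_co) {
    flanks <- c(j - 1, j + 2)
    flanks <- flanks[flanks > 1 & flanks < k & mk$heterozygous[pmax(pmin(flanks, k), 1)]]
    if (length(flanks) > 0) {
      fl <- if (length(flanks) == 1) flanks else sample(flanks, 1)
      on_left <- fl <= j
      calls[fl] <- if (xor(on_left, reciprocal == "RI")) {
        mk$allele_h1[fl]
      } else {
        mk$allele_h2[fl]
      }
    }
  }
  calls
}

# Construct one NCO product on the given background homologue (NRI = h1,
# NRII = h2). A geometric tract around a Normal DSB position covers
# heterozygous markers; the heteroduplex resolves as one contiguous block,
# either back to the background (undetectable) or to the other homologue
# (the observed conversion), with odds given by the product of the per-site
# repair-win weights. With probability p_complex_nco one covered internal
# marker is left unconverted, producing a complex conversion; with
# p_complex_nco = 0 conversions are always contiguous. Returns NULL when no
# conversion is detectable.
nco_gain_weights <- function(donor, params, reciprocal) {
  mk <- donor$map$markers
  other <- if (reciprocal == "NRI") 2 else 1
  vapply(seq_len(nrow(mk)), function(i) allele_weight(mk, i, other, params),
         numeric(1))
}

simulate_nco_calls <- function(donor, params, reciprocal, gain_weights = NULL) {
  mk <- donor$map$markers
  k <- nrow(mk)
  background <- if (reciprocal == "NRI") 1 else 2
  b <- rnorm(1, params$dsb_center, params$dsb_sd)
  len <- draw_tract_length(params)
  covered <- which(mk$heterozygous &
                     mk$position >= b - len / 2 &
                     mk$position <= b + len / 2)
  if (length(covered) == 0) return(NULL)

  win_other <- (gain_weights %||% nco_gain_weights(donor, params, reciprocal))[covered]
  w_other <- prod(win_other)
  w_bg <- prod(1 - win_other)
  if (w_other + w_bg == 0 || runif(1) >= w_other / (w_other + w_bg)) {
    return(NULL)
  }
  converted <- covered

  if (length(covered) >= 3 && runif(1) < params$p_complex_nco) {
    # the tract skips one covered internal marker
    inner <- covered[-c(1, length(covered))]
    skip <- if (length(inner) == 1) inner else sample(inner, 1)
    converted <- setdiff(covered, skip)
  }
  if (length(converted) == 0) return(NULL)

  calls <- if (background == 1) mk$allele_h1 else mk$allele_h2
  calls[converted] <- if (background == 1) mk$allele_h2[converted] else mk$allele_h1[converted]
  calls
}

mask_calls <- function(calls, params) {
  if (params$missing_rate > 0) {
    calls[runif(length(calls)) < params$missing_rate] <- NA_character_
  }
  calls
}

#' Simulate a single meiosis
#'
#' Draws at most one recombinant product from one meiosis: a CO with
#' probability `co_rate`, an NCO with probability `nco_rate` (if its
#' conversion tract covers and converts at least one informative marker),
#' otherwise nothing. The reciprocal is sampled with equal probability, the
#' symmetric counterpart of generating both reciprocals per CO meiosis and
#' assaying one.
#'
#' @param donor A [donor_profile].
#' @param params A [sim_params].
#' @return A one-row molecule tibble (`donor_id`, `assay`, `reciprocal`,
#'   `pool_id`, then one column per marker position) or `NULL`.
#' @examples
#' set.seed(1)
#' d <- donor_profile("d1", "Ht")
#' p <- sim_params(co_rate = 0.5, nco_rate = 0.2)
#' simulate_meiosis(d, p)
#' @export
simulate_meiosis <- function(donor, params) {
  stopifnot(inherits(donor, "donor_profile"), inherits(params, "sim_params"))
  u <- runif(1)
  if (u < params$co_rate) {
    reciprocal <- sample(c("RI", "RII"), 1)
    calls <- mask_calls(simulate_co_calls(donor, params, reciprocal), params)
    assay <- "CO"
  } else if (u < params$co_rate + params$nco_rate) {
    reciprocal <- sample(c("NRI", "NRII"), 1)
    calls <- simulate_nco_calls(donor, params, reciprocal)
    if (is.null(calls)) return(NULL)
    calls <- mask_calls(calls, params)
    assay <- "NCO"
  } else {
    return(NULL)
  }
  molecule_tibble(donor$donor_id, assay, reciprocal, 1L, list(calls),
                  donor$map)
}

molecule_tibble <- function(donor_id, assay, reciprocal, pool_id, calls_list,
                            map) {
  mat <- do.call(rbind, calls_list)
  colnames(mat) <- as.character(map$markers$position)
  bind_cols(
    tibble(donor_id = donor_id, assay = assay, reciprocal = reciprocal,
           pool_id = as.integer(pool_id)),
    as_tibble(mat)
  )
}

#' Simulate a pooled sperm-typing experiment
#'
#' Runs the full assay for one donor: for each assay (CO, NCO) and each
#' reciprocal, the number of collected molecules is Poisson with mean
#' (pools x genomes per pool x correction factor x event rate), molecules are
#' constructed by the meiosis-level model, and each is aliquoted to a
#' reaction pool. Detectable NCOs are those whose conversion tract covers and
#' converts at least one heterozygous marker, so the realised NCO yield sits
#' slightly below `nco_rate`.
#'
#' Output is deterministic given `params$seed`.
#'
#' @param donor A [donor_profile].
#' @param params A [sim_params].
#' @return A list of class `sperm_experiment` with elements
#'   \describe{
#'     \item{molecules}{tibble of collected molecules, one column per marker
#'       position; missing calls are `NA` (written as "." on disk).}
#'     \item{assays}{tibble of per-assay exposures: `donor_id`, `group`,
#'       `assay`, `reciprocal`, `n_pools`, `genomes_assayed`,
#'       `correction_factor`, `amplifiable_genomes`.}
#'     \item{truth}{the donor and parameter objects, for recovery tests.}
#'   }
#' @examples
#' d <- donor_profile("d1", "Ht")
#' ex <- simulate_experiment(d, sim_params(seed = 42, n_pools_co = 20,
#'                                         n_pools_nco = 20))
#' nrow(ex$molecules)
#' @export
simulate_experiment <- function(donor, params) {
  stopifnot(inherits(donor, "donor_profile"), inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  assay_tbl <- tibble(
    donor_id = donor$donor_id,
    group = donor$group,
    assay = rep(c("CO", "NCO"), each = 2),
    reciprocal = c("RI", "RII", "NRI", "NRII"),
    n_pools = rep(c(params$n_pools_co, params$n_pools_nco), each = 2),
    genomes_assayed = .data$n_pools * params$n_meioses_per_pool,
    correction_factor = donor$correction_factor,
    amplifiable_genomes = .data$genomes_assayed * donor$correction_factor
  )

  mol <- vector("list", 4)
  for (i in seq_len(4)) {
    row <- assay_tbl[i, ]
    rate <- if (row$assay == "CO") params$co_rate else params$nco_rate
    n <- rpois(1, row$amplifiable_genomes * rate)
    if (n == 0) next
    wts <- if (row$assay == "CO") {
      co_interval_weights(donor, params, row$reciprocal)
    } else {
      nco_gain_weights(donor, params, row$reciprocal)
    }
    calls <- vector("list", n)
    for (j in seq_len(n)) {
      calls[[j]] <- if (row$assay == "CO") {
        mask_calls(simulate_co_calls(donor, params, row$reciprocal, wts), params)
      } else {
        cl <- simulate_nco_calls(donor, params, row$reciprocal, wts)
        if (is.null(cl)) NULL else mask_calls(cl, params)
      }
    }
    calls <- compact(calls)
    if (length(calls) == 0) next
    pools <- sample.int(row$n_pools, length(calls), replace = TRUE)
    mol[[i]] <- molecule_tibble(donor$donor_id, row$assay, row$reciprocal,
                                pools, calls, donor$map)
  }
  molecules <- bind_rows(mol)
  if (nrow(molecules) == 0) {
    molecules <- molecule_tibble(donor$donor_id, character(), character(),
                                 integer(), list(), donor$map)[0, ]
  }
  structure(
    list(molecules = molecules, assays = assay_tbl,
         truth = list(donor = donor, params = params)),
    class = "sperm_experiment"
  )
}

#' @export
print.sperm_experiment <- function(x, ...) {
  cat("<sperm_experiment> donor ", x$truth$donor$donor_id, " (",
      x$truth$donor$group, "): ", sum(x$molecules$assay == "CO"), " CO and ",
      sum(x$molecules$assay == "NCO"), " NCO molecules\n", sep = "")
  invisible(x)
}
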