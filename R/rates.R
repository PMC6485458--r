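# Event frequencies per amplifiable genome with exact Poisson intervals,
# exact two-sample rate comparison, and genetic-map conversion.

# Garwood exact Poisson 95% CI on a count, as gamma quantiles
poisson_ci <- function(count, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  lo <- if (count == 0) 0 else qgamma(a, count)
  hi <- qgamma(1 - a, count + 1)
  c(lo, hi)
}

#' Estimate a recombination frequency
#'
#' Converts an event count into a rate per amplifiable genome: the assayed
#' genomes are first corrected by the fraction that is amplifiable, then the
#' count is divided by that denominator, with an exact (Garwood) Poisson
#' confidence interval. The per-meiosis rate applies the assay multiplier:
#' two crossovers result per meiosis but only one reciprocal is measured
#' (multiplier 2), while one NCO results per meiosis (multiplier 1).
#'
#' @param count Number of events collected (>= 0).
#' @param genomes Number of genomes assayed (> 0).
#' @param correction_factor Amplifiable fraction in (0, 1].
#' @param assay `"CO"` or `"NCO"`, which fixes the meiosis multiplier.
#' @param conf_level Confidence level of the exact interval.
#' @return A one-row tibble: `assay`, `event_count`, `genomes_assayed`,
#'   `correction_factor`, `amplifiable_genomes`, `meiosis_multiplier`,
#'   `rate_per_amplifiable_genome`, `ci_low`, `ci_high` (on the per-genome
#'   rate) and `rate_per_meiosis`.
#' @examples
#' # 4,448 crossovers from 3,948,418 amplifiable genomes: 1.126e-3
#' estimate_frequency(4448, 3948418, 1, "CO")
#' @export
estimate_frequency <- function(count, genomes, correction_factor,
                               assay = c("CO", "NCO"), conf_level = 0.95) {
  assay <- match.arg(assay)
  check_number(count, "count", lower = 0)
  if (genomes <= 0) abort("`genomes` must be positive")
  if (correction_factor <= 0 || correction_factor > 1) {
    abort("correction_factor must be in (0, 1]")
  }
  denom <- genomes * correction_factor
  ci <- poisson_ci(count, conf_level)
  mult <- if (assay == "CO") 2 else 1
  tibble(
    assay = assay,
    event_count = count,
    genomes_assayed = genomes,
    correction_factor = correction_factor,
    amplifiable_genomes = denom,
    meiosis_multiplier = mult,
    rate_per_amplifiable_genome = count / denom,
    ci_low = ci[1] / denom,
    ci_high = ci[2] / denom,
    rate_per_meiosis = mult * count / denom
  )
}

#' Per-donor frequency table
#'
#' Tabulates scorable events per donor, assay and reciprocal and attaches
#' exact frequency estimates, mirroring the layout of a per-donor frequency
#' supplement (donor, assay, count, amplifiable genomes, rate, CI).
#'
#' @param events Event tibble from [call_events()].
#' @param assays Exposure tibble as returned in
#'   `simulate_experiment()$assays`.
#' @param by_reciprocal Keep reciprocals separate (default) or pool them.
#' @return A tibble with one row per donor x assay (x reciprocal).
#' @export
summarize_rates <- function(events, assays, by_reciprocal = TRUE) {
  keys <- c("donor_id", "assay", if (by_reciprocal) "reciprocal")
  counts <- events |>
    filter(.data$scorable) |>
    count(across(all_of(keys)), name = "event_count")
  exposures <- assays |>
    group_by(across(all_of(c(keys, "correction_factor")))) |>
    summarise(genomes_assayed = sum(.data$genomes_assayed), .groups = "drop")
  exposures |>
    left_join(counts, by = keys) |>
    mutate(
      event_count = coalesce(.data$event_count, 0L),
      est = pmap(
        list(.data$event_count, .data$genomes_assayed,
             .data$correction_factor, .data$assay),
        function(n, g, cf, a) {
          select(estimate_frequency(n, g, cf, a), -"assay", -"event_count",
                 -"genomes_assayed", -"correction_factor")
        }
      )
    ) |>
    select(all_of(keys), "correction_factor", "genomes_assayed",
           "event_count", "est") |>
    unnest("est")
}

#' Compare two event rates by the exact conditional test
#'
#' Two Poisson counts with known exposures are compared by conditioning on
#' their total: given \eqn{x_1 + x_2}, \eqn{x_1} is binomial with success
#' probability \eqn{T_1/(T_1+T_2)} under equal rates. The p-value is the
#' exact two-sided binomial test at that null, and the rate-ratio confidence
#' interval is the Clopper-Pearson interval on the binomial proportion
#' transformed to the ratio scale.
#'
#' @param est1,est2 One-row tibbles from [estimate_frequency()]; the ratio
#'   reported is rate1 / rate2 (per amplifiable genome).
#' @param conf_level Confidence level.
#' @return A one-row tibble: `rate_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `x1`, `x2`, `t1`, `t2`. With both counts zero the ratio is undefined
#'   and returned as `NA` with a warning.
#' @examples
#' ht <- estimate_frequency(60, 100000, 1, "CO")
#' ho <- estimate_frequency(110, 100000, 1, "CO")
#' compare_groups(ht, ho)
#' @export
compare_groups <- function(est1, est2, conf_level = 0.95) {
  x1 <- est1$event_count; t1 <- est1$amplifiable_genomes
  x2 <- est2$event_count; t2 <- est2$amplifiable_genomes
  if (x1 + x2 == 0) {
    warn("both counts are zero: rate ratio undefined")
    return(tibble(rate_ratio = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, p_value = NA_real_,
                  x1 = x1, x2 = x2, t1 = t1, t2 = t2))
  }
  p0 <- t1 / (t1 + t2)
  bt <- binom.test(x1, x1 + x2, p = p0, conf.level = conf_level)
  ci_pi <- bt$conf.int
  to_ratio <- function(p) p / (1 - p) * t2 / t1
  tibble(
    rate_ratio = (x1 / t1) / (x2 / t2),
    ci_low = to_ratio(ci_pi[1]),
    ci_high = to_ratio(ci_pi[2]),
    p_value = bt$p.value,
    x1 = x1, x2 = x2, t1 = t1, t2 = t2
  )
}

#' Convert a per-meiosis rate to cM/Mb
#'
#' @param rate_per_meiosis Recombination events per meiosis across the
#'   interval.
#' @param interval_bp Physical span of the interval in bp (> 0).
#' @return Recombination rate in centimorgans per megabase.
#' @examples
#' cm_per_mb(1e-3, 1000) # 100 cM/Mb
#' @export
cm_per_mb <- function(rate_per_meiosis, interval_bp) {
  check_number(interval_bp, "interval_bp")
  if (any(interval_bp <= 0)) abort("interval_bp must be positive")
  rate_per_meiosis * 100 / (interval_bp / 1e6)
}

#' Complex-event rates
#'
#' Summarises complex crossovers (CCO) as a proportion of all scorable
#' crossovers with an exact Clopper-Pearson interval, and converts CCO and
#' complex-conversion counts into rates per amplifiable genome.
#'
#' @param events Event tibble from [call_events()].
#' @param assays Exposure tibble (see [summarize_rates()]).
#' @param conf_level Confidence level.
#' @return A tibble with rows `CCO_per_CO`, `CCO_per_genome`,
#'   `complex_NCO_per_genome`: `n`, `denominator`, `estimate`, `ci_low`,
#'   `ci_high`. With zero CCOs the proportion is 0 with an exact upper
#'   bound.
#' @export
complex_event_rates <- function(events, assays, conf_level = 0.95) {
  sc <- filter(events, .data$scorable)
  n_co <- sum(sc$event_class %in% c("CO", "CCO"))
  n_cco <- sum(sc$event_class == "CCO")
  n_cnco <- sum(sc$event_class == "NCO_complex")
  if (n_co == 0) abort("no scorable crossovers: CCO/CO undefined")
  bt <- binom.test(n_cco, n_co, conf.level = conf_level)
  t_co <- sum(assays$amplifiable_genomes[assays$assay == "CO"])
  t_nco <- sum(assays$amplifiable_genomes[assays$assay == "NCO"])
  cf <- assays$correction_factor[1]
  cco_rate <- estimate_frequency(n_cco, t_co / cf, cf, "CO", conf_level)
  cnco_rate <- estimate_frequency(n_cnco, max(t_nco, 1) / cf, cf, "NCO",
                                  conf_level)
  tibble(
    statistic = c("CCO_per_CO", "CCO_per_genome", "complex_NCO_per_genome"),
    n = c(n_cco, n_cco, n_cnco),
    denominator = c(n_co, t_co, t_nco),
    estimate = c(n_cco / n_co, cco_rate$rate_per_amplifiable_genome,
                 cnco_rate$rate_per_amplifiable_genome),
    ci_low = c(bt$conf.int[1], cco_rate$ci_low, cnco_rate$ci_low),
    ci_high = c(bt$conf.int[2], cco_rate$ci_high, cnco_rate$ci_high)
  )
}
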