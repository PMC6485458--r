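# Biased transmission at heteroduplex sites: stratified Mantel-Haenszel rate
# ratios for GC-biased (strong vs weak) and insertion-biased (long vs short)
# gene conversion, per-site log rate-ratio diagnostics, the transmission
# fraction / population fraction / selection-coefficient chain, and the
# Li-Bulmer equilibrium.

# class ("favored"/"disfavored"/NA) of one transmitted allele under a
# classification; favored = strong (G/C) or long allele
transmitted_class <- function(marker, allele, classification) {
  if (is.na(allele)) return(NA_character_)
  if (classification == "strong_weak") {
    if (marker$kind != "SNP" || !marker$heterozygous) return(NA_character_)
    if (is.na(marker$class_h1) || is.na(marker$class_h2) ||
        marker$class_h1 == marker$class_h2) {
      return(NA_character_)
    }
    cls <- snp_class(allele)
    if (is.na(cls)) return(NA_character_)
    return(if (cls == "strong") "favored" else "disfavored")
  }
  # long_short
  if (marker$kind != "STR" || !marker$heterozygous) return(NA_character_)
  len <- if (allele == marker$allele_h1) {
    marker$length_h1
  } else if (allele == marker$allele_h2) {
    marker$length_h2
  } else {
    return(NA_character_)
  }
  if (len == max(marker$length_h1, marker$length_h2)) "favored" else "disfavored"
}

# the homologue allele transmitted by a crossover reciprocal at its
# breakpoint flanks: RI keeps h1 left of the exchange and h2 right of it
co_flank_alleles <- function(marker_lo, marker_hi, reciprocal) {
  if (reciprocal == "RI") {
    c(marker_lo$allele_h1, marker_hi$allele_h2)
  } else {
    c(marker_lo$allele_h2, marker_hi$allele_h1)
  }
}

# observation class of one reciprocal at one breakpoint interval:
# gBGC needs both flanking SNP classes defined and concordant (the rate
# ratio is then the squared per-site transmission odds); iBGC reads the STR
# site(s) among the flanks
interval_obs_class <- function(marker_lo, marker_hi, reciprocal,
                               classification) {
  al <- co_flank_alleles(marker_lo, marker_hi, reciprocal)
  cls <- c(transmitted_class(marker_lo, al[1], classification),
           transmitted_class(marker_hi, al[2], classification))
  if (classification == "strong_weak") {
    if (any(is.na(cls)) || cls[1] != cls[2]) return(NA_character_)
    return(cls[1])
  }
  defined <- cls[!is.na(cls)]
  if (length(defined) == 0 || length(unique(defined)) != 1) {
    return(NA_character_)
  }
  defined[1]
}

exposure_lookup <- function(assays) {
  function(donor, reciprocal) {
    t <- assays$amplifiable_genomes[assays$donor_id == donor &
                                      assays$reciprocal == reciprocal]
    if (length(t) == 0) {
      stopf("no exposure recorded for donor %s reciprocal %s", donor, reciprocal)
    }
    sum(t)
  }
}

#' Build transmission-bias strata
#'
#' Constructs the stratified counts behind a Mantel-Haenszel transmission
#' analysis. For crossovers the transmitted allele classes are read at the
#' two markers flanking each breakpoint; an inter-marker interval is
#' informative when the two reciprocal products retain complementary allele
#' classes there (one reciprocal a favored pair, the other a disfavored
#' pair), so each stratum contrasts favored against disfavored exchanges
#' under the reciprocal assays' own amplifiable-genome exposures and the
#' positional breakpoint distribution cancels within the stratum. For
#' non-crossovers each converted site contributes the class of the gained
#' allele (co-conversions count at every converted marker), contrasted
#' between the two background homologues.
#'
#' Markers homozygous in a donor carry no contrast and are skipped with a
#' message.
#'
#' @param molecules Molecule tibble.
#' @param events Matching event tibble from [call_events()].
#' @param map The [hotspot_map].
#' @param assays Exposure tibble (`simulate_experiment()$assays`, or bound
#'   rows of several donors).
#' @param classification `"strong_weak"` (gBGC; favored = strong G/C allele)
#'   or `"long_short"` (iBGC; favored = long allele).
#' @param assay `"CO"` or `"NCO"`.
#' @param markers Optional vector of marker positions to restrict the
#'   analysis to (e.g. a single STR).
#' @param stratify `"donor_marker"` (default) or `"donor"`.
#' @return A `bias_strata` tibble: `stratum`, `donor_id`, `marker`,
#'   `x_favored`, `t_favored`, `x_disfavored`, `t_disfavored`, with the
#'   classification recorded in attributes.
#' @seealso [cmh_rate_ratio()], [estimate_transmission_bias()]
#' @export
build_strata <- function(molecules, events, map, assays,
                         classification = c("strong_weak", "long_short"),
                         assay = c("CO", "NCO"), markers = NULL,
                         stratify = c("donor_marker", "donor")) {
  classification <- match.arg(classification)
  assay <- match.arg(assay)
  stratify <- match.arg(stratify)
  stopifnot(inherits(map, "hotspot_map"))
  mk <- map$markers
  expo <- exposure_lookup(assays)

  if (!is.null(markers)) {
    hom <- markers[!mk$heterozygous[match(markers, mk$position)]]
    if (length(hom) > 0) {
      inform(sprintf("marker(s) %s are homozygous in this map and carry no contrast",
                     paste(hom, collapse = ", ")))
    }
  }
  in_subset <- function(pos) is.null(markers) | pos %in% markers

  rows <- list()
  if (assay == "CO") {
    ev <- events |>
      filter(.data$scorable, .data$event_class == "CO", .data$assay == "CO")
    for (i in seq_len(nrow(ev))) {
      lo <- which(mk$position == ev$bp_lo[i])
      hi <- which(mk$position == ev$bp_hi[i])
      if (classification == "strong_weak" &&
          !(in_subset(ev$bp_lo[i]) && in_subset(ev$bp_hi[i]))) next
      if (classification == "long_short" &&
          !any(in_subset(mk$position[c(lo, hi)]) & mk$kind[c(lo, hi)] == "STR")) next
      rec <- ev$reciprocal[i]
      obs <- interval_obs_class(mk[lo, ], mk[hi, ], rec, classification)
      if (is.na(obs)) next
      other <- if (rec == "RI") "RII" else "RI"
      obs_other <- interval_obs_class(mk[lo, ], mk[hi, ], other, classification)
      # informative only when the reciprocals give opposite classes
      if (is.na(obs_other) || obs_other == obs) next
      fav_rec <- if (obs == "favored") rec else other
      dis_rec <- if (obs == "favored") other else rec
      rows[[length(rows) + 1]] <- tibble(
        donor_id = ev$donor_id[i],
        marker = sprintf("%d-%d", ev$bp_lo[i], ev$bp_hi[i]),
        obs = obs,
        orientation = fav_rec,
        t_favored = expo(ev$donor_id[i], fav_rec),
        t_disfavored = expo(ev$donor_id[i], dis_rec)
      )
    }
  } else {
    ev <- events |>
      filter(.data$scorable, .data$assay == "NCO")
    pos_chr <- as.character(mk$position)
    for (i in seq_len(nrow(ev))) {
      conv <- ev$converted[[i]]
      for (p in conv) {
        if (!in_subset(p)) next
        j <- which(mk$position == p)
        gained <- molecules[[as.character(p)]][ev$molecule_id[i]]
        cls <- transmitted_class(mk[j, ], gained, classification)
        if (is.na(cls)) next
        # which homologue carries the favored allele decides the exposures:
        # gains of it are only observable on the other background
        fav_on_h1 <- if (classification == "strong_weak") {
          identical(mk$class_h1[j], "strong")
        } else {
          mk$length_h1[j] > mk$length_h2[j]
        }
        fav_rec <- if (fav_on_h1) "NRII" else "NRI"
        dis_rec <- if (fav_on_h1) "NRI" else "NRII"
        rows[[length(rows) + 1]] <- tibble(
          donor_id = ev$donor_id[i],
          marker = as.character(p),
          obs = cls,
          orientation = fav_rec,
          t_favored = expo(ev$donor_id[i], fav_rec),
          t_disfavored = expo(ev$donor_id[i], dis_rec)
        )
      }
    }
  }

  obs_tbl <- bind_rows(rows)
  if (nrow(obs_tbl) == 0) {
    out <- tibble(stratum = character(), donor_id = character(),
                  marker = character(), orientation = character(),
                  x_favored = integer(), t_favored = numeric(),
                  x_disfavored = integer(), t_disfavored = numeric())
  } else {
    if (stratify == "donor") obs_tbl$marker <- "all"
    out <- obs_tbl |>
      group_by(.data$donor_id, .data$marker, .data$orientation,
               .data$t_favored, .data$t_disfavored) |>
      summarise(
        x_favored = sum(.data$obs == "favored"),
        x_disfavored = sum(.data$obs == "disfavored"),
        .groups = "drop"
      ) |>
      mutate(stratum = paste(.data$donor_id, .data$marker, sep = ":")) |>
      select("stratum", "donor_id", "marker", "orientation", "x_favored",
             "t_favored", "x_disfavored", "t_disfavored")
  }
  structure(out, class = c("bias_strata", class(out)),
            classification = classification, assay = assay,
            favored = if (classification == "strong_weak") "strong" else "long")
}

#' Mantel-Haenszel pooled rate ratio across strata
#'
#' Pools stratified favored/disfavored event counts with their exposures
#' into a common rate ratio using Mantel-Haenszel person-time weights,
#' \deqn{RR = \sum_s x_{f,s} t_{d,s}/t_s \;/\; \sum_s x_{d,s} t_{f,s}/t_s,}
#' with a Greenland-Robins-type variance for the confidence interval and a
#' two-sided p-value from the corresponding chi-square statistic. When the
#' strata carry an `orientation` column (which reciprocal supplies the
#' favored class), the two orientations are pooled separately and combined
#' symmetrically on the log scale: each reciprocal's breakpoint distribution
#' is normalised to its own total, and the balanced combination makes that
#' normalisation cancel, matching the assay's equal-reciprocal design. When
#' a pooled margin is zero the asymptotic variance is undefined and the
#' exact conditional binomial method is used instead (also available on
#' request): conditional on the total event count, the favored count is
#' binomial with the exposure share as null probability.
#'
#' A single stratum reduces exactly to the plain 2x2 rate ratio, and
#' swapping the favored/disfavored labels maps the ratio to its reciprocal.
#'
#' @param strata A `bias_strata` tibble (or any tibble with columns
#'   `x_favored`, `t_favored`, `x_disfavored`, `t_disfavored`).
#' @param conf_level Confidence level.
#' @param method `"rbg"` (default, asymptotic), `"exact"` (conditional
#'   binomial; exact when the exposure ratio is shared across strata).
#' @return An object of class `cmh_rr`: rate ratio, CI, p-value, counts;
#'   supports [tidy()].
#' @examples
#' s <- tibble::tibble(x_favored = c(20, 10), t_favored = c(1e5, 5e4),
#'                     x_disfavored = c(10, 5), t_disfavored = c(1e5, 5e4))
#' cmh_rate_ratio(s)
#' @export
cmh_rate_ratio <- function(strata, conf_level = 0.95,
                           method = c("rbg", "exact")) {
  method <- match.arg(method)
  req <- c("x_favored", "t_favored", "x_disfavored", "t_disfavored")
  stopifnot(all(req %in% names(strata)))
  s <- as_tibble(strata)[req]
  if (nrow(s) == 0 || sum(s$x_favored) + sum(s$x_disfavored) == 0) {
    abort("no events in any stratum: rate ratio undefined")
  }
  xf <- sum(s$x_favored)
  xd <- sum(s$x_disfavored)
  tf <- sum(s$t_favored)
  td <- sum(s$t_disfavored)

  # Mantel-Haenszel numerator/denominator and variance kernel per group
  mh_parts <- function(g) {
    tt <- g$t_favored + g$t_disfavored
    list(num = sum(g$x_favored * g$t_disfavored / tt),
         den = sum(g$x_disfavored * g$t_favored / tt),
         vk = sum((g$x_favored + g$x_disfavored) * g$t_favored *
                    g$t_disfavored / tt^2))
  }
  orientation <- if ("orientation" %in% names(strata)) {
    as.character(strata$orientation)
  } else {
    rep("all", nrow(s))
  }
  groups <- split(s, orientation)

  single <- mh_parts(s)
  if (method == "rbg" && length(groups) == 1 &&
      (single$num == 0 || single$den == 0)) {
    inform("zero pooled margin: falling back to the exact conditional method")
    method <- "exact"
  }
  if (method == "rbg") {
    # combine the two reciprocal orientations symmetrically on the log
    # scale, so the per-reciprocal normalisation of breakpoint positions
    # cancels; a single orientation reduces to the plain MH estimate
    parts <- map(groups, mh_parts)
    corrected <- any(map_lgl(parts, ~ .x$num == 0 || .x$den == 0)) &&
      length(parts) > 1
    logs <- map_dbl(parts, function(p) {
      cc <- if (p$num == 0 || p$den == 0) 0.5 else 0
      log((p$num + cc) / (p$den + cc))
    })
    vars <- map_dbl(parts, function(p) {
      cc <- if (p$num == 0 || p$den == 0) 0.5 else 0
      p$vk / ((p$num + cc) * (p$den + cc))
    })
    log_rr <- mean(logs)
    v <- sum(vars) / length(parts)^2
    rr <- exp(log_rr)
    z <- qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log_rr + c(-1, 1) * z * sqrt(v))
    p <- 2 * pnorm(-abs(log_rr) / sqrt(v))
  } else {
    p0 <- tf / (tf + td)
    bt <- binom.test(xf, xf + xd, p = p0, conf.level = conf_level)
    to_rr <- function(pi) pi / (1 - pi) * td / tf
    ci <- c(to_rr(bt$conf.int[1]), to_rr(bt$conf.int[2]))
    p <- bt$p.value
    rr <- (xf / tf) / (xd / td) # conditional estimate uses pooled counts
    if (nrow(s) > 1 && length(unique(round(s$t_favored / s$t_disfavored, 9))) > 1) {
      warn("exact method pools exposures although the exposure ratio varies across strata")
    }
  }
  structure(
    list(rate_ratio = rr, ci_low = ci[1], ci_high = ci[2], p_value = p,
         method = method, n_strata = nrow(s), x_favored = xf,
         x_disfavored = xd,
         classification = attr(strata, "classification"),
         favored = attr(strata, "favored")),
    class = "cmh_rr"
  )
}

#' @export
print.cmh_rr <- function(x, ...) {
  cat("<cmh_rr> RR = ", signif(x$rate_ratio, 4), " [",
      signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "], p = ",
      format.pval(x$p_value, digits = 3), " (", x$n_strata, " strata, ",
      x$method, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.cmh_rr <- function(x, ...) {
  tibble(
    rate_ratio = x$rate_ratio, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, n_strata = x$n_strata,
    x_favored = x$x_favored, x_disfavored = x$x_disfavored,
    method = x$method
  )
}

#' Per-site log rate ratio between reciprocals
#'
#' Diagnostic of allele-specific transmission in crossover products: for
#' each marker and allele the log rate ratio
#' \eqn{\log[(n_{RI}/tot_{RI}) / (n_{RII}/tot_{RII})]} compares the two
#' reciprocal recombinant haplotypes, i.e. RI molecules carrying the allele
#' against RII molecules carrying the complementary allele of the same
#' marker — under Mendelian transmission the two fractions are equal at
#' every marker, whatever the breakpoint distribution. A standardized
#' Pearson residual from the marker's 2x2 table gives significance stars at
#' p < 0.05 / 0.01 / 0.001. Zero cells get a 0.5 continuity correction for
#' the log ratio only, and are flagged.
#'
#' @param molecules Molecule tibble (CO assay molecules are used).
#' @param events Matching event tibble; only scorable crossovers enter.
#' @param map The [hotspot_map].
#' @param by_donor Compute per donor (default) or pooled.
#' @return A tibble: `donor_id`, `position`, `allele`, `n_ri`, `n_rii`,
#'   `logrr`, `residual`, `p_value`, `stars`, `corrected`.
#' @export
logrr_per_site <- function(molecules, events, map, by_donor = TRUE) {
  keep <- events |>
    filter(.data$scorable, .data$event_class %in% c("CO", "CCO"))
  mol <- molecules[keep$molecule_id, ]
  if (nrow(mol) == 0) abort("no scorable crossovers")
  mk <- map$markers
  donors <- if (by_donor) unique(mol$donor_id) else "all"
  out <- list()
  for (d in donors) {
    sub <- if (by_donor) filter(mol, .data$donor_id == d) else mol
    tot <- c(RI = sum(sub$reciprocal == "RI"), RII = sum(sub$reciprocal == "RII"))
    if (any(tot == 0)) next
    for (j in seq_len(nrow(mk))) {
      if (!mk$heterozygous[j]) next
      calls <- sub[[as.character(mk$position[j])]]
      alleles <- c(mk$allele_h1[j], mk$allele_h2[j])
      for (ai in 1:2) {
        allele <- alleles[ai]
        other <- alleles[3 - ai]
        # the two reciprocal haplotypes carry complementary alleles on the
        # same side of the exchange, so RI molecules with this allele are
        # compared against RII molecules with the other one: the Mendelian
        # expectation is equality at every marker
        n_ri <- sum(calls == allele & sub$reciprocal == "RI", na.rm = TRUE)
        n_rii <- sum(calls == other & sub$reciprocal == "RII", na.rm = TRUE)
        cells <- c(n_ri, tot[["RI"]] - n_ri, n_rii, tot[["RII"]] - n_rii)
        corrected <- any(cells == 0)
        cc <- if (corrected) cells + 0.5 else cells
        logrr <- log((cc[1] / (cc[1] + cc[2])) / (cc[3] / (cc[3] + cc[4])))
        resid <- tryCatch({
          suppressWarnings(
            chisq.test(matrix(cells, 2, byrow = TRUE), correct = FALSE)
          )$stdres[1, 1]
        }, error = function(e) NA_real_)
        p <- if (is.na(resid)) NA_real_ else 2 * pnorm(-abs(resid))
        out[[length(out) + 1]] <- tibble(
          donor_id = d, position = mk$position[j], allele = allele,
          n_ri = n_ri, n_rii = n_rii, logrr = logrr, residual = resid,
          p_value = p, stars = p_stars(p), corrected = corrected
        )
      }
    }
  }
  bind_rows(out)
}

#' Transmission-fraction chain
#'
#' Translates a favored-class rate ratio into the fraction of recombinant
#' molecules transmitting the favored allele,
#' \eqn{F_{xR} = \sqrt{RR}/(1+\sqrt{RR})} (50\% is equal transmission), the
#' population-wide transmitted fraction
#' \eqn{F_{x,total} = 0.5(1-c) + c\,F_{xR}} for a recombinant fraction `c`
#' of all gametes, and the equivalent selection coefficient
#' \eqn{b = 2F_{x,total} - 1}.
#'
#' The square root is exact for the crossover design, where the rate ratio
#' multiplies the transmission odds at the two breakpoint-flanking sites;
#' for single-site designs (converted NCO sites, a single STR) the
#' first-power mapping \eqn{RR/(1+RR)} is available as
#' `convention = "linear"`.
#'
#' @param rr Rate ratio(s), >= 0.
#' @param c_rate Recombinant products per amplifiable genome
#'   (meiosis-normalised), in `[0, 1]`.
#' @param convention `"sqrt"` (default) or `"linear"`.
#' @return A tibble: `rate_ratio`, `fx_r`, `c`, `fx_total`, `b`.
#' @examples
#' fx_chain(1.27, 2.5e-3) # fx_r = 0.52984 -> 53.0%
#' fx_chain(0, 1.1e-3)    # complete loss of the favored allele
#' @export
fx_chain <- function(rr, c_rate = 0, convention = c("sqrt", "linear")) {
  convention <- match.arg(convention)
  check_number(rr, "rr", lower = 0)
  check_probability(c_rate, "c_rate")
  fx_r <- if (convention == "sqrt") {
    sqrt(rr) / (1 + sqrt(rr))
  } else {
    rr / (1 + rr)
  }
  fx_total <- 0.5 * (1 - c_rate) + c_rate * fx_r
  tibble(rate_ratio = rr, fx_r = fx_r, c = c_rate,
         fx_total = fx_total, b = 2 * fx_total - 1)
}

#' Li-Bulmer equilibrium allele composition
#'
#' Expected equilibrium fraction of the favored state under opposing
#' mutation bias \eqn{\kappa} and a conversion-driven selection-coefficient
#' equivalent \eqn{b} in a population of effective size \eqn{N_e}:
#' \deqn{1 / (1 + \kappa e^{-2 N_e b}).}
#'
#' @param kappa Mutation-rate ratio of the opposing mutations (> 0).
#' @param ne Effective population size (> 0).
#' @param b Selection-coefficient equivalent of the transmission bias.
#' @return Equilibrium fraction in (0, 1).
#' @examples
#' li_bulmer_equilibrium(1, 1e4, 0)      # 0.5
#' li_bulmer_equilibrium(2, 1e4, 2.7e-4) # biased conversion wins
#' @export
li_bulmer_equilibrium <- function(kappa, ne, b) {
  check_number(kappa, "kappa")
  check_number(ne, "ne")
  if (any(kappa <= 0)) abort("kappa must be positive")
  if (any(ne <= 0)) abort("ne must be positive")
  1 / (1 + kappa * exp(-2 * ne * b))
}

#' Estimate transmission bias for one analysis group
#'
#' One-stop wrapper reproducing a transmission-bias table row: builds the
#' strata, pools them into a Mantel-Haenszel rate ratio, computes the
#' recombinant fraction `c` (events per amplifiable genome times the meiosis
#' multiplier: 2 for CO, 1 for NCO) and runs the transmission-fraction
#' chain.
#'
#' @inheritParams build_strata
#' @param method CI/p method passed to [cmh_rate_ratio()].
#' @param convention Passed to [fx_chain()].
#' @param conf_level Confidence level.
#' @return A one-row `bias_result` tibble: `classification`, `assay`,
#'   `rate_ratio`, `ci_low`, `ci_high`, `p_value`, `fx_r`, `c`, `fx_total`,
#'   `b`, `n_strata`, `x_favored`, `x_disfavored`.
#' @examples
#' d <- donor_profile("d1", "Ht")
#' ex <- simulate_experiment(d, sim_params(seed = 11))
#' ev <- call_events(ex$molecules, d$map)
#' estimate_transmission_bias(ex$molecules, ev, d$map, ex$assays)
#' @export
estimate_transmission_bias <- function(molecules, events, map, assays,
                                       classification = c("strong_weak", "long_short"),
                                       assay = c("CO", "NCO"),
                                       markers = NULL,
                                       stratify = c("donor_marker", "donor"),
                                       method = c("rbg", "exact"),
                                       convention = c("sqrt", "linear"),
                                       conf_level = 0.95) {
  classification <- match.arg(classification)
  assay <- match.arg(assay)
  strata <- build_strata(molecules, events, map, assays, classification,
                         assay, markers, match.arg(stratify))
  rr <- cmh_rate_ratio(strata, conf_level, match.arg(method))

  classes <- if (assay == "CO") c("CO", "CCO") else
    c("NCO_simple", "NCO_co", "NCO_complex")
  n_events <- sum(events$scorable & events$event_class %in% classes)
  t_total <- sum(assays$amplifiable_genomes[assays$assay == assay])
  mult <- if (assay == "CO") 2 else 1
  c_rate <- min(1, mult * n_events / t_total)

  fx <- fx_chain(rr$rate_ratio, c_rate, match.arg(convention))
  out <- tibble(
    classification = classification, assay = assay,
    rate_ratio = rr$rate_ratio, ci_low = rr$ci_low, ci_high = rr$ci_high,
    p_value = rr$p_value, fx_r = fx$fx_r, c = c_rate,
    fx_total = fx$fx_total, b = fx$b, n_strata = rr$n_strata,
    x_favored = rr$x_favored, x_disfavored = rr$x_disfavored
  )
  class(out) <- c("bias_result", class(out))
  out
}
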