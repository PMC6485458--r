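# Classification of recombinant molecules into crossover breakpoints and
# simple / co- / complex conversions, with conversion-tract bounds.

# phase of each call against the map: 1 = haplotype 1 allele, 2 = haplotype 2,
# NA = missing, homozygous (uninformative) or unrecognised
call_phases <- function(calls, map) {
  mk <- map$markers
  ph <- rep(NA_integer_, nrow(mk))
  informative <- mk$heterozygous & !is.na(calls) & calls != "."
  ph[informative & calls == mk$allele_h1] <- 1L
  ph[informative & calls == mk$allele_h2] <- 2L
  unknown <- informative & is.na(ph)
  list(phase = ph, unknown = any(unknown))
}

empty_event_row <- function() {
  tibble(
    event_class = NA_character_, scorable = FALSE, reason = NA_character_,
    bp_lo = NA_real_, bp_hi = NA_real_,
    converted = list(numeric(0)), unconverted_internal = list(numeric(0)),
    n_converted = 0L, tract_min = NA_real_, tract_max = NA_real_,
    tract_mid = NA_real_
  )
}

classify_one <- function(calls, assay, reciprocal, map) {
  out <- empty_event_row()
  ph_info <- call_phases(calls, map)
  if (ph_info$unknown) {
    out$reason <- "unknown_allele"
    return(out)
  }
  ph <- ph_info$phase
  pos <- map$markers$position
  inf <- which(!is.na(ph))
  if (length(inf) < 2) {
    out$reason <- "too_few_informative"
    return(out)
  }
  runs <- rle(ph[inf])
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1

  if (assay == "CO") {
    if (length(runs$values) == 1) {
      out$reason <- "no_phase_switch"
      return(out)
    }
    if (runs$values[1] == runs$values[length(runs$values)]) {
      # flanks concordant: a conversion pattern, not a crossover
      out$reason <- "conversion_pattern"
      return(out)
    }
    out$scorable <- TRUE
    # breakpoint uncertainty interval: between the end of the leading flank
    # run and the start of the trailing flank run
    out$bp_lo <- pos[inf[ends[1]]]
    out$bp_hi <- pos[inf[starts[length(starts)]]]
    if (length(runs$values) == 2) {
      out$event_class <- "CO"
    } else {
      out$event_class <- "CCO"
      # interior markers between the two flank runs form the discordant region
      interior <- seq(ends[1] + 1, starts[length(starts)] - 1)
      disc <- inf[interior]
      out$converted <- list(pos[disc])
      out$n_converted <- length(disc)
    }
    return(out)
  }

  # NCO assay
  background <- if (reciprocal == "NRI") 1L else 2L
  if (ph[inf[1]] != background || ph[inf[length(inf)]] != background) {
    out$reason <- "flank_discordant"
    return(out)
  }
  conv_idx <- inf[ph[inf] != background]
  if (length(conv_idx) == 0) {
    out$reason <- "no_conversion"
    return(out)
  }
  span <- inf[inf >= min(conv_idx) & inf <= max(conv_idx)]
  unconv <- span[ph[span] == background]
  out$scorable <- TRUE
  out$converted <- list(pos[conv_idx])
  out$unconverted_internal <- list(pos[unconv])
  out$n_converted <- length(conv_idx)
  out$event_class <- if (length(unconv) > 0) {
    "NCO_complex"
  } else if (length(conv_idx) >= 2) {
    "NCO_co"
  } else {
    "NCO_simple"
  }

  # conversion-tract bounds from the nearest informative unconverted flanks
  left_flank <- inf[inf < min(conv_idx)]
  right_flank <- inf[inf > max(conv_idx)]
  out$tract_min <- pos[max(conv_idx)] - pos[min(conv_idx)] + 1
  if (length(left_flank) > 0 && length(right_flank) > 0) {
    out$tract_max <- pos[min(right_flank)] - pos[max(left_flank)] - 1
    out$tract_mid <- (out$tract_min + out$tract_max) / 2
  } else {
    out$reason <- "tract_unbounded"
  }
  out
}

#' Classify recombinant molecules
#'
#' Calls every molecule of a molecule table against its hotspot map:
#' crossovers (CO) get a breakpoint interval between the last marker of the
#' left-flank phase and the first marker of the right-flank phase; crossovers
#' with an additional discordant block are complex crossovers (CCO);
#' non-crossovers are partitioned into simple conversions (one converted
#' marker), co-conversions (two or more converted, no internal unconverted
#' marker) and complex conversions (an unconverted marker between converted
#' ones). Unscorable molecules are kept with a reason code so that
#' denominators stay explicit.
#'
#' @param molecules Molecule tibble as produced by [simulate_experiment()]
#'   or [read_molecules()].
#' @param map The [hotspot_map] the calls refer to.
#' @return A tibble with one row per molecule: identifiers, `event_class`
#'   (`CO`, `CCO`, `NCO_simple`, `NCO_co`, `NCO_complex` or `NA`),
#'   `scorable`, `reason`, breakpoint interval (`bp_lo`, `bp_hi`), converted
#'   and internal unconverted marker positions (list columns) and
#'   conversion-tract bounds `tract_min`, `tract_max`, `tract_mid` (bp).
#' @seealso [call_co_breakpoint()], [call_nco()], [tract_length()]
#' @examples
#' d <- donor_profile("d1", "Ht")
#' ex <- simulate_experiment(d, sim_params(seed = 7, n_pools_co = 30))
#' ev <- call_events(ex$molecules, d$map)
#' dplyr::count(ev, event_class)
#' @export
call_events <- function(molecules, map) {
  stopifnot(inherits(map, "hotspot_map"))
  cols <- marker_cols(molecules)
  map_pos <- as.character(map$markers$position)
  if (!setequal(cols, map_pos)) {
    abort("molecule marker columns do not match the map positions")
  }
  call_mat <- as.matrix(molecules[, map_pos, drop = FALSE])
  meta <- molecules |>
    select(any_of(c("donor_id", "assay", "reciprocal", "pool_id"))) |>
    mutate(molecule_id = dplyr::row_number(), .before = 1)
  rows <- vector("list", nrow(molecules))
  for (i in seq_len(nrow(molecules))) {
    rows[[i]] <- classify_one(call_mat[i, ], molecules$assay[i],
                              molecules$reciprocal[i], map)
  }
  bind_cols(meta, bind_rows(rows))
}

#' Call a single crossover breakpoint
#'
#' @param molecule A one-row molecule tibble from a CO assay.
#' @param map The [hotspot_map].
#' @return A one-row event tibble (see [call_events()]); molecules without a
#'   scorable phase switch are returned flagged `scorable = FALSE` with a
#'   reason code, never dropped.
#' @examples
#' d <- donor_profile("d1", "Ht")
#' ex <- simulate_experiment(d, sim_params(seed = 3, n_pools_co = 50))
#' co <- dplyr::filter(ex$molecules, assay == "CO")[1, ]
#' call_co_breakpoint(co, d$map)
#' @export
call_co_breakpoint <- function(molecule, map) {
  stopifnot(nrow(molecule) == 1)
  if (molecule$assay != "CO") abort("molecule is not from a CO assay")
  call_events(molecule, map)
}

#' Call a single non-crossover conversion
#'
#' @inheritParams call_co_breakpoint
#' @return A one-row event tibble. A molecule with no converted internal
#'   marker is an error: it is not an NCO.
#' @export
call_nco <- function(molecule, map) {
  stopifnot(nrow(molecule) == 1)
  if (molecule$assay != "NCO") abort("molecule is not from an NCO assay")
  out <- call_events(molecule, map)
  if (!is.na(out$reason) && out$reason == "no_conversion") {
    abort("molecule has no converted marker: not an NCO")
  }
  out
}

#' Conversion-tract length bounds
#'
#' For an NCO call the tract length is only known up to the informative
#' markers: the minimum spans the converted markers themselves, the maximum
#' reaches the nearest informative unconverted markers on either side, and
#' the midpoint of the two is the summary used as "mean tract length".
#'
#' @param call A one-row event tibble for a scorable NCO.
#' @param summary Either `"midpoint"` (default) or `"maximum"`, the statistic
#'   reported as `tract_length`.
#' @return A one-row tibble `tract_min`, `tract_max`, `tract_mid`,
#'   `tract_length`.
#' @examples
#' d <- donor_profile("d1", "Ht")
#' ex <- simulate_experiment(d, sim_params(seed = 5, n_pools_nco = 200))
#' ev <- call_events(ex$molecules, d$map)
#' nco <- dplyr::filter(ev, scorable, grepl("NCO", event_class))
#' if (nrow(nco) > 0) tract_length(nco[1, ])
#' @export
tract_length <- function(call, summary = c("midpoint", "maximum")) {
  summary <- match.arg(summary)
  stopifnot(nrow(call) == 1)
  if (!isTRUE(call$scorable) || !grepl("^NCO", call$event_class)) {
    abort("tract_length needs a scorable NCO call")
  }
  if (is.na(call$tract_max)) {
    warn("tract maximum undefined: converted marker at the map edge")
  }
  tibble(
    tract_min = call$tract_min,
    tract_max = call$tract_max,
    tract_mid = call$tract_mid,
    tract_length = if (summary == "midpoint") call$tract_mid else call$tract_max
  )
}

#' Breakpoint histogram per reciprocal
#'
#' Counts crossover breakpoints per inter-marker interval and reciprocal and
#' adds counts rescaled so that both reciprocals contribute equal totals, the
#' normalisation used when plotting reciprocal breakpoint distributions.
#'
#' @param events Event tibble from [call_events()].
#' @param map The [hotspot_map].
#' @return A tibble: `bp_lo`, `bp_hi`, `reciprocal`, `n`, `n_normalized`.
#' @export
breakpoint_histogram <- function(events, map) {
  co <- events |> filter(.data$scorable, .data$event_class %in% c("CO", "CCO"))
  if (nrow(co) == 0) abort("no scorable crossovers in `events`")
  counts <- co |>
    count(.data$bp_lo, .data$bp_hi, .data$reciprocal, name = "n") |>
    group_by(.data$reciprocal) |>
    mutate(total = sum(.data$n)) |>
    ungroup()
  target <- mean(unique(counts$total))
  counts |>
    mutate(n_normalized = .data$n / .data$total * target) |>
    select(-"total") |>
    arrange(.data$bp_lo, .data$reciprocal)
}
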