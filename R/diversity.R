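# Population-diversity summaries of STR loci and their comparison across
# hotspot/flank zones.

#' Per-locus STR diversity summaries
#'
#' For each locus the allele spectrum (counts per allele length) is reduced
#' to four diversity measures: expected heterozygosity
#' \eqn{1 - \sum_i p_i^2}, allelic asymmetry (longest minus shortest
#' allele), the step sizes between successive allele lengths, and the number
#' of distinct alleles. Allele lengths above `cap` are pooled at `cap`.
#'
#' @param loci Tibble with columns `contig`, `position`, `allele_length`,
#'   `count`.
#' @param cap Length cap (default 26).
#' @return A tibble with one row per locus: `contig`, `position`,
#'   `heterozygosity`, `asymmetry`, `n_alleles`, `step_sizes` (list column)
#'   and `n_obs`.
#' @examples
#' loci <- tibble::tibble(contig = "chr16", position = 6360903,
#'                        allele_length = c(9, 19), count = c(5, 5))
#' diversity_summary(loci) # heterozygosity 0.5, asymmetry 10
#' @export
diversity_summary <- function(loci, cap = 26) {
  stopifnot(all(c("contig", "position", "allele_length", "count") %in%
                  names(loci)))
  if (nrow(loci) == 0) abort("empty allele spectrum")
  if (any(loci$count < 0)) abort("allele counts must be >= 0")
  loci |>
    mutate(allele_length = pmin(.data$allele_length, cap)) |>
    group_by(.data$contig, .data$position, .data$allele_length) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    filter(.data$count > 0) |>
    group_by(.data$contig, .data$position) |>
    summarise(
      heterozygosity = 1 - sum((.data$count / sum(.data$count))^2),
      asymmetry = max(.data$allele_length) - min(.data$allele_length),
      n_alleles = dplyr::n(),
      step_sizes = list(diff(sort(unique(.data$allele_length)))),
      n_obs = sum(.data$count),
      .groups = "drop"
    )
}

#' Compare STR diversity between hotspot and flanking zones
#'
#' Assigns each locus to a zone by position and tests each diversity
#' measure between hotspot loci and pooled flanking loci with a
#' Kruskal-Wallis rank test (step sizes are compared through their mean per
#' locus).
#'
#' @param loci Allele-spectrum tibble (see [diversity_summary()]).
#' @param zones A `zone_set` from [build_zones()].
#' @param cap Length cap passed to [diversity_summary()].
#' @return A list: `summaries` (per-locus measures with their zone group)
#'   and `tests` (one row per measure: `statistic`, `df`, `p_value`,
#'   `n_hotspot`, `n_flank`). Measures that cannot be compared (all loci in
#'   one group) are returned with `NA` statistics and a warning.
#' @export
diversity_by_zone <- function(loci, zones, cap = 26) {
  summ <- diversity_summary(loci, cap)
  idx <- assign_zone_rows(
    tibble(contig = summ$contig, start = summ$position), zones
  )
  summ <- summ |>
    mutate(
      zone = ifelse(is.na(idx), NA, zones$zone[idx]),
      group = case_when(
        zone == "hotspot" ~ "hotspot",
        grepl("^flank", zone) ~ "flank",
        TRUE ~ NA_character_
      ),
      mean_step = map_dbl(.data$step_sizes,
                          ~ if (length(.x) == 0) NA_real_ else mean(.x))
    ) |>
    filter(!is.na(.data$group))

  measures <- c("heterozygosity", "asymmetry", "n_alleles", "mean_step")
  tests <- map(measures, function(m) {
    vals <- split(summ[[m]], summ$group)
    vals <- map(vals, ~ .x[!is.na(.x)])
    if (length(vals) < 2 || any(lengths(vals) == 0)) {
      warn(sprintf("comparison undefined for %s: a zone group is empty", m))
      return(tibble(measure = m, statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_,
                    n_hotspot = length(vals$hotspot %||% numeric(0)),
                    n_flank = length(vals$flank %||% numeric(0))))
    }
    kw <- kruskal.test(list(vals$hotspot, vals$flank))
    tibble(measure = m, statistic = unname(kw$statistic),
           df = unname(kw$parameter), p_value = kw$p.value,
           n_hotspot = length(vals$hotspot), n_flank = length(vals$flank))
  }) |> list_rbind()

  list(summaries = summ, tests = tests)
}
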