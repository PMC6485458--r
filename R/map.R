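#' Construct a hotspot map
#'
#' A hotspot map is the coordinate frame for every downstream analysis: an
#' ordered set of phased heterozygous markers (SNPs and short tandem repeats)
#' on one contig, together with the position of the PRDM9 binding motif and
#' the hotspot interval. Coordinates are 1-based and inclusive throughout the
#' package.
#'
#' @param markers A data frame with one row per marker and columns
#'   `position` (1-based bp), `kind` (`"SNP"` or `"STR"`), `allele_h1`,
#'   `allele_h2` (allele text, e.g. `"G"` or `"19A"`), and for STRs
#'   `length_h1`, `length_h2` (repeat units). Strong/weak classes for SNP
#'   alleles are derived from the bases (G/C strong, A/T weak).
#' @param contig Contig label, e.g. `"chr16"`.
#' @param motif_position 1-based position of the first base of the PRDM9
#'   motif. Must fall inside `hotspot_interval`.
#' @param hotspot_interval Length-2 numeric, closed bp interval of the
#'   hotspot.
#'
#' @return An object of class `hotspot_map`: a list with elements `contig`,
#'   `markers` (a tibble with derived columns `class_h1`, `class_h2`,
#'   `heterozygous`), `motif_position` and `hotspot_interval`.
#'
#' @examples
#' map <- build_default_map()
#' map$markers
#' @export
hotspot_map <- function(markers, contig, motif_position, hotspot_interval) {
  markers <- as_tibble(markers)
  required <- c("position", "kind", "allele_h1", "allele_h2")
  missing <- setdiff(required, names(markers))
  if (length(missing) > 0) {
    stopf("markers is missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (!"length_h1" %in% names(markers)) markers$length_h1 <- NA_real_
  if (!"length_h2" %in% names(markers)) markers$length_h2 <- NA_real_

  markers <- markers |>
    arrange(.data$position) |>
    mutate(
      kind = as.character(.data$kind),
      class_h1 = if_else(.data$kind == "SNP", snp_class(.data$allele_h1), NA_character_),
      class_h2 = if_else(.data$kind == "SNP", snp_class(.data$allele_h2), NA_character_),
      heterozygous = .data$allele_h1 != .data$allele_h2
    )

  if (any(duplicated(markers$position)) || is.unsorted(markers$position, strictly = TRUE)) {
    abort("marker positions must be strictly increasing")
  }
  bad_snp <- markers$kind == "SNP" &
    (nchar(markers$allele_h1) != 1 | nchar(markers$allele_h2) != 1)
  if (any(bad_snp)) abort("SNP alleles must be single bases")
  bad_str <- markers$kind == "STR" &
    (is.na(markers$length_h1) | is.na(markers$length_h2) |
       markers$length_h1 < 1 | markers$length_h2 < 1)
  if (any(bad_str)) abort("STR markers need repeat lengths >= 1 on both haplotypes")
  if (length(hotspot_interval) != 2 || hotspot_interval[1] > hotspot_interval[2]) {
    abort("hotspot_interval must be c(lo, hi) with lo <= hi")
  }
  if (motif_position < hotspot_interval[1] || motif_position > hotspot_interval[2]) {
    abort("motif_position must lie inside hotspot_interval")
  }

  structure(
    list(
      contig = contig,
      markers = markers,
      motif_position = motif_position,
      hotspot_interval = as.numeric(hotspot_interval)
    ),
    class = "hotspot_map"
  )
}

#' @export
print.hotspot_map <- function(x, ...) {
  cat("<hotspot_map> ", x$contig, ":",
      format(x$hotspot_interval[1], big.mark = ","), "-",
      format(x$hotspot_interval[2], big.mark = ","), "\n", sep = "")
  cat("  motif at ", format(x$motif_position, big.mark = ","),
      "; ", sum(x$markers$kind == "SNP"), " SNPs, ",
      sum(x$markers$kind == "STR"), " STRs\n", sep = "")
  invisible(x)
}

#' Default hotspot map (HSII-like layout)
#'
#' Builds a map emulating a chromosome-16 hotspot with an average density of
#' about 4 heterozygous SNPs per kb over ~3 kb and three poly-A repeats:
#' a 6A/7A repeat 490 bp upstream, an asymmetric 9A/19A repeat 154 bp
#' upstream, and a homozygous 23A repeat 239 bp downstream of the first base
#' of the central PRDM9 motif.
#'
#' Haplotype 1 carries the shorter poly-A alleles (6A and 9A). SNP alleles
#' were chosen so that strong (G/C) and weak (A/T) alleles are balanced
#' between haplotypes and most adjacent SNP pairs are informative for
#' GC-biased transmission; one SNP is a strong/strong (G/C) polymorphism,
#' which is phase-informative but carries no strong/weak contrast, as is
#' common in real marker sets.
#'
#' @param motif_position Position of the first motif base (default
#'   6,361,057).
#' @return A [hotspot_map].
#' @examples
#' build_default_map()
#' @export
build_default_map <- function(motif_position = 6361057) {
  offs <- c(-1450, -1200, -950, -700, -490, -350, -154, -50,
            100, 239, 380, 600, 850, 1100, 1350)
  markers <- tibble(
    position = motif_position + offs,
    kind = c("SNP", "SNP", "SNP", "SNP", "STR", "SNP", "STR", "SNP",
             "SNP", "STR", "SNP", "SNP", "SNP", "SNP", "SNP"),
    allele_h1 = c("G", "T", "C", "G", "6A", "A", "9A", "C",
                  "T", "23A", "G", "A", "G", "T", "C"),
    allele_h2 = c("A", "C", "T", "T", "7A", "G", "19A", "A",
                  "G", "23A", "C", "C", "A", "G", "T"),
    length_h1 = c(NA, NA, NA, NA, 6, NA, 9, NA, NA, 23, NA, NA, NA, NA, NA),
    length_h2 = c(NA, NA, NA, NA, 7, NA, 19, NA, NA, 23, NA, NA, NA, NA, NA)
  )
  hotspot_map(
    markers,
    contig = "chr16",
    motif_position = motif_position,
    hotspot_interval = motif_position + c(-1600, 1500)
  )
}

#' Describe a sperm donor
#'
#' A donor profile fixes the donor's genotype at the central asymmetric
#' poly-A (heterozygous 9A/19A, group `"Ht"`, or homozygous 19A/19A, group
#' `"Ho"`) and the donor-specific amplifiable-genome correction factor of the
#' pooled typing assay.
#'
#' @param donor_id Donor label.
#' @param group `"Ht"` (9A/19A heterozygous) or `"Ho"` (19A homozygous).
#' @param map A [hotspot_map]; for `"Ho"` donors the central long-heterology
#'   STR is made homozygous for the long allele.
#' @param correction_factor Fraction of assayed genomes that are amplifiable,
#'   in (0, 1]. Reported assay efficiencies fall between 0.10 and 0.35.
#' @return An object of class `donor_profile`.
#' @examples
#' donor_profile("d1", "Ht")
#' donor_profile("d5", "Ho", correction_factor = 0.2)
#' @export
donor_profile <- function(donor_id, group = c("Ht", "Ho"),
                          map = build_default_map(),
                          correction_factor = 0.25) {
  group <- match.arg(group)
  check_number(correction_factor, "correction_factor")
  if (correction_factor <= 0 || correction_factor > 1) {
    abort("correction_factor must be in (0, 1]")
  }
  stopifnot(inherits(map, "hotspot_map"))
  if (group == "Ho") {
    mk <- map$markers
    central <- which(mk$kind == "STR" & mk$heterozygous &
                       abs(mk$length_h1 - mk$length_h2) > 2)
    if (length(central) > 0) {
      long_allele <- if_else(mk$length_h1[central] >= mk$length_h2[central],
                             mk$allele_h1[central], mk$allele_h2[central])
      long_len <- pmax(mk$length_h1[central], mk$length_h2[central])
      mk$allele_h1[central] <- long_allele
      mk$allele_h2[central] <- long_allele
      mk$length_h1[central] <- long_len
      mk$length_h2[central] <- long_len
      mk$heterozygous[central] <- FALSE
    }
    map$markers <- mk
  }
  structure(
    list(donor_id = donor_id, group = group, map = map,
         correction_factor = correction_factor),
    class = "donor_profile"
  )
}

#' @export
print.donor_profile <- function(x, ...) {
  cat("<donor_profile> ", x$donor_id, " (", x$group,
      "), correction factor ", x$correction_factor, "\n", sep = "")
  invisible(x)
}
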