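# Perfect mononucleotide-run detection and hotspot/flank zone enrichment.

#' Find perfect mononucleotide runs
#'
#' Scans sequence for maximal perfect runs of one base (default A) of a
#' minimum length (default 6). Matching is case-insensitive; any other
#' character, including N, breaks a run. Runs longer than `cap` keep their
#' true length but get a capped length class for pooled reporting.
#'
#' @param x A named character vector of sequences, a `Biostrings`
#'   DNAString/DNAStringSet, or a single unnamed string (contig `"seq1"`).
#' @param base Single base to scan for (`"A"` or `"T"` in practice).
#' @param min_len Minimum run length to report (>= 1), default 6.
#' @param cap Length class cap, default 26.
#' @return A tibble: `contig`, `start`, `end` (1-based inclusive), `base`,
#'   `length`, `capped_length`.
#' @examples
#' find_runs("CCAAAAAATT")          # one run at 3-8
#' find_runs("AAAAA")               # below the length threshold
#' @export
find_runs <- function(x, base = "A", min_len = 6, cap = 26) {
  if (inherits(x, "DNAString")) x <- as.character(x)
  if (inherits(x, "DNAStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  stopifnot(is.character(x))
  if (is.null(names(x))) {
    names(x) <- if (length(x) == 1) "seq1" else paste0("seq", seq_along(x))
  }
  if (nchar(base) != 1) abort("base must be a single character")
  if (min_len < 1) abort("min_len must be >= 1")
  base <- str_to_upper(base)

  per_contig <- function(contig, s) {
    if (nchar(s) == 0) return(NULL)
    hits <- str_to_upper(strsplit(s, "", fixed = TRUE)[[1]]) == base
    r <- rle(hits)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    if (!any(keep)) return(NULL)
    tibble(
      contig = contig,
      start = starts[keep],
      end = ends[keep],
      base = base,
      length = r$lengths[keep],
      capped_length = as.integer(pmin(r$lengths[keep], cap))
    )
  }
  out <- bind_rows(map2(names(x), unname(x), per_contig))
  if (nrow(out) == 0) {
    out <- tibble(contig = character(), start = integer(), end = integer(),
                  base = character(), length = integer(),
                  capped_length = integer())
  }
  out
}

# clip an interval matrix (lo, hi) and drop empties
clip_interval <- function(lo, hi, lim_lo, lim_hi) {
  lo <- max(lo, lim_lo)
  hi <- min(hi, lim_hi)
  if (lo > hi) NULL else c(lo, hi)
}

#' Partition a genome around DSB hotspots into zones
#'
#' Hotspot zones extend each DSB interval by `hotspot_pad` bp on both sides
#' (overlaps merged); `n_flanks` successive flanking windows of `flank_size`
#' bp are laid out on each side of every hotspot zone, with left and right
#' windows of the same index pooled into one zone. Between two nearby
#' hotspots the flanks are truncated at the midpoint of the gap, so zones
#' never overlap: the hotspot zone takes precedence over flanks and inner
#' flanks over outer ones. Whatever remains is the `outside` zone.
#'
#' @param dsb Tibble of DSB intervals: `contig`, `start`, `end` (1-based
#'   inclusive; see [read_bed()] for BED input).
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param hotspot_pad Padding added to each DSB interval (default 500 bp).
#' @param flank_size Width of each flanking window (default 1000 bp).
#' @param n_flanks Number of flanking windows per side (default 5).
#' @return A `zone_set` tibble: `contig`, `hotspot_id`, `zone`
#'   (`"hotspot"`, `"flank1"`..., `"outside"`), `start`, `end`; total bp per
#'   zone in `attr(, "zone_lengths")`.
#' @examples
#' zs <- build_zones(tibble::tibble(contig = "c1", start = 5000, end = 5999),
#'                   c(c1 = 20000))
#' attr(zs, "zone_lengths")
#' @export
build_zones <- function(dsb, contig_lengths, hotspot_pad = 500,
                        flank_size = 1000, n_flanks = 5) {
  stopifnot(is.data.frame(dsb),
            all(c("contig", "start", "end") %in% names(dsb)))
  bad <- which(!is.finite(dsb$start) | !is.finite(dsb$end) |
                 dsb$start > dsb$end | dsb$start < 1 |
                 !(dsb$contig %in% names(contig_lengths)) |
                 dsb$end > contig_lengths[dsb$contig])
  if (length(bad) > 0) {
    stopf("malformed or out-of-bounds DSB interval(s) at row(s): %s",
          paste(bad, collapse = ", "))
  }

  rows <- list()
  for (ctg in unique(dsb$contig)) {
    len <- unname(contig_lengths[[ctg]])
    d <- filter(dsb, .data$contig == ctg)
    padded <- IRanges::reduce(IRanges::IRanges(
      start = pmax(1, d$start - hotspot_pad),
      end = pmin(len, d$end + hotspot_pad)
    ))
    hs_start <- IRanges::start(padded)
    hs_end <- IRanges::end(padded)
    n_hs <- length(padded)
    # flanks of adjacent hotspots may meet: cut at the midpoint of each gap
    right_lim <- c(if (n_hs > 1) floor((hs_end[-n_hs] + hs_start[-1]) / 2), len)
    left_lim <- c(1, if (n_hs > 1) floor((hs_end[-n_hs] + hs_start[-1]) / 2) + 1)

    crows <- list()
    for (i in seq_len(n_hs)) {
      hid <- sprintf("%s:%d", ctg, i)
      crows[[length(crows) + 1]] <- tibble(
        contig = ctg, hotspot_id = hid, zone = "hotspot",
        start = hs_start[i], end = hs_end[i]
      )
      for (k in seq_len(n_flanks)) {
        zk <- paste0("flank", k)
        r <- clip_interval(hs_end[i] + (k - 1) * flank_size + 1,
                           hs_end[i] + k * flank_size,
                           hs_end[i] + 1, right_lim[i])
        if (!is.null(r)) {
          crows[[length(crows) + 1]] <- tibble(
            contig = ctg, hotspot_id = hid, zone = zk,
            start = r[1], end = r[2]
          )
        }
        l <- clip_interval(hs_start[i] - k * flank_size,
                           hs_start[i] - (k - 1) * flank_size - 1,
                           left_lim[i], hs_start[i] - 1)
        if (!is.null(l)) {
          crows[[length(crows) + 1]] <- tibble(
            contig = ctg, hotspot_id = hid, zone = zk,
            start = l[1], end = l[2]
          )
        }
      }
    }
    ctbl <- bind_rows(crows)
    # the rest of the contig is outside
    zoned <- IRanges::reduce(IRanges::IRanges(start = as.integer(ctbl$start),
                                              end = as.integer(ctbl$end)))
    out_r <- IRanges::setdiff(IRanges::IRanges(1L, as.integer(len)), zoned)
    if (length(out_r) > 0) {
      ctbl <- bind_rows(ctbl, tibble(
        contig = ctg, hotspot_id = NA_character_, zone = "outside",
        start = IRanges::start(out_r), end = IRanges::end(out_r)
      ))
    }
    rows[[length(rows) + 1]] <- ctbl
  }
  zones <- bind_rows(rows) |> arrange(.data$contig, .data$start)
  if (any(zones$end[-nrow(zones)] >= zones$start[-1] &
            zones$contig[-nrow(zones)] == zones$contig[-1])) {
    abort("internal error: zones overlap") # safety net for the invariant
  }
  lengths_tbl <- zones |>
    group_by(.data$zone) |>
    summarise(total_bp = sum(.data$end - .data$start + 1), .groups = "drop")
  structure(zones, class = c("zone_set", class(zones)),
            zone_lengths = lengths_tbl, contig_lengths = contig_lengths,
            hotspot_pad = hotspot_pad, flank_size = flank_size,
            n_flanks = n_flanks)
}

# zone row index for each run (assigned by run start position)
assign_zone_rows <- function(runs, zones) {
  idx <- rep(NA_integer_, nrow(runs))
  for (ctg in unique(runs$contig)) {
    z <- which(zones$contig == ctg)
    if (length(z) == 0) next
    r <- which(runs$contig == ctg)
    hits <- findInterval(runs$start[r], zones$start[z])
    ok <- hits > 0 & runs$start[r] <= zones$end[z][pmax(hits, 1)]
    idx[r[ok]] <- z[hits[ok]]
  }
  idx
}

#' Per-zone run densities
#'
#' Counts runs per zone (a run belongs to the zone containing its start) and
#' derives the run density (runs per bp), the base density (run bases per
#' bp) and length-class-stratified densities, with the hotspot/flank
#' enrichment ratios.
#'
#' @param runs Run tibble from [find_runs()].
#' @param zones A `zone_set` from [build_zones()].
#' @param cap Length-class cap (default 26; classes `min_len`..`cap`).
#' @param renormalize Also report per-length densities renormalised to sum
#'   to 1 across zones within each length class.
#' @return A list of class `zone_densities`: `summary` (per zone), `by_length`
#'   (per zone and capped length), `enrichment` (hotspot density over mean
#'   flank density, for runs and bases).
#' @export
zone_densities <- function(runs, zones, cap = 26, renormalize = FALSE) {
  zl <- attr(zones, "zone_lengths")
  if (any(zl$total_bp <= 0)) abort("zero-length zone")
  idx <- assign_zone_rows(runs, zones)
  if (any(is.na(idx)) && nrow(runs) > 0) {
    warn(sprintf("%d run(s) fall on contigs absent from the zone set and are dropped",
                 sum(is.na(idx))))
  }
  assigned <- runs |>
    mutate(zone = ifelse(is.na(idx), NA, zones$zone[idx]),
           capped_length = pmin(.data$length, cap)) |>
    filter(!is.na(.data$zone))

  summary <- assigned |>
    group_by(.data$zone) |>
    summarise(n_runs = dplyr::n(), base_sum = sum(.data$length),
              .groups = "drop") |>
    right_join(zl, by = "zone") |>
    mutate(
      n_runs = coalesce(.data$n_runs, 0L),
      base_sum = coalesce(.data$base_sum, 0),
      run_density = .data$n_runs / .data$total_bp,
      base_density = .data$base_sum / .data$total_bp
    ) |>
    arrange(factor(.data$zone, levels = c("hotspot",
                                          paste0("flank", 1:9), "outside")))

  by_length <- assigned |>
    count(.data$zone, .data$capped_length, name = "n_runs") |>
    left_join(zl, by = "zone") |>
    mutate(density = .data$n_runs / .data$total_bp)
  if (renormalize) {
    by_length <- by_length |>
      group_by(.data$capped_length) |>
      mutate(density_renorm = .data$density / sum(.data$density)) |>
      ungroup()
  }

  hs <- filter(summary, .data$zone == "hotspot")
  fl <- filter(summary, grepl("^flank", .data$zone))
  enrichment <- tibble(
    measure = c("run_density", "base_density"),
    hotspot = c(hs$run_density, hs$base_density),
    flank_mean = c(mean(fl$run_density), mean(fl$base_density))
  ) |>
    mutate(ratio = .data$hotspot / .data$flank_mean)

  structure(list(summary = summary, by_length = by_length,
                 enrichment = enrichment),
            class = "zone_densities")
}

#' @export
print.zone_densities <- function(x, ...) {
  cat("<zone_densities>\n")
  print(x$summary)
  cat("enrichment (hotspot / mean flank):",
      sprintf("%s = %.3f", x$enrichment$measure, x$enrichment$ratio), "\n")
  invisible(x)
}

#' Per-hotspot density observations
#'
#' One observation per hotspot and zone group: the run density inside the
#' hotspot zone and in its pooled flanking windows. These are the sampling
#' units of the enrichment test.
#'
#' @inheritParams zone_densities
#' @return A tibble: `contig`, `hotspot_id`, `group` (`"hotspot"` or
#'   `"flank"`), `n_runs`, `zone_bp`, `density`.
#' @export
per_hotspot_densities <- function(runs, zones) {
  idx <- assign_zone_rows(runs, zones)
  counts <- tibble(row = idx[!is.na(idx)]) |>
    count(.data$row, name = "n_runs")
  ztab <- as_tibble(zones) |>
    mutate(row = dplyr::row_number(),
           width = .data$end - .data$start + 1) |>
    left_join(counts, by = "row") |>
    mutate(n_runs = coalesce(.data$n_runs, 0L)) |>
    filter(!is.na(.data$hotspot_id)) |>
    mutate(group = if_else(.data$zone == "hotspot", "hotspot", "flank"))
  ztab |>
    group_by(.data$contig, .data$hotspot_id, .data$group) |>
    summarise(n_runs = sum(.data$n_runs), zone_bp = sum(.data$width),
              .groups = "drop") |>
    mutate(density = .data$n_runs / .data$zone_bp)
}

#' Hotspot-versus-flank enrichment test
#'
#' Kruskal-Wallis rank test of per-hotspot run densities, hotspot zones
#' against pooled flanking zones.
#'
#' @inheritParams zone_densities
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`,
#'   `n_hotspot_obs`, `n_flank_obs`.
#' @export
enrichment_test <- function(runs, zones) {
  obs <- per_hotspot_densities(runs, zones)
  groups <- split(obs$density, obs$group)
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("enrichment test undefined: a group has no observations")
  }
  kw <- kruskal.test(list(groups$hotspot, groups$flank))
  tibble(
    statistic = unname(kw$statistic), df = unname(kw$parameter),
    p_value = kw$p.value,
    n_hotspot_obs = length(groups$hotspot),
    n_flank_obs = length(groups$flank)
  )
}
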