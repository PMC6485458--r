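# Fixtures and independent reference implementations used across tests.

# a minimal all-SNP hotspot map with markers at the given positions;
# haplotype 1 alleles alternate G (strong) / A (weak) so phases 1/2 are
# always well defined
snp_map <- function(positions, h1 = NULL, h2 = NULL) {
  k <- length(positions)
  if (is.null(h1)) h1 <- rep(c("G", "A"), length.out = k)
  if (is.null(h2)) h2 <- ifelse(h1 %in% c("G", "C"), "A", "G")
  hotspot_map(
    tibble::tibble(position = positions, kind = "SNP",
                   allele_h1 = h1, allele_h2 = h2),
    contig = "chrT",
    motif_position = round(mean(range(positions))),
    hotspot_interval = range(positions) + c(-10, 10)
  )
}

# one molecule from a phase vector (1 = haplotype 1 allele, 2 = haplotype 2,
# NA = missing call)
mol_from_phases <- function(map, phases, assay = "CO", reciprocal = "RI",
                            donor_id = "d1", pool_id = 1L) {
  mk <- map$markers
  stopifnot(length(phases) == nrow(mk))
  calls <- ifelse(is.na(phases), NA_character_,
                  ifelse(phases == 1, mk$allele_h1, mk$allele_h2))
  out <- tibble::tibble(donor_id = donor_id, assay = assay,
                        reciprocal = reciprocal, pool_id = pool_id)
  for (i in seq_len(nrow(mk))) out[[as.character(mk$position[i])]] <- calls[i]
  out
}

# brute-force reference classifier working directly on the phase string;
# deliberately independent of the package's run-length logic
reference_classify <- function(phases, assay, reciprocal) {
  obs <- phases[!is.na(phases)]
  if (length(obs) < 2) return("unscorable")
  s <- paste(obs, collapse = "")
  if (assay == "CO") {
    if (grepl("^1+2+$", s) || grepl("^2+1+$", s)) return("CO")
    first <- substr(s, 1, 1)
    last <- substr(s, nchar(s), nchar(s))
    if (first != last) return("CCO")
    return("unscorable")
  }
  bg <- if (reciprocal == "NRI") "1" else "2"
  other <- if (bg == "1") "2" else "1"
  if (substr(s, 1, 1) != bg || substr(s, nchar(s), nchar(s)) != bg) {
    return("unscorable")
  }
  n_conv <- sum(obs == as.integer(other))
  if (n_conv == 0) return("unscorable")
  if (n_conv == 1) return("NCO_simple")
  # complex iff an unconverted call sits strictly between converted ones
  conv_idx <- which(obs == as.integer(other))
  span <- seq(min(conv_idx), max(conv_idx))
  if (any(obs[span] == as.integer(bg))) "NCO_complex" else "NCO_co"
}

# quadratic regex scanner used as the run-detection oracle
regex_find_runs <- function(seq, base = "A", min_len = 6) {
  m <- gregexpr(sprintf("(?i)%s{%d,}", base, min_len), seq, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  tibble::tibble(start = as.integer(m),
                 end = as.integer(m) + attr(m, "match.length") - 1L)
}

# random DNA sequence with controllable A-richness
random_seq <- function(n, p_a = 0.25, with_n = FALSE) {
  letters <- c("A", "C", "G", "T")
  probs <- c(p_a, rep((1 - p_a) / 3, 3))
  if (with_n) {
    letters <- c(letters, "N")
    probs <- c(probs * 0.98, 0.02)
  }
  paste(sample(letters, n, replace = TRUE, prob = probs), collapse = "")
}

# runs tibble drawn as a Poisson process: planted density per bp inside
# hotspot zones and half that elsewhere, run lengths 6-10
planted_runs <- function(zones, rate_hotspot, rate_elsewhere) {
  z <- tibble::as_tibble(zones)
  z$width <- z$end - z$start + 1
  rows <- lapply(seq_len(nrow(z)), function(i) {
    rate <- if (z$zone[i] == "hotspot") rate_hotspot else rate_elsewhere
    n <- stats::rpois(1, rate * z$width[i])
    if (n == 0) return(NULL)
    starts <- sort(sample.int(z$width[i], n, replace = TRUE)) + z$start[i] - 1
    tibble::tibble(contig = z$contig[i], start = starts,
                   end = starts + sample(5:9, n, replace = TRUE),
                   base = "A",
                   length = NA_integer_)
  })
  out <- dplyr::bind_rows(rows)
  out$length <- out$end - out$start + 1L
  out$capped_length <- pmin(out$length, 26L)
  out
}

# small strata tibble generator for property tests
random_strata <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    stratum = paste0("s", seq_len(n)),
    donor_id = "d1",
    marker = paste0("m", seq_len(n)),
    orientation = sample(c("RI", "RII"), n, replace = TRUE),
    x_favored = rpois(n, 8) + 1L,
    t_favored = sample(c(1e4, 2e4, 5e4), n, replace = TRUE),
    x_disfavored = rpois(n, 8) + 1L,
    t_disfavored = sample(c(1e4, 2e4, 5e4), n, replace = TRUE)
  )
}

swap_strata_labels <- function(s) {
  tibble::tibble(
    stratum = s$stratum, donor_id = s$donor_id, marker = s$marker,
    orientation = s$orientation,
    x_favored = s$x_disfavored, t_favored = s$t_disfavored,
    x_disfavored = s$x_favored, t_disfavored = s$t_favored
  )
}
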