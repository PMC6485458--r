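# internal helpers shared across modules

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || any(is.na(x))) {
    stopf("`%s` must be numeric and non-missing", name)
  }
  if (any(x < lower) || any(x > upper)) {
    stopf("`%s` must lie in [%s, %s]", name, format(lower), format(upper))
  }
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

# significance stars at the conventional cutpoints
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

# strong (G/C) vs weak (A/T) classification of a single base
snp_class <- function(base) {
  dplyr::case_when(
    base %in% c("G", "C") ~ "strong",
    base %in% c("A", "T") ~ "weak",
    TRUE ~ NA_character_
  )
}

marker_cols <- function(molecules) {
  cols <- names(molecules)
  cols[grepl("^[0-9]+$", cols)]
}
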