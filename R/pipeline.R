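# End-to-end pipeline: simulate -> classify -> rates -> centers -> bias,
# with a reproducibility manifest.

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full hotspot analysis pipeline
#'
#' Simulates pooled sperm-typing experiments for a panel of donors and runs
#' every analysis stage: event classification, per-donor and per-group
#' frequency estimates with the heterozygous/homozygous rate comparison,
#' CO/NCO centre fits, the transmission-bias table (gBGC and iBGC for CO
#' and NCO), and complex-event rates. When `out_dir` is given all tables
#' are written as TSV together with a JSON manifest recording the seed, a
#' hash of the configuration, per-stage row counts and the package version.
#'
#' @param donors List of [donor_profile()] objects.
#' @param params A [sim_params()]; its `seed` drives every draw (donor i is
#'   simulated with `seed + i - 1`).
#' @param out_dir Optional output directory (created if needed).
#' @return A list with `molecules`, `assays`, `events`, `rates`,
#'   `group_comparison`, `centers`, `bias`, `complex_rates` and `manifest`,
#'   invisibly when writing to disk.
#' @examples
#' donors <- list(donor_profile("d1", "Ht"), donor_profile("d2", "Ho"))
#' res <- run_hotspot_pipeline(donors, sim_params(seed = 1, n_pools_co = 30,
#'                                                n_pools_nco = 30))
#' res$bias
#' @export
run_hotspot_pipeline <- function(donors, params = sim_params(seed = 1),
                                 out_dir = NULL) {
  stopifnot(length(donors) > 0,
            all(map_lgl(donors, inherits, "donor_profile")))
  if (is.null(params$seed)) abort("params$seed must be set for a pipeline run")
  hmap <- donors[[1]]$map

  sim <- pipeline_stage("simulate", {
    exps <- map2(donors, seq_along(donors) - 1, function(d, off) {
      p <- params
      p$seed <- params$seed + off
      simulate_experiment(d, p)
    })
    list(molecules = bind_rows(map(exps, "molecules")),
         assays = bind_rows(map(exps, "assays")))
  })

  events <- pipeline_stage("call-events", {
    ev <- call_events(sim$molecules, hmap)
    # molecule_id must index the bound molecule table
    ev$molecule_id <- seq_len(nrow(ev))
    ev
  })

  rates <- pipeline_stage("rates", summarize_rates(events, sim$assays))

  group_cmp <- pipeline_stage("rates", {
    groups <- sim$assays |> distinct(.data$donor_id, .data$group)
    per_group <- events |>
      filter(.data$scorable) |>
      left_join(groups, by = "donor_id") |>
      count(.data$group, .data$assay, name = "event_count")
    expo <- sim$assays |>
      group_by(.data$group, .data$assay) |>
      summarise(amplifiable = sum(.data$amplifiable_genomes), .groups = "drop")
    cmp <- function(a) {
      g <- function(grp) {
        n <- per_group$event_count[per_group$group == grp & per_group$assay == a]
        t <- expo$amplifiable[expo$group == grp & expo$assay == a]
        list(n = if (length(n) == 0) 0L else n, t = t)
      }
      ht <- g("Ht"); ho <- g("Ho")
      if (length(ht$t) == 0 || length(ho$t) == 0) return(NULL)
      est <- function(x) tibble(event_count = x$n, amplifiable_genomes = x$t)
      compare_groups(est(ht), est(ho)) |>
        mutate(assay = a, comparison = "Ht_vs_Ho", .before = 1)
    }
    bind_rows(cmp("CO"), cmp("NCO"))
  })

  centers <- pipeline_stage("centers", {
    fits <- list()
    for (a in c("CO", "NCO")) {
      model <- if (a == "CO") "normal_cdf" else "logistic3"
      fit <- tryCatch({
        glance(fit_center(cumulative_curve(events, a), model))
      }, error = function(e) {
        tibble(model = model, center = NA_real_, se = NA_real_,
               width = NA_real_, rss = NA_real_, n_events = NA_integer_,
               converged = FALSE)
      })
      fits[[a]] <- mutate(fit, assay = a, .before = 1)
    }
    bind_rows(fits)
  })

  bias <- pipeline_stage("bias", {
    str_pos <- hmap$markers$position[hmap$markers$kind == "STR"]
    grid <- tidyr::expand_grid(
      classification = c("strong_weak", "long_short"),
      assay = c("CO", "NCO")
    )
    pmap(grid, function(classification, assay) {
      tryCatch({
        estimate_transmission_bias(
          sim$molecules, events, hmap, sim$assays,
          classification = classification, assay = assay,
          markers = if (classification == "long_short") str_pos else NULL
        )
      }, error = function(e) NULL)
    }) |>
      compact() |>
      bind_rows()
  })

  complex_rates <- pipeline_stage("rates", {
    tryCatch(complex_event_rates(events, sim$assays),
             error = function(e) tibble())
  })

  manifest <- list(
    package = "recombias",
    version = as.character(utils::packageVersion("recombias")),
    seed = params$seed,
    config_hash = rlang::hash(list(params = unclass(params),
                                   donors = map_chr(donors, "donor_id"))),
    rows = list(
      molecules = nrow(sim$molecules), events = nrow(events),
      scorable = sum(events$scorable), rates = nrow(rates),
      bias = nrow(bias)
    )
  )

  out <- list(molecules = sim$molecules, assays = sim$assays,
              events = events, rates = rates, group_comparison = group_cmp,
              centers = centers, bias = bias, complex_rates = complex_rates,
              manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_molecules(sim$molecules, file.path(out_dir, "molecules.tsv"))
    write_events(events, file.path(out_dir, "events.tsv"))
    for (nm in c("rates", "group_comparison", "centers", "bias",
                 "complex_rates")) {
      readr::write_tsv(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
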