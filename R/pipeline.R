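#' Pipeline configuration
#'
#' Collects every tunable threshold with its documented default. All values
#' are echoed into the report for provenance.
#'
#' @param min_reads Minimum unique reads for a novel junction (default 3).
#' @param min_psi Minimum carrier PSI for specificity (default 0.10).
#' @param fold Fold over control p95 PSI for specificity (default 5).
#' @param min_denominator Minimum PSI denominator for determinate calls
#'   (default 100).
#' @param rtpcr_cutoff PSI denominator below which RT-PCRseq confirmation is
#'   required (default 500).
#' @param masking_offset Reporting-range half-width in intronic nt (default 5).
#' @param pwm_delta Log-odds change for mechanism calls (default 2).
#' @param branch_window Branch-point search window upstream of acceptors
#'   (default 18-44 nt).
#' @param assoc_window Variant-to-event linkage window in nt (default 5000).
#' @param filter_mode DNA quality filter combination (`"conjunction"`).
#' @param rounding Per-patient frequency rounding (`"nearest"`).
#' @param seed Integer seed for any stochastic step.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_reads = 3L, min_psi = 0.10, fold = 5,
                            min_denominator = 100L, rtpcr_cutoff = 500L,
                            masking_offset = 5L, pwm_delta = 2,
                            branch_window = c(18L, 44L), assoc_window = 5000L,
                            filter_mode = c("conjunction", "disjunction"),
                            rounding = c("nearest", "ceiling"), seed = 1L) {
  structure(list(
    min_reads = as.integer(min_reads), min_psi = min_psi, fold = fold,
    min_denominator = as.integer(min_denominator),
    rtpcr_cutoff = as.integer(rtpcr_cutoff),
    masking_offset = as.integer(masking_offset), pwm_delta = pwm_delta,
    branch_window = as.integer(branch_window),
    assoc_window = as.integer(assoc_window),
    filter_mode = match.arg(filter_mode), rounding = match.arg(rounding),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the paired DNA-RNA splicing pipeline on a cohort
#'
#' Executes the full workflow on an in-memory cohort (typically from
#' [simulate_cohort()] or assembled from files with the readers): DNA
#' quality filtering, per-carrier event detection, carrier PSI, control-pool
#' profiles, specificity, mechanism inference, association, RNA-informed
#' reclassification, reporting-range masking, and cohort summarisation.
#' Deterministic given the cohort and config.
#'
#' @param cohort List with `model`, `controls`, `carriers`, `variants` (see
#'   [simulate_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report tables are
#'   written there (evidence JSON, PSI TSV, masked-variant audit TSV,
#'   summary JSON).
#' @return A `splice_report`: list with `evidence`, `outcomes`, `psi`,
#'   `events`, `masked_audit`, `reported_variants`, `summary`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  model <- cohort$model
  variants <- tibble::as_tibble(cohort$variants)
  if (nrow(variants) == 0L) stop("cohort has no variants")
  if (is.null(cohort$controls) || nrow(cohort$controls) == 0L) {
    stop("control pool is empty")
  }

  variants <- dna_variant_filter(variants, mode = config$filter_mode)
  kept <- variants[variants$keep, ]

  events <- detect_events(cohort$carriers, model, min_reads = config$min_reads)
  events_ok <- events[events$event_type != "UNCLASSIFIED", ]

  uniq <- dplyr::distinct(events_ok, .data$event_key, .keep_all = TRUE)
  psi <- purrr::map_dfr(unique(events_ok$sample_id), function(s) {
    compute_psi(uniq, cohort$carriers[cohort$carriers$sample_id == s, ],
                model, sample_id = s)
  })
  profiles <- control_profile(uniq, cohort$controls, model)
  psi <- specificity_test(psi, profiles, min_psi = config$min_psi,
                          fold = config$fold,
                          min_denominator = config$min_denominator)
  psi$needs_rtpcr <- needs_rtpcr_confirmation(psi$region_total_reads,
                                              config$rtpcr_cutoff)

  kept <- mechanism_inference(kept, model, pwm_delta = config$pwm_delta,
                              branch_window = config$branch_window)
  evidence <- associate(kept, events_ok, psi, cohort$carriers, model,
                        window = config$assoc_window,
                        min_denominator = config$min_denominator)
  outcomes <- reclassify(kept, evidence, adequate_depth = config$rtpcr_cutoff)

  has_rna <- evidence$overall == "associated"
  masked <- reporting_range_mask(kept, has_rna,
                                 masking_offset = config$masking_offset)
  reported <- masked[masked$reportable, ]
  audit <- masked[!masked$reportable, ]

  n_individuals <- length(unique(cohort$carriers$sample_id))
  carrier_map <- tibble::tibble(variant_id = kept$variant_id,
                                individual_id = kept$carrier_ids) |>
    tidyr::unnest(cols = "individual_id")
  outcome_ind <- dplyr::inner_join(outcomes, carrier_map, by = "variant_id")
  deltas <- yield_and_vus_delta(outcome_ind, n_individuals)

  summary <- list(
    n_individuals = n_individuals,
    n_variants = nrow(variants),
    n_reported = nrow(reported),
    n_masked = nrow(audit),
    variant_types = variant_type_distribution(kept),
    position_table = position_classification_table(kept),
    event_types = event_type_counts(events_ok),
    impacts = dplyr::count(outcomes, .data$impact, name = "n"),
    yield_delta_pct = deltas$yield_delta_pct,
    vus_delta_pct = deltas$vus_delta_pct
  )
  rep <- structure(
    list(evidence = evidence, outcomes = outcomes, psi = psi,
         events = events, masked_audit = audit, reported_variants = reported,
         summary = summary, config = config),
    class = "splice_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(x) x[!vapply(x, is.list, TRUE)]
  jsonlite::write_json(
    list(config = unclass(report$config),
         evidence = report$evidence),
    file.path(out_dir, "evidence.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(
    report$psi[, c("event_key", "sample_id", "supporting_reads",
                   "region_total_reads", "psi", "median_psi", "p95_psi",
                   "specificity", "needs_rtpcr")],
    file.path(out_dir, "psi_report.tsv"))
  readr::write_tsv(flat_variants(report$masked_audit),
                   file.path(out_dir, "masked_audit.tsv"))
  jsonlite::write_json(
    list(n_individuals = report$summary$n_individuals,
         n_reported = report$summary$n_reported,
         n_masked = report$summary$n_masked,
         yield_delta_pct = report$summary$yield_delta_pct,
         vus_delta_pct = report$summary$vus_delta_pct,
         config = unclass(report$config)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

flat_variants <- function(v) {
  v$carrier_ids <- purrr::map_chr(v$carrier_ids, paste, collapse = ",")
  v[, !vapply(v, is.list, TRUE)]
}

#' @export
print.splice_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<splice_report> %d individuals, %d variants (%d reported, %d masked)\n",
              s$n_individuals, s$n_variants, s$n_reported, s$n_masked))
  imp <- x$outcomes |> dplyr::count(.data$impact)
  cat("  impacts:", paste(sprintf("%s=%d", imp$impact, imp$n), collapse = ", "), "\n")
  cat(sprintf("  yield delta %.1f%%, VUS delta %.1f%%\n",
              s$yield_delta_pct, s$vus_delta_pct))
  invisible(x)
}

#' Tidy the per-variant evidence of a pipeline report
#'
#' @param x A `splice_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-variant association evidence joined with the
#'   reclassification outcome, one row per variant.
#' @method tidy splice_report
#' @export
tidy.splice_report <- function(x, ...) {
  dplyr::left_join(x$evidence, x$outcomes, by = "variant_id")
}

#' @rdname tidy.splice_report
#' @details `glance()` returns a one-row cohort summary.
#' @method glance splice_report
#' @export
glance.splice_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_individuals = s$n_individuals, n_variants = s$n_variants,
    n_reported = s$n_reported, n_masked = s$n_masked,
    n_upgrades = sum(x$outcomes$impact == "upgrade"),
    n_downgrades = sum(x$outcomes$impact == "downgrade"),
    yield_delta_pct = s$yield_delta_pct, vus_delta_pct = s$vus_delta_pct
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
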