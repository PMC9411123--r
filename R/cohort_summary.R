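#' Distribution of variant types
#'
#' Percentage of reported variants per variant type, to one decimal
#' (round half up), over the P/LP/VUS reported variants.
#'
#' @param variants Variant tibble with `variant_type` and `classification`.
#' @param reported_only Restrict the denominator to P/LP/VUS variants
#'   (default TRUE, the reporting convention).
#' @return A tibble: `variant_type`, `n`, `pct`.
#' @export
variant_type_distribution <- function(variants, reported_only = TRUE) {
  v <- tibble::as_tibble(variants)
  if (nrow(v) == 0L) stop("no variants supplied")
  if (reported_only) v <- v[v$classification %in% c("P", "LP", "VUS"), ]
  if (nrow(v) == 0L) stop("no reported (P/LP/VUS) variants supplied")
  v |>
    dplyr::count(.data$variant_type, name = "n") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Cohort-level yield and VUS-rate deltas from RNA evidence
#'
#' The positive-yield delta is the percentage of tested individuals who
#' gained their first P/LP result through RNA evidence; the VUS delta is the
#' percentage whose VUS was resolved. Both count individuals, not variants:
#' an individual with two upgrades counts once. One decimal, round half up.
#'
#' @param outcomes A tibble with one row per (individual, variant) outcome:
#'   columns `individual_id` and `impact` (`upgrade`/`downgrade`/...), plus
#'   optionally `gained_first_plp` and `vus_resolved` logical columns; when
#'   absent, `upgrade` implies both a first P/LP gain and a VUS resolution,
#'   and `downgrade` implies a VUS resolution.
#' @param n_individuals Total individuals tested.
#' @return A tibble: `yield_delta_pct`, `vus_delta_pct`, `n_yield`, `n_vus`.
#' @export
yield_and_vus_delta <- function(outcomes, n_individuals) {
  stopifnot(n_individuals > 0)
  o <- tibble::as_tibble(outcomes)
  if (!"gained_first_plp" %in% names(o)) o$gained_first_plp <- o$impact == "upgrade"
  if (!"vus_resolved" %in% names(o)) {
    o$vus_resolved <- o$impact %in% c("upgrade", "downgrade")
  }
  n_yield <- dplyr::n_distinct(o$individual_id[o$gained_first_plp])
  n_vus <- dplyr::n_distinct(o$individual_id[o$vus_resolved])
  tibble::tibble(
    yield_delta_pct = round_half_up(100 * n_yield / n_individuals, 1),
    vus_delta_pct = round_half_up(100 * n_vus / n_individuals, 1),
    n_yield = n_yield, n_vus = n_vus
  )
}

#' Per-patient carrier frequency ("one per N patients")
#'
#' @param n_carriers Number of carriers observed (must be >= 1 for a defined
#'   frequency; 0 returns NA).
#' @param n_individuals Total individuals tested.
#' @param rounding `"nearest"` (default) or `"ceiling"`.
#' @return Integer N such that the frequency is one per N patients.
#' @export
per_patient_frequency <- function(n_carriers, n_individuals,
                                  rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  out <- rep(NA_integer_, length(n_carriers))
  ok <- n_carriers >= 1
  ratio <- n_individuals / n_carriers[ok]
  out[ok] <- as.integer(if (rounding == "nearest") round_half_up(ratio) else ceiling(ratio))
  out
}

#' Position-bin by classification cross-tabulation
#'
#' Counts unique variants per position bin and classification, with row-wise
#' percentages (one decimal, round half up).
#'
#' @param variants Variant tibble with `position_bin` and `classification`.
#' @return A tibble: `position_bin`, `classification`, `n`, `row_pct`.
#' @export
position_classification_table <- function(variants) {
  v <- tibble::as_tibble(variants)
  v |>
    dplyr::count(.data$position_bin, .data$classification, name = "n",
                 .drop = FALSE) |>
    dplyr::group_by(.data$position_bin) |>
    dplyr::mutate(row_total = sum(.data$n),
                  row_pct = ifelse(.data$row_total > 0,
                                   round_half_up(100 * .data$n / .data$row_total, 1),
                                   NA_real_)) |>
    dplyr::ungroup() |>
    dplyr::select(-"row_total")
}

#' Total reported variants from per-class counts
#'
#' @param n_p,n_lp,n_vus Non-negative counts of P, LP and VUS variants.
#' @return Their sum (integer).
#' @export
reported_variant_total <- function(n_p, n_lp, n_vus) {
  stopifnot(all(c(n_p, n_lp, n_vus) >= 0))
  as.integer(n_p + n_lp + n_vus)
}

#' Distribution of splicing events by type
#'
#' @param events Event tibble ([detect_events()] output); `UNCLASSIFIED`
#'   events are excluded.
#' @param by_unique_key Count unique event keys rather than per-sample
#'   observations (default TRUE).
#' @return A tibble: `event_type`, `n`.
#' @export
event_type_counts <- function(events, by_unique_key = TRUE) {
  e <- tibble::as_tibble(events)
  e <- e[e$event_type != "UNCLASSIFIED", ]
  if (by_unique_key) e <- dplyr::distinct(e, .data$event_key, .keep_all = TRUE)
  e$event_type <- factor(e$event_type, levels = c("ESF", "ESP", "ES", "IP", "IC"))
  dplyr::count(e, .data$event_type, name = "n", .drop = FALSE)
}
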