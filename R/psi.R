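# round half up (the reporting convention for printed percentages and for the
# cryptic-exon numerator rule)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# canonical junctions whose intron is overlapped by any of the event's novel
# junction intervals (these share a splice region with the event)
sharing_canonical <- function(event_junctions, model) {
  cj <- canonical_junctions(model)
  if (nrow(cj) == 0L) return(cj[0L, ])
  ov <- vapply(seq_len(nrow(cj)), function(i) {
    any(event_junctions$intron_start <= cj$intron_end[i] &
          event_junctions$intron_end >= cj$intron_start[i])
  }, logical(1L))
  cj[ov, ]
}

#' Compute the percent-spliced index of events in a sample
#'
#' PSI is the number of reads supporting the alternative splicing event
#' divided by all reads in the region covering the event. Operationally, on
#' junction tables: the numerator is the read count on the event's novel
#' junction(s) (for a two-junction cryptic-exon event, the mean of the two
#' flanking junction counts, rounded half-up); the denominator adds the reads
#' on canonical junctions sharing a splice region with the event (for a
#' cryptic exon, the canonical junction spanning the host intron). A zero
#' denominator yields an undefined PSI with a `no_coverage` flag.
#'
#' @param events Event tibble ([detect_events()] output, or hypothesized
#'   events with a `junctions` list-column).
#' @param junctions Junction tibble for one sample (novel junction rows may be
#'   absent, in which case they count 0 reads).
#' @param model A [gene_model()].
#' @param sample_id Sample label for the output (default: taken from
#'   `junctions`).
#' @return A tibble: `event_key`, `sample_id`, `supporting_reads`,
#'   `region_total_reads`, `psi`, `no_coverage`.
#' @export
compute_psi <- function(events, junctions, model, sample_id = NULL) {
  jt <- tibble::as_tibble(junctions)
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% names(jt) && nrow(jt) > 0L) {
      jt$sample_id[1L]
    } else "sample"
  }
  lookup <- function(starts, ends) {
    vapply(seq_along(starts), function(i) {
      hit <- jt$intron_start == starts[i] & jt$intron_end == ends[i]
      if (any(hit)) sum(jt$unique_reads[hit]) else 0L
    }, numeric(1L))
  }
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    nj <- events$junctions[[i]]
    counts <- lookup(nj$intron_start, nj$intron_end)
    num <- if (events$event_type[i] == "IC" && nrow(nj) == 2L) {
      round_half_up(mean(counts))
    } else {
      sum(counts)
    }
    cj <- sharing_canonical(nj, model)
    canon <- if (nrow(cj) == 0L) 0 else {
      round_half_up(mean(lookup(cj$intron_start, cj$intron_end)))
    }
    denom <- num + canon
    tibble::tibble(
      event_key = events$event_key[i],
      sample_id = sample_id,
      supporting_reads = as.integer(num),
      region_total_reads = as.integer(denom),
      psi = if (denom > 0) num / denom else NA_real_,
      no_coverage = denom == 0
    )
  })
}

#' Build a control-pool PSI profile for events
#'
#' Computes PSI for each event in every control sample of the pool. Controls
#' lacking the novel junction contribute PSI 0 when canonical coverage exists;
#' controls with no junction coverage at all over the region are excluded from
#' the statistics and counted.
#'
#' @param events Event tibble (`event_key` + `junctions` list-column).
#' @param control_junctions Stacked junction tibble for all controls, with a
#'   `sample_id` column.
#' @param model A [gene_model()].
#' @return A tibble per event: `event_key`, `n_controls`, `n_undefined`,
#'   `median_psi`, `p95_psi`, `max_psi`, and `per_sample_psi` (list-column).
#' @export
control_profile <- function(events, control_junctions, model) {
  ct <- tibble::as_tibble(control_junctions)
  if (nrow(ct) == 0L) stop("control manifest is empty")
  samples <- unique(ct$sample_id)
  obs <- purrr::map_dfr(samples, function(s) {
    compute_psi(events, ct[ct$sample_id == s, ], model, sample_id = s)
  })
  obs |>
    dplyr::group_by(.data$event_key) |>
    dplyr::summarise(
      n_controls = length(samples),
      n_undefined = sum(.data$no_coverage),
      median_psi = stats::median(.data$psi, na.rm = TRUE),
      p95_psi = as.numeric(stats::quantile(.data$psi, 0.95, na.rm = TRUE)),
      max_psi = suppressWarnings(max(.data$psi, na.rm = TRUE)),
      per_sample_psi = list(.data$psi[!.data$no_coverage]),
      .groups = "drop"
    )
}

#' Test event specificity against the control pool
#'
#' An event in a carrier is `specific` when its PSI is both at least
#' `min_psi` and at least `fold` times the control pool's 95th-percentile
#' PSI; `indeterminate` when the carrier's PSI denominator is below
#' `min_denominator` (insufficient coverage to judge); otherwise
#' `not_specific`.
#'
#' @param psi Carrier PSI observations ([compute_psi()] output).
#' @param controls Control profile ([control_profile()] output).
#' @param min_psi Minimum carrier PSI (default 0.10).
#' @param fold Required fold over the control p95 (default 5).
#' @param min_denominator Minimum PSI denominator for a determinate call
#'   (default 100).
#' @return `psi` joined with control statistics plus a `specificity` column.
#' @export
specificity_test <- function(psi, controls, min_psi = 0.10, fold = 5,
                             min_denominator = 100L) {
  out <- dplyr::left_join(
    psi, controls[, c("event_key", "median_psi", "p95_psi", "max_psi")],
    by = "event_key")
  out$specificity <- dplyr::case_when(
    is.na(out$psi) | out$region_total_reads < min_denominator ~ "indeterminate",
    out$psi >= min_psi & out$psi >= fold * dplyr::coalesce(out$p95_psi, 0) ~ "specific",
    TRUE ~ "not_specific"
  )
  out
}

#' RT-PCRseq confirmation trigger
#'
#' Events whose PSI denominator (total junction coverage over the region) is
#' below 500x require orthogonal confirmation by targeted RT-PCR amplicon
#' sequencing. The boundary is strict: a denominator of exactly 500 does not
#' trigger confirmation.
#'
#' @param region_total_reads Integer vector of PSI denominators.
#' @param cutoff Coverage threshold (default 500).
#' @return Logical vector.
#' @export
needs_rtpcr_confirmation <- function(region_total_reads, cutoff = 500L) {
  region_total_reads < cutoff
}

#' Allele-skew test for nonsense-mediated decay
#'
#' Uses an exonic heterozygous SNP's RNA allele counts to detect allelic
#' imbalance, an indirect sign that one allele's transcript is degraded (e.g.
#' by NMD). Two-sided exact binomial test against a balanced 0.5 proportion.
#'
#' @param ref_reads,alt_reads Integer vectors of allele read counts.
#' @param alpha Significance level for calling skew (default 0.01).
#' @param min_total Minimum total reads for a determinate call (default 20).
#' @return A tibble: `ref_reads`, `alt_reads`, `p_value`, `call`
#'   (`skewed` / `balanced` / `indeterminate`).
#' @export
allele_skew_test <- function(ref_reads, alt_reads, alpha = 0.01,
                             min_total = 20L) {
  n <- max(length(ref_reads), length(alt_reads))
  ref_reads <- rep_len(as.integer(ref_reads), n)
  alt_reads <- rep_len(as.integer(alt_reads), n)
  total <- ref_reads + alt_reads
  p <- vapply(seq_len(n), function(i) {
    if (total[i] == 0L) return(NA_real_)
    stats::binom.test(ref_reads[i], total[i], p = 0.5,
                      alternative = "two.sided")$p.value
  }, numeric(1L))
  tibble::tibble(
    ref_reads = ref_reads, alt_reads = alt_reads, p_value = p,
    call = dplyr::case_when(
      total < min_total ~ "indeterminate",
      p < alpha ~ "skewed",
      TRUE ~ "balanced"
    )
  )
}

#' RNA sample sequencing quality control
#'
#' A sample passes when the percentage of Q30 bases exceeds 75, mean base
#' quality exceeds 30, the percentage of perfect index reads exceeds 85, and
#' at least 85 percent of panel exons have average coverage of at least 50x.
#'
#' @param metrics A data frame with columns `pct_q30`, `mean_base_quality`,
#'   `pct_perfect_index`, `pct_exons_ge_50x` (and optionally `sample_id`).
#' @return `metrics` as a tibble with `passed` and `failure_reasons` added.
#' @export
rna_sample_qc <- function(metrics) {
  m <- tibble::as_tibble(metrics)
  need <- c("pct_q30", "mean_base_quality", "pct_perfect_index", "pct_exons_ge_50x")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0L) {
    stop("missing RNA QC metric(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(m[need])) stop("RNA QC metrics must not contain missing values")
  fails <- list(
    "Q30" = m$pct_q30 <= 75,
    "mean base quality" = m$mean_base_quality <= 30,
    "perfect index" = m$pct_perfect_index <= 85,
    "exon coverage" = m$pct_exons_ge_50x < 85
  )
  m$failure_reasons <- purrr::map_chr(seq_len(nrow(m)), function(i) {
    paste(names(fails)[vapply(fails, `[`, TRUE, i)], collapse = "; ")
  })
  m$passed <- m$failure_reasons == ""
  m
}
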