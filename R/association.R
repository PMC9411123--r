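mechanism_levels <- function() {
  c("NOVEL_SITE_CREATION", "NATIVE_SITE_WEAKENING", "BRANCH_POINT_DELETION",
    "POSSIBLE_ESE_DISRUPTION", "UNKNOWN")
}

#' Infer the splicing mechanism of a DNA variant
#'
#' Scores every donor and acceptor PWM window overlapping the variant for the
#' reference and alternate alleles and applies, in order:
#' * a deletion overlapping the branch-point window (18-44 nt upstream of a
#'   native acceptor) is a `BRANCH_POINT_DELETION`;
#' * a score drop of at least `pwm_delta` log-odds units at a native splice
#'   site is `NATIVE_SITE_WEAKENING`;
#' * a score gain of at least `pwm_delta` at a non-native window is
#'   `NOVEL_SITE_CREATION`;
#' * an exonic substitution with no site-score change but an associated
#'   exon-skipping event is flagged `POSSIBLE_ESE_DISRUPTION` (flag only, not
#'   a quantitative ESE model);
#' * anything else (including variants on models without sequence) is
#'   `UNKNOWN`.
#'
#' Alleles are interpreted in transcript orientation.
#'
#' @param variants Variant tibble with `coding_pos`, `intron_offset`, `ref`,
#'   `alt` (and for deletion ranges `coding_pos2`, `intron_offset2`).
#' @param model A [gene_model()] with attached sequence.
#' @param exon_skip_event Logical vector (recycled): does this variant have an
#'   associated exon-skipping event?
#' @param pwm_delta Log-odds change needed for a creation/weakening call
#'   (default 2).
#' @param branch_window Intronic distance range upstream of the acceptor
#'   scanned for branch-point loss (default 18-44 nt).
#' @return `variants` with a `mechanism` column added.
#' @export
mechanism_inference <- function(variants, model, exon_skip_event = FALSE,
                                pwm_delta = 2, branch_window = c(18L, 44L)) {
  v <- tibble::as_tibble(variants)
  if (!"coding_pos2" %in% names(v)) {
    v$coding_pos2 <- NA_integer_
    v$intron_offset2 <- NA_integer_
  }
  exon_skip_event <- rep_len(exon_skip_event, nrow(v))
  nm <- norm_model(model)
  have_seq <- !is.null(model$seq)

  v$mechanism <- vapply(seq_len(nrow(v)), function(i) {
    g1 <- tryCatch(
      pos_norm1(model, cdna_to_genomic(model, v$coding_pos[i], v$intron_offset[i])),
      error = function(e) NA_integer_)
    if (is.na(g1)) return("UNKNOWN")
    is_del <- nchar(v$ref[i]) > nchar(v$alt[i]) || !is.na(v$coding_pos2[i])
    if (is_del) {
      g2 <- if (!is.na(v$coding_pos2[i])) {
        pos_norm1(model, cdna_to_genomic(model, v$coding_pos2[i], v$intron_offset2[i]))
      } else {
        g1 + nchar(v$ref[i]) - nchar(v$alt[i])
      }
      del <- sort(c(g1, g2))
      # branch windows of native acceptors (first exonic base f of exon 2..n)
      for (k in seq_len(nm$n - 1L)) {
        f <- nm$exons$start[k + 1L] + 1L
        if (del[1L] <= f - branch_window[1L] && del[2L] >= f - branch_window[2L]) {
          return("BRANCH_POINT_DELETION")
        }
      }
      return("UNKNOWN")
    }
    if (!have_seq || nchar(v$ref[i]) != 1L || nchar(v$alt[i]) != 1L) {
      return("UNKNOWN")
    }
    deltas <- pwm_deltas_at(nm, g1, toupper(v$alt[i]))
    native_drop <- deltas$delta[deltas$native]
    novel_gain <- deltas$delta[!deltas$native]
    if (length(native_drop) > 0L && min(native_drop) <= -pwm_delta) {
      return("NATIVE_SITE_WEAKENING")
    }
    if (length(novel_gain) > 0L && max(novel_gain) >= pwm_delta) {
      return("NOVEL_SITE_CREATION")
    }
    if (v$intron_offset[i] == 0L && exon_skip_event[i]) {
      return("POSSIBLE_ESE_DISRUPTION")
    }
    "UNKNOWN"
  }, character(1L))
  v
}

# score ref/alt PWM windows overlapping normalized position g for a
# substitution to `alt_base`; returns one row per evaluable window
pwm_deltas_at <- function(nm, g, alt_base) {
  rows <- list()
  native_don <- nm$exons$end[-nm$n]           # last exonic base per intron
  native_acc <- nm$exons$start[-1L] + 1L      # first exonic base of exons 2..n
  seq_lo <- nm$span_lo + 1L
  seq_hi <- nm$span_hi
  eval_win <- function(from, to, native, type) {
    if (from < seq_lo || to > seq_hi) return(NULL)
    refw <- norm_seq_window(nm, from, to)
    off <- g - from + 1L
    altw <- refw
    substr(altw, off, off) <- alt_base
    if (identical(refw, altw)) return(NULL)
    tibble::tibble(
      delta = splice_site_strength(altw, type) - splice_site_strength(refw, type),
      native = native, site_type = type)
  }
  for (e in seq.int(g - 6L, g + 2L)) {
    w <- donor_window_at(e)
    rows[[length(rows) + 1L]] <- eval_win(w[["from"]], w[["to"]],
                                          e %in% native_don, "donor")
  }
  for (f in seq.int(g - 2L, g + 20L)) {
    w <- acceptor_window_at(f)
    rows[[length(rows) + 1L]] <- eval_win(w[["from"]], w[["to"]],
                                          f %in% native_acc, "acceptor")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) tibble::tibble(delta = numeric(), native = logical(),
                                      site_type = character())
  else out
}

#' Integrate RNA evidence for variants
#'
#' For each variant, gathers splicing events detected in its carriers within
#' a genomic window of the variant, takes the specific event with the highest
#' carrier PSI, counts additional carriers reproducing the same event, and
#' decides the overall association: `associated` requires a specific event
#' and either at least one reproducing carrier or an inferred mechanism.
#' Variants whose carriers lack RNA data are `indeterminate`; variants with
#' adequate junction coverage but no qualifying event are `not_associated`.
#'
#' @param variants Variant tibble (with `variant_id`, `pos`, `carrier_ids`,
#'   and a `mechanism` column from [mechanism_inference()]; missing
#'   mechanisms are treated as `UNKNOWN`).
#' @param events Event tibble across carrier samples ([detect_events()]).
#' @param psi Specificity-annotated carrier PSI ([specificity_test()] output,
#'   one row per event per carrier sample).
#' @param carrier_junctions Stacked junction tibble for carrier samples (used
#'   to judge coverage when no event is found).
#' @param model A [gene_model()].
#' @param window Maximum distance (nt) between variant and event junctions
#'   (default 5000).
#' @param min_denominator Coverage needed for a determinate negative call
#'   (default 100).
#' @return One row per variant: `variant_id`, `event_key`, `carrier_psi`,
#'   `region_total_reads`, `specificity`, `n_reproducing_carriers`,
#'   `mechanism`, `frame_effect`, `needs_rtpcr`, `overall`.
#' @export
associate <- function(variants, events, psi, carrier_junctions, model,
                      window = 5000L, min_denominator = 100L) {
  v <- tibble::as_tibble(variants)
  if (!"mechanism" %in% names(v)) v$mechanism <- "UNKNOWN"
  psi <- tibble::as_tibble(psi)
  for (col in c("event_key", "sample_id", "psi", "region_total_reads",
                "specificity")) {
    if (!col %in% names(psi)) {
      psi[[col]] <- if (col %in% c("psi")) numeric(0) else
        if (col == "region_total_reads") integer(0) else character(0)
    }
  }
  ev <- dplyr::left_join(
    events, psi[, c("event_key", "sample_id", "psi", "region_total_reads",
                    "specificity")],
    by = c("event_key", "sample_id"))
  cj <- canonical_junctions(model)
  ct <- tibble::as_tibble(carrier_junctions)

  purrr::map_dfr(seq_len(nrow(v)), function(i) {
    out <- tibble::tibble(
      variant_id = v$variant_id[i], event_key = NA_character_,
      carrier_psi = NA_real_, region_total_reads = NA_integer_,
      specificity = NA_character_, n_reproducing_carriers = 0L,
      mechanism = v$mechanism[i], frame_effect = "not_applicable",
      needs_rtpcr = NA, overall = "indeterminate")
    carriers <- v$carrier_ids[[i]]
    has_rna <- length(carriers) > 0L && any(ct$sample_id %in% carriers)
    if (!has_rna) return(out)
    near <- ev$sample_id %in% carriers &
      purrr::map_lgl(ev$junctions, function(j) {
        any(j$intron_start - window <= v$pos[i] & j$intron_end + window >= v$pos[i])
      }) & ev$event_type != "UNCLASSIFIED"
    cand <- ev[near, ]
    spec <- cand[!is.na(cand$specificity) & cand$specificity == "specific", ]
    if (nrow(spec) > 0L) {
      best <- spec[which.max(spec$psi), ]
      repro <- ev$event_key == best$event_key & ev$sample_id %in% carriers &
        ev$sample_id != best$sample_id & !is.na(ev$specificity) &
        ev$specificity == "specific"
      out$event_key <- best$event_key
      out$carrier_psi <- best$psi
      out$region_total_reads <- best$region_total_reads
      out$specificity <- "specific"
      out$n_reproducing_carriers <- length(unique(ev$sample_id[repro]))
      out$frame_effect <- best$frame_effect
      out$needs_rtpcr <- needs_rtpcr_confirmation(best$region_total_reads)
      out$overall <- if (out$n_reproducing_carriers >= 1L ||
                         out$mechanism != "UNKNOWN") "associated" else "indeterminate"
      return(out)
    }
    # no specific event: determinate negative only with adequate coverage
    if (nrow(cand) > 0L && all(cand$specificity == "indeterminate", na.rm = TRUE)) {
      return(out)
    }
    near_cov <- cj$intron_start - window <= v$pos[i] &
      cj$intron_end + window >= v$pos[i]
    cov <- ct[ct$sample_id %in% carriers &
                paste(ct$intron_start, ct$intron_end) %in%
                paste(cj$intron_start[near_cov], cj$intron_end[near_cov]), ]
    depth <- if (nrow(cov) == 0L) 0 else max(cov$unique_reads)
    if (nrow(cand) > 0L) {
      worst <- cand[which.max(cand$psi), ]
      out$event_key <- worst$event_key
      out$carrier_psi <- worst$psi
      out$region_total_reads <- worst$region_total_reads
      out$specificity <- worst$specificity
      out$frame_effect <- worst$frame_effect
      out$needs_rtpcr <- needs_rtpcr_confirmation(worst$region_total_reads)
    } else {
      out$region_total_reads <- as.integer(depth)
    }
    out$overall <- if (depth >= min_denominator) "not_associated" else "indeterminate"
    out
  })
}

#' RNA-informed reclassification
#'
#' Applies a deterministic rule set in place of expert review, with a
#' machine-readable reason for every decision:
#' * upgrade: a VUS with an associated, specific event that alters the coding
#'   region (frameshift or in-frame coding change), whose PSI denominator is
#'   adequate (or the event was orthogonally confirmed), becomes LP;
#' * tandem duplication upgrade: a gross-duplication VUS whose back-junction
#'   confirms a tandem configuration with a frameshift becomes LP;
#' * downgrade: a splicing-candidate VUS with no associated event at adequate
#'   coverage, lying beyond the canonical dinucleotides (|offset| > 2),
#'   becomes LB;
#' * confirm: an associated event under a prior P/LP leaves the class
#'   unchanged (impact `confirm`, not counted as an RNA reclassification);
#' * anything else: no impact.
#'
#' @param variants Variant tibble with `variant_id`, `classification`,
#'   `intron_offset`, `insilico_deleterious`, `variant_type`.
#' @param evidence Association evidence ([associate()] output), optionally
#'   with a logical `tandem` column from [tandem_duplication_check()].
#' @param confirmed Logical (recycled): the event was confirmed by RT-PCRseq.
#' @param adequate_depth Minimum PSI denominator treated as adequate for a
#'   downgrade (default 500).
#' @return One row per variant: `variant_id`, `prior_classification`,
#'   `rna_informed_classification`, `impact`, `reason`.
#' @export
reclassify <- function(variants, evidence, confirmed = FALSE,
                       adequate_depth = 500L) {
  v <- tibble::as_tibble(variants)
  e <- tibble::as_tibble(evidence)
  if (!"tandem" %in% names(e)) e$tandem <- FALSE
  d <- dplyr::left_join(
    v, e[, c("variant_id", "overall", "frame_effect", "needs_rtpcr",
             "region_total_reads", "tandem")],
    by = "variant_id")
  d$confirmed <- rep_len(confirmed, nrow(d))
  candidate <- is_splicing_candidate(v, has_abnormal_rna = d$overall %in% "associated")

  coding_altered <- d$frame_effect %in% c("frameshift", "in_frame")
  upgrade <- d$classification == "VUS" & d$overall %in% "associated" &
    coding_altered & (!dplyr::coalesce(d$needs_rtpcr, TRUE) | d$confirmed)
  dup_upgrade <- d$classification == "VUS" & d$variant_type %in% "gross_del_dup" &
    dplyr::coalesce(d$tandem, FALSE) & d$frame_effect %in% "frameshift"
  downgrade <- d$classification == "VUS" & candidate &
    d$overall %in% "not_associated" & abs(d$intron_offset) > 2L &
    dplyr::coalesce(d$region_total_reads, 0L) >= adequate_depth
  confirm <- d$classification %in% c("P", "LP") & d$overall %in% "associated"

  impact <- dplyr::case_when(
    upgrade | dup_upgrade ~ "upgrade",
    downgrade ~ "downgrade",
    confirm ~ "confirm",
    TRUE ~ "none"
  )
  tibble::tibble(
    variant_id = d$variant_id,
    prior_classification = d$classification,
    rna_informed_classification = dplyr::case_when(
      impact == "upgrade" ~ "LP",
      impact == "downgrade" ~ "LB",
      TRUE ~ d$classification
    ),
    impact = impact,
    reason = dplyr::case_when(
      dup_upgrade ~ "tandem duplication with frameshift back-junction",
      upgrade ~ "associated specific event altering coding region",
      downgrade ~ "splicing candidate with no event at adequate coverage",
      confirm ~ "RNA evidence concordant with prior P/LP",
      TRUE ~ ""
    )
  )
}
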