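# helper: one hypothesized event with given novel junction(s)
hyp_event <- function(model, starts, ends, type) {
  tibble::tibble(
    event_key = splicedx:::event_key_of(model$chrom, starts, ends),
    event_type = type,
    junctions = list(tibble::tibble(chrom = model$chrom,
                                    intron_start = as.integer(starts),
                                    intron_end = as.integer(ends),
                                    strand = model$strand)))
}

test_that("PSI is supporting reads over region total reads", {
  m <- toy_gene(3)
  cj <- canonical_junctions(m)
  ev <- hyp_event(m, cj$intron_start[1], cj$intron_end[2], "ESF")
  # novel 30 reads, both overlapped canonical junctions 70 reads
  j <- jt(m, c(cj$intron_start[1], cj$intron_start[1], cj$intron_start[2]),
          c(cj$intron_end[2], cj$intron_end[1], cj$intron_end[2]),
          reads = c(30L, 70L, 70L))
  p <- compute_psi(ev, j, m)
  expect_equal(p$supporting_reads, 30L)
  expect_equal(p$region_total_reads, 100L)
  expect_equal(p$psi, 0.30)
  # novel absent, canonical 500: PSI 0
  j0 <- jt(m, cj$intron_start, cj$intron_end, reads = 500L)
  p <- compute_psi(ev, j0, m)
  expect_equal(p$psi, 0)
  # no coverage at all: undefined, flagged
  p <- compute_psi(ev, jt(m, cj$intron_start[1], cj$intron_end[1], reads = 0L), m)
  expect_true(p$no_coverage)
  expect_true(is.na(p$psi))
})

test_that("cryptic-exon PSI uses the rounded mean of flanking junctions", {
  m <- toy_gene(3)
  cj <- canonical_junctions(m)
  cs <- cj$intron_start[1] + 100L
  ev <- hyp_event(m, c(cj$intron_start[1], cs + 150L),
                  c(cs - 1L, cj$intron_end[1]), "IC")
  j <- jt(m, c(cj$intron_start[1], cs + 150L, cj$intron_start[1]),
          c(cs - 1L, cj$intron_end[1], cj$intron_end[1]),
          reads = c(38L, 42L, 60L))
  p <- compute_psi(ev, j, m)
  expect_equal(p$supporting_reads, 40L)       # mean(38, 42)
  expect_equal(p$region_total_reads, 100L)    # + host canonical 60
  expect_equal(p$psi, 0.40)
})

test_that("control profiles summarise per-sample PSI exactly", {
  m <- toy_gene(3)
  cj <- canonical_junctions(m)
  ev <- hyp_event(m, cj$intron_start[1], cj$intron_end[2], "ESF")
  # event absent in all 10 controls with canonical coverage
  ctl <- purrr::map_dfr(1:10, function(i) {
    jt(m, cj$intron_start, cj$intron_end, reads = 800L,
       sample_id = sprintf("c%02d", i))
  })
  prof <- control_profile(ev, ctl, m)
  expect_equal(prof$median_psi, 0)
  expect_equal(prof$max_psi, 0)
  expect_equal(prof$n_controls, 10L)
  expect_equal(prof$n_undefined, 0L)

  # per-sample PSI {0, 0, 0.01, 0.02} via exact junction counts (depth 100)
  novel <- c(0L, 0L, 1L, 2L)
  ctl <- purrr::map_dfr(1:4, function(i) {
    dplyr::bind_rows(
      jt(m, cj$intron_start, cj$intron_end, reads = 100L - novel[i],
         sample_id = paste0("c", i)),
      if (novel[i] > 0) jt(m, cj$intron_start[1], cj$intron_end[2],
                           reads = novel[i], sample_id = paste0("c", i)))
  })
  prof <- control_profile(ev, ctl, m)
  expect_equal(prof$median_psi, 0.005)
  expect_equal(prof$max_psi, 0.02)
  # statistics match a brute-force recomputation from the per-sample PSI
  ps <- sort(prof$per_sample_psi[[1]])
  expect_equal(prof$median_psi, stats::median(ps))
  expect_equal(prof$p95_psi, as.numeric(stats::quantile(ps, 0.95)))
  expect_equal(prof$max_psi, max(ps))
  expect_error(control_profile(ev, ctl[0, ], m), "empty")
})

test_that("control medians of simulated pools sit inside the binomial band", {
  m <- toy_gene(3)
  bp <- event_blueprint(m, "ESF", exon = 2)
  depth <- 1000L
  ctl <- purrr::map_dfr(1:60, function(i) {
    simulate_sample(m, list(bp), 0.01, depth = depth,
                    sample_id = sprintf("c%03d", i), seed = 3000L + i)
  })
  ev <- hyp_event(m, bp$junctions$intron_start, bp$junctions$intron_end, "ESF")
  prof <- control_profile(ev, ctl, m)
  band <- stats::qbinom(c(0.005, 0.995), depth, 0.01) / depth
  expect_gte(prof$median_psi, band[1])
  expect_lte(prof$median_psi, band[2])
})

test_that("specificity requires PSI above floor and fold over controls", {
  base <- tibble::tibble(event_key = "e", sample_id = "s",
                         supporting_reads = 35L, region_total_reads = 100L,
                         psi = 0.35, no_coverage = FALSE)
  ctl0 <- tibble::tibble(event_key = "e", median_psi = 0, p95_psi = 0, max_psi = 0)
  expect_equal(specificity_test(base, ctl0)$specificity, "specific")
  # carrier 0.02 vs controls p95 0.02: fails both criteria
  low <- dplyr::mutate(base, psi = 0.02, supporting_reads = 2L)
  ctl <- dplyr::mutate(ctl0, p95_psi = 0.02, max_psi = 0.03)
  expect_equal(specificity_test(low, ctl)$specificity, "not_specific")
  # denominator below the floor: indeterminate regardless of PSI
  thin <- dplyr::mutate(base, region_total_reads = 80L)
  expect_equal(specificity_test(thin, ctl0)$specificity, "indeterminate")
})

test_that("specificity is monotone in carrier PSI", {
  ctl <- tibble::tibble(event_key = "e", median_psi = 0.002, p95_psi = 0.015,
                        max_psi = 0.03)
  psis <- seq(0, 1, by = 0.01)
  obs <- tibble::tibble(event_key = "e", sample_id = "s",
                        supporting_reads = as.integer(psis * 1000),
                        region_total_reads = 1000L, psi = psis,
                        no_coverage = FALSE)
  calls <- specificity_test(obs, ctl)$specificity
  # once specific, always specific as PSI grows
  first <- match("specific", calls)
  expect_false(is.na(first))
  expect_true(all(calls[first:length(calls)] == "specific"))
})

test_that("RT-PCR confirmation triggers strictly below 500x", {
  expect_true(needs_rtpcr_confirmation(499L))
  expect_false(needs_rtpcr_confirmation(500L))
  expect_false(needs_rtpcr_confirmation(10000L))
})

test_that("allele skew uses an exact two-sided binomial test", {
  r <- allele_skew_test(50L, 50L)
  expect_equal(r$p_value, 1.0)
  expect_equal(r$call, "balanced")
  r <- allele_skew_test(80L, 20L)
  expect_equal(r$call, "skewed")
  # independent oracle: two-sided exact tail sum for a symmetric null
  expect_equal(r$p_value, 2 * stats::pbinom(20, 100, 0.5), tolerance = 1e-12)
  r <- allele_skew_test(6L, 4L)
  expect_equal(r$call, "indeterminate")
})

test_that("RNA sample QC applies all four thresholds", {
  qc <- function(q30, mbq, idx, cov) {
    rna_sample_qc(tibble::tibble(pct_q30 = q30, mean_base_quality = mbq,
                                 pct_perfect_index = idx, pct_exons_ge_50x = cov))
  }
  expect_true(qc(80, 35, 90, 90)$passed)
  r <- qc(80, 35, 90, 80)
  expect_false(r$passed)
  expect_match(r$failure_reasons, "exon coverage")
  r <- qc(70, 35, 90, 90)
  expect_false(r$passed)
  expect_match(r$failure_reasons, "Q30")
  # boundaries are strict for the sequencing metrics, inclusive for coverage
  expect_false(qc(75, 35, 90, 90)$passed)
  expect_false(qc(80, 30, 90, 90)$passed)
  expect_false(qc(80, 35, 85, 90)$passed)
  expect_true(qc(75.1, 30.1, 85.1, 85)$passed)
  expect_error(rna_sample_qc(tibble::tibble(pct_q30 = 80)), "missing")
})
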