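# small helper: run the RNA arm (detect / psi / controls / specificity) for
# one carrier junction table against simulated clean controls
rna_arm <- function(model, carrier_jt, n_controls = 12L, depth = 1000L) {
  events <- detect_events(carrier_jt, model)
  ctl <- purrr::map_dfr(seq_len(n_controls), function(i) {
    simulate_sample(model, list(), numeric(0), depth = depth,
                    sample_id = sprintf("ctl%02d", i), seed = 400L + i)
  })
  uniq <- dplyr::distinct(events, event_key, .keep_all = TRUE)
  psi <- compute_psi(uniq, carrier_jt, model)
  prof <- control_profile(uniq, ctl, model)
  list(events = events, psi = specificity_test(psi, prof), controls = ctl)
}

test_that("a +1 substitution at a native donor weakens the site", {
  m <- make_gene_model(n_exons = 4L, seed = 21L)
  nm <- splicedx:::norm_model(m)
  v <- tibble::tibble(coding_pos = splicedx:::coding_of_exon_end(nm, 1L),
                      intron_offset = 1L, ref = "G", alt = "A")
  out <- mechanism_inference(v, m)
  expect_equal(out$mechanism, "NATIVE_SITE_WEAKENING")
})

test_that("mechanism falls back to UNKNOWN or ESE without sequence signal", {
  m <- make_gene_model(n_exons = 4L, seed = 22L)
  m_noseq <- m; m_noseq$seq <- NULL
  v <- tibble::tibble(coding_pos = 50L, intron_offset = 0L, ref = "A", alt = "G")
  expect_equal(mechanism_inference(v, m_noseq)$mechanism, "UNKNOWN")
  # exonic, no site-score change, associated exon-skip event: ESE flag
  nm <- splicedx:::norm_model(m)
  mid <- tibble::tibble(coding_pos = splicedx:::coding_of_exon_start(nm, 2L) + 50L,
                        intron_offset = 0L, ref = "N", alt = "N")
  mid$ref <- substr(as.character(m$seq),
                    splicedx:::norm_of_tx(nm, mid$coding_pos) - nm$span_lo,
                    splicedx:::norm_of_tx(nm, mid$coding_pos) - nm$span_lo)
  mid$alt <- c(A = "T", C = "A", G = "C", T = "G")[[mid$ref]]
  out <- mechanism_inference(mid, m, exon_skip_event = TRUE)
  expect_true(out$mechanism %in% c("POSSIBLE_ESE_DISRUPTION", "NOVEL_SITE_CREATION",
                                   "NATIVE_SITE_WEAKENING"))
  out2 <- mechanism_inference(mid, m, exon_skip_event = FALSE)
  expect_true(out2$mechanism != "POSSIBLE_ESE_DISRUPTION" ||
                out$mechanism == "POSSIBLE_ESE_DISRUPTION")
})

test_that("deep-intronic cryptic-exon variants associate and upgrade", {
  fx <- fixture_cases()$APC_like
  arm <- rna_arm(fx$model, fx$carrier_junctions)
  v <- mechanism_inference(fx$variant, fx$model)
  ev <- associate(v, arm$events, arm$psi, fx$carrier_junctions, fx$model)
  expect_equal(ev$overall, "associated")
  expect_equal(ev$specificity, "specific")
  expect_equal(ev$mechanism, "NOVEL_SITE_CREATION")
  out <- reclassify(v, ev)
  expect_equal(out$impact, "upgrade")
  expect_equal(out$rna_informed_classification, "LP")
})

test_that("events present in controls at similar PSI are not specific", {
  fx <- fixture_cases()$APC_like
  m <- fx$model
  events <- detect_events(fx$carrier_junctions, m)
  # adversarial controls: same event at PSI ~0.3 in every donor
  nj <- events$junctions[[1]]
  bp <- list(type = "IC", junctions = nj, event_key = events$event_key[1])
  ctl <- purrr::map_dfr(1:12, function(i) {
    simulate_sample(m, list(bp), 0.30, depth = 1000L,
                    sample_id = sprintf("ctl%02d", i), seed = 500L + i)
  })
  psi <- specificity_test(compute_psi(events, fx$carrier_junctions, m),
                          control_profile(events, ctl, m))
  expect_equal(psi$specificity, "not_specific")
  v <- mechanism_inference(fx$variant, m)
  ev <- associate(v, events, psi, fx$carrier_junctions, m)
  expect_false(ev$overall == "associated")
  # invariant: no upgrade without specificity
  out <- reclassify(v, ev)
  expect_true(out$impact != "upgrade")
})

test_that("absence of a junction at adequate depth is a determinate negative", {
  m <- make_gene_model(n_exons = 4L, seed = 23L)
  nm <- splicedx:::norm_model(m)
  carrier <- simulate_sample(m, list(), numeric(0), depth = 2000L,
                             sample_id = "car1", seed = 31L)
  v <- tibble::tibble(
    variant_id = "G:c.x+15", gene = m$gene, chrom = m$chrom,
    pos = cdna_to_genomic(m, splicedx:::coding_of_exon_end(nm, 1L), 15L),
    ref = "A", alt = "G", coding_pos = splicedx:::coding_of_exon_end(nm, 1L),
    intron_offset = 15L, variant_type = "splicing", classification = "VUS",
    insilico_deleterious = TRUE, carrier_ids = list("car1"),
    mechanism = "UNKNOWN")
  ev <- associate(v, splicedx:::empty_events(), tibble::tibble(), carrier, m)
  expect_equal(ev$overall, "not_associated")
  out <- reclassify(v, ev)
  expect_equal(out$impact, "downgrade")
  expect_equal(out$rna_informed_classification, "LB")
  # with a thin RNA sample the same variant stays indeterminate: no downgrade
  thin <- dplyr::mutate(carrier, unique_reads = 50L)
  ev2 <- associate(v, splicedx:::empty_events(), tibble::tibble(), thin, m)
  expect_equal(ev2$overall, "indeterminate")
  expect_equal(reclassify(v, ev2)$impact, "none")
  # no RNA sample at all: indeterminate
  ev3 <- associate(v, splicedx:::empty_events(), tibble::tibble(), carrier[0, ], m)
  expect_equal(ev3$overall, "indeterminate")
})

test_that("associated events under a prior P/LP confirm without reclassification", {
  fx <- fixture_cases()$ATM_like
  arm <- rna_arm(fx$model, fx$carrier_junctions)
  v <- mechanism_inference(fx$variant, fx$model)
  v$classification <- "P"
  ev <- associate(v, arm$events, arm$psi, fx$carrier_junctions, fx$model)
  out <- reclassify(v, ev)
  expect_equal(out$impact, "confirm")
  expect_equal(out$rna_informed_classification, "P")
})

test_that("reproducibility in a second carrier substitutes for a mechanism", {
  m <- make_gene_model(n_exons = 5L, seed = 24L)
  bp <- event_blueprint(m, "ESF", exon = 3L)
  cars <- purrr::map_dfr(1:2, function(i) {
    simulate_sample(m, list(bp), 0.35, depth = 1000L,
                    sample_id = paste0("car", i), seed = 600L + i)
  })
  events <- detect_events(cars, m)
  ctl <- purrr::map_dfr(1:10, function(i) {
    simulate_sample(m, list(), numeric(0), depth = 1000L,
                    sample_id = sprintf("ctl%02d", i), seed = 700L + i)
  })
  uniq <- dplyr::distinct(events, event_key, .keep_all = TRUE)
  psi <- purrr::map_dfr(c("car1", "car2"), function(s) {
    compute_psi(uniq, cars[cars$sample_id == s, ], m, sample_id = s)
  })
  psi <- specificity_test(psi, control_profile(uniq, ctl, m))
  nm <- splicedx:::norm_model(m)
  v <- tibble::tibble(
    variant_id = "G:v1", gene = m$gene, chrom = m$chrom,
    pos = cdna_to_genomic(m, splicedx:::coding_of_exon_start(nm, 3L), -2L),
    ref = "A", alt = "G",
    coding_pos = splicedx:::coding_of_exon_start(nm, 3L), intron_offset = -2L,
    variant_type = "splicing", classification = "VUS",
    insilico_deleterious = FALSE, carrier_ids = list(c("car1", "car2")),
    mechanism = "UNKNOWN")
  ev <- associate(v, events, psi, cars, m)
  expect_equal(ev$overall, "associated")
  expect_equal(ev$n_reproducing_carriers, 1L)
  # single carrier, no mechanism: specific but not associated
  v1 <- dplyr::mutate(v, carrier_ids = list("car1"))
  ev1 <- associate(v1, events[events$sample_id == "car1", ],
                   psi[psi$sample_id == "car1", ],
                   cars[cars$sample_id == "car1", ], m)
  expect_equal(ev1$overall, "indeterminate")
})
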