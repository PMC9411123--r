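test_that("variant type proportions are exact on toy sets", {
  v <- tibble::tibble(
    variant_type = c(rep("missense", 7), rep("splicing", 2), "gross_del_dup"),
    classification = "VUS")
  d <- variant_type_distribution(v)
  expect_equal(d$pct[d$variant_type == "missense"], 70.0)
  expect_equal(d$pct[d$variant_type == "splicing"], 20.0)
  expect_equal(d$pct[d$variant_type == "gross_del_dup"], 10.0)
  expect_equal(sum(d$pct), 100.0, tolerance = 0.1)
  # single type
  one <- tibble::tibble(variant_type = "missense", classification = "P")
  expect_equal(variant_type_distribution(one)$pct, 100.0)
  expect_error(variant_type_distribution(one[0, ]), "no variants")
  # B/LB variants are excluded from the reported denominator
  v2 <- dplyr::bind_rows(v, tibble::tibble(variant_type = "other",
                                           classification = "B"))
  expect_equal(variant_type_distribution(v2), d)
})

test_that("simulated cohorts recover the generating type weights", {
  m <- make_gene_model(n_exons = 6L, seed = 5L)
  v <- simulate_variant_table(5000L, m, seed = 17L)
  d <- variant_type_distribution(v)
  w <- c(missense = 69.2, splicing = 6.2, gross_del_dup = 2.8, other = 21.8)
  for (ty in names(w)) {
    expect_lt(abs(d$pct[d$variant_type == ty] - w[[ty]]), 2)
  }
})

test_that("yield and VUS deltas reproduce the printed cohort arithmetic", {
  up <- tibble::tibble(individual_id = sprintf("i%03d", 1:87), impact = "upgrade",
                       gained_first_plp = TRUE, vus_resolved = TRUE)
  res <- tibble::tibble(individual_id = sprintf("r%03d", 1:305), impact = "downgrade",
                        gained_first_plp = FALSE, vus_resolved = TRUE)
  d <- yield_and_vus_delta(dplyr::bind_rows(up, dplyr::mutate(res, vus_resolved = TRUE)),
                           n_individuals = 43524)
  expect_equal(d$yield_delta_pct, 0.2)
  d2 <- yield_and_vus_delta(res, n_individuals = 43524)
  expect_equal(d2$vus_delta_pct, 0.7)
  # no upgrades
  expect_equal(yield_and_vus_delta(res, 43524)$yield_delta_pct, 0.0)
  # an individual with two upgrades counts once
  dup <- dplyr::bind_rows(up[1, ], up[1, ])
  expect_equal(yield_and_vus_delta(dup, 1000)$n_yield, 1L)
  # order invariance
  shuffled <- dplyr::bind_rows(res, up)[sample(392), ]
  expect_equal(yield_and_vus_delta(shuffled, 43524),
               yield_and_vus_delta(dplyr::bind_rows(up, res), 43524))
})

test_that("per-patient frequency supports both rounding conventions", {
  expect_equal(per_patient_frequency(28, 43524), 1554L)
  expect_equal(per_patient_frequency(1, 1000), 1000L)
  expect_equal(per_patient_frequency(3, 10, rounding = "ceiling"), 4L)
  expect_equal(per_patient_frequency(3, 10), 3L)
  expect_true(is.na(per_patient_frequency(0, 1000)))
})

test_that("position-classification cross-tab matches a hand tally", {
  v <- tibble::tibble(
    position_bin = factor(c(rep("CANONICAL_1_2", 4), rep("EXONIC_INTERNAL", 4),
                            rep("DEEP_INTRONIC_GT20", 2)),
                          levels = position_bin_levels()),
    classification = c("P", "P", "LP", "VUS", "VUS", "VUS", "VUS", "P",
                       "LP", "VUS"))
  tab <- position_classification_table(v)
  take <- function(b, c) tab$n[tab$position_bin == b & tab$classification == c]
  expect_equal(take("CANONICAL_1_2", "P"), 2L)
  expect_equal(take("CANONICAL_1_2", "VUS"), 1L)
  expect_equal(take("EXONIC_INTERNAL", "VUS"), 3L)
  pct <- tab$row_pct[tab$position_bin == "CANONICAL_1_2" & tab$classification == "P"]
  expect_equal(pct, 50.0)
  # marginals equal input counts
  expect_equal(sum(tab$n), nrow(v))
  by_bin <- tapply(tab$n, tab$position_bin, sum)
  expect_equal(unname(by_bin[["DEEP_INTRONIC_GT20"]]), 2L)
  # all-VUS input: 100% VUS in every non-empty row
  v2 <- dplyr::mutate(v, classification = "VUS")
  tab2 <- position_classification_table(v2)
  expect_true(all(tab2$row_pct[tab2$n > 0] == 100.0))
})

test_that("bin-conditional class rates are recovered from simulation", {
  m <- make_gene_model(n_exons = 6L, seed = 5L)
  v <- simulate_variant_table(2000L, m, seed = 23L)
  tab <- position_classification_table(v)
  can <- tab[tab$position_bin == "CANONICAL_1_2", ]
  plp <- sum(can$row_pct[can$classification %in% c("P", "LP")])
  expect_lt(abs(plp - 95.6), 3)
})

test_that("reported variant totals add the printed class counts", {
  expect_equal(reported_variant_total(4565, 565, 10158), 15288L)
  expect_equal(reported_variant_total(0, 0, 0), 0L)
  expect_equal(reported_variant_total(1, 2, 3), 6L)
})

test_that("event type counts cover the five-type taxonomy", {
  m <- toy_gene(4)
  cj <- canonical_junctions(m)
  ex <- m$exons
  j <- dplyr::bind_rows(
    jt(m, cj$intron_start[1], cj$intron_end[2]),
    jt(m, cj$intron_start[2], ex$start[3] + 30L),
    jt(m, cj$intron_start[2] + 25L, cj$intron_end[2]))
  counts <- event_type_counts(detect_events(j, m))
  expect_equal(counts$n[counts$event_type == "ESF"], 1L)
  expect_equal(counts$n[counts$event_type == "ESP"], 1L)
  expect_equal(counts$n[counts$event_type == "IP"], 1L)
  expect_equal(sum(counts$n), 3L)
})
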