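test_that("canonical junctions span each intron exactly", {
  m <- toy_gene(3)
  cj <- canonical_junctions(m)
  expect_equal(nrow(cj), 2L)                       # n_exons - 1
  expect_equal(cj$intron_start, c(1121L, 1541L))   # first intronic base
  expect_equal(cj$intron_end, c(1420L, 1840L))     # last intronic base
  # single-exon gene: no junctions
  expect_equal(nrow(canonical_junctions(toy_gene(1))), 0L)
  # identical genomic junctions regardless of strand (transcription order
  # reverses, the genomic coordinates do not)
  mm <- toy_gene(3, strand = "-")
  cjm <- canonical_junctions(mm)
  expect_equal(sort(cjm$intron_start), cj$intron_start)
  expect_equal(sort(cjm$intron_end), cj$intron_end)
})

test_that("the five-type taxonomy is assigned from junction geometry", {
  m <- toy_gene(4)
  cj <- canonical_junctions(m)
  ex <- m$exons
  # exon1 donor -> exon3 acceptor: full skip of exon 2
  ev <- detect_events(jt(m, cj$intron_start[1], cj$intron_end[2]), m)
  expect_equal(ev$event_type, "ESF")
  expect_equal(ev$skipped_exons[[1]], 2L)
  # acceptor 30 nt inside exon 3: partial skip
  ev <- detect_events(jt(m, cj$intron_start[2], ex$start[3] + 30L), m)
  expect_equal(ev$event_type, "ESP")
  # donor 25 nt inside intron 2, acceptor canonical: intron inclusion partial
  ev <- detect_events(jt(m, cj$intron_start[2] + 25L, cj$intron_end[2]), m)
  expect_equal(ev$event_type, "IP")
  # skip exon 2 fully AND truncate exon 3: combined
  ev <- detect_events(jt(m, cj$intron_start[1], ex$start[3] + 30L), m)
  expect_equal(ev$event_type, "ES")
  expect_equal(ev$skipped_exons[[1]], 2L)
  # two novel junctions inside intron 1 bounding a 150-nt interval: one IC
  cs <- cj$intron_start[1] + 100L                  # cryptic exon start
  ev <- detect_events(jt(m, c(cj$intron_start[1], cs + 150L),
                         c(cs - 1L, cj$intron_end[1])), m)
  expect_equal(ev$event_type, "IC")
  expect_equal(ev$cryptic_end[1] - ev$cryptic_start[1] + 1L, 150L)
  # canonical junction: not an event
  ev <- detect_events(jt(m, cj$intron_start[1], cj$intron_end[1]), m)
  expect_equal(nrow(ev), 0L)
})

test_that("classify_event answers for hypothesized junction sets", {
  m <- toy_gene(4)
  cj <- canonical_junctions(m)
  expect_equal(classify_event(jt(m, cj$intron_start[2] + 25L, cj$intron_end[2]), m),
               "IP")
  expect_equal(classify_event(jt(m, cj$intron_start[1], cj$intron_end[1]), m),
               "CANONICAL")
  # trans-gene geometry: unclassifiable, flagged
  ev <- detect_events(jt(m, cj$intron_start[1], cj$intron_end[2] - 15L), m)
  expect_equal(ev$event_type, "UNCLASSIFIED")
  expect_match(ev$flags, "not adjacent")
})

test_that("junctions below min_reads or outside the gene are not events", {
  m <- toy_gene(3)
  cj <- canonical_junctions(m)
  j <- jt(m, cj$intron_start[1], cj$intron_end[2], reads = 2L)
  expect_equal(nrow(detect_events(j, m, min_reads = 3L)), 0L)
  j$unique_reads <- 3L
  expect_equal(nrow(detect_events(j, m, min_reads = 3L)), 1L)
  out <- jt(m, 10L, 50L)
  expect_warning(ev <- detect_events(out, m), "outside")
  expect_equal(nrow(ev), 0L)
})

test_that("every novel junction above threshold lands in exactly one event", {
  m <- toy_gene(4)
  cj <- canonical_junctions(m)
  ex <- m$exons
  cs <- cj$intron_start[3] + 80L
  j <- jt(m,
          c(cj$intron_start[1], cj$intron_start[2], cj$intron_start[3], cs + 90L),
          c(cj$intron_end[2], ex$start[2] + 150L, cs - 1L, cj$intron_end[3]))
  ev <- detect_events(j, m)
  used <- dplyr::bind_rows(ev$junctions)
  expect_equal(nrow(used), 4L)                    # all junctions assigned
  expect_equal(nrow(dplyr::distinct(used, intron_start, intron_end)), 4L)
})

test_that("classifier agrees with the geometric oracle exhaustively", {
  for (n_ex in 2:4) {
    m <- toy_gene(n_ex, exon_len = 120L, intron_len = 300L)
    ends <- enumerate_junction_ends(m)
    grid <- tidyr::expand_grid(a = ends$donors, b = ends$acceptors)
    grid <- grid[grid$b > grid$a, ]
    grid$sample_id <- sprintf("j%04d", seq_len(nrow(grid)))
    j <- tibble::tibble(chrom = m$chrom, intron_start = grid$a,
                        intron_end = grid$b, strand = "+",
                        unique_reads = 10L, sample_id = grid$sample_id)
    ev <- detect_events(j, m, min_reads = 1L)
    got <- rep("CANONICAL", nrow(grid))
    names(got) <- grid$sample_id
    got[ev$sample_id] <- ev$event_type
    want <- vapply(seq_len(nrow(grid)), function(i) {
      oracle_classify(m, grid$a[i], grid$b[i])
    }, character(1))
    expect_identical(unname(got), want)
    # full intron retention is never emitted
    expect_true(all(got %in% c("CANONICAL", "ESF", "ESP", "ES", "IP", "IC",
                               "UNCLASSIFIED")))
  }
})

test_that("frame effect follows the net coding-length change mod 3", {
  m <- toy_gene(4, exon_len = 120L)         # 120 mod 3 == 0
  cj <- canonical_junctions(m)
  ev <- detect_events(jt(m, cj$intron_start[1], cj$intron_end[2]), m)
  expect_equal(ev$frame_effect, "in_frame")   # full 120-nt exon skip
  # 121-nt cryptic exon insertion
  cs <- cj$intron_start[2] + 60L
  ev <- detect_events(jt(m, c(cj$intron_start[2], cs + 121L),
                         c(cs - 1L, cj$intron_end[2])), m)
  expect_equal(ev$frame_effect, "frameshift")
  # UTR-only event: gene whose CDS excludes exon 1
  ex <- tibble::tibble(start = c(1000, 1500, 2000), end = c(1120, 1620, 2120))
  mu <- gene_model("UTR", "chrT", "+", ex, cds_start = 1520, cds_end = 2100)
  cju <- canonical_junctions(mu)
  evu <- detect_events(jt(mu, cju$intron_start[1] + 20L, cju$intron_end[1]), mu)
  expect_equal(evu$event_type, "IP")
  expect_equal(evu$frame_effect, "not_applicable")
})

test_that("tandem duplications are recognised by their back-junction", {
  m <- toy_gene(5)
  ex <- m$exons
  bj_start <- ex$start[3] + 1L
  bj_end <- ex$end[5]
  j <- jt(m, bj_start, bj_end, reads = 40L)
  res <- tandem_duplication_check(j, m, dup_exons = c(3L, 5L))
  expect_true(res$tandem)
  expect_equal(res$supporting_reads, 40L)
  # no back-junction
  cj <- canonical_junctions(m)
  res <- tandem_duplication_check(jt(m, cj$intron_start[1], cj$intron_end[1]),
                                  m, dup_exons = c(3L, 5L))
  expect_false(res$tandem)
  expect_equal(res$flag, "no back-junction")
  # below threshold: flagged low evidence
  res <- tandem_duplication_check(jt(m, bj_start, bj_end, reads = 2L), m,
                                  dup_exons = c(3L, 5L))
  expect_false(res$tandem)
  expect_equal(res$flag, "low evidence")
  # no junctions over the gene at all
  res <- tandem_duplication_check(jt(m, 1L, 5L), m, dup_exons = c(3L, 5L))
  expect_equal(res$flag, "insufficient data")
})
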