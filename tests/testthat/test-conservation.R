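test_that("column consensus matches hand counts", {
  rows <- c(a = "C", b = "C", c = "C", d = "C")
  cc <- column_consensus(gpx_alignment(rows), 1)
  expect_identical(cc$consensus, "C")
  expect_equal(cc$proportion, 1.0)

  # 10 rows: 6 L, 3 V, 1 G; {L,V} share a partition cell -> 0.9 grouped
  rows2 <- setNames(c(rep("L", 6), rep("V", 3), "G"), letters[1:10])
  aln2 <- gpx_alignment(rows2)
  single <- column_consensus(aln2, 1)
  expect_equal(single$proportion, 0.6)
  grouped <- column_consensus(aln2, 1, default_grouping())
  expect_setequal(grouped$group, c("L", "V"))
  expect_equal(grouped$proportion, 0.9)

  # all-gap column: proportion 0, gap fraction 1 (documented convention)
  rows3 <- c(a = "-A", b = "-C")
  cc3 <- column_consensus(gpx_alignment(rows3), 1)
  expect_equal(cc3$proportion, 0)
  expect_equal(cc3$gap_fraction, 1)
  expect_error(column_consensus(gpx_alignment(rows3), 5), "out of range")
})

test_that("profiles are permutation-invariant and grouped >= single", {
  set.seed(2)
  rows <- setNames(vapply(1:12, function(i) random_seq(40), ""),
                   sprintf("s%02d", 1:12))
  aln <- gpx_alignment(rows)
  p1 <- conservation_profile(aln)
  pg <- conservation_profile(aln, default_grouping())
  expect_true(all(pg$proportion >= p1$proportion - 1e-12))
  expect_true(all(p1$proportion >= 0 & p1$proportion <= 1))
  # permuting rows changes nothing
  perm <- gpx_alignment(rows[sample(names(rows))])
  expect_equal(conservation_profile(perm)$proportion, p1$proportion)
  # identical gap-free rows: all 1
  same <- gpx_alignment(setNames(rep(random_seq(25), 4), letters[1:4]))
  expect_true(all(conservation_profile(same)$proportion == 1))
})

test_that("ties in the modal letter break alphabetically", {
  rows <- setNames(c("V", "L", "V", "L"), letters[1:4])
  cc <- column_consensus(gpx_alignment(rows), 1)
  expect_identical(cc$consensus, "L")
})

test_that("conserved domains recover planted blocks", {
  # uniform profile: one segment covering everything
  prof <- data.frame(column = 1:100, consensus = "A", group = "A",
                     proportion = 1, gap_fraction = 0)
  d <- conserved_domains(prof)
  expect_equal(nrow(d$segments), 1)
  expect_equal(d$coverage, 1)

  # two planted 25-column blocks in 190 columns
  set.seed(4)
  rows <- t(vapply(1:20, function(i) sample(AA20, 190, replace = TRUE),
                   character(190)))
  rows[, 31:55] <- "L"; rows[, 101:125] <- "W"
  aln <- gpx_alignment(setNames(apply(rows, 1, paste, collapse = ""),
                                sprintf("s%02d", 1:20)))
  prof2 <- conservation_profile(aln)
  d2 <- conserved_domains(prof2, threshold = 0.7, min_run = 5)
  expect_equal(nrow(d2$segments), 2)
  expect_equal(d2$segments$start_column, c(31, 101), tolerance = 0)
  expect_equal(d2$segments$end_column, c(55, 125), tolerance = 0)
  expect_equal(d2$coverage, 50 / 190, tolerance = 2 / 190)

  # below threshold everywhere: nothing
  prof3 <- data.frame(column = 1:50, consensus = "A", group = "A",
                      proportion = 0.3, gap_fraction = 0)
  d3 <- conserved_domains(prof3)
  expect_equal(nrow(d3$segments), 0)
  expect_equal(d3$coverage, 0)
})

test_that("short interior breaks are bridged, long ones split", {
  p <- rep(1, 30)
  p[c(10, 11)] <- 0.2              # break of 2 <= max_break
  prof <- data.frame(column = 1:30, consensus = "A", group = "A",
                     proportion = p, gap_fraction = 0)
  d <- conserved_domains(prof, max_break = 2)
  expect_equal(nrow(d$segments), 1)
  p[c(20, 21, 22)] <- 0.2          # break of 3 > max_break
  prof$proportion <- p
  d2 <- conserved_domains(prof, max_break = 2)
  expect_equal(nrow(d2$segments), 2)
})

test_that("domain segmentation is idempotent on its own mask", {
  set.seed(6)
  prop <- runif(120)
  prof <- data.frame(column = 1:120, consensus = "A", group = "A",
                     proportion = prop, gap_fraction = 0)
  d1 <- conserved_domains(prof)
  mask <- rep(0, 120)
  for (i in seq_len(nrow(d1$segments)))
    mask[d1$segments$start_column[i]:d1$segments$end_column[i]] <- 1
  prof2 <- prof; prof2$proportion <- mask
  d2 <- conserved_domains(prof2)
  expect_equal(d2$segments$start_column, d1$segments$start_column)
  expect_equal(d2$segments$end_column, d1$segments$end_column)
})

test_that("residue reports mirror the conservation tables", {
  spec <- scaffold_spec(seed = 15)
  co <- synth_cohort(spec, c(TRX_GPXLIKE_PRX = 12), divergence = 0.1,
                     seed = 15)
  recs <- rbind(co$reference, co$records)
  class(recs) <- c("protein_records", "data.frame")
  aln <- progressive_msa(recs)
  cm <- map_reference_columns(aln, "scaffold")
  prof <- conservation_profile(aln, default_grouping())
  rep61 <- residue_report(prof, cm, c(61, 107, 9999),
                          labels = c("peroxidatic Cys", "resolving Cys", NA))
  expect_identical(rep61$consensus[1], "C")
  expect_gte(rep61$proportion[1], 0.9)   # protected -> fully conserved
  expect_identical(rep61$consensus[2], "C")
  expect_true(rep61$unmapped[3])
  expect_identical(rep61$label[2], "resolving Cys")
})
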