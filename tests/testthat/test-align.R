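test_that("single-residue and identical-sequence alignments are exact", {
  a1 <- global_align("A", "A")
  expect_equal(a1$score, 4)                     # BLOSUM62 (A,A)
  s <- "ACDEFGHIKL"
  a2 <- global_align(s, s)
  expect_identical(a2$aligned_a, s)
  expect_identical(a2$aligned_b, s)             # no gaps
  expect_error(global_align("", "A"), "non-empty")
  expect_error(global_align("A", "A", matrix = "NOPE"), "unknown")
})

test_that("alignment round-trips inputs and is score-symmetric", {
  set.seed(3)
  for (k in 1:20) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    aln <- global_align(a, b)
    expect_identical(gsub("-", "", aln$aligned_a), a)
    expect_identical(gsub("-", "", aln$aligned_b), b)
    # no dual-gap columns
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
    expect_equal(global_align(b, a)$score, aln$score)
  }
})

test_that("Gotoh scores equal the exhaustive-enumeration oracle", {
  set.seed(11)
  for (k in 1:60) {
    a <- random_seq(sample(1:8, 1))
    b <- random_seq(sample(1:8, 1))
    go <- sample(c(5, 10, 12), 1); ge <- sample(c(0.5, 1, 2), 1)
    expect_equal(global_align(a, b, gap_open = go, gap_extend = ge)$score,
                 oracle_align_score(a, b, gap_open = go, gap_extend = ge))
  }
})

test_that("selenocysteine aligns like Cys but is preserved verbatim", {
  aln <- global_align("ACUDE", "ACCDE")
  expect_match(aln$aligned_a, "U")
  SM <- scoring_matrix("BLOSUM62")
  expect_equal(SM["U", "C"], SM["C", "C"])
  expect_equal(unname(SM["X", "W"]), 0)
})

test_that("percent similarity follows the column-count definition", {
  same <- global_align("ACDEFGHIKL", "ACDEFGHIKL")
  expect_equal(percent_similarity(same), 100)
  expect_equal(percent_similarity(same, "identity"), 100)
  # fully mismatched, negative-scoring pair
  neg <- global_align("WWWW", "PPPP", gap_open = 100)
  expect_equal(percent_similarity(neg), 0)
  # hand-built 10-column case: 8 ungapped columns, 6 positive -> 75%
  hand <- structure(list(aligned_a = "ACDEFGHI-K",
                         aligned_b = "ACDEFGPGW-",
                         matrix_name = "BLOSUM62"),
                    class = "pairwise_alignment")
  SM <- scoring_matrix("BLOSUM62")
  ca <- strsplit(hand$aligned_a, "")[[1]]; cb <- strsplit(hand$aligned_b, "")[[1]]
  ung <- ca != "-" & cb != "-"
  expect_equal(sum(ung), 8)
  expect_equal(sum(SM[cbind(ca[ung], cb[ung])] > 0), 6)
  expect_equal(percent_similarity(hand), 75)
})

test_that("progressive MSA reduces to pairwise and keeps rows intact", {
  set.seed(5)
  a <- random_seq(30); b <- random_seq(28)
  recs <- protein_records(c("x", "y"), c(a, b))
  msa <- progressive_msa(recs)
  pw <- global_align(a, b)
  expect_identical(unname(msa$rows), c(pw$aligned_a, pw$aligned_b))
  # identical sequences: gap-free alignment
  recs3 <- protein_records(c("a", "b", "c"), rep(random_seq(40), 3))
  msa3 <- progressive_msa(recs3)
  expect_false(any(grepl("-", msa3$rows, fixed = TRUE)))
  expect_error(progressive_msa(recs3[1, ]), "at least 2")
})

test_that("MSA rows degap to their inputs and keep input order", {
  spec <- scaffold_spec(seed = 4)
  co <- synth_cohort(spec, c(TRX_GPXLIKE_PRX = 6, CANONICAL_GSH_GPX = 6),
                     divergence = 0.1, seed = 4)
  recs <- rbind(co$reference, co$records)
  class(recs) <- c("protein_records", "data.frame")
  msa <- progressive_msa(recs)
  expect_identical(names(msa$rows), recs$id)
  for (i in seq_len(nrow(recs)))
    expect_identical(degap(msa, recs$id[i]), recs$sequence[i])
})

test_that("diagnostic columns stay anchored at mild divergence", {
  spec <- scaffold_spec(seed = 10)
  co <- synth_cohort(spec, c(TRX_GPXLIKE_PRX = 25, CANONICAL_GSH_GPX = 25),
                     divergence = 0.05, seed = 10)
  recs <- rbind(co$reference, co$records)
  class(recs) <- c("protein_records", "data.frame")
  msa <- progressive_msa(recs)
  cm <- map_reference_columns(msa, "scaffold")
  M <- as.matrix(msa)
  # the planted tetrad letters sit in the mapped columns for >= 99% of rows
  expected <- c(`61` = NA, `95` = "Q", `150` = "W", `151` = "N")
  ok <- vapply(co$records$id, function(id) {
    all(M[id, cm$map[c(95, 150, 151)]] == c("Q", "W", "N")) &&
      M[id, cm$map[61]] %in% c("C", "U")
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("aligned FASTA import validates and round-trips", {
  rows <- c(r1 = "AC-DEF", r2 = "ACW.EF", r3 = "ACWDE-")
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "AC-DEF", ">r2", "ACW.EF", ">r3", "ACWDE-"), path)
  aln <- import_alignment(path)
  expect_equal(aln$n_columns, 6)
  expect_identical(aln$rows[["r2"]], "ACW-EF")  # '.' normalized
  out <- tempfile(fileext = ".fasta")
  export_alignment(aln, out)
  expect_identical(import_alignment(out)$rows, aln$rows)
  writeLines(c(">a", "ACDE", ">b", "AC"), path)
  expect_error(import_alignment(path), "ragged.*\\bb\\b|ragged")
})

test_that("gap-column masking removes gappy columns and trims ends", {
  rows <- c(a = "--ACD-EF--", b = "--ACDWEF--", c = "G-ACD-EF--")
  aln <- gpx_alignment(rows)
  full <- mask_gap_columns(aln, 0.5)
  expect_equal(attr(full, "kept_columns"), c(3L, 4L, 5L, 7L, 8L))
  ends <- mask_gap_columns(aln, 0.5, ends_only = TRUE)
  expect_equal(attr(ends, "kept_columns"), 3:8)
  # interior gappy column kept in ends_only mode when flanked
  rows2 <- c(a = "ACD-EF", b = "ACD-EF", c = "ACDWEF")
  keep2 <- mask_gap_columns(gpx_alignment(rows2), 0.5, ends_only = TRUE)
  expect_equal(attr(keep2, "kept_columns"), 1:6)
})
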