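test_that("scaffold generation is deterministic and validated", {
  spec <- scaffold_spec(seed = 11)
  s1 <- make_scaffold(spec)
  s2 <- make_scaffold(spec)
  expect_identical(s1$sequence, s2$sequence)
  expect_equal(nchar(s1$sequence), 190)
  expect_true(all(strsplit(s1$sequence, "")[[1]] %in%
                    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                      "K", "M", "F", "P", "S", "T", "W", "Y", "V")))
  # different seed, different sequence
  expect_false(identical(make_scaffold(scaffold_spec(seed = 12))$sequence,
                         s1$sequence))
  expect_error(scaffold_spec(length = 190, tetrad_positions =
                               c(61, 95, 150, 200)),
               "tetrad_positions")
  expect_error(scaffold_spec(dimer_loop_region = c(146, 126)),
               "dimer_loop_region")
  expect_error(scaffold_spec(tetrad_positions = c(61, 61, 150, 151)),
               "distinct")
  expect_error(scaffold_spec(oligo_loop_region = c(149, 156)),
               "oligo_loop_region")
})

test_that("planted classes carry their diagnostic signatures", {
  spec <- scaffold_spec(seed = 5)
  sc <- make_scaffold(spec)

  trx <- plant_class(sc, spec, "TRX_GPXLIKE_PRX")
  ref <- attr(trx, "ref_map")[[trx$id]]
  s <- strsplit(trx$sequence, "")[[1]]
  expect_identical(s[which(ref == 61)], "C")    # peroxidatic Cys
  expect_identical(s[which(ref == 107)], "C")   # resolving Cys
  expect_identical(s[which(ref == 95)], "Q")
  expect_identical(s[which(ref == 150)], "W")
  expect_identical(s[which(ref == 151)], "N")
  # interface regions deleted
  expect_false(any(ref %in% 126:146))
  expect_false(any(ref %in% 155:175))

  can <- plant_class(sc, spec, "CANONICAL_GSH_GPX")
  refc <- attr(can, "ref_map")[[can$id]]
  sc2 <- strsplit(can$sequence, "")[[1]]
  expect_identical(sc2[which(refc == 61)], "U") # SeCys
  dimer <- paste(sc2[which(refc %in% 126:146)], collapse = "")
  expect_match(dimer, "PGGG")
  expect_gte(sum(is.na(refc)), 8)               # oligomerization insertion
  expect_identical(sc2[which(refc == 57)], "R")
  expect_identical(sc2[which(refc == 185)], "R")
  expect_identical(sc2[which(refc == 147)], "M")

  amb <- plant_class(sc, spec, "AMBIGUOUS")
  refa <- attr(amb, "ref_map")[[amb$id]]
  sa <- strsplit(amb$sequence, "")[[1]]
  cys <- c(sa[which(refa == 61)], sa[which(refa == 107)])
  expect_equal(sum(cys == "C"), 1)              # exactly one of the pair

  expect_error(plant_class(sc, spec, "NOT_A_CLASS"), "unknown class")
})

test_that("mutation respects rate, protection and determinism", {
  spec <- scaffold_spec(seed = 2)
  sc <- make_scaffold(spec)
  trx <- plant_class(sc, spec, "TRX_GPXLIKE_PRX")

  # zero rate: identical copies
  fam0 <- mutate_family(trx, 5, 0, seed = 1)
  expect_true(all(fam0$records$sequence == trx$sequence))

  # determinism
  f1 <- mutate_family(trx, 10, 0.2, seed = 42)
  f2 <- mutate_family(trx, 10, 0.2, seed = 42)
  expect_identical(f1$records$sequence, f2$records$sequence)

  # protection: planted features survive any rate
  prot <- gpxlike:::protected_positions(trx, spec)
  fam <- mutate_family(trx, 20, 0.5, protected = prot, seed = 9)
  ref <- attr(trx, "ref_map")[[trx$id]]
  for (s in fam$records$sequence) {
    ch <- strsplit(s, "")[[1]]
    expect_identical(ch[which(ref == 61)], "C")
    expect_identical(ch[which(ref == 107)], "C")
  }

  expect_error(mutate_family(trx, 2, 1.0), "rate")
  expect_error(mutate_family(trx, 2, -0.1), "rate")
})

test_that("mutation counts follow the binomial expectation", {
  spec <- scaffold_spec(seed = 6)
  sc <- make_scaffold(spec)
  parent <- strsplit(sc$sequence, "")[[1]]
  protected <- 1:30
  fam <- mutate_family(sc, 1000, 0.1, protected = protected, seed = 33)
  L <- 190 - 30
  hits <- vapply(fam$records$sequence, function(s)
    sum(strsplit(s, "")[[1]] != parent), 0, USE.NAMES = FALSE)
  # protected sites untouched
  expect_true(all(vapply(fam$records$sequence[1:20], function(s)
    all(strsplit(s, "")[[1]][protected] == parent[protected]), TRUE)))
  # Binomial(160, 0.1) moments
  expect_equal(mean(hits), L * 0.1, tolerance = 0.05)
  expect_equal(var(hits), L * 0.1 * 0.9, tolerance = 0.15)
})

test_that("truth tables round-trip and reject empty families", {
  spec <- scaffold_spec(seed = 3)
  co <- synth_cohort(spec, c(TRX_GPXLIKE_PRX = 6, AMBIGUOUS = 4),
                     divergence = 0.05, seed = 3)
  path <- tempfile(fileext = ".tsv")
  emit_truth_table(co$records, path)
  tab <- read_truth_table(path)
  expect_equal(nrow(tab), 10)
  expect_identical(tab$id, co$records$id)
  expect_identical(tab$truth_class, co$records$truth_class)
  expect_identical(tab$phylum, co$records$phylum)
  empty <- co$records[0, ]
  expect_error(emit_truth_table(empty, tempfile()), "empty")
})

test_that("identical seeds reproduce whole cohorts byte-for-byte", {
  spec <- scaffold_spec(seed = 8)
  a <- synth_cohort(spec, c(TRX_GPXLIKE_PRX = 5, CANONICAL_GSH_GPX = 5),
                    divergence = 0.1, seed = 21)
  b <- synth_cohort(spec, c(TRX_GPXLIKE_PRX = 5, CANONICAL_GSH_GPX = 5),
                    divergence = 0.1, seed = 21)
  expect_identical(a$records$sequence, b$records$sequence)
  expect_identical(a$reference$sequence, b$reference$sequence)
})
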