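#' Default feature-extraction configuration
#'
#' Reference-coordinate positions and regions of the diagnostic features,
#' plus detection parameters. Positions follow the conventional Gpx
#' numbering (tetrad 61/95/150/151, resolving Cys 107, TRX-binding
#' 97/106/111, GSH-binding 57/185/147 in bovine numbering). The dimer-loop
#' and oligomerization-loop intervals are configuration placeholders for
#' real data; synthetic cohorts carry their own generator truth via the
#' matching [scaffold_spec()].
#'
#' @param peroxidatic,gln,trp,asn tetrad reference positions.
#' @param resolving resolving-Cys reference position.
#' @param cys_block reference window scanned for the resolving Cys.
#' @param trx_sites,gsh_sites binding-residue reference positions.
#' @param dimer_loop,oligo_loop reference intervals of the interface loops.
#' @param motif dimer-loop motif (default "PGGG").
#' @param motif_max_mismatch mismatches tolerated in the motif match.
#' @param min_insertion minimum ungapped insertion length (residues) for an
#'   oligomerization loop call.
#' @param max_region_gap maximum row gap fraction inside the dimer-loop
#'   region for a motif call to count.
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(peroxidatic = 61L, gln = 95L, trp = 150L,
                           asn = 151L, resolving = 107L,
                           cys_block = c(103L, 113L),
                           trx_sites = c(97L, 106L, 111L),
                           gsh_sites = c(57L, 185L, 147L),
                           dimer_loop = c(126L, 146L),
                           oligo_loop = c(155L, 175L),
                           motif = "PGGG", motif_max_mismatch = 1L,
                           min_insertion = 8L, max_region_gap = 0.5) {
  structure(list(peroxidatic = peroxidatic, gln = gln, trp = trp, asn = asn,
                 resolving = resolving, cys_block = cys_block,
                 trx_sites = trx_sites, gsh_sites = gsh_sites,
                 dimer_loop = dimer_loop, oligo_loop = oligo_loop,
                 motif = motif, motif_max_mismatch = motif_max_mismatch,
                 min_insertion = min_insertion,
                 max_region_gap = max_region_gap),
            class = "feature_config")
}

#' Feature configuration matching a synthetic scaffold
#' @param spec a [scaffold_spec()].
#' @param ... overrides passed to [feature_config()].
#' @export
feature_config_from_spec <- function(spec, ...) {
  feature_config(peroxidatic = spec$tetrad_positions[1],
                 gln = spec$tetrad_positions[2],
                 trp = spec$tetrad_positions[3],
                 asn = spec$tetrad_positions[4],
                 resolving = spec$resolving_cys_position,
                 cys_block = spec$cys_block,
                 trx_sites = spec$trx_binding_positions,
                 gsh_sites = spec$gsh_binding_positions,
                 dimer_loop = spec$dimer_loop_region,
                 oligo_loop = spec$oligo_loop_region, ...)
}

#' Map reference residue numbering to alignment columns
#'
#' Reference position k (the k-th non-gap residue of the reference row,
#' 1-based) maps to the alignment column holding it; the mapping is
#' strictly increasing and bijective over reference residues.
#'
#' @param aln a `gpx_alignment`.
#' @param reference_id id of the reference row.
#' @return an object of class `column_map`: list with `reference_id`,
#'   `map` (integer vector, reference position -> column), `ref_length`.
#' @export
map_reference_columns <- function(aln, reference_id) {
  if (!reference_id %in% names(aln$rows))
    stop("reference row '", reference_id, "' not in alignment")
  chars <- strsplit(aln$rows[[reference_id]], "")[[1]]
  cols <- which(chars != GAP)
  if (length(cols) == 0) stop("reference row is all gaps")
  structure(list(reference_id = reference_id, map = cols,
                 ref_length = length(cols), n_columns = aln$n_columns),
            class = "column_map")
}

# columns spanned by a reference interval, including insertion columns
# strictly inside the interval
region_columns <- function(colmap, region) {
  lo <- max(1L, region[1]); hi <- min(colmap$ref_length, region[2])
  if (lo > hi) return(integer(0))
  seq.int(colmap$map[lo], colmap$map[hi])
}

#' Extract diagnostic features for one aligned sequence
#'
#' Reads the residues found at the mapped tetrad, resolving-Cys, TRX- and
#' GSH-binding positions, and calls the two interface loops:
#' `has_dimer_loop` requires a motif match (at most
#' `config$motif_max_mismatch` mismatches) within the dimer-loop region
#' with the region less than 50% gapped for this row; `has_oligo_loop`
#' requires an ungapped insertion of at least `config$min_insertion`
#' residues (columns where the reference row is gapped) inside the
#' oligomerization-loop region.
#'
#' @param aln a `gpx_alignment`.
#' @param colmap a `column_map` from [map_reference_columns()].
#' @param seq_id row to profile.
#' @param config a [feature_config()].
#' @return a list of class `feature_profile_row`.
#' @export
extract_features <- function(aln, colmap, seq_id, config = feature_config()) {
  if (!seq_id %in% names(aln$rows)) stop("no row '", seq_id, "'")
  row <- strsplit(aln$rows[[seq_id]], "")[[1]]
  ref <- strsplit(aln$rows[[colmap$reference_id]], "")[[1]]
  at <- function(refpos) {
    if (refpos < 1 || refpos > colmap$ref_length) return(NA_character_)
    ch <- row[colmap$map[refpos]]
    if (ch == GAP) NA_character_ else ch
  }
  perox <- at(config$peroxidatic)
  tetrad <- c(at(config$gln), at(config$trp), at(config$asn))
  trx <- vapply(config$trx_sites, at, "")
  gsh <- vapply(config$gsh_sites, at, "")

  # resolving Cys at the canonical position or anywhere in the Cys block
  cb_cols <- region_columns(colmap, config$cys_block)
  resolving <- identical(at(config$resolving), "C") ||
    any(row[cb_cols] == "C")

  # dimer loop: motif within the region, region not mostly gapped
  dl_cols <- region_columns(colmap, config$dimer_loop)
  has_dimer <- FALSE
  if (length(dl_cols)) {
    gapfrac <- mean(row[dl_cols] == GAP)
    if (gapfrac < config$max_region_gap) {
      sub <- paste(row[dl_cols][row[dl_cols] != GAP], collapse = "")
      has_dimer <- motif_match(sub, config$motif, config$motif_max_mismatch)
    }
  }

  # oligomerization loop: long ungapped insertion relative to the reference
  ol_cols <- region_columns(colmap, config$oligo_loop)
  has_oligo <- FALSE
  if (length(ol_cols)) {
    ins <- ref[ol_cols] == GAP & row[ol_cols] != GAP
    has_oligo <- max_run(ins) >= config$min_insertion
  }

  diag_cols <- colmap$map[stats::na.omit(c(config$peroxidatic, config$gln,
                                           config$trp, config$asn,
                                           config$resolving))]
  unalignable <- all(row[diag_cols] == GAP)

  structure(list(id = seq_id, peroxidatic_residue = perox,
                 tetrad_ok = identical(tetrad, c("Q", "W", "N")),
                 resolving_cys = resolving,
                 has_dimer_loop = has_dimer, has_oligo_loop = has_oligo,
                 trx_residues = trx, gsh_residues = gsh,
                 unalignable = unalignable),
            class = "feature_profile_row")
}

motif_match <- function(s, motif, max_mismatch) {
  k <- nchar(motif)
  n <- nchar(s)
  if (n < k) return(FALSE)
  mc <- strsplit(motif, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  for (i in seq_len(n - k + 1))
    if (sum(sc[i + seq_len(k) - 1] != mc) <= max_mismatch) return(TRUE)
  FALSE
}

max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Feature profiles for every row of an alignment
#'
#' @inheritParams extract_features
#' @param ids rows to profile (default all rows except the reference).
#' @return a data.frame of class `feature_profile`, one row per sequence.
#' @export
feature_table <- function(aln, colmap, config = feature_config(),
                          ids = NULL) {
  if (is.null(ids)) ids <- setdiff(names(aln$rows), colmap$reference_id)
  rows <- lapply(ids, function(id) {
    p <- extract_features(aln, colmap, id, config)
    data.frame(id = p$id, peroxidatic_residue = p$peroxidatic_residue,
               tetrad_ok = p$tetrad_ok, resolving_cys = p$resolving_cys,
               has_dimer_loop = p$has_dimer_loop,
               has_oligo_loop = p$has_oligo_loop,
               trx_residues = paste(p$trx_residues, collapse = ""),
               gsh_residues = paste(p$gsh_residues, collapse = ""),
               unalignable = p$unalignable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_profile", "data.frame")
  out
}

#' Three-criterion classification of a feature profile
#'
#' Criterion 1: the peroxidatic residue is Cys. Criterion 2: a resolving
#' Cys is present. Criterion 3: both interface loops are absent. A
#' sequence is a TRX-dependent Gpx-like peroxiredoxin iff all three hold;
#' it is a canonical GSH-dependent Gpx if the peroxidatic residue is
#' selenocysteine ('U'), or if it is Cys with no resolving Cys and at
#' least one interface loop present; anything else (including a peroxidatic
#' residue that is neither C nor U) is AMBIGUOUS.
#'
#' @param profile a `feature_profile_row` from [extract_features()], or a
#'   `feature_profile` data frame (classified row-wise).
#' @return for a single profile, a list of class `classification_result`
#'   (`id`, `class`, `criteria`, `note`); for a table, a data.frame of
#'   class `classification` with columns id, class, crit1..crit3.
#' @export
classify <- function(profile) {
  if (is.data.frame(profile)) {
    if (nrow(profile) == 0) stop("empty feature profile")
    rows <- lapply(seq_len(nrow(profile)), function(i) {
      p <- as.list(profile[i, ])
      r <- classify_one(p)
      data.frame(id = p$id, class = r$class, crit1 = r$criteria[1],
                 crit2 = r$criteria[2], crit3 = r$criteria[3],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("classification", "data.frame")
    return(out)
  }
  r <- classify_one(profile)
  structure(r, class = "classification_result")
}

classify_one <- function(p) {
  if (isTRUE(p$unalignable))
    stop("profile for '", p$id, "' is unalignable; inspect the alignment ",
         "before classifying")
  crit1 <- identical(p$peroxidatic_residue, "C")
  crit2 <- isTRUE(p$resolving_cys)
  crit3 <- !isTRUE(p$has_dimer_loop) && !isTRUE(p$has_oligo_loop)
  cls <- if (crit1 && crit2 && crit3) "TRX_GPXLIKE_PRX"
  else if (identical(p$peroxidatic_residue, "U") ||
           (crit1 && !crit2 && !crit3)) "CANONICAL_GSH_GPX"
  else "AMBIGUOUS"
  note <- sprintf("peroxidatic=%s resolving=%s dimer_loop=%s oligo_loop=%s",
                  p$peroxidatic_residue, crit2,
                  isTRUE(p$has_dimer_loop), isTRUE(p$has_oligo_loop))
  list(id = p$id, class = cls, criteria = c(crit1, crit2, crit3),
       note = note)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s -> %s [%s]\n", x$id, x$class, x$note))
  invisible(x)
}

#' Cohort-level classification summary
#'
#' Class counts and fractions, plus the fraction of sequences carrying the
#' oligomerization loop and the fraction with a conserved resolving Cys.
#'
#' @param results a `classification` data frame from [classify()].
#' @param profiles the matching `feature_profile` data frame.
#' @return a list of class `cohort_summary`.
#' @export
summarize_cohort <- function(results, profiles) {
  if (nrow(results) == 0) stop("empty classification results")
  n <- nrow(results)
  counts <- table(factor(results$class, levels = CLASSES))
  structure(list(
    n = n,
    class_counts = as.vector(counts) |> stats::setNames(names(counts)),
    class_fractions = as.vector(counts / n) |> stats::setNames(names(counts)),
    oligo_loop_fraction = mean(profiles$has_oligo_loop),
    dimer_loop_fraction = mean(profiles$has_dimer_loop),
    resolving_cys_fraction = mean(profiles$resolving_cys)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", x$n))
  for (cl in names(x$class_counts))
    cat(sprintf("  %-18s %4d (%.1f%%)\n", cl, x$class_counts[[cl]],
                100 * x$class_fractions[[cl]]))
  cat(sprintf("  oligomerization loop: %.1f%%  resolving Cys: %.1f%%\n",
              100 * x$oligo_loop_fraction, 100 * x$resolving_cys_fraction))
  invisible(x)
}

#' Write per-sequence classification and cohort summary TSVs
#' @param results `classification` data frame.
#' @param profiles `feature_profile` data frame.
#' @param path output TSV path for the per-sequence table.
#' @export
write_classification <- function(results, profiles, path) {
  merged <- merge(results, profiles, by = "id", sort = FALSE)
  utils::write.table(merged, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
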