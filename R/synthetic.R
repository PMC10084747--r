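#' Scaffold specification for synthetic Gpx-like families
#'
#' Defines the reference coordinate system in which diagnostic features are
#' planted. Defaults follow the conventional Gpx numbering: catalytic tetrad
#' Cys/SeCys61, Gln95, Trp150, Asn151; resolving Cys107 in the "Cys block"
#' on helix alpha-1a; TRX-binding Pro97/Phe106/Tyr111; GSH-binding
#' Arg57/Arg185/Met147 (bovine numbering); dimer-loop and oligomerization-
#' loop regions as reference intervals.
#'
#' @param length scaffold length in residues.
#' @param tetrad_positions four distinct positions: peroxidatic site, Gln,
#'   Trp, Asn.
#' @param resolving_cys_position position of the resolving Cys.
#' @param trx_binding_positions,gsh_binding_positions three positions each.
#' @param dimer_loop_region,oligo_loop_region closed intervals
#'   `c(start, end)`; must not overlap the tetrad positions.
#' @param cys_block window bracketing the resolving Cys.
#' @param seed integer seed controlling scaffold generation.
#' @return an object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(length = 190L,
                          tetrad_positions = c(61L, 95L, 150L, 151L),
                          resolving_cys_position = 107L,
                          trx_binding_positions = c(97L, 106L, 111L),
                          gsh_binding_positions = c(57L, 185L, 147L),
                          dimer_loop_region = c(126L, 146L),
                          oligo_loop_region = c(155L, 175L),
                          cys_block = c(103L, 113L),
                          seed = 1L) {
  spec <- list(length = as.integer(length),
               tetrad_positions = as.integer(tetrad_positions),
               resolving_cys_position = as.integer(resolving_cys_position),
               trx_binding_positions = as.integer(trx_binding_positions),
               gsh_binding_positions = as.integer(gsh_binding_positions),
               dimer_loop_region = as.integer(dimer_loop_region),
               oligo_loop_region = as.integer(oligo_loop_region),
               cys_block = as.integer(cys_block),
               seed = as.integer(seed))
  validate_scaffold_spec(spec)
  class(spec) <- "scaffold_spec"
  spec
}

validate_scaffold_spec <- function(spec) {
  L <- spec$length
  if (L < 1) stop("invalid scaffold_spec field 'length': must be >= 1")
  chk <- function(x, name, k = NULL) {
    if (!is.null(k) && length(x) != k)
      stop("invalid scaffold_spec field '", name, "': needs ", k, " values")
    if (any(x < 1 | x > L))
      stop("invalid scaffold_spec field '", name,
           "': position outside [1, ", L, "]")
  }
  chk(spec$tetrad_positions, "tetrad_positions", 4)
  if (anyDuplicated(spec$tetrad_positions))
    stop("invalid scaffold_spec field 'tetrad_positions': must be distinct")
  chk(spec$resolving_cys_position, "resolving_cys_position", 1)
  chk(spec$trx_binding_positions, "trx_binding_positions", 3)
  chk(spec$gsh_binding_positions, "gsh_binding_positions", 3)
  for (nm in c("dimer_loop_region", "oligo_loop_region", "cys_block")) {
    r <- spec[[nm]]
    chk(r, nm, 2)
    if (r[1] > r[2]) stop("invalid scaffold_spec field '", nm,
                          "': start > end")
  }
  for (nm in c("dimer_loop_region", "oligo_loop_region")) {
    r <- spec[[nm]]
    if (any(spec$tetrad_positions >= r[1] & spec$tetrad_positions <= r[2]))
      stop("invalid scaffold_spec field '", nm,
           "': overlaps a tetrad position")
  }
  invisible(spec)
}

# positions carrying planted diagnostic residues, in scaffold coordinates;
# the whole Cys-block window counts as diagnostic because the presence or
# absence of a Cys anywhere in it is what the classifier reads
diagnostic_positions <- function(spec) {
  sort(unique(c(spec$tetrad_positions, spec$resolving_cys_position,
                spec$trx_binding_positions, spec$gsh_binding_positions,
                spec$cys_block[1]:spec$cys_block[2])))
}

#' Generate the neutral scaffold sequence
#'
#' Draws background residues uniformly from the 20 canonical amino acids
#' (a conservative null for consensus statistics) and places the neutral
#' residue 'A' at every diagnostic position, to be overwritten by
#' [plant_class()]. Deterministic given `spec$seed`.
#'
#' @param spec a [scaffold_spec()].
#' @return a single-row `protein_records` data frame (id "scaffold") with a
#'   `ref_map` attribute mapping record positions to scaffold positions.
#' @export
make_scaffold <- function(spec) {
  validate_scaffold_spec(spec)
  with_seed(spec$seed, {
    s <- sample(AA20, spec$length, replace = TRUE)
    s[diagnostic_positions(spec)] <- "A"
    rec <- protein_records("scaffold", paste(s, collapse = ""))
    attr(rec, "ref_map") <- list(scaffold = seq_len(spec$length))
    rec
  })
}

CLASSES <- c("TRX_GPXLIKE_PRX", "CANONICAL_GSH_GPX", "AMBIGUOUS")

#' Plant class-defining features into a scaffold
#'
#' Overwrites diagnostic positions so that the sequence carries the
#' signature of one of the three classes:
#' \describe{
#' \item{TRX_GPXLIKE_PRX}{peroxidatic Cys and resolving Cys present,
#'   Gln/Trp/Asn tetrad, Pro/Phe/Tyr at the TRX-binding sites, and both
#'   interface-loop regions deleted (monomeric architecture).}
#' \item{CANONICAL_GSH_GPX}{selenocysteine 'U' at the peroxidatic site, no
#'   resolving Cys, Arg/Arg/Met at the GSH-binding sites, a "PGGG" motif
#'   inside the dimer-loop region and an insertion (>= 8 residues) inside
#'   the oligomerization-loop region.}
#' \item{AMBIGUOUS}{peroxidatic Cys but no resolving Cys and no loops
#'   (a 1-Cys-like architecture).}
#' }
#'
#' @param scaffold single-row `protein_records` from [make_scaffold()].
#' @param spec the [scaffold_spec()] used to build the scaffold.
#' @param class_label one of `"TRX_GPXLIKE_PRX"`, `"CANONICAL_GSH_GPX"`,
#'   `"AMBIGUOUS"`.
#' @param insertion_length residues inserted into the oligomerization loop
#'   for the canonical class (>= 8).
#' @return a single-row `protein_records` with `truth_class` set and a
#'   `ref_map` attribute (scaffold position per record position, `NA` for
#'   inserted residues).
#' @export
plant_class <- function(scaffold, spec, class_label, insertion_length = 10L) {
  if (!class_label %in% CLASSES)
    stop("unknown class label: ", class_label)
  s <- strsplit(scaffold$sequence[1], "")[[1]]
  tp <- spec$tetrad_positions
  s[tp[2]] <- "Q"; s[tp[3]] <- "W"; s[tp[4]] <- "N"
  ref <- seq_len(spec$length)
  dim_r <- spec$dimer_loop_region; oli_r <- spec$oligo_loop_region
  if (class_label == "TRX_GPXLIKE_PRX") {
    s[tp[1]] <- "C"
    s[spec$resolving_cys_position] <- "C"
    s[spec$trx_binding_positions] <- c("P", "F", "Y")
    drop <- c(dim_r[1]:dim_r[2], oli_r[1]:oli_r[2])
    s <- s[-drop]; ref <- ref[-drop]
  } else if (class_label == "CANONICAL_GSH_GPX") {
    s[tp[1]] <- "U"
    s[spec$resolving_cys_position] <- "S"
    s[spec$gsh_binding_positions] <- c("R", "R", "M")
    motif_at <- dimer_motif_start(spec)
    s[motif_at + 0:3] <- c("P", "G", "G", "G")
    ins_at <- floor((oli_r[1] + oli_r[2]) / 2)   # insert after this position
    ins <- with_seed(spec$seed + 7L,
                     sample(AA20, max(8L, insertion_length), replace = TRUE))
    s <- append(s, ins, after = ins_at)
    ref <- append(ref, rep(NA_integer_, length(ins)), after = ins_at)
  } else {                                       # AMBIGUOUS
    s[tp[1]] <- "C"
    s[spec$resolving_cys_position] <- "S"
    drop <- c(dim_r[1]:dim_r[2], oli_r[1]:oli_r[2])
    s <- s[-drop]; ref <- ref[-drop]
  }
  rec <- protein_records(paste0("planted_", tolower(class_label)),
                         paste(s, collapse = ""),
                         truth_class = class_label)
  attr(rec, "ref_map") <- stats::setNames(list(ref), rec$id)
  rec
}

# fixed placement of the planted PGGG motif inside the dimer-loop region
dimer_motif_start <- function(spec) {
  r <- spec$dimer_loop_region
  if (r[2] - r[1] + 1 < 4) stop("dimer_loop_region too short for PGGG motif")
  r[1] + min(4L, r[2] - r[1] - 3L)
}

# record-coordinate positions that must stay fixed for the planted class
# signature to survive mutation (diagnostics + planted motif + insertion)
protected_positions <- function(record, spec) {
  ref <- attr(record, "ref_map")[[record$id[1]]]
  keep_ref <- c(diagnostic_positions(spec),
                dimer_motif_start(spec) + 0:3)
  which(is.na(ref) | ref %in% keep_ref)
}

#' Mutate a planted record into a family
#'
#' Creates `n` copies of `record`, substituting each unprotected site
#' independently with probability `rate` (replacement drawn uniformly from
#' the 19 other canonical residues). Truth labels and the reference map are
#' inherited. Deterministic given `seed`.
#'
#' @param record single-row `protein_records`.
#' @param n number of copies.
#' @param rate per-site substitution probability in \[0, 1).
#' @param protected integer positions (record coordinates) exempt from
#'   mutation; `NULL` protects nothing.
#' @param seed integer seed.
#' @param prefix id prefix for the copies (default the parent id).
#' @return a `labeled_family`: list with `records` (a `protein_records`
#'   with n rows), `divergence`, and the parent's `ref_map` carried across
#'   rows.
#' @export
mutate_family <- function(record, n, rate, protected = NULL, seed = 1L,
                          prefix = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  s0 <- strsplit(record$sequence[1], "")[[1]]
  L <- length(s0)
  if (!is.null(protected) && length(protected) &&
      (min(protected) < 1 || max(protected) > L))
    stop("protected positions outside [1, ", L, "]")
  free <- setdiff(seq_len(L), protected)
  if (is.null(prefix)) prefix <- record$id[1]
  ids <- sprintf("%s_%03d", prefix, seq_len(n))
  seqs <- with_seed(seed, vapply(seq_len(n), function(k) {
    s <- s0
    hit <- free[stats::runif(length(free)) < rate]
    for (p in hit) {
      alt <- setdiff(AA20, s[p])
      s[p] <- alt[sample.int(length(alt), 1)]
    }
    paste(s, collapse = "")
  }, ""))
  recs <- protein_records(ids, seqs,
                          truth_class = record$truth_class[1])
  ref <- attr(record, "ref_map")[[record$id[1]]]
  attr(recs, "ref_map") <- stats::setNames(rep(list(ref), n), ids)
  structure(list(records = recs, divergence = rate,
                 parent = record$id[1]),
            class = "labeled_family")
}

#' @export
print.labeled_family <- function(x, ...) {
  cat(sprintf("<labeled_family> %d records from '%s' at divergence %.3f\n",
              nrow(x$records), x$parent, x$divergence))
  invisible(x)
}

#' Generate a full synthetic cohort with planted truth
#'
#' Convenience wrapper: builds the scaffold, plants each requested class,
#' mutates each planted parent into a family at the given divergence with
#' all diagnostic positions protected, assigns phylum labels, and returns
#' the combined records together with the scaffold reference row.
#'
#' @param spec a [scaffold_spec()].
#' @param n_per_class named integer vector, names among the three class
#'   labels, e.g. `c(TRX_GPXLIKE_PRX = 50, CANONICAL_GSH_GPX = 50,
#'   AMBIGUOUS = 50)`.
#' @param divergence per-site substitution rate applied to each family.
#' @param seed integer seed.
#' @param phyla character vector of phylum labels assigned round-robin
#'   across the cohort (scattering each phylum over all clades).
#' @return list with `records` (cohort, `protein_records`), `reference`
#'   (scaffold record), `spec`.
#' @export
synth_cohort <- function(spec, n_per_class, divergence = 0.05, seed = 1L,
                         phyla = paste0("phylum", 1:4)) {
  stopifnot(all(names(n_per_class) %in% CLASSES), length(n_per_class) >= 1)
  scaffold <- make_scaffold(spec)
  fams <- lapply(seq_along(n_per_class), function(k) {
    cls <- names(n_per_class)[k]
    parent <- plant_class(scaffold, spec, cls)
    mutate_family(parent, n_per_class[[k]], divergence,
                  protected = protected_positions(parent, spec),
                  seed = seed + k, prefix = tolower(cls))
  })
  recs <- do.call(rbind, lapply(fams, `[[`, "records"))
  class(recs) <- c("protein_records", "data.frame")
  recs$phylum <- rep_len(phyla, nrow(recs))
  ref_maps <- do.call(c, lapply(fams, function(f) attr(f$records, "ref_map")))
  attr(recs, "ref_map") <- ref_maps
  list(records = recs, reference = scaffold, spec = spec)
}

#' Write the planted truth table
#'
#' @param family a `labeled_family` or a `protein_records` data frame with
#'   `truth_class` (and optionally `phylum`) columns.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
emit_truth_table <- function(family, path) {
  recs <- if (inherits(family, "labeled_family")) family$records else family
  if (is.null(recs) || nrow(recs) == 0) stop("empty family")
  tab <- data.frame(id = recs$id, truth_class = recs$truth_class,
                    phylum = if (!is.null(recs$phylum)) recs$phylum else
                      NA_character_,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth/label table written by [emit_truth_table()]
#' @param path TSV path.
#' @return data.frame with columns id, truth_class, phylum.
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

# run code with a local, restored RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
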