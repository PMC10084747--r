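#' Construct a set of protein sequence records
#'
#' The package's basic sequence container: a data frame with one row per
#' protein, columns `id`, `sequence`, and optional `taxon_label`, `phylum`
#' and `truth_class` annotations. Sequences use the 20 canonical amino-acid
#' letters plus 'U' (selenocysteine) and 'X' (unknown); unaligned records
#' must not contain gap characters.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param sequence character vector of amino-acid strings.
#' @param taxon_label,phylum,truth_class optional per-record annotations.
#' @return a data.frame of class `protein_records`.
#' @export
protein_records <- function(id, sequence, taxon_label = NA_character_,
                            phylum = NA_character_,
                            truth_class = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence))
    stop("id and sequence must have the same length")
  if (any(!nzchar(id))) stop("empty record id")
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  bad <- grepl(paste0("[^", paste(AA_ALPHA, collapse = ""), "]"), sequence)
  if (any(bad))
    stop("invalid residue letters (gaps are not allowed in unaligned ",
         "records): ", paste(id[bad], collapse = ", "))
  out <- data.frame(id = id, sequence = sequence,
                    taxon_label = rep_len(as.character(taxon_label), length(id)),
                    phylum = rep_len(as.character(phylum), length(id)),
                    truth_class = rep_len(as.character(truth_class), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

#' @export
print.protein_records <- function(x, ...) {
  cat(sprintf("<protein_records> %d sequence(s), lengths %d-%d\n",
              nrow(x), min(nchar(x$sequence)), max(nchar(x$sequence))))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Headers are parsed as `id [key=value ...]`; recognized tags are `taxon`,
#' `phylum` and `class` and populate the corresponding record columns.
#' Selenocysteine ('U') and unknown ('X') letters are accepted and preserved
#' verbatim. Record order follows file order.
#'
#' @param path FASTA file path.
#' @return a `protein_records` data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) stop("no FASTA records in ", path)
  headers <- names(aa)
  toks <- strsplit(headers, "[ \t]+")
  ids <- vapply(toks, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  tag <- function(tk, key) {
    hit <- grep(paste0("^", key, "="), tk, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  seqs <- toupper(as.character(aa))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record ", which(empty)[1], " (id '",
         ids[which(empty)[1]], "')")
  protein_records(
    id = ids, sequence = seqs,
    taxon_label = vapply(toks, tag, "", key = "taxon"),
    phylum = vapply(toks, tag, "", key = "phylum"),
    truth_class = vapply(toks, tag, "", key = "class"))
}

#' Write protein records to FASTA
#'
#' Annotations present in the records (`taxon`, `phylum`, `class`) are
#' appended to the header as `key=value` tags so that
#' [read_fasta()] round-trips them.
#'
#' @param records a `protein_records` data frame.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  hdr <- records$id
  add <- function(hdr, val, key)
    ifelse(is.na(val), hdr, paste0(hdr, " ", key, "=", val))
  if (!is.null(records$taxon_label)) hdr <- add(hdr, records$taxon_label, "taxon")
  if (!is.null(records$phylum)) hdr <- add(hdr, records$phylum, "phylum")
  if (!is.null(records$truth_class)) hdr <- add(hdr, records$truth_class, "class")
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Filter records by sequence length
#'
#' Drops sequences that are too short or too long. Defaults follow a
#' median-anchored rule: keep lengths within `[0.5, 2] * median(length)`.
#'
#' @param records a `protein_records` data frame.
#' @param min_len,max_len inclusive length bounds; `NULL` uses the median
#'   rule.
#' @return the retained records (possibly empty, with a warning).
#' @export
filter_by_length <- function(records, min_len = NULL, max_len = NULL) {
  len <- nchar(records$sequence)
  med <- stats::median(len)
  if (is.null(min_len)) min_len <- floor(0.5 * med)
  if (is.null(max_len)) max_len <- ceiling(2 * med)
  if (min_len > max_len) stop("min_len must be <= max_len")
  keep <- len >= min_len & len <= max_len
  message(sprintf("length filter [%s, %s]: kept %d of %d sequences",
                  format(min_len), format(max_len), sum(keep), length(keep)))
  if (!any(keep)) warning("length filter removed every sequence")
  records[keep, , drop = FALSE]
}

#' Fractional identity of two sequences under global alignment
#'
#' Identity is the number of identically matching columns divided by the
#' total number of alignment columns (dual-gap columns cannot occur in a
#' pairwise global alignment). Symmetric in its arguments.
#'
#' @param a,b amino-acid strings (or single-row `protein_records`).
#' @param ... passed to [global_align()] (matrix, gap penalties).
#' @return a fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, ...) {
  aln <- global_align(as_seq(a), as_seq(b), ...)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  sum(ca == cb & ca != GAP) / length(ca)
}

# fraction of ungapped columns whose substitution score is positive
pairwise_positive_fraction <- function(a, b, matrix = "BLOSUM62", ...) {
  aln <- global_align(as_seq(a), as_seq(b), matrix = matrix, ...)
  percent_similarity(aln) / 100
}

as_seq <- function(x) {
  if (is.data.frame(x)) x$sequence[1] else as.character(x)[1]
}

#' All-pairs global-alignment identity matrix
#'
#' Batch version of [pairwise_identity()] (single C pass over all pairs).
#'
#' @param records a `protein_records` data frame.
#' @inheritParams global_align
#' @return symmetric matrix of fractional identities, unit diagonal.
#' @export
identity_matrix <- function(records, matrix = "BLOSUM62", gap_open = 10,
                            gap_extend = 1) {
  SM <- scoring_matrix(matrix)
  codes <- lapply(records$sequence, encode_seq)
  M <- .identity_matrix_cpp(codes, SM, gap_open, gap_extend)
  dimnames(M) <- list(records$id, records$id)
  M
}

#' Greedy identity-threshold clustering (cd-hit style)
#'
#' Produces a non-redundant representative set: records are sorted by
#' decreasing length (ties broken lexicographically by id) and each record
#' joins the first existing cluster whose representative it matches at an
#' identity (or similarity) strictly greater than `threshold`; otherwise it
#' founds a new cluster. This is the scheme used to merge redundant protein
#' sets at, e.g., 80% or 70% similarity.
#'
#' The greedy assignment depends on the processing order; determinism for a
#' fixed input is guaranteed, invariance under input permutation is not.
#'
#' @param records a `protein_records` data frame.
#' @param threshold fractional identity in (0, 1); members join a cluster
#'   when identity > threshold.
#' @param mode "identity" (fraction of identical columns) or "similarity"
#'   (fraction of positively scoring columns among ungapped columns).
#' @param ... alignment parameters passed on.
#' @return an object of class `cluster_set`: list with `clusters` (list of
#'   `list(representative, members, identity)`), `threshold`, `mode`.
#' @export
greedy_cluster <- function(records, threshold = 0.8,
                           mode = c("identity", "similarity"), ...) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold < 1)
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  idn_mat <- NULL
  if (mode == "identity")
    idn_mat <- identity_matrix(records, ...)[ids, ids, drop = FALSE]
  metric <- function(k, r)
    if (!is.null(idn_mat)) idn_mat[k, r] else
      pairwise_positive_fraction(seqs[k], seqs[r], ...)
  reps <- integer(0)           # indices into ord-ed vectors
  members <- list()
  memb_ident <- list()
  for (k in seq_along(ids)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      idn <- metric(k, reps[ci])
      if (idn > threshold) {
        members[[ci]] <- c(members[[ci]], ids[k])
        memb_ident[[ci]] <- c(memb_ident[[ci]], idn)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, k)
      members[[length(reps)]] <- ids[k]
      memb_ident[[length(reps)]] <- 1.0
    }
  }
  clusters <- lapply(seq_along(reps), function(ci)
    list(representative = ids[reps[ci]], members = members[[ci]],
         identity = memb_ident[[ci]]))
  out <- list(clusters = clusters, threshold = threshold, mode = mode)
  class(out) <- "cluster_set"
  out
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), 0L)
  cat(sprintf("<cluster_set> %d clusters over %d sequences (threshold %.2f, %s)\n",
              length(sizes), sum(sizes), x$threshold, x$mode))
  invisible(x)
}

#' Representative ids of a cluster set, in founding order
#' @param clusters a `cluster_set`.
#' @export
cluster_representatives <- function(clusters) {
  vapply(clusters$clusters, function(cl) cl$representative, "")
}

#' Cluster membership as a table
#'
#' @param clusters a `cluster_set`.
#' @return data.frame with columns representative, member, identity.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(clusters$clusters, function(cl)
    data.frame(representative = cl$representative, member = cl$members,
               identity = cl$identity, stringsAsFactors = FALSE)))
}

#' Write a cluster table as TSV
#' @param clusters a `cluster_set`.
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(cluster_table(clusters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
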