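#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch alignment under the Gotoh three-state recurrences: a gap
#' run of length k costs `gap_open + (k - 1) * gap_extend`. Traceback is
#' deterministic (diagonal preferred over up over left on ties).
#' Selenocysteine 'U' is scored as Cys but written out verbatim; 'X' scores
#' 0 against everything.
#'
#' @param a,b amino-acid strings.
#' @param matrix substitution matrix name (see [scoring_matrix()]).
#' @param gap_open,gap_extend nonnegative penalties (defaults 10 and 1).
#' @return an object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b`, `score`, `matrix_name`, `gap_open`, `gap_extend`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_extend = 1) {
  a <- as_seq(a); b <- as_seq(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  SM <- scoring_matrix(matrix)
  ia <- encode_seq(a); ib <- encode_seq(b)
  S <- SM[ia, ib, drop = FALSE]
  dp <- .gotoh_dp(S, gap_open, gap_extend)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na_ <- length(ca); i <- 0L; j <- 0L
  out_a <- character(length(dp$moves)); out_b <- character(length(dp$moves))
  for (k in seq_along(dp$moves)) {
    mv <- dp$moves[k]
    if (mv == 1L) { i <- i + 1L; j <- j + 1L; out_a[k] <- ca[i]; out_b[k] <- cb[j] }
    else if (mv == 2L) { i <- i + 1L; out_a[k] <- ca[i]; out_b[k] <- GAP }
    else { j <- j + 1L; out_a[k] <- GAP; out_b[k] <- cb[j] }
  }
  structure(list(aligned_a = paste(out_a, collapse = ""),
                 aligned_b = paste(out_b, collapse = ""),
                 score = dp$score, matrix_name = matrix,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %.1f (%s, open %g extend %g)\n",
              x$score, x$matrix_name, x$gap_open, x$gap_extend))
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}

#' Percent similarity (or identity) of a pairwise alignment
#'
#' Similarity counts columns whose substitution-matrix score is strictly
#' positive, as a percentage of columns without gaps in either row; identity
#' counts identically matching columns over all alignment columns.
#'
#' @param aln a `pairwise_alignment`.
#' @param what "similarity" or "identity".
#' @return a percentage in \[0, 100\].
#' @export
percent_similarity <- function(aln, what = c("similarity", "identity")) {
  what <- match.arg(what)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  if (what == "identity")
    return(100 * sum(ca == cb & ca != GAP) / length(ca))
  ung <- ca != GAP & cb != GAP
  if (!any(ung)) return(0)
  SM <- scoring_matrix(aln$matrix_name)
  sc <- SM[cbind(ca[ung], cb[ung])]
  100 * sum(sc > 0) / sum(ung)
}

# ---- multiple alignments ----------------------------------------------------

#' Construct a multiple alignment from gapped rows
#'
#' @param rows named character vector of equal-length gapped sequences
#'   ('-' gaps).
#' @return an object of class `gpx_alignment` with elements `rows` and
#'   `n_columns`.
#' @export
gpx_alignment <- function(rows) {
  stopifnot(length(rows) >= 1, !is.null(names(rows)))
  w <- nchar(rows)
  if (length(unique(w)) != 1)
    stop("ragged alignment rows: ",
         paste(names(rows)[w != w[1]], collapse = ", "))
  structure(list(rows = rows, n_columns = unname(w[1])),
            class = "gpx_alignment")
}

new_alignment <- gpx_alignment

#' @export
print.gpx_alignment <- function(x, ...) {
  cat(sprintf("<gpx_alignment> %d rows x %d columns\n",
              length(x$rows), x$n_columns))
  invisible(x)
}

#' @export
as.matrix.gpx_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$rows), ""))
  rownames(m) <- names(x$rows)
  m
}

#' Remove gaps from an alignment row
#' @param aln a `gpx_alignment`.
#' @param id row id.
#' @return the ungapped sequence string.
#' @export
degap <- function(aln, id) {
  gsub("-", "", aln$rows[[id]], fixed = TRUE)
}

#' Progressive multiple sequence alignment
#'
#' Builds a neighbor-joining guide tree on pairwise global-alignment
#' identity distances (1 - identity), then merges sequence profiles from
#' the leaves inward by profile-profile affine-gap alignment ("once a gap,
#' always a gap"). Row order in the result equals input order.
#'
#' @param records a `protein_records` data frame (>= 2 rows).
#' @inheritParams global_align
#' @return a `gpx_alignment`.
#' @export
progressive_msa <- function(records, matrix = "BLOSUM62", gap_open = 10,
                            gap_extend = 1) {
  n <- nrow(records)
  if (is.null(n) || n < 2) stop("progressive_msa needs at least 2 records")
  SM <- scoring_matrix(matrix)
  codes <- lapply(records$sequence, encode_seq)
  names(codes) <- records$id

  align_profiles <- function(A, B) {
    # A, B: integer matrices (members x columns), 0 = gap
    PA <- profile_freq(A); PB <- profile_freq(B)
    S <- crossprod(PA, SM %*% PB)
    dp <- .gotoh_dp(S, gap_open, gap_extend)
    la <- ncol(A); lb <- ncol(B)
    out <- matrix(0L, nrow(A) + nrow(B), length(dp$moves))
    i <- 0L; j <- 0L
    for (k in seq_along(dp$moves)) {
      mv <- dp$moves[k]
      if (mv != 3L) { i <- i + 1L; out[seq_len(nrow(A)), k] <- A[, i] }
      if (mv != 2L) { j <- j + 1L; out[nrow(A) + seq_len(nrow(B)), k] <- B[, j] }
    }
    rownames(out) <- c(rownames(A), rownames(B))
    out
  }

  if (n == 2) {
    pw <- global_align(records$sequence[1], records$sequence[2],
                       matrix = matrix, gap_open = gap_open,
                       gap_extend = gap_extend)
    rows <- stats::setNames(c(pw$aligned_a, pw$aligned_b), records$id)
    return(new_alignment(rows))
  }

  # guide tree from pairwise identity distances
  D <- 1 - identity_matrix(records, matrix = matrix, gap_open = gap_open,
                           gap_extend = gap_extend)
  diag(D) <- 0
  guide <- ape::nj(D)
  guide$edge.length[guide$edge.length < 0] <- 0
  guide <- tryCatch(phangorn::midpoint(guide),
                    error = function(e) ape::root(guide, outgroup = 1,
                                                  resolve.root = TRUE))

  merge_node <- function(node) {
    kids <- guide$edge[guide$edge[, 1] == node, 2]
    profs <- lapply(kids, function(k) {
      if (k <= n) {
        tip <- guide$tip.label[k]
        matrix(codes[[tip]], 1, dimnames = list(tip, NULL))
      } else merge_node(k)
    })
    Reduce(align_profiles, profs)
  }
  root <- n + 1L
  M <- merge_node(root)
  rows <- apply(M, 1, decode_seq)
  rows <- rows[records$id]
  new_alignment(rows)
}

# frequency profile over the 22-letter alphabet; gaps contribute nothing,
# columns normalized by number of rows (gappy columns score low)
profile_freq <- function(A) {
  P <- matrix(0, 22, ncol(A))
  for (r in seq_len(nrow(A))) {
    nz <- A[r, ] > 0L
    idx <- cbind(A[r, nz], which(nz))
    P[idx] <- P[idx] + 1
  }
  P / nrow(A)
}

#' Import an aligned FASTA file
#'
#' Rows must have equal lengths; '.' gaps are normalized to '-'.
#'
#' @param path aligned FASTA path.
#' @return a `gpx_alignment`.
#' @export
import_alignment <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) stop("no records in ", path)
  ids <- vapply(strsplit(names(aa), "[ \t]+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- gsub(".", "-", toupper(as.character(aa)), fixed = TRUE)
  names(rows) <- ids
  w <- nchar(rows)
  if (length(unique(w)) != 1)
    stop("ragged alignment rows: ",
         paste(ids[w != max(w)], collapse = ", "))
  new_alignment(rows)
}

#' Export an alignment as aligned FASTA
#' @param aln a `gpx_alignment`.
#' @param path output path.
#' @export
export_alignment <- function(aln, path) {
  x <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Drop high-gap columns from an alignment
#'
#' Used both for trimming divergent termini (`ends_only = TRUE`) and for
#' masking large gap regions (such as the oligomerization loop) before tree
#' building.
#'
#' @param aln a `gpx_alignment`.
#' @param max_gap_frac columns with gap fraction > this are dropped
#'   (default 0.5; terminus trimming conventionally uses 0.8).
#' @param ends_only if TRUE only trim runs of gappy columns at the two ends.
#' @return a `gpx_alignment` with an attribute `kept_columns`.
#' @export
mask_gap_columns <- function(aln, max_gap_frac = 0.5, ends_only = FALSE) {
  M <- as.matrix(aln)
  gf <- colMeans(M == GAP)
  bad <- gf > max_gap_frac
  if (ends_only) {
    keep <- rep(TRUE, length(bad))
    i <- 1; while (i <= length(bad) && bad[i]) { keep[i] <- FALSE; i <- i + 1 }
    i <- length(bad); while (i >= 1 && bad[i]) { keep[i] <- FALSE; i <- i - 1 }
  } else keep <- !bad
  rows <- apply(M[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- new_alignment(stats::setNames(rows, rownames(M)))
  attr(out, "kept_columns") <- which(keep)
  out
}
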