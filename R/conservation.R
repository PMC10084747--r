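#' Default physicochemical residue grouping
#'
#' Partition used to report grouped consensus ("residue types") in the
#' style of conservation tables: hydrophobic \{I,L,V,M,F\}, aromatic
#' \{W,Y\}, hydroxyl \{S,T\}, acidic \{D,E\}, basic \{K,R,H\}, amide
#' \{N,Q\}, small \{A,G\}, \{C\} (with U), \{P\}.
#'
#' @return named list of character vectors.
#' @export
default_grouping <- function() {
  list(hydrophobic = c("I", "L", "V", "M", "F"),
       aromatic = c("W", "Y"),
       hydroxyl = c("S", "T"),
       acidic = c("D", "E"),
       basic = c("K", "R", "H"),
       amide = c("N", "Q"),
       small = c("A", "G"),
       cys = c("C", "U"),
       pro = "P")
}

#' Consensus residue group and proportion of one alignment column
#'
#' In single-residue mode the proportion is the frequency of the modal
#' letter among non-gap rows (ties broken alphabetically). In grouped mode
#' the modal letter is greedily extended with other letters from its
#' physicochemical partition cell, keeping each added letter only if it
#' contributes at least `min_contrib` of the non-gap rows; the grouped
#' proportion is reported. All-gap columns report proportion 0 with gap
#' fraction 1.
#'
#' @param aln a `gpx_alignment`.
#' @param column column index (1-based).
#' @param grouping `NULL` for single-residue mode, or a partition such as
#'   [default_grouping()].
#' @param min_contrib minimum per-letter contribution to join the group.
#' @return list with `consensus`, `group` (character vector), `proportion`,
#'   `gap_fraction`.
#' @export
column_consensus <- function(aln, column, grouping = NULL,
                             min_contrib = 0.05) {
  if (column < 1 || column > aln$n_columns)
    stop("column ", column, " out of range 1..", aln$n_columns)
  col <- substring(unname(aln$rows), column, column)
  gap_fraction <- mean(col == GAP)
  res <- col[col != GAP]
  if (length(res) == 0)
    return(list(consensus = NA_character_, group = character(0),
                proportion = 0, gap_fraction = 1))
  freq <- table(res) / length(res)
  freq <- freq[order(-freq, names(freq))]      # modal, ties alphabetical
  consensus <- names(freq)[1]
  group <- consensus
  if (!is.null(grouping)) {
    cell <- grouping[[which(vapply(grouping, function(g)
      consensus %in% g, TRUE))[1]]]
    if (!is.null(cell)) {
      extras <- setdiff(intersect(names(freq), cell), consensus)
      extras <- extras[order(-freq[extras], extras)]
      for (e in extras)
        if (freq[[e]] >= min_contrib) group <- c(group, e)
    }
  }
  list(consensus = consensus, group = group,
       proportion = sum(freq[group]), gap_fraction = gap_fraction)
}

#' Per-column conservation profile of an alignment
#'
#' Applies [column_consensus()] to every column.
#'
#' @inheritParams column_consensus
#' @return a data.frame of class `conservation_profile` with columns
#'   `column`, `consensus`, `group` (letters collapsed with "/"),
#'   `proportion`, `gap_fraction`.
#' @export
conservation_profile <- function(aln, grouping = NULL, min_contrib = 0.05) {
  rows <- lapply(seq_len(aln$n_columns), function(j) {
    cc <- column_consensus(aln, j, grouping, min_contrib)
    data.frame(column = j, consensus = cc$consensus,
               group = paste(cc$group, collapse = "/"),
               proportion = cc$proportion,
               gap_fraction = cc$gap_fraction, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Conserved-domain segmentation of a conservation profile
#'
#' Finds maximal runs of columns whose consensus proportion meets the
#' threshold, bridging interior below-threshold stretches of at most
#' `max_break` columns; runs spanning fewer than `min_run` columns are
#' discarded, and columns with gap fraction above `max_gap` never qualify.
#' Segments start and end on qualifying columns.
#'
#' @param profile a `conservation_profile`.
#' @param threshold consensus-proportion threshold (default 0.7).
#' @param min_run minimum segment span in columns (default 5).
#' @param max_break maximum bridged below-threshold stretch (default 2).
#' @param max_gap maximum column gap fraction (default 0.5).
#' @param ref_length reference length used for the coverage denominator
#'   (default the number of profile columns).
#' @param colmap optional `column_map` used to also report segment bounds
#'   in reference coordinates.
#' @return list of class `domain_segments`: `segments` (data.frame with
#'   start/end columns, span, mean proportion, and reference positions if
#'   mapped) and `coverage`.
#' @export
conserved_domains <- function(profile, threshold = 0.7, min_run = 5L,
                              max_break = 2L, max_gap = 0.5,
                              ref_length = NULL, colmap = NULL) {
  stopifnot(threshold >= 0, threshold <= 1, min_run >= 1, max_break >= 0)
  ok <- profile$proportion >= threshold & profile$gap_fraction <= max_gap
  n <- length(ok)
  if (is.null(ref_length))
    ref_length <- if (!is.null(colmap)) colmap$ref_length else n
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!ok[i]) { i <- i + 1L; next }
    start <- i
    end <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (ok[j]) { end <- j; gap <- 0L }
      else { gap <- gap + 1L; if (gap > max_break) break }
      j <- j + 1L
    }
    if (end - start + 1L >= min_run)
      segs[[length(segs) + 1L]] <- c(start, end)
    i <- end + gap + 1L
  }
  if (length(segs)) {
    df <- do.call(rbind, lapply(segs, function(s) {
      cols <- s[1]:s[2]
      data.frame(start_column = s[1], end_column = s[2],
                 span = s[2] - s[1] + 1L,
                 mean_proportion = mean(profile$proportion[cols]))
    }))
    if (!is.null(colmap)) {
      col2ref <- function(cl) {
        hits <- which(colmap$map <= cl)
        if (length(hits)) max(hits) else NA_integer_
      }
      df$start_ref <- vapply(df$start_column, function(cl) {
        h <- which(colmap$map >= cl)
        if (length(h)) min(h) else NA_integer_
      }, 0L)
      df$end_ref <- vapply(df$end_column, col2ref, 0L)
    }
  } else {
    df <- data.frame(start_column = integer(0), end_column = integer(0),
                     span = integer(0), mean_proportion = numeric(0))
  }
  coverage <- sum(df$span) / ref_length
  structure(list(segments = df, coverage = coverage,
                 threshold = threshold, min_run = min_run,
                 max_break = max_break),
            class = "domain_segments")
}

#' @export
print.domain_segments <- function(x, ...) {
  cat(sprintf("<domain_segments> %d segment(s), coverage %.1f%%\n",
              nrow(x$segments), 100 * x$coverage))
  if (nrow(x$segments)) print.data.frame(x$segments, row.names = FALSE)
  invisible(x)
}

#' Conservation report at selected reference positions
#'
#' Table-style report (consensus residue types and proportions) at the
#' requested reference positions, with optional annotation labels.
#'
#' @param profile a `conservation_profile`.
#' @param colmap a `column_map`.
#' @param positions reference positions to report.
#' @param labels optional character vector of annotations (recycled).
#' @return data.frame with position, column, consensus, group, proportion,
#'   gap_fraction, label, unmapped.
#' @export
residue_report <- function(profile, colmap, positions, labels = NA) {
  labels <- rep_len(labels, length(positions))
  rows <- lapply(seq_along(positions), function(k) {
    p <- positions[k]
    if (p < 1 || p > colmap$ref_length)
      return(data.frame(position = p, column = NA_integer_,
                        consensus = NA_character_, group = NA_character_,
                        proportion = NA_real_, gap_fraction = NA_real_,
                        label = labels[k], unmapped = TRUE,
                        stringsAsFactors = FALSE))
    cl <- colmap$map[p]
    data.frame(position = p, column = cl,
               consensus = profile$consensus[cl], group = profile$group[cl],
               proportion = profile$proportion[cl],
               gap_fraction = profile$gap_fraction[cl],
               label = labels[k], unmapped = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
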