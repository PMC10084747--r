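#' Pairwise distance matrix from an alignment
#'
#' p-distance = mismatches / shared non-gap columns; the Poisson-corrected
#' distance is `-log(1 - p)`. Pairs with no shared non-gap columns, or with
#' `p >= 1` under the Poisson model, raise an error naming the pair.
#'
#' @param aln a `gpx_alignment` (>= 3 rows for downstream tree building).
#' @param model "poisson" (default) or "p_distance".
#' @return a symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
distance_matrix <- function(aln, model = c("poisson", "p_distance")) {
  model <- match.arg(model)
  M <- as.matrix(aln)
  n <- nrow(M)
  ids <- rownames(M)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  ng <- M != GAP
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- ng[i, ] & ng[j, ]
    ns <- sum(shared)
    if (ns == 0)
      stop("no shared non-gap columns for pair ", ids[i], " / ", ids[j])
    p <- sum(M[i, shared] != M[j, shared]) / ns
    if (model == "poisson") {
      if (p >= 1)
        stop("undefined Poisson distance (p >= 1) for pair ",
             ids[i], " / ", ids[j])
      p <- -log(1 - p)
    }
    D[i, j] <- p; D[j, i] <- p
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix. Negative branch-length
#' estimates are clamped to zero and counted in the `clamped` attribute
#' (the usual presentation convention).
#'
#' @param D symmetric distance matrix with ids as dimnames (n >= 3).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(D)) || any(D < 0) || any(abs(diag(D)) > 1e-12) ||
      max(abs(D - t(D))) > 1e-8)
    stop("invalid distance matrix (must be finite, symmetric, ",
         "nonnegative, zero diagonal)")
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and attaches to each internal edge of the full-alignment tree
#' the percentage of replicates containing the same bipartition (stored in
#' `node.label`; the root entry is empty). Replicates whose resampled rows
#' are all identical are skipped with a warning and excluded from the
#' denominator.
#'
#' @param aln a `gpx_alignment`.
#' @param model distance model, see [distance_matrix()].
#' @param n_reps number of bootstrap replicates (>= 1; a desk-scale run
#'   might use 100-200, a full analysis 1000).
#' @param seed integer seed.
#' @return an `ape::phylo` with numeric `node.label` supports in
#'   \[0, 100\] and attribute `n_used` (replicates effectively used).
#' @export
bootstrap_support <- function(aln, model = "poisson", n_reps = 1000L,
                              seed = 1L) {
  stopifnot(n_reps >= 1)
  base <- nj_tree(distance_matrix(aln, model))
  M <- as.matrix(aln)
  reps <- list()
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      Mb <- M[, cols, drop = FALSE]
      if (all(vapply(seq_len(nrow(Mb))[-1], function(i)
        identical(Mb[i, ], Mb[1, ]), TRUE))) {
        skipped <- skipped + 1L
        next
      }
      rows <- apply(Mb, 1, paste, collapse = "")
      alnb <- new_alignment(stats::setNames(rows, rownames(M)))
      tb <- tryCatch(nj_tree(distance_matrix(alnb, model)),
                     error = function(e) NULL)
      if (!is.null(tb)) reps[[length(reps) + 1L]] <- tb
    }
  })
  if (skipped > 0)
    warning(skipped, " degenerate bootstrap replicate(s) skipped")
  n_used <- length(reps)
  if (n_used == 0) stop("no usable bootstrap replicates")
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_used, 6)
  support[1] <- NA  # root "node" of an unrooted tree carries no bipartition
  base$node.label <- ifelse(is.na(support), "", format(support,
                                                       trim = TRUE))
  attr(base, "n_used") <- n_used
  base
}

# numeric supports of internal edges (node labels minus the root)
internal_supports <- function(tree) {
  if (is.null(tree$node.label)) stop("tree has no bootstrap supports")
  s <- suppressWarnings(as.numeric(tree$node.label))
  s[!is.na(s)]
}

#' Star-likeness of a bootstrapped tree
#'
#' Fraction of internal edges with bootstrap support below the threshold.
#' A star-like radiation has mostly weakly supported internal branches.
#'
#' @param tree an `ape::phylo` with supports in `node.label`.
#' @param support_threshold threshold (default 70).
#' @return fraction in \[0, 1\].
#' @export
star_likeness <- function(tree, support_threshold = 70) {
  s <- internal_supports(tree)
  if (length(s) == 0) {
    warning("tree has no internal edges; star-likeness defined as 0")
    return(0)
  }
  mean(s < support_threshold)
}

#' Phylum-mixing statistics on a phylogeny
#'
#' For each phylum, counts the maximal monophyletic same-phylum clades: the
#' nodes (including single leaves) whose subtree contains only that phylum
#' while the enclosing subtree does not. One clade per phylum means the
#' phylum is perfectly clustered; a count equal to the leaf count means its
#' members are fully scattered. The mixing index is the mean over phyla of
#' clades-per-phylum divided by leaves-per-phylum, ranging from near 0
#' (monophyletic phyla) to 1 (complete interleaving). Counting uses the
#' tree's stored rooting.
#'
#' @param tree an `ape::phylo`.
#' @param labels named character vector, leaf id -> phylum.
#' @return list of class `phylum_mixing`: `clades_per_phylum`,
#'   `leaves_per_phylum`, `mixing_index`.
#' @export
phylum_mixing <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("unlabeled leaf/leaves: ",
         paste(setdiff(tips, names(labels)), collapse = ", "))
  states <- unique(unname(labels[tips]))
  ntip <- length(tips)
  total <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- ntip + 1L
  parent <- integer(total)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent[root] <- root

  # children-before-parent ordering (iterative, recursion-free)
  ord <- integer(0)
  queue <- root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    ch <- kids[[as.character(v)]]
    queue <- c(queue, ch[ch > ntip])
  }
  # phyla present in each subtree ("" marks a mixed subtree)
  sub <- character(total)
  for (i in seq_len(ntip)) sub[i] <- labels[[tips[i]]]
  for (v in rev(ord)) {
    cs <- unique(sub[kids[[as.character(v)]]])
    sub[v] <- if (length(cs) == 1 && all(cs != "")) cs else ""
  }
  # maximal pure nodes: pure, with a mixed (or absent) parent
  pure <- sub != ""
  maximal <- pure & (seq_len(total) == root | !pure[parent])
  clades <- vapply(states, function(s) sum(maximal & sub == s), 0L)
  leaf_state <- unname(labels[tips])
  leaves <- vapply(states, function(s) sum(leaf_state == s), 0L)
  structure(list(clades_per_phylum = stats::setNames(clades, states),
                 leaves_per_phylum = stats::setNames(leaves, states),
                 mixing_index = mean(clades / leaves)),
            class = "phylum_mixing")
}

#' @export
print.phylum_mixing <- function(x, ...) {
  cat(sprintf("<phylum_mixing> index %.3f\n", x$mixing_index))
  for (s in names(x$clades_per_phylum))
    cat(sprintf("  %-12s %d clade(s) over %d leaves\n", s,
                x$clades_per_phylum[[s]], x$leaves_per_phylum[[s]]))
  invisible(x)
}

#' Write / read a tree in Newick format
#'
#' Bootstrap supports (if present) are written as internal node labels.
#'
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a distance matrix in square PHYLIP format
#' @param D distance matrix with dimnames.
#' @param path output path.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste0(formatC(rownames(D)[i], width = -12),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  invisible(path)
}
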