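# Shared fixtures and independent reference implementations used as oracles.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                collapse = "")

# Exhaustive affine-gap alignment score (recursion over every alignment);
# see src/gotoh.cpp. Thin wrapper doing the letter encoding.
oracle_align_score <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                               gap_extend = 1) {
  SM <- scoring_matrix(matrix)
  enc <- function(s) match(strsplit(s, "")[[1]], rownames(SM))
  gpxlike:::.enum_align_score(enc(a), enc(b), SM, gap_open, gap_extend)
}

# Independent greedy clustering on a precomputed identity matrix: sort by
# descending length (ties by id), join the first representative with
# identity > threshold, else found a new cluster.
oracle_greedy_cluster <- function(records, threshold) {
  idn <- identity_matrix(records)
  ord <- order(-nchar(records$sequence), records$id, method = "radix")
  ids <- records$id[ord]
  assignment <- character(0)
  reps <- character(0)
  for (id in ids) {
    hit <- NA_character_
    for (r in reps) {
      if (idn[id, r] > threshold) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, id); hit <- id }
    assignment[id] <- hit
  }
  assignment
}

# RMSD oracle: minimize over explicit rotations (Euler angles, many random
# restarts with Nelder-Mead refinement) after centering both point sets.
oracle_min_rmsd <- function(A, B, n_starts = 40) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A - B %*% t(rot(ang)))^2)))
  best <- Inf
  for (k in seq_len(n_starts)) {
    st <- runif(3, -pi, pi)
    fit <- optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
    if (fit$value < best) best <- fit$value
  }
  best
}

# toy PDB writer (fixed-column ATOM records)
write_toy_pdb <- function(path, serial, name, resname, chain, resno,
                          xyz, element, altloc = "") {
  n <- length(serial)
  altloc <- rep_len(altloc, n)
  name <- rep_len(name, n)
  resname <- rep_len(resname, n)
  chain <- rep_len(chain, n)
  resno <- rep_len(resno, n)
  element <- rep_len(element, n)
  lines <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial[i], sprintf(" %-3s", name[i]), altloc[i], resname[i],
            chain[i], resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
            element[i])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# alignment-free two-clade cohort: equal-length sequences, no indels
make_two_clades <- function(seed, n_per = 8, within = 0.02, between = 0.5) {
  spec <- scaffold_spec(seed = seed)
  anc1 <- make_scaffold(spec)
  anc2_fam <- mutate_family(anc1, 1, between, seed = seed + 100,
                            prefix = "anc2")
  anc2 <- anc2_fam$records
  attr(anc2, "ref_map") <- attr(anc1, "ref_map") |>
    setNames(anc2$id)
  famA <- mutate_family(anc1, n_per, within, seed = seed + 1, prefix = "A")
  famB <- mutate_family(anc2, n_per, within, seed = seed + 2, prefix = "B")
  rows <- c(setNames(famA$records$sequence, famA$records$id),
            setNames(famB$records$sequence, famB$records$id))
  list(aln = gpx_alignment(rows),
       clade_a = famA$records$id, clade_b = famB$records$id)
}

# bootstrap support of the edge separating a given tip set, NA if the
# bipartition is absent from the tree
support_for_clade <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  for (nd in (ntip + 2):(ntip + tree$Nnode)) {
    below <- ape::extract.clade(tree, nd)$tip.label
    if (setequal(below, tips) ||
        setequal(below, setdiff(tree$tip.label, tips)))
      return(suppressWarnings(as.numeric(tree$node.label[nd - ntip])))
  }
  NA_real_
}
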