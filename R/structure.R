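#' Van der Waals radii by element
#'
#' Defaults used for solvent-accessibility calculations: C 1.70, N 1.55,
#' O 1.52, S 1.80, H 1.20, P 1.80, Se 1.90 Angstrom.
#' @return named numeric vector.
#' @export
element_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80, SE = 1.90)
}

#' Read a protein structure from a PDB file
#'
#' Fixed-column PDB parsing (via bio3d) of ATOM/HETATM records; for
#' alternate locations only blank or 'A' altloc atoms are kept. Atoms are
#' assigned van der Waals radii by element.
#'
#' @param path PDB file path.
#' @param atom_filter "all", "CA" (alpha carbons), or "backbone".
#' @param radii named radius table, see [element_radii()]; elements missing
#'   from the table get the carbon radius with a warning.
#' @return object of class `pdb_structure`: data.frame of atoms with
#'   columns chain, resno, resid, elety (atom name), elesy (element),
#'   x, y, z, radius.
#' @export
read_pdb <- function(path, atom_filter = c("all", "CA", "backbone"),
                     radii = element_radii()) {
  atom_filter <- match.arg(atom_filter)
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (atom_filter == "CA") at <- at[at$elety == "CA", , drop = FALSE]
  if (atom_filter == "backbone")
    at <- at[at$elety %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after filter '", atom_filter, "'")
  ele <- toupper(trimws(at$elesy))
  miss <- ele == "" | is.na(ele)
  # fall back to the first letter of the atom name
  ele[miss] <- substr(gsub("[0-9]", "", at$elety[miss]), 1, 1)
  r <- radii[ele]
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(ele[is.na(r)]),
                                         collapse = ", "),
            "; using carbon radius")
    r[is.na(r)] <- radii[["C"]]
  }
  out <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = at$elety, elesy = ele,
                    x = at$x, y = at$y, z = at$z, radius = unname(r),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(out[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  class(out) <- c("pdb_structure", "data.frame")
  out
}

#' Build a structure object from explicit atoms
#'
#' Programmatic constructor used for fixtures and toy systems.
#' @param xyz n x 3 coordinate matrix.
#' @param element element symbols (recycled).
#' @param resno residue numbers (recycled).
#' @param resid residue names (recycled).
#' @param elety atom names (recycled).
#' @param chain chain ids (recycled).
#' @param radii radius table.
#' @export
structure_from_atoms <- function(xyz, element = "C", resno = 1L,
                                 resid = "GLY", elety = "CA", chain = "A",
                                 radii = element_radii()) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  ele <- rep_len(toupper(element), n)
  out <- data.frame(chain = rep_len(chain, n), resno = rep_len(resno, n),
                    resid = rep_len(resid, n), elety = rep_len(elety, n),
                    elesy = ele, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    radius = unname(radii[ele]), stringsAsFactors = FALSE)
  if (anyNA(out$radius)) stop("unknown element in radius table")
  class(out) <- c("pdb_structure", "data.frame")
  out
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation (reflection-corrected, det +1) and translation
#' minimizing the RMSD between two paired coordinate sets.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (n >= 3).
#' @return object of class `superposition`: `rotation` (3 x 3, applied to
#'   centered `coords_b` to match `coords_a`), `translation`, `rmsd`,
#'   `n_atoms`, `degenerate` (TRUE when the point sets are essentially
#'   collinear, in which case the rotation is not unique).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (ncol(A) != 3 || ncol(B) != 3 || nrow(A) != nrow(B))
    stop("coordinate sets must be paired n x 3 matrices")
  n <- nrow(A)
  if (n < 3) stop("superposition needs at least 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)            # rotation applied to B0
  diff <- A0 - B0 %*% t(R)
  rmsd <- sqrt(sum(diff^2) / n)
  degenerate <- sum(sv$d > max(sv$d) * 1e-8) < 2
  structure(list(rotation = R, translation = ca - as.vector(R %*% cb),
                 rmsd = rmsd, n_atoms = n, degenerate = degenerate),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms%s\n", x$rmsd,
              x$n_atoms, if (x$degenerate) " (degenerate geometry)" else ""))
  invisible(x)
}

#' RMSD between matched atoms of two structures
#'
#' Convenience wrapper: pairs atoms of the chosen name by chain/residue
#' number intersection and superposes them.
#'
#' @param sa,sb `pdb_structure` objects.
#' @param atom_name atom used for pairing (default "CA").
#' @return a `superposition`.
#' @export
superpose_structures <- function(sa, sb, atom_name = "CA") {
  a <- sa[sa$elety == atom_name, ]
  b <- sb[sb$elety == atom_name, ]
  key_a <- paste(a$chain, a$resno)
  key_b <- paste(b$chain, b$resno)
  shared <- intersect(key_a, key_b)
  if (length(shared) < 3) stop("fewer than 3 shared ", atom_name, " atoms")
  A <- as.matrix(a[match(shared, key_a), c("x", "y", "z")])
  B <- as.matrix(b[match(shared, key_b), c("x", "y", "z")])
  kabsch_superpose(A, B)
}

#' Distance between two named atoms
#'
#' Euclidean distance between `atom_name` of residue `res_a` and of
#' `res_b` (e.g. the SG atoms of the peroxidatic and resolving cysteines).
#'
#' @param s a `pdb_structure`.
#' @param res_a,res_b residue numbers.
#' @param atom_name atom name (default "SG", the cysteine sulfur).
#' @param chain chain id (default first chain).
#' @return distance in Angstrom.
#' @export
residue_pair_distance <- function(s, res_a, res_b, atom_name = "SG",
                                  chain = NULL) {
  if (is.null(chain)) chain <- s$chain[1]
  get1 <- function(rn) {
    hit <- s[s$chain == chain & s$resno == rn & s$elety == atom_name, ]
    if (nrow(hit) == 0)
      stop("residue ", rn, " has no atom '", atom_name, "' in chain ",
           chain)
    as.numeric(hit[1, c("x", "y", "z")])
  }
  sqrt(sum((get1(res_a) - get1(res_b))^2))
}

# quasi-uniform points on the unit sphere (golden-section spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places quasi-uniform test points (golden-section spiral) on each atom's
#' solvent-accessible sphere (radius + probe) and counts the fraction not
#' occluded by any neighboring atom's accessible sphere. At 960 points the
#' single-sphere area is exact to well under 1%.
#'
#' @param s a `pdb_structure`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points test points per atom (>= 92; default 960).
#' @return the structure with an added `sasa` column (Angstrom^2 per atom).
#' @export
shrake_rupley_sasa <- function(s, probe = 1.4, n_points = 960L) {
  stopifnot(probe >= 0, n_points >= 92)
  pts <- sphere_points(n_points)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rr <- s$radius + probe
  n <- nrow(xyz)
  sasa <- numeric(n)
  # pairwise distances once, for the neighbor lists
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    p <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & dj > rr[j]^2
    }
    sasa[i] <- 4 * pi * rr[i]^2 * sum(free) / n_points
  }
  s$sasa <- sasa
  s
}

#' Maximal residue solvent accessibilities (Gly-X-Gly convention)
#'
#' Published theoretical maximum accessible areas of residue X in an
#' extended Gly-X-Gly tripeptide (Tien et al. 2013), in Angstrom^2, used to
#' normalize relative accessibility.
#' @return named numeric vector over the 20 three-letter residue codes.
#' @export
max_asa_table <- function() {
  c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
    GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
    MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
    TYR = 263, VAL = 174, SEC = 167)
}

#' Relative solvent accessibility of a residue set
#'
#' 100 x (summed SASA of the residues) / (summed reference maxima of their
#' residue types). Used, e.g., to report how solvent-exposed the catalytic
#' tetrad cleft is.
#'
#' @param s a `pdb_structure`; if it lacks a `sasa` column,
#'   [shrake_rupley_sasa()] is run first.
#' @param residue_set residue numbers to aggregate.
#' @param chain chain id (default first chain).
#' @param reference_max named table of per-residue maxima, see
#'   [max_asa_table()].
#' @param ... passed to [shrake_rupley_sasa()].
#' @return percentage.
#' @export
relative_accessibility <- function(s, residue_set, chain = NULL,
                                   reference_max = max_asa_table(), ...) {
  if (is.null(s$sasa)) s <- shrake_rupley_sasa(s, ...)
  if (is.null(chain)) chain <- s$chain[1]
  tot <- 0; ref <- 0
  for (rn in residue_set) {
    hit <- s[s$chain == chain & s$resno == rn, ]
    if (nrow(hit) == 0) stop("residue ", rn, " not found in chain ", chain)
    rtype <- hit$resid[1]
    if (!rtype %in% names(reference_max))
      stop("residue type '", rtype, "' missing from the reference table")
    tot <- tot + sum(hit$sasa)
    ref <- ref + reference_max[[rtype]]
  }
  100 * tot / ref
}

#' Write per-atom and per-residue SASA as TSV
#' @param s a `pdb_structure` with `sasa` column.
#' @param path output path.
#' @export
write_sasa_table <- function(s, path) {
  if (is.null(s$sasa)) stop("run shrake_rupley_sasa() first")
  utils::write.table(as.data.frame(s), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
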