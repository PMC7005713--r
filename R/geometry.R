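# Pure-geometry kernel: dihedrals, rotamer bins, contacts, Kabsch superposition.
# All functions are seedless and operate on plain numeric vectors/matrices or
# on atom tibbles as produced by read_structure()/build_his_residue().

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

#' Signed dihedral (torsion) angle of four points
#'
#' Computes the torsion angle about the p2-p3 axis under the IUPAC sign
#' convention: the angle is 0 for a cis (eclipsed) arrangement and positive
#' when, looking from p2 towards p3, the far bond is rotated clockwise
#' relative to the near bond.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors, Cartesian coordinates in Angstrom.
#' @return Angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)) # 0 (cis)
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # 180 (trans)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("degenerate geometry: collinear triple among the four points")
  }
  m1 <- cross3(n1, b2 / vnorm(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Chi-1 side-chain dihedrals of a residue, one per alternate-conformer group
#'
#' chi-1 is the torsion N-CA-CB-CG about the CA-CB bond (the His convention;
#' the same four atom names apply to most side chains with a CG). Atoms with a
#' blank altloc are shared between conformer groups; a group is measurable
#' only when all four atoms exist within it.
#'
#' @param residue Atom tibble for a single residue (see [select_residue()]).
#' @param atoms_used Character vector of the four atom names defining the
#'   torsion, in order.
#' @return Tibble with one row per altloc group: `altloc`, `chi1` (degrees),
#'   `occupancy` (minimum occupancy among group-specific atoms; 1 when the
#'   side chain is single-conformer), `complete` (logical).
#' @export
chi1_angles <- function(residue, atoms_used = c("N", "CA", "CB", "CG")) {
  stopifnot(is.data.frame(residue), nrow(residue) > 0)
  side <- residue[residue$atom_name %in% atoms_used, , drop = FALSE]
  groups <- sort(unique(side$altloc[side$altloc != ""]))
  if (length(groups) == 0) groups <- ""
  purrr::map_dfr(groups, function(g) {
    pick <- function(name) {
      hit <- side[side$atom_name == name & side$altloc %in% c(g, ""), , drop = FALSE]
      if (nrow(hit) == 0) return(NULL)
      # prefer the group-specific atom over a shared one
      hit[order(hit$altloc != g), ][1, , drop = FALSE]
    }
    picked <- purrr::map(atoms_used, pick)
    missing <- atoms_used[purrr::map_lgl(picked, is.null)]
    if (length(missing) > 0) {
      return(tibble::tibble(altloc = g, chi1 = NA_real_,
                            occupancy = NA_real_, complete = FALSE))
    }
    pts <- purrr::map(picked, ~ c(.x$x, .x$y, .x$z))
    own <- purrr::keep(picked, ~ .x$altloc == g)
    occ <- if (length(own) == 0) 1 else min(purrr::map_dbl(own, "occupancy"))
    tibble::tibble(
      altloc = g,
      chi1 = dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
      occupancy = occ,
      complete = TRUE
    )
  })
}

#' Classify a chi-1 angle into a canonical rotamer bin
#'
#' Default partition of (-180, 180]: gauche- is `[-120, 0)`, gauche+ is
#' `[0, 120)` and trans is the remainder (`[120, 180]` together with
#' `(-180, -120)`). Bin edges belong to the bin whose lower edge they are,
#' so the classification is a total, deterministic partition. The gauche-
#' label follows the IUPAC/penultimate "m" convention (chi1 near -60 deg);
#' set `mirror = TRUE` to use the sign-flipped convention instead.
#'
#' @param chi1 Numeric vector of angles in degrees in (-180, 180].
#' @param mirror Flip the sign convention (classify -chi1).
#' @return Character vector with values `"gauche-"`, `"gauche+"`, `"trans"`.
#' @export
classify_rotamer <- function(chi1, mirror = FALSE) {
  stopifnot(is.numeric(chi1), all(is.na(chi1) | (chi1 > -180 & chi1 <= 180)))
  x <- if (mirror) -chi1 else chi1
  # the mirrored -180 edge case: -(-180,180] maps 180 -> -180; renormalize
  x <- ifelse(!is.na(x) & x <= -180, x + 360, x)
  # snap values within 1e-9 deg of a bin edge onto it, so edge-constructed
  # angles classify deterministically despite floating-point measurement
  for (edge in c(-120, 0, 120)) {
    x <- ifelse(!is.na(x) & abs(x - edge) < 1e-9, edge, x)
  }
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    x >= -120 & x < 0 ~ "gauche-",
    x >= 0 & x < 120 ~ "gauche+",
    TRUE ~ "trans"
  )
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rigid alignment of the mobile point set onto the reference
#' via SVD of the cross-covariance, with reflection correction so the
#' returned rotation is proper (det = +1).
#'
#' @param reference,mobile n x 3 numeric matrices of paired coordinates
#'   (row i of `mobile` corresponds to row i of `reference`).
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (3-vector such that
#'   `mobile %*% t(rotation) + translation` approximates `reference`),
#'   `rmsd` (Angstrom) and `n_pairs`.
#' @export
kabsch_superpose <- function(reference, mobile) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (!identical(dim(reference), dim(mobile))) {
    stop("paired coordinate sets must have identical dimensions")
  }
  n <- nrow(reference)
  if (n < 3) stop("need at least 3 paired points")
  ca <- colMeans(reference)
  cb <- colMeans(mobile)
  A <- sweep(reference, 2, ca)
  B <- sweep(mobile, 2, cb)
  H <- crossprod(B, A) # 3 x 3 cross-covariance
  s <- svd(H)
  if (s$d[2] < 1e-12) stop("degenerate (rank-deficient) point cloud")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(
    list(rotation = R, translation = as.numeric(ca - R %*% cb),
         rmsd = rmsd, n_pairs = n),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Kabsch superposition: %d paired atoms, RMSD %.3f A\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup A `superposition`.
#' @param xyz n x 3 matrix of mobile-frame coordinates.
#' @return n x 3 matrix in the reference frame.
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

#' All cross-set atomic contacts within a distance cutoff
#'
#' @param atoms_a,atoms_b Atom tibbles (need columns `atom_name`, `x`, `y`,
#'   `z`; other columns are carried through with `a_`/`b_` prefixes dropped).
#' @param cutoff Distance cutoff in Angstrom (default 3.6, a typical
#'   heavy-atom hydrogen-bond upper bound).
#' @return Tibble of pairs sorted by ascending distance: `atom_a`, `atom_b`,
#'   `distance`, plus index columns `idx_a`, `idx_b` into the inputs.
#' @export
contact_search <- function(atoms_a, atoms_b, cutoff = 3.6) {
  stopifnot(cutoff > 0)
  empty <- tibble::tibble(atom_a = character(), atom_b = character(),
                          distance = numeric(), idx_a = integer(),
                          idx_b = integer())
  if (nrow(atoms_a) == 0 || nrow(atoms_b) == 0) return(empty)
  xa <- as.matrix(atoms_a[, c("x", "y", "z")])
  xb <- as.matrix(atoms_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- tibble::tibble(
    atom_a = atoms_a$atom_name[hit[, 1]],
    atom_b = atoms_b$atom_name[hit[, 2]],
    distance = sqrt(pmax(d2[hit], 0)),
    idx_a = as.integer(hit[, 1]),
    idx_b = as.integer(hit[, 2])
  )
  dplyr::arrange(out, .data$distance)
}
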