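# Synthetic inputs: idealized His residues built in internal coordinates
# (so chi-1 is exact by construction), multi-chain PDB fixtures with
# prescribed rotamers / pH metadata / sulfate placement, helical Ca traces
# for superposition work, and noisy exponential-decay time courses.

unit <- function(v) v / vnorm(v)

#' Place an atom from internal coordinates (bond, angle, torsion)
#'
#' Given three reference positions a-b-c, returns the position d such that
#' |c-d| = `bond`, the angle b-c-d equals `angle` and the torsion a-b-c-d
#' equals `torsion` (degrees, IUPAC sign convention).
#'
#' @param a,b,c Numeric 3-vectors.
#' @param bond Bond length in Angstrom (> 0).
#' @param angle Bond angle in degrees, in (0, 180).
#' @param torsion Torsion in degrees.
#' @return Numeric 3-vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  stopifnot(bond > 0, angle > 0, angle < 180)
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- unit(c - b)
  ab <- unit(b - a)
  n <- cross3(ab, bc)
  if (vnorm(n) < 1e-10) stop("degenerate frame: collinear reference atoms")
  n <- unit(n)
  m <- cross3(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  as.numeric(c + cbind(bc, m, n) %*% d_local)
}

his_atom <- function(name, xyz, element, chain, resno, altloc = "",
                     occupancy = 1, resname = "HIS", record = "ATOM") {
  tibble::tibble(
    record_type = record, atom_name = name, altloc = altloc,
    residue_name = resname, chain_id = chain, residue_number = as.integer(resno),
    insertion_code = "", x = xyz[1], y = xyz[2], z = xyz[3],
    occupancy = occupancy, b_factor = 20, element = element,
    model_number = 1L
  )
}

#' Build an idealized histidine residue at a prescribed chi-1
#'
#' Atoms are placed by internal coordinates (bond length, bond angle,
#' torsion), so the recomputed chi-1 equals the target to numerical
#' precision. The imidazole ring beyond CG is completed with planar ideal
#' geometry at a fixed chi-2 (default -75 deg, a common His value) solely so
#' ND1/NE2 exist for contact analysis.
#'
#' @param chi1 Target chi-1 in degrees, in (-180, 180].
#' @param chi2 chi-2 (CA-CB-CG-ND1 torsion) in degrees.
#' @param chain,resno Chain ID and residue number for the emitted atoms.
#' @param altloc Altloc tag for the side-chain atoms ("" = single conformer).
#' @param occupancy Occupancy for the side-chain atoms.
#' @param origin 3-vector added to all coordinates (chain placement).
#' @param backbone Include backbone N/CA/C/O rows (set FALSE for the second
#'   conformer of a double-conformer residue, which shares the backbone).
#' @param bond_n_ca,bond_ca_cb,bond_cb_cg Bond lengths, Angstrom.
#' @param angle_n_ca_cb,angle_ca_cb_cg Bond angles, degrees.
#' @return Atom tibble (N, CA, C, O, CB, CG, ND1, CD2, CE1, NE2).
#' @export
build_his_residue <- function(chi1, chi2 = -75, chain = "A", resno = 260,
                              altloc = "", occupancy = 1,
                              origin = c(0, 0, 0), backbone = TRUE,
                              bond_n_ca = 1.46, bond_ca_cb = 1.53,
                              bond_cb_cg = 1.50,
                              angle_n_ca_cb = 110.5, angle_ca_cb_cg = 113.8) {
  stopifnot(chi1 > -180, chi1 <= 180,
            bond_n_ca > 0, bond_ca_cb > 0, bond_cb_cg > 0,
            angle_n_ca_cb > 0, angle_n_ca_cb < 180,
            angle_ca_cb_cg > 0, angle_ca_cb_cg < 180)
  N <- c(0, 0, 0)
  CA <- c(bond_n_ca, 0, 0)
  a <- angle_n_ca_cb * pi / 180
  CB <- CA + bond_ca_cb * c(-cos(a), sin(a), 0)
  CG <- place_atom(N, CA, CB, bond_cb_cg, angle_ca_cb_cg, chi1)
  # carbonyl, for a complete-looking residue
  C <- place_atom(CB, N, CA, 1.52, 110.1, 122)
  O <- place_atom(N, CA, C, 1.23, 120.5, 180)
  # planar imidazole: ring torsions fixed by chi2
  ND1 <- place_atom(CA, CB, CG, 1.38, 122.7, chi2)
  CD2 <- place_atom(CA, CB, CG, 1.36, 131.1, chi2 + 180)
  CE1 <- place_atom(CB, CG, ND1, 1.32, 105.7, 180)
  NE2 <- place_atom(CG, ND1, CE1, 1.32, 111.7, 0)
  rows <- list()
  if (backbone) {
    rows <- c(rows, list(
      his_atom("N", N, "N", chain, resno),
      his_atom("CA", CA, "C", chain, resno),
      his_atom("C", C, "C", chain, resno),
      his_atom("O", O, "O", chain, resno)
    ))
  }
  rows <- c(rows, list(
    his_atom("CB", CB, "C", chain, resno, altloc, occupancy),
    his_atom("CG", CG, "C", chain, resno, altloc, occupancy),
    his_atom("ND1", ND1, "N", chain, resno, altloc, occupancy),
    his_atom("CD2", CD2, "C", chain, resno, altloc, occupancy),
    his_atom("CE1", CE1, "C", chain, resno, altloc, occupancy),
    his_atom("NE2", NE2, "N", chain, resno, altloc, occupancy)
  ))
  out <- dplyr::bind_rows(rows)
  out$x <- out$x + origin[1]; out$y <- out$y + origin[2]
  out$z <- out$z + origin[3]
  out
}

# Tetrahedral sulfate whose nearest oxygen sits at `distance` from `ne2`
# along the exocyclic direction `u`.
build_sulfate <- function(ne2, u, distance, chain = "S", resno = 500) {
  u <- unit(u)
  O1 <- ne2 + distance * u
  S <- O1 + 1.47 * u
  w1 <- unit(cross3(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  w2 <- cross3(u, w1)
  # directions at 109.47 deg from S->O1 (= -u), spaced 120 deg
  dirs <- purrr::map(0:2, function(k) {
    ang <- 2 * pi * k / 3
    unit(cos(109.47 * pi / 180) * (-u) +
           sin(109.47 * pi / 180) * (cos(ang) * w1 + sin(ang) * w2))
  })
  atoms <- list(his_atom("S", S, "S", chain, resno, resname = "SO4",
                         record = "HETATM"),
                his_atom("O1", O1, "O", chain, resno, resname = "SO4",
                         record = "HETATM"))
  for (k in 1:3) {
    atoms <- c(atoms, list(his_atom(paste0("O", k + 1), S + 1.47 * dirs[[k]],
                                    "O", chain, resno, resname = "SO4",
                                    record = "HETATM")))
  }
  dplyr::bind_rows(atoms)
}

#' Build a multi-chain synthetic structure file with prescribed His rotamers
#'
#' One target His per chain at the prescribed chi-1 (a chain given two
#' chi-1 values becomes a double conformer with altlocs A/B sharing the
#' backbone), REMARK 280 carrying the declared crystallization pH, and an
#' optional sulfate ion whose nearest oxygen sits at a prescribed distance
#' from the Nepsilon-2 of a chosen chain.
#'
#' @param chains Named list mapping chain ID to chi-1 (length-1) or to two
#'   chi-1 values (double conformer), e.g. `list(A = -60, B = c(-60, 175))`.
#' @param ph Declared crystallization pH in `[0, 14]`, or NULL.
#' @param ph_range Optional textual pH range instead of a single value.
#' @param path Output PDB path.
#' @param resno Target residue number (default 260).
#' @param sulfate NULL, or `list(chain = "A", distance = 3.2)` placing a
#'   sulfate near that chain's NE2 (first conformer).
#' @param occupancies Occupancies for double conformers (default 0.5/0.5).
#' @param spacing Translation between consecutive chains, Angstrom.
#' @return `path`, invisibly.
#' @export
build_structure <- function(chains, ph = NULL, path, ph_range = NULL,
                            resno = 260, sulfate = NULL,
                            occupancies = c(0.5, 0.5), spacing = 25) {
  stopifnot(is.list(chains), length(chains) >= 1, !is.null(names(chains)))
  if (!is.null(ph)) stopifnot(ph >= 0, ph <= 14)
  all_atoms <- list()
  for (i in seq_along(chains)) {
    ch <- names(chains)[i]
    chis <- chains[[i]]
    origin <- c((i - 1) * spacing, 0, 0)
    if (length(chis) == 1) {
      all_atoms[[ch]] <- build_his_residue(chis, chain = ch, resno = resno,
                                           origin = origin)
    } else {
      a1 <- build_his_residue(chis[1], chain = ch, resno = resno,
                              altloc = "A", occupancy = occupancies[1],
                              origin = origin)
      a2 <- build_his_residue(chis[2], chain = ch, resno = resno,
                              altloc = "B", occupancy = occupancies[2],
                              origin = origin, backbone = FALSE)
      all_atoms[[ch]] <- dplyr::bind_rows(a1, a2)
    }
  }
  atoms <- dplyr::bind_rows(all_atoms)
  if (!is.null(sulfate)) {
    res <- atoms[atoms$chain_id == sulfate$chain, , drop = FALSE]
    grp <- res[res$altloc %in% c("", "A"), , drop = FALSE]
    getv <- function(n) {
      r <- grp[grp$atom_name == n, ][1, ]
      c(r$x, r$y, r$z)
    }
    ne2 <- getv("NE2"); ce1 <- getv("CE1"); cd2 <- getv("CD2")
    u <- unit(unit(ne2 - ce1) + unit(ne2 - cd2)) # exocyclic bisector
    atoms <- dplyr::bind_rows(atoms, build_sulfate(ne2, u, sulfate$distance))
  }
  write_pdb_fixture(atoms, path, ph = ph, ph_range = ph_range)
  invisible(path)
}

#' Build a synthetic structure set emulating a survey manifest
#'
#' For every structure in the manifest, writes `<pdb_id>.pdb` into `dir`
#' with one His subunit per manifest call at a chi-1 drawn inside the bin of
#' its printed rotamer (gauche-: -60 +/- `jitter` deg; trans: 180 +/-
#' `jitter`), the manifest pH in REMARK 280, and chains labelled A, B, ...
#' (a `conformer` column groups altloc pairs onto one chain). Reproducible
#' under `seed`.
#'
#' @param manifest Call-level manifest tibble (see [hiska_manifest()]):
#'   columns `pdb_id`, `subunit`, `conformer`, `rotamer`, `ph`, `ph_range`.
#' @param dir Output directory (created if needed).
#' @param selectors Selector table ([hiska_selectors()] default); each
#'   fixture's His is numbered by its protein's selector (260 when the
#'   selector is unknown), so coordinate-mode survey runs resolve it with
#'   the same table.
#' @param jitter Half-width of the uniform chi-1 spread, degrees (< 60 keeps
#'   every draw inside its bin).
#' @param seed Integer seed.
#' @return Tibble of generated calls (`pdb_id`, `chain`, `resno`, `altloc`,
#'   `chi1`, `rotamer`, `path`) -- the generator's own bookkeeping, usable
#'   as ground truth.
#' @export
simulate_survey_structures <- function(manifest, dir,
                                       selectors = hiska_selectors(),
                                       jitter = 25, seed = 1) {
  stopifnot(jitter >= 0, jitter < 60)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  draw_chi <- function(rot) {
    centre <- switch(rot, "gauche-" = -60, "gauche+" = 60, "trans" = 180)
    x <- centre + stats::runif(1, -jitter, jitter)
    if (x > 180) x <- x - 360
    x
  }
  out <- list()
  for (id in unique(manifest$pdb_id)) {
    rows <- manifest[manifest$pdb_id == id, , drop = FALSE]
    resno <- 260L
    if ("protein" %in% names(rows) && !is.null(selectors)) {
      sel <- selectors$his_resno[match(rows$protein[1], selectors$protein)]
      if (length(sel) == 1 && !is.na(sel)) resno <- sel
    }
    subunits <- unique(rows$subunit)
    chain_ids <- LETTERS[seq_along(subunits)]
    chains <- list()
    book <- list()
    for (j in seq_along(subunits)) {
      sub_rows <- rows[rows$subunit == subunits[j], , drop = FALSE]
      chis <- vapply(sub_rows$rotamer, draw_chi, numeric(1))
      chains[[chain_ids[j]]] <- unname(chis)
      book[[j]] <- tibble::tibble(
        pdb_id = id, chain = chain_ids[j], resno = as.integer(resno),
        altloc = if (nrow(sub_rows) == 1) "" else c("A", "B"),
        chi1 = unname(chis), rotamer = sub_rows$rotamer
      )
    }
    path <- file.path(dir, paste0(id, ".pdb"))
    ph <- rows$ph[1]
    build_structure(chains, ph = if (is.na(ph)) NULL else ph, path = path,
                    ph_range = if (is.na(rows$ph_range[1])) NULL
                               else rows$ph_range[1],
                    resno = resno)
    out[[id]] <- dplyr::bind_rows(book) |> dplyr::mutate(path = path)
  }
  dplyr::bind_rows(out)
}

#' Build an idealized multi-chain alpha-helical Ca trace
#'
#' Used to exercise superposition at realistic problem sizes (hundreds of
#' matched residues) without real deposits. Rise 1.5 A and 100 deg twist per
#' residue on a 2.3 A radius.
#'
#' @param n_res Residues per chain (recycled), e.g. `c(354, 353)`.
#' @param chains Chain IDs.
#' @param spacing Offset between chains, Angstrom.
#' @return Atom tibble of CA atoms.
#' @export
build_ca_trace <- function(n_res, chains = LETTERS[seq_along(n_res)],
                           spacing = 15) {
  purrr::map2_dfr(n_res, seq_along(chains), function(n, i) {
    k <- seq_len(n)
    th <- k * 100 * pi / 180
    tibble::tibble(
      record_type = "ATOM", atom_name = "CA", altloc = "",
      residue_name = "ALA", chain_id = chains[i], residue_number = k,
      insertion_code = "",
      x = 2.3 * cos(th) + (i - 1) * spacing,
      y = 2.3 * sin(th),
      z = 1.5 * k,
      occupancy = 1, b_factor = 20, element = "C", model_number = 1L
    )
  })
}

#' Apply a rigid transform plus optional coordinate noise to an atom tibble
#'
#' @param atoms Atom tibble.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector.
#' @param noise_sd Per-coordinate Gaussian noise sd, Angstrom.
#' @param seed Optional integer seed for the noise.
#' @return Transformed atom tibble.
#' @export
transform_atoms <- function(atoms, rotation = diag(3),
                            translation = c(0, 0, 0), noise_sd = 0,
                            seed = NULL) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, `+`)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd), ncol = 3)
  }
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Simulate exponential phospho-decay time courses
#'
#' signal(t) = 100 * exp(-ln 2 * t / half_life) * exp(eps), with
#' eps ~ Normal(0, sigma^2) i.i.d. per point (multiplicative lognormal
#' noise: gel band signals are positive and their error scales with
#' intensity). The default grid is the experimental sampling scheme
#' (t = 0 plus 1, 3, 5, 15, 30 min).
#'
#' @param half_life True half-life in minutes (> 0).
#' @param times Sampling times in minutes (first point 0).
#' @param sigma Noise sd on the log scale (fraction; default 0.05).
#' @param reps Number of replicate courses.
#' @param seed Integer seed; same seed, same output, bitwise.
#' @param condition Condition label attached to the output.
#' @return Tibble: `condition`, `replicate`, `time`, `signal`.
#' @export
simulate_decay <- function(half_life, times = c(0, 1, 3, 5, 15, 30),
                           sigma = 0.05, reps = 1, seed = NULL,
                           condition = sprintf("t_half=%g min", half_life)) {
  stopifnot(half_life > 0, sigma >= 0, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  tidyr::expand_grid(replicate = seq_len(reps), time = times) |>
    dplyr::mutate(
      condition = condition,
      signal = 100 * exp(-log(2) * .data$time / half_life) *
        exp(stats::rnorm(dplyr::n(), 0, sigma))
    ) |>
    dplyr::select("condition", "replicate", "time", "signal")
}
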