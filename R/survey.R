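# Rotamer survey: assign per-subunit chi-1 rotamer calls across a structure
# set, join them to crystallization pH, tally classes and dimer concordance,
# and flag His-anion coordination.

#' The packaged HisKA survey manifest
#'
#' Curated per-subunit rotamer calls and crystallization conditions for the
#' 28 deposited HisKA-family histidine-kinase structures surveyed by this
#' package (66 subunit/conformer calls in total; double-conformer subunits
#' contribute one call per conformer). The pH column is the curated
#' crystallization pH (a printed range is reduced to its midpoint and kept
#' in `ph_range`).
#'
#' @param level `"calls"` (default; one row per subunit/conformer call,
#'   joined to structure metadata) or `"structures"` (one row per entry).
#' @return A tibble.
#' @export
hiska_manifest <- function(level = c("calls", "structures")) {
  level <- match.arg(level)
  ext <- function(f) system.file("extdata", f, package = "rotamerph",
                                 mustWork = TRUE)
  structures <- readr::read_tsv(
    ext("hiska_survey_structures.tsv"),
    col_types = readr::cols(
      pdb_id = "c", protein = "c", ph = "d", ph_range = "c",
      mother_liquor = "c", sulfate_at_his = "l"
    ), na = "NA", progress = FALSE
  )
  if (level == "structures") return(structures)
  calls <- readr::read_tsv(
    ext("hiska_survey_calls.tsv"),
    col_types = readr::cols(pdb_id = "c", subunit = "i", conformer = "c",
                            rotamer = "c"),
    progress = FALSE
  )
  calls$conformer[calls$conformer == "."] <- ""
  dplyr::left_join(calls, structures, by = "pdb_id")
}

#' Packaged phosphorylatable-His selectors
#'
#' Residue numbers of the phosphoacceptor His per surveyed protein, for
#' coordinate-mode runs. Entries whose number is not established in the
#' sources this package relies on are `NA` and must be supplied by the
#' caller.
#'
#' @return Tibble: `protein`, `his_resno`, `note`.
#' @export
hiska_selectors <- function() {
  readr::read_tsv(
    system.file("extdata", "hiska_selectors.tsv", package = "rotamerph",
                mustWork = TRUE),
    col_types = readr::cols(protein = "c", his_resno = "i", note = "c"),
    na = "NA", progress = FALSE
  )
}

#' Assign chi-1 rotamer calls for the target His of every kinase subunit
#'
#' One call per chain per qualifying alternate-conformer group. Groups below
#' the occupancy floor are skipped with a message; gauche+ calls are
#' permitted but flagged (none occur in the packaged survey).
#'
#' @param model A `structure_model`.
#' @param resno Residue number of the phosphorylatable His.
#' @param chains Chains to call (default: every chain that carries an ATOM
#'   residue `resno` named HIS).
#' @param min_occupancy Altloc groups below this occupancy are skipped.
#' @param mirror Passed to [classify_rotamer()].
#' @return Tibble: `pdb_id`, `chain`, `resno`, `altloc`, `occupancy`,
#'   `chi1`, `rotamer`, `flagged_gauche_plus`.
#' @export
assign_rotamers <- function(model, resno, chains = NULL,
                            min_occupancy = 0.2, mirror = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (is.null(chains)) {
    chains <- sort(unique(
      at$chain_id[at$residue_number == resno & at$residue_name == "HIS" &
                    at$record_type == "ATOM"]
    ))
  }
  if (length(chains) == 0) {
    stop("no HIS residue numbered ", resno, " in any chain of ",
         model$metadata$pdb_id)
  }
  purrr::map_dfr(chains, function(ch) {
    res <- select_residue(model, ch, resno, require_resname = "HIS")
    ang <- chi1_angles(res)
    ang <- ang[ang$complete, , drop = FALSE]
    if (nrow(ang) == 0) {
      stop("His ", ch, "/", resno, " side chain incomplete in ",
           model$metadata$pdb_id)
    }
    low <- ang$occupancy < min_occupancy
    if (any(low)) {
      message(model$metadata$pdb_id, " ", ch, "/", resno, ": skipping ",
              sum(low), " altloc group(s) below occupancy ", min_occupancy)
      ang <- ang[!low, , drop = FALSE]
    }
    if (nrow(ang) == 0) return(NULL)
    rot <- classify_rotamer(ang$chi1, mirror = mirror)
    tibble::tibble(
      pdb_id = model$metadata$pdb_id, chain = ch, resno = as.integer(resno),
      altloc = ang$altloc, occupancy = ang$occupancy, chi1 = ang$chi1,
      rotamer = rot, flagged_gauche_plus = rot == "gauche+"
    )
  })
}

#' Dimer (multi-subunit) rotamer concordance of one structure's calls
#'
#' `"identical"` when every single-conformer subunit carries the same label,
#' `"mixed-altloc"` when any subunit carries two labels, `"distinct"`
#' otherwise; `NA` ("not evaluated") for single-subunit structures.
#'
#' @param calls Call tibble for one structure, with columns identifying the
#'   subunit (`chain` or `subunit`) and `rotamer`.
#' @return Length-1 character (or NA).
#' @export
dimer_concordance <- function(calls) {
  key <- if ("chain" %in% names(calls)) calls$chain else calls$subunit
  if (length(unique(key)) < 2) return(NA_character_)
  per_sub <- tapply(calls$rotamer, key, function(r) length(unique(r)))
  if (any(per_sub > 1)) return("mixed-altloc")
  labels <- tapply(calls$rotamer, key, unique)
  if (length(unique(unlist(labels))) == 1) "identical" else "distinct"
}

#' Flag His-anion coordination for rotamer calls
#'
#' A call is anion-coordinated when any anion atom (by default sulfate
#' oxygens and sulfur) lies within `cutoff` of the imidazole ND1 or NE2 of
#' the called altloc group. Calls whose imidazole nitrogens are absent get
#' `NA` (not evaluated).
#'
#' @param model The `structure_model` the calls came from.
#' @param calls Tibble from [assign_rotamers()].
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 3.6).
#' @param anion_resnames HETATM residue names treated as anions.
#' @return `calls` with an `anion_coordinated` column.
#' @export
annotate_anion_coordination <- function(model, calls, cutoff = 3.6,
                                        anion_resnames = c("SO4", "PO4")) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  anions <- at[at$residue_name %in% anion_resnames, , drop = FALSE]
  calls$anion_coordinated <- purrr::pmap_lgl(
    calls[, c("chain", "resno", "altloc")],
    function(chain, resno, altloc) {
      res <- at[at$chain_id == chain & at$residue_number == resno &
                  at$record_type == "ATOM" &
                  at$altloc %in% c("", altloc), , drop = FALSE]
      nitro <- res[res$atom_name %in% c("ND1", "NE2"), , drop = FALSE]
      if (nrow(nitro) == 0) return(NA)
      if (nrow(anions) == 0) return(FALSE)
      nrow(contact_search(nitro, anions, cutoff)) > 0
    }
  )
  calls
}

#' Compile the rotamer survey across a structure set
#'
#' In `"manifest"` mode the packaged (or supplied) per-subunit calls are
#' tallied directly -- no coordinate files needed. In `"coordinates"` mode
#' every manifest entry's file (`<pdb_id>.pdb` or `.cif`) is read from
#' `structures_dir`, the target His is called per subunit and conformer,
#' anion coordination is flagged, and the curated manifest pH is joined as
#' the pH source of truth (the header-extracted pH is reported alongside
#' for auditing). Missing files are recorded and the survey is marked
#' partial, never silently complete.
#'
#' @param manifest Call-level manifest tibble ([hiska_manifest()] default).
#' @param mode `"manifest"` or `"coordinates"`.
#' @param structures_dir Directory of coordinate files (coordinates mode).
#' @param selectors Tibble mapping `protein` to `his_resno`
#'   ([hiska_selectors()] default). Proteins with `NA` selectors cannot be
#'   called and error in coordinates mode.
#' @param cutoff Anion-contact cutoff, Angstrom.
#' @param min_occupancy,mirror Passed to [assign_rotamers()].
#' @return Object of class `rotamer_survey`: list with `calls` (tibble),
#'   `counts` (named integer: gauche-, gauche+, trans), `concordance`
#'   (per-structure tibble), `mode`, `missing` (pdb_ids without files),
#'   `partial` (logical).
#' @export
compile_survey <- function(manifest = hiska_manifest(),
                           mode = c("manifest", "coordinates"),
                           structures_dir = NULL,
                           selectors = hiska_selectors(),
                           cutoff = 3.6, min_occupancy = 0.2,
                           mirror = FALSE) {
  mode <- match.arg(mode)
  missing_ids <- character()
  if (nrow(manifest) == 0) {
    calls <- tibble::tibble(pdb_id = character(), protein = character(),
                            chain = character(), altloc = character(),
                            chi1 = numeric(), rotamer = character(),
                            ph = numeric(), anion_coordinated = logical())
  } else if (mode == "manifest") {
    calls <- manifest |>
      dplyr::transmute(
        pdb_id = .data$pdb_id, protein = .data$protein,
        chain = as.character(.data$subunit), altloc = .data$conformer,
        chi1 = NA_real_, rotamer = .data$rotamer, ph = .data$ph,
        ph_range = .data$ph_range,
        anion_coordinated = NA
      )
  } else {
    if (is.null(structures_dir)) {
      stop("structures_dir is required in coordinates mode")
    }
    per_structure <- manifest |>
      dplyr::distinct(.data$pdb_id, .data$protein, .data$ph, .data$ph_range)
    pieces <- purrr::pmap(per_structure, function(pdb_id, protein, ph,
                                                  ph_range) {
      path <- NULL
      for (ext in c(".pdb", ".cif")) {
        cand <- file.path(structures_dir, paste0(pdb_id, ext))
        if (file.exists(cand)) { path <- cand; break }
      }
      if (is.null(path)) return(list(missing = pdb_id))
      resno <- selectors$his_resno[match(protein, selectors$protein)]
      if (length(resno) == 0 || is.na(resno)) resno <- 260L
      model <- read_structure(path)
      raw <- assign_rotamers(model, resno, min_occupancy = min_occupancy,
                             mirror = mirror)
      raw <- annotate_anion_coordination(model, raw, cutoff = cutoff)
      raw$pdb_id <- pdb_id # manifest id wins over filename-derived id
      list(calls = raw |>
             dplyr::mutate(protein = protein, ph = ph, ph_range = ph_range,
                           header_ph = model$metadata$crystallization_ph))
    })
    missing_ids <- purrr::map_chr(pieces,
                                  ~ .x$missing %||% NA_character_) |>
      stats::na.omit() |> as.character()
    calls <- purrr::map_dfr(pieces, "calls")
  }
  counts <- c(
    `gauche-` = sum(calls$rotamer == "gauche-"),
    `gauche+` = sum(calls$rotamer == "gauche+"),
    trans = sum(calls$rotamer == "trans")
  )
  concordance <- calls |>
    dplyr::group_by(.data$pdb_id) |>
    dplyr::summarise(
      n_calls = dplyr::n(),
      concordance = dimer_concordance(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    )
  structure(
    list(calls = calls, counts = counts, concordance = concordance,
         mode = mode, missing = missing_ids,
         partial = length(missing_ids) > 0),
    class = "rotamer_survey"
  )
}

#' @export
print.rotamer_survey <- function(x, ...) {
  cat(sprintf(
    "<rotamer_survey> %s mode: %d calls in %d structures (gauche- %d, gauche+ %d, trans %d)%s\n",
    x$mode, nrow(x$calls), length(unique(x$calls$pdb_id)),
    x$counts[["gauche-"]], x$counts[["gauche+"]], x$counts[["trans"]],
    if (x$partial) sprintf(" [PARTIAL: %d file(s) missing]",
                           length(x$missing)) else ""
  ))
  print(table(x$concordance$concordance, useNA = "ifany"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rotamer_survey <- function(x, ...) x$calls

#' @exportS3Method generics::glance
glance.rotamer_survey <- function(x, ...) {
  conc <- table(factor(x$concordance$concordance,
                       levels = c("identical", "distinct", "mixed-altloc")))
  tibble::tibble(
    n_calls = nrow(x$calls),
    n_structures = length(unique(x$calls$pdb_id)),
    n_gauche_minus = x$counts[["gauche-"]],
    n_gauche_plus = x$counts[["gauche+"]],
    n_trans = x$counts[["trans"]],
    n_identical = as.integer(conc[["identical"]]),
    n_distinct = as.integer(conc[["distinct"]]),
    n_mixed_altloc = as.integer(conc[["mixed-altloc"]]),
    partial = x$partial
  )
}

#' Rotamer-versus-pH scatter for a survey
#'
#' @param object A `rotamer_survey`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rotamer_survey <- function(object, ...) {
  calls <- object$calls[!is.na(object$calls$ph), , drop = FALSE]
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$ph, y = .data$rotamer)) +
    ggplot2::geom_jitter(width = 0, height = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "crystallization pH", y = NULL,
                  title = "Phosphorylatable-His rotamer vs crystallization pH") +
    ggplot2::theme_minimal()
}
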