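# End-to-end entry points: the survey pipeline (calls + counts +
# association + reports) and pairwise complex superposition.

#' Run the full rotamer survey pipeline and write reports
#'
#' Compiles the survey ([compile_survey()]), tests the pH association at the
#' configured threshold ([test_ph_association()]), and optionally writes a
#' TSV call table plus a JSON summary. Every JSON report carries a
#' provenance block (package version, configuration echo, input checksums)
#' sufficient to re-execute the run.
#'
#' @param manifest Call-level manifest ([hiska_manifest()] default).
#' @param mode `"manifest"` or `"coordinates"`.
#' @param structures_dir Coordinate-file directory (coordinates mode).
#' @param threshold_ph Association threshold (default 6.5).
#' @param cutoff Anion-contact cutoff, Angstrom (default 3.6).
#' @param out_tsv,out_json Optional output paths.
#' @param selectors Selector table ([hiska_selectors()] default).
#' @param mirror Sign-convention flip, passed through.
#' @return Invisibly, list with `survey`, `association`, `status` (0 clean,
#'   3 partial: some manifest entries had no coordinate file).
#' @export
run_survey_pipeline <- function(manifest = hiska_manifest(),
                                mode = c("manifest", "coordinates"),
                                structures_dir = NULL, threshold_ph = 6.5,
                                cutoff = 3.6, out_tsv = NULL,
                                out_json = NULL,
                                selectors = hiska_selectors(),
                                mirror = FALSE) {
  mode <- match.arg(mode)
  stopifnot(threshold_ph >= 0, threshold_ph <= 14, cutoff > 0)
  survey <- compile_survey(manifest, mode = mode,
                           structures_dir = structures_dir,
                           selectors = selectors, cutoff = cutoff,
                           mirror = mirror)
  assoc <- test_ph_association(survey, threshold = threshold_ph)
  calls <- dplyr::arrange(survey$calls, .data$pdb_id, .data$chain,
                          .data$altloc)
  if (!is.null(out_tsv)) readr::write_tsv(calls, out_tsv)
  if (!is.null(out_json)) {
    inputs <- character()
    if (mode == "coordinates" && !is.null(structures_dir)) {
      files <- list.files(structures_dir, pattern = "\\.(pdb|cif)$",
                          full.names = TRUE)
      inputs <- stats::setNames(unname(tools::md5sum(files)),
                                basename(files))
    }
    report <- list(
      provenance = list(
        package = "rotamerph",
        version = as.character(utils::packageVersion("rotamerph")),
        mode = mode, threshold_ph = threshold_ph, cutoff = cutoff,
        mirror = mirror, input_md5 = as.list(inputs)
      ),
      counts = as.list(survey$counts),
      concordance = as.list(table(survey$concordance$concordance,
                                  useNA = "no")),
      missing = survey$missing,
      association = list(
        p_value = assoc$p_value, odds_ratio = assoc$odds_ratio,
        threshold_ph = assoc$threshold, table = assoc$table,
        degenerate = assoc$degenerate,
        excluded = as.list(assoc$excluded)
      )
    )
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(survey = survey, association = assoc,
                 status = if (survey$partial) 3L else 0L))
}

#' Superpose one complex onto another over matched C-alpha atoms
#'
#' C-alpha atoms are paired by (chain, residue number) intersection after
#' mapping mobile chains through `chain_map`; the compared structures are
#' assumed to share author numbering (no sequence alignment is attempted).
#'
#' @param reference,mobile `structure_model`s or coordinate-file paths.
#' @param chain_map Named character vector mapping mobile chain IDs to
#'   reference chain IDs (default: identity).
#' @param min_pairs Minimum matched pairs (default 3).
#' @return A `superposition` (rotation, translation, `rmsd`, `n_pairs`).
#' @export
run_superposition <- function(reference, mobile, chain_map = NULL,
                              min_pairs = 3) {
  as_model <- function(x) {
    if (inherits(x, "structure_model")) x else read_structure(x)
  }
  ref <- as_model(reference)
  mob <- as_model(mobile)
  ca <- function(m) {
    a <- m$atoms
    a <- a[a$record_type == "ATOM" & a$atom_name == "CA" &
             a$altloc %in% c("", "A"), , drop = FALSE]
    a[!duplicated(a[, c("chain_id", "residue_number")]), , drop = FALSE]
  }
  ra <- ca(ref)
  ma <- ca(mob)
  if (!is.null(chain_map)) {
    mapped <- chain_map[ma$chain_id]
    keep <- !is.na(mapped)
    ma <- ma[keep, , drop = FALSE]
    ma$chain_id <- unname(mapped[keep])
  }
  key <- function(a) paste(a$chain_id, a$residue_number)
  common <- intersect(key(ra), key(ma))
  if (length(common) < min_pairs) {
    stop("only ", length(common), " matched C-alpha pairs; need >= ",
         min_pairs)
  }
  ri <- match(common, key(ra))
  mi <- match(common, key(ma))
  kabsch_superpose(as.matrix(ra[ri, c("x", "y", "z")]),
                   as.matrix(ma[mi, c("x", "y", "z")]))
}
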