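# Coordinate-file I/O and crystallization metadata.
#
# Coordinate parsing for both PDB and mmCIF is delegated to bio3d
# (read.pdb / read.cif with rm.alt = FALSE so alternate conformers are
# preserved); the atom table is normalised into a tidy tibble. Header
# metadata (REMARK 280 pH, _exptl_crystal_grow, space group) is not exposed
# by bio3d and is scanned from the raw text here.

#' Read a PDB or mmCIF coordinate file into a structure model
#'
#' All ATOM and HETATM records are kept, including waters, sulfate (SO4) and
#' glycerol (GOL) heteroatoms, and alternate-location conformers. For
#' multi-model files only the requested model is represented.
#'
#' @param path Path to a coordinate file.
#' @param format `"auto"` (from the file extension), `"pdb"` or `"mmcif"`.
#' @param model Model number to load (default 1, the first).
#' @return Object of class `structure_model`: list with
#'   * `atoms`: tibble with one row per atom (`record_type`, `atom_name`,
#'     `altloc`, `residue_name`, `chain_id`, `residue_number`,
#'     `insertion_code`, `x`, `y`, `z`, `occupancy`, `b_factor`, `element`,
#'     `model_number`);
#'   * `metadata`: crystal metadata (`pdb_id`, `crystallization_ph`,
#'     `ph_range`, `mother_liquor`, `space_group`);
#'   * `path`, `format`, `model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"), model = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      pdb = , ent = "pdb",
      cif = , mmcif = "pdb_or_cif_by_ext_cif",
      stop("cannot infer format from extension '", ext,
           "'; pass format = 'pdb' or 'mmcif'")
    )
    if (format == "pdb_or_cif_by_ext_cif") format <- "mmcif"
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, multi = model > 1, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, multi = model > 1,
                                       verbose = FALSE))
    },
    error = function(e) stop("parse error in ", basename(path), " [", format,
                             "]: ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  xyz <- at[, c("x", "y", "z")]
  if (model > 1) {
    if (nrow(parsed$xyz) < model) {
      stop("model ", model, " not present in ", basename(path),
           " (", nrow(parsed$xyz), " models)")
    }
    m <- matrix(parsed$xyz[model, ], ncol = 3, byrow = TRUE)
    xyz <- stats::setNames(as.data.frame(m), c("x", "y", "z"))
  }
  atoms <- tibble::tibble(
    record_type = at$type,
    atom_name = at$elety,
    altloc = dplyr::coalesce(at$alt, ""),
    residue_name = at$resid,
    chain_id = dplyr::coalesce(at$chain, ""),
    residue_number = as.integer(at$resno),
    insertion_code = dplyr::coalesce(at$insert, ""),
    x = xyz$x, y = xyz$y, z = xyz$z,
    occupancy = dplyr::coalesce(as.numeric(at$o), 1),
    b_factor = dplyr::coalesce(as.numeric(at$b), 0),
    element = dplyr::coalesce(at$elesy, ""),
    model_number = as.integer(model)
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", basename(path))
  }
  meta <- extract_crystal_ph(path, format = format)
  structure(
    list(atoms = atoms, metadata = meta, path = path, format = format,
         model = as.integer(model)),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %s: %d atoms, %d chain(s)%s\n",
    x$metadata$pdb_id, nrow(x$atoms),
    length(unique(x$atoms$chain_id)),
    if (is.na(x$metadata$crystallization_ph)) ""
    else sprintf(", crystallization pH %.2f", x$metadata$crystallization_ph)
  ))
  invisible(x)
}

#' Extract crystallization metadata (pH, mother liquor, space group)
#'
#' For PDB files the REMARK 280 free text is scanned for a pH token; for
#' mmCIF the `_exptl_crystal_grow` category is read. A pH range is reduced
#' to its midpoint with the range recorded separately. When no parseable pH
#' is present the value is `NA` (missing) -- never a guess -- and malformed
#' numeric tokens yield `NA` with a warning.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"` or `"mmcif"`.
#' @return List: `pdb_id`, `crystallization_ph` (numeric or NA),
#'   `ph_range` (text like `"7.6-8.6"` or NA), `mother_liquor` (text or NA),
#'   `space_group` (text or NA).
#' @export
extract_crystal_ph <- function(path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  pdb_id <- toupper(tools::file_path_sans_ext(basename(path)))
  ph <- NA_real_; ph_range <- NA_character_
  liquor <- NA_character_; sg <- NA_character_

  if (format == "pdb") {
    hdr <- grep("^HEADER", lines, value = TRUE)
    if (length(hdr) > 0 && nchar(hdr[1]) >= 66) {
      id <- trimws(substr(hdr[1], 63, 66))
      if (nchar(id) == 4) pdb_id <- toupper(id)
    }
    r280 <- grep("^REMARK 280", lines, value = TRUE)
    if (length(r280) > 0) {
      txt <- paste(trimws(sub("^REMARK 280", "", r280)), collapse = " ")
      txt <- trimws(txt)
      if (nzchar(txt)) liquor <- txt
      tok <- regmatches(
        txt,
        regexpr("\\bPH\\s*[:=]?\\s*[0-9]{1,2}(\\.[0-9]+)?(\\s*-\\s*[0-9]{1,2}(\\.[0-9]+)?)?",
                txt, ignore.case = TRUE, perl = TRUE)
      )
      if (length(tok) == 1) {
        nums <- as.numeric(regmatches(
          tok, gregexpr("[0-9]{1,2}(\\.[0-9]+)?", tok))[[1]])
        parsed <- parse_ph_numbers(nums, pdb_id)
        ph <- parsed$ph; ph_range <- parsed$range
      }
    }
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr) > 0 && nchar(cr[1]) >= 66) {
      sg0 <- trimws(substr(cr[1], 56, 66))
      if (nzchar(sg0)) sg <- sg0
    }
  } else {
    val <- function(key) {
      hit <- grep(paste0("^\\s*", key, "\\s"), lines, value = TRUE)
      if (length(hit) == 0) return(NA_character_)
      v <- trimws(sub(paste0("^\\s*", key, "\\s+"), "", hit[1]))
      v <- gsub("^['\"]|['\"]$", "", v)
      if (v %in% c("?", ".", "")) NA_character_ else v
    }
    id <- grep("^data_", lines, value = TRUE)
    if (length(id) > 0) pdb_id <- toupper(sub("^data_", "", id[1]))
    raw <- val("_exptl_crystal_grow\\.pH")
    rng <- val("_exptl_crystal_grow\\.pdbx_pH_range")
    liquor <- val("_exptl_crystal_grow\\.pdbx_details")
    sg <- val("_symmetry\\.space_group_name_H-M")
    nums <- numeric()
    if (!is.na(raw)) {
      v <- suppressWarnings(as.numeric(raw))
      if (is.na(v)) warning("malformed pH token '", raw, "' in ", pdb_id)
      else nums <- v
    }
    if (length(nums) == 0 && !is.na(rng)) {
      nums <- suppressWarnings(as.numeric(
        regmatches(rng, gregexpr("[0-9]+(\\.[0-9]+)?", rng))[[1]]))
    }
    if (length(nums) > 0) {
      parsed <- parse_ph_numbers(nums, pdb_id)
      ph <- parsed$ph; ph_range <- parsed$range
    }
  }
  list(pdb_id = pdb_id, crystallization_ph = ph, ph_range = ph_range,
       mother_liquor = liquor, space_group = sg)
}

# Reduce the numeric tokens of a pH field to a single value: a lone number is
# taken as-is, two numbers as a range -> midpoint (range kept). Values
# outside [0, 14] are rejected as missing, with a warning.
parse_ph_numbers <- function(nums, id) {
  nums <- nums[!is.na(nums)]
  if (length(nums) == 0) return(list(ph = NA_real_, range = NA_character_))
  if (any(nums < 0 | nums > 14)) {
    warning("pH token outside [0, 14] in ", id, "; treating as missing")
    return(list(ph = NA_real_, range = NA_character_))
  }
  if (length(nums) >= 2) {
    list(ph = mean(nums[1:2]),
         range = sprintf("%g-%g", nums[1], nums[2]))
  } else {
    list(ph = nums[1], range = NA_character_)
  }
}

#' Select one residue from a structure model
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param resno Author residue number.
#' @param insert Insertion code (default blank).
#' @param require_resname If non-NULL (e.g. `"HIS"`), error unless the
#'   selected residue has this name.
#' @return Atom tibble for the residue (all altloc groups).
#' @export
select_residue <- function(model, chain, resno, insert = "",
                           require_resname = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  res <- at[at$chain_id == chain & at$residue_number == resno &
              at$insertion_code == insert & at$record_type == "ATOM", ,
            drop = FALSE]
  if (nrow(res) == 0) {
    stop("residue ", chain, "/", resno,
         " not found; available chains: ",
         paste(sort(unique(at$chain_id)), collapse = ", "))
  }
  if (!is.null(require_resname) && !all(res$residue_name == require_resname)) {
    stop("residue ", chain, "/", resno, " is ",
         unique(res$residue_name)[1], ", expected ", require_resname)
  }
  res
}

#' Write a minimal PDB fixture file
#'
#' Emits REMARK 280 (crystallization pH), ATOM/HETATM records and END. The
#' output round-trips through [read_structure()]: coordinates to 1e-3 A
#' (the PDB fixed-point format), altloc and occupancy fields exactly.
#'
#' @param atoms Atom tibble (columns as in a `structure_model`).
#' @param path Output path.
#' @param ph Crystallization pH to record, or NULL.
#' @param ph_range Optional pH range string (e.g. `"7.6-8.6"`); written as a
#'   textual range so the reader recovers the midpoint.
#' @param details Optional extra REMARK 280 free text (mother liquor).
#' @return `path`, invisibly.
#' @export
write_pdb_fixture <- function(atoms, path, ph = NULL, ph_range = NULL,
                              details = NULL) {
  lines <- character()
  txt <- "REMARK 280 CRYSTALLIZATION CONDITIONS:"
  if (!is.null(details)) txt <- paste(txt, toupper(details))
  if (!is.null(ph_range)) {
    txt <- paste0(txt, " PH ", ph_range)
  } else if (!is.null(ph)) {
    txt <- paste0(txt, sprintf(" PH %.2f", ph))
  }
  lines <- c(lines, strwrap(txt, width = 68, prefix = "REMARK 280 ",
                            initial = ""))
  fmt_name <- function(n) {
    # names shorter than 4 chars start in column 14 by PDB convention
    if (nchar(n) < 4) formatC(paste0(" ", n), width = -4) else substr(n, 1, 4)
  }
  serial <- seq_len(nrow(atoms))
  recs <- vapply(seq_len(nrow(atoms)), function(i) {
    a <- atoms[i, ]
    sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            a$record_type, serial[i] %% 100000L, fmt_name(a$atom_name),
            ifelse(a$altloc == "", " ", a$altloc), a$residue_name,
            a$chain_id, a$residue_number,
            ifelse(a$insertion_code == "", " ", a$insertion_code),
            a$x, a$y, a$z, a$occupancy, a$b_factor,
            formatC(a$element, width = 2))
  }, character(1))
  writeLines(c(lines, recs, "END"), path)
  invisible(path)
}
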