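#' Atomic coordinate model
#'
#' A light container for atomic coordinates: a data frame with columns
#' \code{chain}, \code{resno}, \code{insert}, \code{resid}, \code{elety}
#' (atom name), \code{elesy} (element symbol), \code{x}, \code{y}, \code{z}
#' (angstrom) and \code{weight}.
#'
#' @param atoms data frame with the columns above (\code{insert} and
#'   \code{weight} optional; insert defaults to \code{""}, weight to the
#'   atomic mass of the element, or 1 if unknown).
#' @return An object of class \code{atomic_model}.
#' @export
atomic_model <- function(atoms) {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("missing atom columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom positions must be finite")
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$weight)) atoms$weight <- element_mass(atoms$elesy)
  structure(list(atoms = atoms), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("atomic_model: %d atoms, %d chain(s) [%s]\n", nrow(a),
              length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ", ")))
  invisible(x)
}

# atomic masses for common protein/nucleic elements; unknown -> 1
element_mass <- function(elesy) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
         P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305)
  out <- m[toupper(trimws(elesy))]
  out[is.na(out)] <- 1
  unname(out)
}

# Bondi van der Waals radii (angstrom); used for SASA
element_vdw <- function(elesy) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         SE = 1.90, FE = 1.80, ZN = 1.39, MG = 1.73)
  out <- r[toupper(trimws(elesy))]
  out[is.na(out)] <- 1.70
  unname(out)
}

#' Read an atomic structure from PDB or mmCIF
#'
#' Loads all ATOM/HETATM records. Alternate locations are resolved to the
#' highest-occupancy conformer, waters are excluded by default, and for
#' multi-model (NMR-style) files the first model is used with a notice.
#'
#' @param path path to a \code{.pdb} or \code{.cif} file.
#' @param keep_waters keep HOH/WAT residues (default \code{FALSE}).
#' @return An \code{atomic_model}.
#' @export
read_structure <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    # bio3d's mmCIF reader warns about its beta status and about secondary
    # structure records we do not consume
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
  } else {
    bio3d::read.pdb(path, verbose = FALSE, multi = TRUE, rm.alt = FALSE)
  }
  xyz <- pdb$xyz
  if (is.matrix(xyz) && nrow(xyz) > 1) {
    message("multi-model file; using the first model: ", basename(path))
  }
  a <- pdb$atom
  if (!keep_waters) a <- a[!(a$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms parsed from ", path)
  # resolve altlocs: keep highest occupancy per (chain, resno, insert, elety)
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  if (any(nzchar(alt) & alt != "A") || anyDuplicated(
      paste(a$chain, a$resno, a$insert, a$elety))) {
    key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
                 a$elety, sep = "\r")
    ord <- order(key, -occ)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(!nzchar(trimws(elesy)))) {
    elesy <- substr(trimws(a$elety), 1, 1)
  }
  chain <- a$chain
  chain[is.na(chain)] <- "A"
  atomic_model(data.frame(
    chain = chain, resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid, elety = a$elety, elesy = elesy,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Write an atomic model as PDB
#' @param model an \code{atomic_model}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resid,
                   elety = a$elety, elesy = a$elesy)
  invisible(path)
}

#' Write an atomic model as a minimal mmCIF
#'
#' Emits a single \code{atom_site} loop sufficient for round-tripping through
#' standard mmCIF readers (the reading side uses bio3d).
#' @param model an \code{atomic_model}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_structure_cif <- function(model, path) {
  a <- model$atoms
  lines <- c(
    "data_model",
    "#",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
            seq_len(nrow(a)), a$elesy, a$elety, a$resid, a$chain, a$resno,
            ifelse(nzchar(a$insert), a$insert, "?"), a$x, a$y, a$z,
            a$resno, a$resid, a$chain, a$elety),
    "#")
  writeLines(lines, path)
  invisible(path)
}

#' Apply a rigid transform to an atomic model
#' @param model an \code{atomic_model}.
#' @param tr a \code{rigid_transform}.
#' @return The transformed \code{atomic_model}.
#' @export
apply_transform <- function(model, tr) {
  a <- model$atoms
  xyz <- transform_points(tr, as.matrix(a[, c("x", "y", "z")]))
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  atomic_model(a)
}

#' Atom coordinates as a matrix
#' @param model an \code{atomic_model}.
#' @param calpha_only keep only CA atoms.
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model, calpha_only = FALSE) {
  a <- model$atoms
  if (calpha_only) a <- a[trimws(a$elety) == "CA", , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# weighted centroid
model_centroid <- function(model) {
  a <- model$atoms
  w <- a$weight / sum(a$weight)
  c(sum(a$x * w), sum(a$y * w), sum(a$z * w))
}

#' C-alpha RMSD between two placements of the same model
#' @param model an \code{atomic_model}.
#' @param t1,t2 \code{rigid_transform}s.
#' @return RMSD in angstrom.
#' @export
placement_rmsd <- function(model, t1, t2) {
  p <- coords(model, calpha_only = TRUE)
  if (nrow(p) == 0) p <- coords(model)
  sqrt(mean(rowSums((transform_points(t1, p) - transform_points(t2, p))^2)))
}

#' Residue-interval selection
#'
#' A chain id plus a list of inclusive residue-number intervals.
#' @param chain chain identifier.
#' @param intervals numeric vector \code{c(from1, to1, from2, to2, ...)} or
#'   2-column matrix of inclusive bounds.
#' @return An object of class \code{residue_selection}.
#' @export
residue_selection <- function(chain, intervals) {
  if (is.matrix(intervals)) iv <- intervals
  else iv <- matrix(as.numeric(intervals), ncol = 2, byrow = TRUE)
  if (nrow(iv) == 0 || any(iv[, 2] < iv[, 1]))
    stop("intervals must be non-empty with from <= to")
  structure(list(chain = as.character(chain), intervals = iv),
            class = "residue_selection")
}

#' Parse a selection string like "C:566-592,600-610"
#' @param text selection string \code{"<chain>:<from>-<to>[,<from>-<to>...]"}.
#' @return A \code{residue_selection}.
#' @export
parse_selection <- function(text) {
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("selection must be '<chain>:<from>-<to>,...'")
  rng <- do.call(rbind, lapply(strsplit(parts[2], ",")[[1]], function(s) {
    ab <- as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])
    if (length(ab) == 1) ab <- c(ab, ab)
    ab
  }))
  residue_selection(parts[1], rng)
}

# logical index of model atoms inside a selection
selection_index <- function(model, sel) {
  a <- model$atoms
  inside <- a$chain == sel$chain &
    Reduce(`|`, lapply(seq_len(nrow(sel$intervals)), function(i)
      a$resno >= sel$intervals[i, 1] & a$resno <= sel$intervals[i, 2]))
  inside
}

#' Subset a model by selection
#' @param model an \code{atomic_model}.
#' @param sel a \code{residue_selection}.
#' @return An \code{atomic_model} with the selected atoms.
#' @export
select_atoms <- function(model, sel) {
  a <- model$atoms[selection_index(model, sel), , drop = FALSE]
  if (nrow(a) == 0) stop("selection matches no atoms")
  atomic_model(a)
}
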