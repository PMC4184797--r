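# Ensemble data model and multi-model PDB I/O.
#
# A "model" is a data.frame with one row per atom:
#   resno   residue number (mature-protein numbering)
#   resname three-letter residue code
#   atom    atom label ("CA", "CD1", ...)
#   element chemical element symbol ("C", "N", "O", "S", "H", ...)
#   x, y, z coordinates in Angstrom
# An ensemble is an ordered list of topologically identical models.

#' Construct a single-conformer structural model
#'
#' @param resno integer residue numbers (non-decreasing; atoms of a residue
#'   are contiguous).
#' @param resname three-letter residue codes, one per atom.
#' @param atom atom labels, one per atom.
#' @param element element symbols, one per atom.
#' @param xyz numeric matrix (n x 3) of coordinates in Angstrom.
#' @return a `data.frame` of class `"structure_model"`.
#' @export
structure_model <- function(resno, resname, atom, element, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(resno),
            length(resname) == length(resno), length(atom) == length(resno),
            length(element) == length(resno))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (any(!nzchar(atom))) stop("empty atom name")
  m <- data.frame(resno = as.integer(resno), resname = as.character(resname),
                  atom = as.character(atom), element = as.character(element),
                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                  stringsAsFactors = FALSE)
  if (is.unsorted(m$resno)) stop("residue numbers must be non-decreasing")
  key <- paste(m$resno, m$atom)
  if (anyDuplicated(key)) stop("duplicate atom within a residue: ",
                               key[duplicated(key)][1])
  class(m) <- c("structure_model", "data.frame")
  m
}

#' Construct a structure ensemble
#'
#' @param models list of [structure_model()] objects sharing an identical
#'   residue/atom topology.
#' @param id free-text label (e.g. an accession).
#' @return object of class `"structure_ensemble"`.
#' @export
structure_ensemble <- function(models, id = "") {
  if (length(models) < 1) stop("ensemble must contain at least one model")
  ref <- models[[1]]
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (nrow(m) != nrow(ref) ||
        !identical(m$resno, ref$resno) || !identical(m$atom, ref$atom)) {
      stop("model ", i, " does not share the topology of model 1")
    }
  }
  structure(list(models = models, id = id), class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  m <- x$models[[1]]
  cat("Structure ensemble", if (nzchar(x$id)) paste0("'", x$id, "'"), "\n")
  cat("  models:  ", length(x$models), "\n")
  cat("  residues:", length(unique(m$resno)), "\n")
  cat("  atoms:   ", nrow(m), "\n")
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$models)

#' Number of models in an ensemble
#' @param ensemble a [structure_ensemble()].
#' @return integer count.
#' @export
n_models <- function(ensemble) length(ensemble$models)

#' Coordinates of a model as an n x 3 matrix
#' @param model a structure model.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(model) as.matrix(model[, c("x", "y", "z")])

`coords<-` <- function(model, value) {
  model$x <- value[, 1]; model$y <- value[, 2]; model$z <- value[, 3]
  model
}

# validate per-MODEL atom counts before handing the file to the reader so a
# topology mismatch is reported as such, not as a matrix-shape failure
.check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) < 2) return(invisible(TRUE))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("malformed PDB '", path,
    "': MODEL/ENDMDL records unbalanced")
  counts <- mapply(function(s, e)
    sum(grepl("^ATOM  |^HETATM", lines[s:e])), starts, ends)
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop("topology mismatch: MODEL ", bad, " has ", counts[bad],
         " atoms but MODEL 1 has ", counts[1])
  }
  invisible(TRUE)
}

#' Read a multi-model PDB file into a structure ensemble
#'
#' Reads every MODEL of a PDB file (a MODEL-less file yields a one-model
#' ensemble). By default only the first chain is kept; where alternate
#' locations are present the highest-occupancy atom is retained. Hydrogens
#' are kept on read but excluded from the default atom selections used in
#' downstream geometry. Files with insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param offset integer added to deposited residue numbers so that internal
#'   numbering matches mature-protein numbering (default 0).
#' @param id label stored on the ensemble (default: file base name).
#' @return a [structure_ensemble()].
#' @export
read_ensemble <- function(path, offset = 0L, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .check_model_atom_counts(path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported (file '", path, "')")
  keep <- rep(TRUE, nrow(at))
  # first chain only (NA chain counts as a chain label)
  ch <- at$chain; ch[is.na(ch)] <- ""
  keep <- keep & ch == ch[1]
  # alternate locations: keep highest occupancy per (resno, atom)
  alt <- at$alt; alt[is.na(alt)] <- ""
  if (any(nzchar(alt) & alt != "A")) {
    occ <- at$o; occ[is.na(occ)] <- 1
    key <- paste(at$resno, at$elety)
    ord <- order(key, -occ)
    dupe <- duplicated(key[ord])
    drop <- ord[dupe]
    keep[drop] <- FALSE
  }
  idx <- which(keep)
  ele <- at$elesy[idx]
  if (any(is.na(ele) | !nzchar(ele))) {
    guess <- bio3d::atom2ele(at$elety[idx])
    bad <- is.na(ele) | !nzchar(ele)
    ele[bad] <- guess[bad]
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  models <- lapply(seq_len(nrow(xyz)), function(m) {
    xm <- matrix(xyz[m, cols], ncol = 3, byrow = TRUE)
    structure_model(resno = at$resno[idx] + as.integer(offset),
                    resname = at$resid[idx], atom = at$elety[idx],
                    element = ele, xyz = xm)
  })
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  structure_ensemble(models, id = id)
}

#' Write a structure ensemble as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per model with fixed-width ATOM records.
#'
#' @param ensemble a [structure_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  m1 <- ensemble$models[[1]]
  xyz <- do.call(rbind, lapply(ensemble$models,
                               function(m) as.vector(t(coords(m)))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = m1$resno, resid = m1$resname,
                   eleno = seq_len(nrow(m1)), elety = m1$atom,
                   chain = rep("A", nrow(m1)), elesy = m1$element)
  invisible(path)
}

# ---- atom selection -------------------------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Select atoms of a model by residue range and atom class
#'
#' @param model a structure model.
#' @param resno residue numbers to keep (`NULL` = all).
#' @param atoms `"backbone"` (N, CA, C, O), `"heavy"` (all non-hydrogen),
#'   `"all"`, or a character vector of atom labels.
#' @return integer row indices into `model`.
#' @export
select_atoms <- function(model, resno = NULL, atoms = "backbone") {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (length(atoms) == 1 && atoms %in% c("backbone", "heavy", "all")) {
    keep <- keep & switch(atoms,
      backbone = model$atom %in% BACKBONE_ATOMS,
      heavy    = toupper(model$element) != "H",
      all      = TRUE)
  } else {
    keep <- keep & model$atom %in% atoms
  }
  which(keep)
}

#' Pick the model closest to the ensemble mean
#'
#' Superposes all models onto their iteratively refined coordinate mean and
#' returns the (1-based) index of the model with the lowest RMSD to that
#' mean; ties break toward the lowest index. This is the "most
#' representative structure" used for single-model measurements.
#'
#' @inheritParams select_atoms
#' @param ensemble a [structure_ensemble()].
#' @return integer model index.
#' @export
representative_model <- function(ensemble, resno = NULL, atoms = "backbone") {
  if (length(select_atoms(ensemble$models[[1]], resno, atoms)) == 0)
    stop("selection matches no atoms")
  if (n_models(ensemble) == 1) return(1L)
  r <- ensemble_rmsd_to_mean(ensemble, resno = resno, atoms = atoms)
  which.min(r$per_model)
}
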