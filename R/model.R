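#' Atomic coordinate model
#'
#' A flat table of atoms on a P1 cell. Coordinates are Cartesian Angstrom.
#' Every atom carries a `(resi, atom)` label pair that must be unique; masks
#' and rotation axes refer to atoms through these labels.
#'
#' @param atoms A data.frame with columns `element`, `resi` (integer),
#'   `resn` (residue name), `atom` (atom name), `x`, `y`, `z` (Cartesian
#'   Angstrom), `occ` (occupancy in \[0,1\]), `b` (isotropic B-factor,
#'   Angstrom^2).
#' @param cell A [unit_cell()].
#' @return An object of class `atom_model`.
#' @export
atom_model <- function(atoms, cell) {
  stopifnot(inherits(cell, "unit_cell"), is.data.frame(atoms))
  need <- c("element", "resi", "resn", "atom", "x", "y", "z", "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0,1]")
  if (any(atoms$b < 0)) stop("B-factors must be >= 0")
  lab <- paste(atoms$resi, atoms$atom)
  if (anyDuplicated(lab)) stop("duplicate (resi, atom) labels: ",
                               paste(unique(lab[duplicated(lab)]), collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell), class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("<atom_model> %d atoms, %d residues\n",
              nrow(x$atoms), length(unique(x$atoms$resi))))
  print(x$cell)
  invisible(x)
}

#' Atom labels of a model
#' @param model An `atom_model`.
#' @return Character vector `"<resi> <atom>"`, one per atom.
#' @export
atom_labels <- function(model) paste(model$atoms$resi, model$atoms$atom)

#' Fractional coordinates of a model's atoms
#' @param model An `atom_model`.
#' @return Matrix with one row per atom, columns along a, b, c.
#' @export
frac_coords <- function(model) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz %*% t(cell_frac_matrix(model$cell))
}

#' Select atom indices by a small selection grammar
#'
#' The grammar mirrors common molecular-viewer syntax:
#' `"resi 2"`, `"resi 2-4"`, `"name CB,CG"`, and conjunctions with `and`,
#' e.g. `"resi 2 and name CG,OD1,ND2"`. Matching is case-insensitive for
#' atom names.
#'
#' @param model An `atom_model`.
#' @param selection Selection string, or a character vector of
#'   `"<resi> <atom>"` labels.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(model, selection) {
  at <- model$atoms
  if (length(selection) > 1 || grepl("^[0-9]+ ", selection[1])) {
    idx <- match(selection, atom_labels(model))
    if (anyNA(idx)) stop("unknown atom labels: ",
                         paste(selection[is.na(idx)], collapse = ", "))
    return(idx)
  }
  keep <- rep(TRUE, nrow(at))
  for (clause in strsplit(selection, "\\s+and\\s+")[[1]]) {
    clause <- trimws(clause)
    if (grepl("^resi\\s+", clause)) {
      spec <- sub("^resi\\s+", "", clause)
      resis <- integer(0)
      for (part in strsplit(spec, ",")[[1]]) {
        if (grepl("-", part)) {
          rng <- as.integer(strsplit(part, "-")[[1]])
          resis <- c(resis, seq(rng[1], rng[2]))
        } else resis <- c(resis, as.integer(part))
      }
      keep <- keep & at$resi %in% resis
    } else if (grepl("^name\\s+", clause)) {
      nms <- toupper(trimws(strsplit(sub("^name\\s+", "", clause), ",")[[1]]))
      keep <- keep & toupper(at$atom) %in% nms
    } else stop("cannot parse selection clause: '", clause, "'")
  }
  which(keep)
}

#' Read a coordinate model from a PDB file
#'
#' Parses CRYST1 plus ATOM/HETATM records (fixed-width columns).
#'
#' @param path Path to a PDB file.
#' @return An `atom_model`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  cr <- lines[startsWith(lines, "CRYST1")]
  if (!length(cr)) stop("PDB file lacks a CRYST1 record: ", path)
  cv <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                     substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                     substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  cell <- unit_cell(cv[1], cv[2], cv[3], cv[4], cv[5], cv[6])
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop("no ATOM/HETATM records in ", path)
  atoms <- data.frame(
    element = trimws(substr(rec, 77, 78)),
    resi = as.integer(substr(rec, 23, 26)),
    resn = trimws(substr(rec, 18, 20)),
    atom = trimws(substr(rec, 13, 16)),
    x = as.numeric(substr(rec, 31, 38)),
    y = as.numeric(substr(rec, 39, 46)),
    z = as.numeric(substr(rec, 47, 54)),
    occ = as.numeric(substr(rec, 55, 60)),
    b = as.numeric(substr(rec, 61, 66)),
    stringsAsFactors = FALSE)
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- substr(atoms$atom[blank], 1, 1)
  atom_model(atoms, cell)
}

#' Write a coordinate model to a PDB file
#' @param model An `atom_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  cl <- model$cell
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                 cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma)
  at <- model$atoms
  for (i in seq_len(nrow(at))) {
    nm <- at$atom[i]
    nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
    out <- c(out, sprintf(
      "ATOM  %5d %4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, nm_fmt, at$resn[i], at$resi[i], at$x[i], at$y[i], at$z[i],
      at$occ[i], at$b[i], toupper(at$element[i])))
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
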