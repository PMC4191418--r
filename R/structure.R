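## Atomistic nucleic-acid data model and PDB I/O.
##
## A `dna_structure` is an ordered atom table plus one or more coordinate
## frames (an ensemble).  PDB reading/writing is delegated to bio3d; the
## class itself stays a plain list so downstream code can index cheaply.

.allowed_elements <- c("C", "N", "O", "P", "H")

#' Construct a DNA structure (single- or multi-frame)
#'
#' @param atoms data frame with columns `name` (PDB atom name), `element`,
#'   `resno` (1-based residue number), `resname` (e.g. `"DA"`), `chain`.
#' @param xyz coordinates in Angstrom: an `n_atoms x 3` matrix for a single
#'   frame, or an `n_atoms x 3 x n_frames` array for an ensemble.
#' @return object of class `dna_structure`.
#' @export
dna_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "resno", "resname", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3, 1))
  if (length(dim(xyz)) != 3 || dim(xyz)[2] != 3)
    stop("xyz must be n_atoms x 3 (x n_frames)")
  if (dim(xyz)[1] != nrow(atoms))
    stop("coordinate rows (", dim(xyz)[1], ") do not match atom count (",
         nrow(atoms), ")")
  bad <- !atoms$element %in% .allowed_elements
  if (any(bad))
    stop("unsupported element(s): ", paste(unique(atoms$element[bad]),
                                           collapse = ", "))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "dna_structure")
}

#' Number of frames in a structure ensemble
#' @param x a `dna_structure`.
#' @return integer frame count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "dna_structure"))
  dim(x$xyz)[3]
}

#' Coordinates of one frame
#' @param x a `dna_structure`.
#' @param frame frame index (default 1).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(x, frame = 1) {
  stopifnot(inherits(x, "dna_structure"))
  if (frame < 1 || frame > n_frames(x)) stop("frame index out of range")
  m <- x$xyz[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Replace coordinates of one frame
#' @keywords internal
#' @noRd
set_frame_coords <- function(x, frame, coords) {
  x$xyz[, , frame] <- coords
  x
}

#' Row indices of atoms matching residue/name filters
#'
#' @param x a `dna_structure`.
#' @param resno residue numbers to keep (NULL = all).
#' @param name atom names to keep (NULL = all).
#' @param chain chain ids to keep (NULL = all).
#' @return integer vector of atom row indices.
#' @export
atom_indices <- function(x, resno = NULL, name = NULL, chain = NULL) {
  keep <- rep(TRUE, nrow(x$atoms))
  if (!is.null(resno)) keep <- keep & x$atoms$resno %in% resno
  if (!is.null(name)) keep <- keep & x$atoms$name %in% name
  if (!is.null(chain)) keep <- keep & x$atoms$chain %in% chain
  which(keep)
}

#' @export
print.dna_structure <- function(x, ...) {
  cat(sprintf("<dna_structure> %d atoms, %d residue(s), %d frame(s)\n",
              nrow(x$atoms), length(unique(x$atoms$resno)), n_frames(x)))
  cat("  chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## PDB I/O (bio3d-backed)

#' Read a PDB file into a `dna_structure`
#'
#' Multi-MODEL files become multi-frame ensembles.  Atom order and 1-based
#' residue numbering are preserved as in the file.
#'
#' @param path PDB file path.
#' @param model_policy `"all"` (default) keeps every MODEL as a frame;
#'   `"first"` keeps only the first.
#' @return a `dna_structure`.
#' @export
read_structure <- function(path, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM/HETATM record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords))
      stop("malformed ATOM/HETATM record at line ", i,
           ": unparseable coordinates")
  }
  ## consistency of MODEL blocks: identical atom counts and names
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    blocks <- split(which(is_atom),
                    findInterval(which(is_atom), model_starts))
    sig <- vapply(blocks, function(ix)
      paste(substr(lines[ix], 13, 27), collapse = "|"), "")
    if (length(unique(sig)) != 1)
      stop("inconsistent MODEL blocks: atom records differ between models")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nfr <- nrow(pdb$xyz)
  if (model_policy == "first") nfr <- 1
  nat <- nrow(pdb$atom)
  xyz <- array(NA_real_, dim = c(nat, 3, nfr))
  for (f in seq_len(nfr))
    xyz[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
  elem <- pdb$atom$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(pdb$atom$elety), 1, 1)
  elem <- trimws(elem)
  elem[elem == ""] <- substr(trimws(pdb$atom$elety), 1, 1)[elem == ""]
  atoms <- data.frame(
    name = trimws(pdb$atom$elety),
    element = elem,
    resno = pdb$atom$resno,
    resname = trimws(pdb$atom$resid),
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    stringsAsFactors = FALSE
  )
  dna_structure(atoms, xyz)
}

#' Write a `dna_structure` to a PDB file
#'
#' Multi-frame ensembles are written as MODEL/ENDMDL blocks.  Coordinates
#' are fixed-width `%8.3f`; values that do not fit raise an error.
#'
#' @param x a `dna_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "dna_structure"))
  if (any(abs(x$xyz) >= 10000) || any(x$xyz <= -1000))
    stop("coordinate exceeds the PDB fixed-width field (%8.3f)")
  nfr <- n_frames(x)
  xyz <- t(apply(x$xyz, 3, function(m) as.vector(t(m))))
  if (nfr == 1) xyz <- matrix(xyz, nrow = 1)
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = x$atoms$resno,
                     resid = x$atoms$resname,
                     eleno = seq_len(nrow(x$atoms)),
                     elety = x$atoms$name,
                     chain = x$atoms$chain,
                     elesy = x$atoms$element)
    TRUE
  }, error = function(e) stop("cannot write PDB to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
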