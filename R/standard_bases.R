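## Idealized base geometries in the standard nucleic-acid reference frame.
##
## Heavy-atom coordinates follow the published standard-reference-frame
## convention for nucleic-acid bases (origin at the pair midpoint, x toward
## the major groove, y along the long pair axis, bases in the xy-plane).
## These are the reference geometries that base-frame fitting superposes
## onto observed coordinates, and that the synthetic builder places when
## rebuilding helices from step parameters.
##
## Two additions beyond the published heavy-atom fixture (both flagged
## `synthetic = TRUE`):
##   * H3 of thymine, placed 1.03 A from N3 along the idealized
##     N3 -> N1(partner adenine) hydrogen-bond direction.  It is the SASA
##     reporter atom for pyrimidine opening.
##   * a single pseudo-phosphate P per nucleotide at an idealized B-like
##     position in the base frame (radius ~9 A from the helical axis of a
##     canonical rebuilt B helix).  It supports groove-width and Zp analyses
##     on rebuilt structures; rebuilt helices carry no further backbone.

.base_tables <- local({
  ade <- data.frame(
    name = c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    x = c(-2.479, -1.291, 0.024, 0.877, 0.071, 0.369, 1.611, -0.668, -1.912,
          -2.320, -1.267),
    y = c(5.346, 4.498, 4.897, 3.902, 2.771, 1.398, 0.909, 0.532, 1.023,
          2.290, 3.124),
    z = 0,
    stringsAsFactors = FALSE
  )
  gua <- data.frame(
    name = c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2",
             "N3", "C4"),
    x = c(-2.477, -1.289, 0.023, 0.870, 0.071, 0.424, 1.554, -0.700, -1.999,
          -2.949, -2.342, -1.265),
    y = c(5.399, 4.551, 4.962, 3.969, 2.833, 1.460, 0.955, 0.641, 1.087,
          0.139, 2.364, 3.177),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0, -0.001, 0.001, 0),
    stringsAsFactors = FALSE
  )
  cyt <- data.frame(
    name = c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    x = c(-2.477, -1.285, -1.472, -2.628, -0.391, 0.837, 1.875, 1.056,
          -0.023),
    y = c(5.402, 4.542, 3.158, 2.709, 2.344, 2.868, 2.027, 4.275, 5.068),
    z = c(0, 0, 0, 0.001, 0, 0, 0.001, 0, 0),
    stringsAsFactors = FALSE
  )
  thy <- data.frame(
    name = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6",
             "H3"),
    x = c(-2.481, -1.284, -1.462, -2.562, -0.298, 0.994, 1.944, 1.106,
          2.466, -0.024, -0.169),
    y = c(5.354, 4.500, 3.135, 2.608, 2.407, 2.897, 2.119, 4.338, 4.961,
          5.057, 1.385),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0.001, 0, 0),
    stringsAsFactors = FALSE
  )
  list(A = ade, G = gua, C = cyt, T = thy)
})

.ring_atoms <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.exocyclic_atoms <- list(
  A = "N6",
  G = c("O6", "N2"),
  C = c("O2", "N4"),
  T = c("O2", "O4", "C7")
)

## Pseudo-phosphate position in the base standard frame (synthetic; see top
## comment).  Polar angle ~100 deg, radius 9.0 A, 2.0 A below the base plane
## on the 5' side.
.pseudo_phosphate <- c(-1.5628, 8.8632, -2.0)

#' Standard base geometry in the reference frame
#'
#' Returns the idealized atom set for one base type placed in the standard
#' nucleic-acid reference frame, with ring/exocyclic membership flags.
#'
#' @param base one of `"A"`, `"T"`, `"G"`, `"C"`.
#' @param backbone if `TRUE` (default) include the `C1'` atom and the
#'   synthetic pseudo-phosphate `P`; if `FALSE` return base atoms only.
#' @return data frame with columns `name`, `x`, `y`, `z`, `element`,
#'   `ring`, `exocyclic`, `synthetic`.
#' @examples
#' g <- standard_base_geometry("G")
#' g[g$ring, "name"]
#' @export
standard_base_geometry <- function(base, backbone = TRUE) {
  base <- toupper(base)
  if (!base %in% names(.base_tables))
    stop("unknown base type: ", base)
  tab <- .base_tables[[base]]
  tab$element <- substr(tab$name, 1, 1)
  tab$ring <- tab$name %in% .ring_atoms[[base]]
  tab$exocyclic <- tab$name %in% .exocyclic_atoms[[base]]
  tab$synthetic <- tab$name %in% "H3"
  if (backbone) {
    tab <- rbind(tab, data.frame(
      name = "P", x = .pseudo_phosphate[1], y = .pseudo_phosphate[2],
      z = .pseudo_phosphate[3], element = "P", ring = FALSE,
      exocyclic = FALSE, synthetic = TRUE
    ))
  } else {
    tab <- tab[tab$name != "C1'", , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Is a base type a purine?
#' @param base base letter(s), `"A"/"G"/"C"/"T"`.
#' @return logical vector.
#' @export
is_purine <- function(base) toupper(base) %in% c("A", "G")

#' Watson-Crick complement
#' @param base vector of base letters.
#' @return complementary letters.
#' @export
wc_complement <- function(base) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  out <- comp[toupper(base)]
  if (anyNA(out)) stop("unknown base in sequence")
  unname(out)
}

#' Split a sequence string into base letters
#' @keywords internal
#' @noRd
seq_letters <- function(s) {
  if (length(s) == 1 && nchar(s) > 1) strsplit(s, "")[[1]] else as.character(s)
}

#' PDB residue name for a base letter
#' @keywords internal
#' @noRd
base_resname <- function(base) paste0("D", toupper(base))

#' Base letter from a PDB residue name
#' @keywords internal
#' @noRd
resname_base <- function(resname) {
  b <- sub("^D", "", toupper(resname))
  b <- substr(b, 1, 1)
  if (!all(b %in% c("A", "T", "G", "C")))
    stop("residue name(s) not recognized as DNA bases: ",
         paste(unique(resname[!b %in% c("A", "T", "G", "C")]), collapse = ", "))
  b
}
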