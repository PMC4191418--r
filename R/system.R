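## System definition and pairing/region annotation for duplex and triplex
## helices.
##
## Numbering convention for the bundled 30-mer + 10-mer example system:
## leading strand 1-30 (5'->3'), complementary strand 31-60 (5'->3' of its
## own strand, so Watson-Crick partner of leading residue i is 61 - i), and
## the triplex-forming oligonucleotide (TFO) 61-70.  The TFO runs
## antiparallel to the purine strand and reads on the homo-purine region
## through reverse-Hoogsteen pairs (G-G.C and A-A.T triplets).

#' Define a duplex/triplex system
#'
#' @param duplex_seq leading-strand sequence, 5'->3'.
#' @param tfo_seq optional TFO sequence, 5'->3' (NULL for duplex only).
#' @param tfo_target 1-based range of leading-strand positions the TFO binds
#'   (must be all purines); default covers the central third.
#' @param regions named list of base-pair index ranges (each `c(from, to)`);
#'   defaults to first duplex / homo-purine / second duplex thirds.
#' @return object of class `system_definition`.
#' @export
system_definition <- function(duplex_seq, tfo_seq = NULL, tfo_target = NULL,
                              regions = NULL) {
  lead <- seq_letters(duplex_seq)
  n <- length(lead)
  if (!all(lead %in% c("A", "C", "G", "T")))
    stop("duplex sequence contains non-ACGT letters")
  if (!is.null(tfo_seq)) {
    tfo <- seq_letters(tfo_seq)
    if (is.null(tfo_target)) {
      k <- length(tfo)
      start <- (n - k) %/% 2 + 1
      tfo_target <- seq(start, start + k - 1)
    }
    if (length(tfo_target) != length(tfo))
      stop("tfo_target length must equal TFO length")
    tgt <- lead[tfo_target]
    if (!all(is_purine(tgt)))
      stop("TFO target region is not all-purine on the leading strand: ",
           paste(tfo_target[!is_purine(tgt)], collapse = ", "))
    ## antiparallel register: TFO residue t (5'->3') pairs leading residue
    ## rev(tfo_target)[t]; for purine-motif triplets TFO base == purine base
    mism <- tfo != rev(tgt)
    if (any(mism))
      stop("TFO sequence does not match the purine strand in antiparallel ",
           "register at TFO position(s): ",
           paste(which(mism), collapse = ", "))
  } else {
    tfo <- NULL
    tfo_target <- NULL
  }
  if (is.null(regions)) {
    if (!is.null(tfo_target)) {
      a <- min(tfo_target); b <- max(tfo_target)
      regions <- list()
      if (a > 1) regions[["first_duplex"]] <- c(1L, a - 1L)
      regions[["homo_purine"]] <- c(a, b)
      if (b < n) regions[["second_duplex"]] <- c(b + 1L, n)
    } else {
      regions <- list(all = c(1L, n))
    }
  }
  structure(list(duplex_seq = lead, tfo_seq = tfo, tfo_target = tfo_target,
                 n_bp = n, regions = regions),
            class = "system_definition")
}

#' The bundled purine-motif triplex example system
#'
#' A 30-mer duplex (5'-AACTGCTAAAGAGGGAGGGACTTGATGTAT-3') whose central
#' homo-purine stretch (base pairs 11-20) is targeted by the antiparallel
#' 10-mer TFO 5'-AGGGAGGGAG-3'.
#'
#' @param with_tfo include the third strand (default TRUE).
#' @return a `system_definition`.
#' @export
purine_triplex_system <- function(with_tfo = TRUE) {
  system_definition(
    duplex_seq = "AACTGCTAAAGAGGGAGGGACTTGATGTAT",
    tfo_seq = if (with_tfo) "AGGGAGGGAG" else NULL,
    tfo_target = if (with_tfo) 11:20 else NULL,
    regions = list(first_duplex = c(1L, 10L),
                   homo_purine = c(11L, 20L),
                   second_duplex = c(21L, 30L))
  )
}

#' Annotate pairing and regions of a structure
#'
#' Checks the residues of `structure` against the declared sequences and
#' returns the Watson-Crick pair list, reverse-Hoogsteen pair list and
#' region ranges.  Watson-Crick pairs follow `(i, 2n + 1 - i)`; Hoogsteen
#' pairs map TFO residues onto the purine-strand target in antiparallel
#' register.
#'
#' @param structure a `dna_structure`.
#' @param sysdef a `system_definition`.
#' @return object of class `pairing_annotation`: list with `wc_pairs`
#'   (two-column matrix), `hoogsteen_pairs` (two-column matrix or NULL),
#'   `regions`, `n_bp`.
#' @export
annotate_system <- function(structure, sysdef) {
  stopifnot(inherits(structure, "dna_structure"),
            inherits(sysdef, "system_definition"))
  n <- sysdef$n_bp
  res <- unique(structure$atoms[, c("resno", "resname")])
  res <- res[order(res$resno), ]
  expected <- c(sysdef$duplex_seq,
                rev(wc_complement(sysdef$duplex_seq)),
                sysdef$tfo_seq)
  if (nrow(res) != length(expected))
    stop("structure has ", nrow(res), " residues; system defines ",
         length(expected))
  got <- resname_base(res$resname)
  bad <- got != expected
  if (any(bad))
    stop("sequence mismatch at residue(s): ",
         paste(sprintf("%d (%s, expected %s)", res$resno[bad], got[bad],
                       expected[bad]), collapse = ", "))
  wc <- cbind(i = seq_len(n), j = 2L * n + 1L - seq_len(n))
  hg <- NULL
  if (!is.null(sysdef$tfo_seq)) {
    k <- length(sysdef$tfo_seq)
    hg <- cbind(tfo = 2L * n + seq_len(k),
                purine = rev(sysdef$tfo_target))
  }
  structure(list(wc_pairs = wc, hoogsteen_pairs = hg,
                 regions = sysdef$regions, n_bp = n),
            class = "pairing_annotation")
}

#' @export
print.pairing_annotation <- function(x, ...) {
  cat(sprintf("<pairing_annotation> %d WC pairs", nrow(x$wc_pairs)))
  if (!is.null(x$hoogsteen_pairs))
    cat(sprintf(", %d reverse-Hoogsteen pairs", nrow(x$hoogsteen_pairs)))
  cat("\n  regions:",
      paste(sprintf("%s [%d-%d]", names(x$regions),
                    vapply(x$regions, `[`, 1L, 1),
                    vapply(x$regions, `[`, 1L, 2)), collapse = ", "), "\n")
  invisible(x)
}
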