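#' C-alpha structures
#'
#' A `CaStructure` is an ordered single-chain C-alpha trace: one row per
#' residue with the author residue number (`seq_id`), an optional insertion
#' code, the one-letter amino-acid code (`X` when unknown), the CA
#' coordinates in Angstrom and an optional per-residue confidence in
#' \[0, 100\] (pLDDT for predicted models). Rows are strictly ordered by
#' `(seq_id, ins_code)`, insertion codes sorting after the bare number.
#'
#' @param label non-empty character scalar identifying the chain/structure.
#' @param seq_id integer author residue numbers.
#' @param xyz numeric matrix, one row per residue, columns x, y, z (Angstrom).
#' @param aa one-letter amino-acid codes (recycled `"X"` if omitted).
#' @param ins_code insertion codes (`""` if none).
#' @param confidence optional numeric in \[0, 100\] or NA.
#' @return object of class `CaStructure`.
#' @export
ca_structure <- function(label, seq_id, xyz, aa = NULL, ins_code = NULL,
                         confidence = NULL) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label))
    stop_cp("label must be a non-empty string")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop_cp("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 1) stop_cp("structure must have at least one residue")
  if (length(seq_id) != n) stop_cp("seq_id length must match xyz rows")
  if (!all(is.finite(xyz))) stop_cp("non-finite CA coordinates")
  aa <- if (is.null(aa)) rep("X", n) else as.character(aa)
  ins_code <- if (is.null(ins_code)) rep("", n) else as.character(ins_code)
  confidence <- if (is.null(confidence)) rep(NA_real_, n) else as.numeric(confidence)
  if (any(!is.na(confidence) & (confidence < 0 | confidence > 100)))
    stop_cp("confidence values must lie in [0, 100]")
  res <- data.frame(seq_id = as.integer(seq_id), ins_code = ins_code,
                    aa = aa, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    confidence = confidence, stringsAsFactors = FALSE)
  ord <- order(res$seq_id, res$ins_code)
  res <- res[ord, , drop = FALSE]
  key <- paste(res$seq_id, res$ins_code)
  if (anyDuplicated(key)) stop_cp("duplicate (seq_id, ins_code) in structure '%s'", label)
  rownames(res) <- NULL
  structure(list(label = label, residues = res), class = "CaStructure")
}

#' @export
print.CaStructure <- function(x, ...) {
  r <- x$residues
  cat(sprintf("CaStructure '%s': %d residues, seq_id %d..%d\n",
              x$label, nrow(r), r$seq_id[1], r$seq_id[nrow(r)]))
  invisible(x)
}

#' @export
length.CaStructure <- function(x) nrow(x$residues)

#' Coordinate matrix of a CaStructure
#' @param s a `CaStructure`.
#' @return numeric matrix n x 3.
#' @export
ca_coords <- function(s) {
  stopifnot(inherits(s, "CaStructure"))
  as.matrix(s$residues[, c("x", "y", "z")])
}

#' Amino-acid sequence of a CaStructure
#' @param s a `CaStructure`.
#' @return character scalar of one-letter codes.
#' @export
ca_sequence <- function(s) paste(s$residues$aa, collapse = "")

aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

#' Read a C-alpha structure from a PDB-format file
#'
#' Extracts one residue per CA atom from the ATOM records of a PDB-format
#' coordinate file (parsing via \pkg{bio3d}). HETATM records are ignored and
#' only the first MODEL of a multi-model file is used. Alternate locations
#' are resolved by keeping the highest-occupancy altloc, ties broken by the
#' lexicographically smallest altloc identifier. When `predicted = TRUE` the
#' temperature-factor column is interpreted as per-residue confidence
#' (pLDDT, 0-100); for experimental models it is left unread so that
#' B-factors are never mistaken for confidences.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier; default: the first chain with CA
#'   atoms.
#' @param predicted logical; treat the file as a predicted model and read
#'   the B-factor column as confidence.
#' @param label label for the returned structure (default: file base name,
#'   plus `_<chain>` when a chain is selected explicitly).
#' @return a [ca_structure()] object.
#' @export
read_ca_structure <- function(path, chain = NULL, predicted = FALSE,
                              label = NULL) {
  if (!file.exists(path)) stop_cp("file not found: %s", path)
  # pre-scan ATOM records so format errors carry a line number
  raw <- readLines(path, warn = FALSE)
  for (ln in which(startsWith(raw, "ATOM"))) {
    l <- raw[ln]
    resno <- suppressWarnings(as.integer(substr(l, 23, 26)))
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (nchar(l) < 54 || is.na(resno) || anyNA(xyz))
      stop_cp("unparseable ATOM record at line %d of %s", ln, path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop_cp("cannot parse '%s': %s",
                                              path, conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop_cp("no ATOM records in %s", path)
  if (!is.null(chain)) {
    if (!chain %in% at$chain) stop_cp("chain '%s' not present in %s", chain, path)
    at <- at[at$chain == chain, , drop = FALSE]
  } else {
    ca_chains <- unique(at$chain[at$elety == "CA"])
    if (length(ca_chains) == 0) stop_cp("no CA atoms in %s", path)
    at <- at[at$chain == ca_chains[1], , drop = FALSE]
  }
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop_cp("no CA atoms for the requested chain in %s", path)
  ca$insert[is.na(ca$insert)] <- ""
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  # altloc rule: per residue keep highest occupancy, tie -> smallest altloc id
  key <- paste(ca$resno, ca$insert)
  keep <- unlist(lapply(split(seq_len(nrow(ca)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- ca[idx, ]
    idx[order(-sub$o, sub$alt)][1]
  }), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  aa <- unname(aa3to1[ca$resid])
  aa[is.na(aa)] <- "X"
  if (is.null(label)) {
    label <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
    if (!is.null(chain)) label <- paste0(label, "_", chain)
  }
  conf <- if (predicted) pmin(pmax(ca$b, 0), 100) else NULL
  ca_structure(label, seq_id = ca$resno, xyz = cbind(ca$x, ca$y, ca$z),
               aa = aa, ins_code = ca$insert, confidence = conf)
}

#' Write a CaStructure as a PDB-format CA trace
#'
#' One ATOM record per residue (element CA), chain A, occupancy 1.00;
#' the temperature-factor column carries the residue confidence when
#' present, otherwise 0. Coordinates keep the standard 3-decimal PDB
#' precision.
#'
#' @param s a `CaStructure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ca_structure <- function(s, path) {
  stopifnot(inherits(s, "CaStructure"))
  r <- s$residues
  aa1to3 <- setNames(names(aa3to1)[1:20], unname(aa3to1[1:20]))
  res3 <- aa1to3[r$aa]
  res3[is.na(res3)] <- "UNK"
  b <- ifelse(is.na(r$confidence), 0, r$confidence)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(r)), res3, r$seq_id, substr(paste0(r$ins_code, " "), 1, 1),
    r$x, r$y, r$z, 1, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Locate exact motif occurrences in a protein sequence
#'
#' Finds every (possibly overlapping) exact occurrence of an amino-acid
#' motif, e.g. the DDF/EDF maturation-cleavage motifs of capsid proteins,
#' returning 1-based inclusive positions in ascending order.
#'
#' @param seq character scalar (or `SequenceRecord`) amino-acid sequence.
#' @param motif non-empty amino-acid string.
#' @return data.frame with columns `start`, `end` (0 rows if absent).
#' @examples
#' motif_locate("ADDF", "DDF")   # 2..4
#' motif_locate("AAAA", "AA")    # three overlapping hits
#' @export
motif_locate <- function(seq, motif) {
  if (is.list(seq) && !is.null(seq$seq)) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1)
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) < 1)
    stop_cp("motif must be a non-empty string")
  seq <- toupper(seq); motif <- toupper(motif)
  n <- nchar(seq); m <- nchar(motif)
  starts <- integer(0)
  if (m <= n) {
    for (i in seq_len(n - m + 1)) {
      if (substr(seq, i, i + m - 1) == motif) starts <- c(starts, i)
    }
  }
  data.frame(start = starts, end = starts + m - 1L)
}
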