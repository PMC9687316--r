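#' Read a protein structure from PDB text
#'
#' Parses ATOM records of a PDB file into a [ProteinStructure-class].
#' HETATM records and water residues (HOH/WAT/DOD) are dropped, mirroring
#' the usual docking preprocessing that strips waters and hetero atoms.
#' The B-factor column is preserved per atom (`bscore`), so predicted-model
#' confidence scores written there survive parsing. When alternate locations
#' are present, the highest-occupancy altloc of each atom is kept (ties go
#' to the first encountered). For multi-model files only the first model is
#' read; use [readEnsemble()] to keep all models.
#'
#' @param x path to a PDB file, or PDB text (single string or a character
#'   vector of lines).
#' @param id identifier stored in the result; defaults to the file name or
#'   `"structure"`.
#' @return a [ProteinStructure-class].
#' @examples
#' pdb <- makePeptideChain("ACDEF")
#' txt <- writePDB(pdb)
#' identical(atoms(readStructure(txt))$resname, atoms(pdb)$resname)
#' @export
readStructure <- function(x, id = NULL) {
  src <- pdb_lines(x)
  if (is.null(id)) id <- src$id
  lines <- src$lines
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    end1 <- grep("^ENDMDL", lines)
    if (length(end1)) lines <- lines[seq_len(end1[1])]
  }
  parsed <- parse_atom_records(lines, lineno = seq_along(lines))
  if (nrow(parsed) == 0L)
    stop("no ATOM records found in input")
  title <- sub("^TITLE\\s+", "", grep("^TITLE", src$lines, value = TRUE)[1])
  if (is.na(title)) title <- ""
  new("ProteinStructure", id = id, atoms = parsed, title = title)
}

#' Read a docked-pose ensemble from multi-model PDB text
#'
#' Each MODEL/ENDMDL block becomes one frame. All models must contain the
#' same number of atoms in the same order; a model whose atom count differs
#' from the first model raises an error naming that model. A file without
#' MODEL records yields a single-frame ensemble.
#'
#' @inheritParams readStructure
#' @return a [PoseEnsemble-class] whose topology is taken from the first
#'   model.
#' @examples
#' ens <- makePoseEnsemble(seed = 1, sizes = c(3, 2))$ensemble
#' ens2 <- readEnsemble(writePDB(ens))
#' nFrames(ens2)
#' @export
readEnsemble <- function(x, id = NULL) {
  src <- pdb_lines(x)
  if (is.null(id)) id <- src$id
  lines <- src$lines
  starts <- grep("^MODEL", lines)
  blocks <- if (length(starts) == 0L) {
    list(seq_along(lines))
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(starts))
      ends <- c(ends, length(lines))
    mapply(function(s, e) seq(s, e), starts, ends[seq_along(starts)],
           SIMPLIFY = FALSE)
  }
  first <- parse_atom_records(lines[blocks[[1]]], lineno = blocks[[1]])
  if (nrow(first) == 0L) stop("no ATOM records found in input")
  n_atoms <- nrow(first)
  coords <- array(NA_real_, dim = c(n_atoms, 3, length(blocks)))
  coords[, , 1] <- as.matrix(first[, c("x", "y", "z")])
  if (length(blocks) > 1L) {
    for (m in 2:length(blocks)) {
      pm <- parse_atom_records(lines[blocks[[m]]], lineno = blocks[[m]])
      if (nrow(pm) != n_atoms)
        stop(sprintf(
          "model %d has %d atoms; expected %d (inconsistent ensemble)",
          m, nrow(pm), n_atoms))
      coords[, , m] <- as.matrix(pm[, c("x", "y", "z")])
    }
  }
  topo <- new("ProteinStructure", id = id, atoms = first, title = "")
  new("PoseEnsemble", id = id, topology = topo, coords = coords)
}

#' Write structures, ensembles and trajectories as PDB text
#'
#' Coordinates are written at the PDB column precision (3 decimals);
#' `bscore` goes to the B-factor column. Multi-frame objects are written as
#' MODEL/ENDMDL blocks.
#'
#' @param x a [ProteinStructure-class], [PoseEnsemble-class] or
#'   [Trajectory-class].
#' @param file optional path; when omitted the PDB text is returned as a
#'   single string.
#' @return the PDB text, invisibly when `file` is given.
#' @export
setGeneric("writePDB", function(x, file = NULL) standardGeneric("writePDB"))

#' @rdname writePDB
setMethod("writePDB", "ProteinStructure", function(x, file = NULL) {
  txt <- paste(c(format_atom_lines(x@atoms), "END", ""), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
})

#' @rdname writePDB
setMethod("writePDB", "PoseEnsemble", function(x, file = NULL) {
  a <- x@topology@atoms
  out <- character(0)
  for (m in seq_len(nFrames(x))) {
    a[, c("x", "y", "z")] <- x@coords[, , m]
    out <- c(out, sprintf("MODEL     %4d", m), format_atom_lines(a),
             "ENDMDL")
  }
  txt <- paste(c(out, "END", ""), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
})

# -- internals ---------------------------------------------------------------

.WATER_RESNAMES <- c("HOH", "WAT", "DOD")

pdb_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    list(lines = readLines(x, warn = FALSE),
         id = sub("\\.(pdb|ent)$", "", basename(x), ignore.case = TRUE))
  } else {
    lines <- if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]] else x
    list(lines = lines, id = "structure")
  }
}

parse_atom_records <- function(lines, lineno) {
  is_atom <- startsWith(lines, "ATOM")
  if (!any(is_atom))
    return(empty_atom_table())
  ln <- lineno[is_atom]
  rec <- lines[is_atom]
  short <- nchar(rec) < 54
  if (any(short))
    stop("malformed ATOM record at line ", ln[which(short)[1]],
         ": line shorter than coordinate fields")
  f <- function(from, to) trimws(substr(rec, from, to))
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!nzchar(s) | is.na(v))
    if (length(bad) && what != "optional")
      stop("malformed ATOM record at line ", ln[bad[1]],
           ": cannot parse ", what)
    v
  }
  serial <- suppressWarnings(as.integer(f(7, 11)))
  serial[is.na(serial)] <- seq_len(sum(is_atom))[is.na(serial)]
  name <- f(13, 16)
  altloc <- f(17, 17)
  resname <- f(18, 20)
  chain <- f(22, 22)
  resno <- suppressWarnings(as.integer(f(23, 26)))
  if (anyNA(resno))
    stop("malformed ATOM record at line ", ln[which(is.na(resno))[1]],
         ": cannot parse residue number")
  icode <- f(27, 27)
  xs <- num(f(31, 38), "x coordinate")
  ys <- num(f(39, 46), "y coordinate")
  zs <- num(f(47, 54), "z coordinate")
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(f(61, 66)))
  b[is.na(b)] <- 0
  elem <- toupper(f(77, 78))
  guess <- toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]
  a <- data.frame(serial = serial, name = name, altloc = altloc,
                  resname = resname, chain = chain, resno = resno,
                  icode = icode, x = xs, y = ys, z = zs,
                  occupancy = occ, bscore = b, element = elem,
                  stringsAsFactors = FALSE)
  a <- a[!(a$resname %in% .WATER_RESNAMES), , drop = FALSE]
  # altloc policy: keep the highest-occupancy location of each atom,
  # first-encountered on ties
  if (any(nzchar(a$altloc))) {
    key <- paste(a$chain, a$resno, a$icode, a$name, sep = "\r")
    ord <- order(factor(key, levels = unique(key)), -a$occupancy)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$icode, a$name,
                             sep = "\r")), , drop = FALSE]
    a$altloc <- ""
  }
  rownames(a) <- NULL
  a
}

empty_atom_table <- function() {
  data.frame(serial = integer(0), name = character(0),
             altloc = character(0), resname = character(0),
             chain = character(0), resno = integer(0), icode = character(0),
             x = numeric(0), y = numeric(0), z = numeric(0),
             occupancy = numeric(0), bscore = numeric(0),
             element = character(0), stringsAsFactors = FALSE)
}

format_atom_lines <- function(a) {
  name_fmt <- ifelse(nchar(a$name) < 4 &
                       nchar(a$element) == 1,
                     sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L, name_fmt, a$altloc, a$resname, a$chain,
          a$resno, a$icode, a$x, a$y, a$z, a$occupancy, a$bscore,
          a$element)
}
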