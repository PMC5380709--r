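#' Read a molecular structure file
#'
#' Supports plain XYZ (count / comment / atom records) and PDB
#' (ATOM/HETATM records; first MODEL only; altloc 'A' or blank; CRYST and
#' other records ignored).  Element order is preserved exactly as in the
#' file and masses are assigned from the built-in atomic-mass table.
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; guessed from the extension by default.
#' @return a [geometry()].
#' @export
read_structure <- function(path, format = c("auto", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  switch(format, xyz = read_xyz(path), pdb = read_pdb(path))
}

#' @rdname read_structure
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: expected an atom count, got '",
         lines[1L], "'")
  }
  recs <- lines[-(1:2)]
  recs <- recs[nzchar(trimws(recs))]
  if (length(recs) < n) {
    stop("XYZ parse error: header declares ", n, " atoms but only ",
         length(recs), " atom records found (first missing at line ",
         length(recs) + 3L, ")")
  }
  recs <- recs[seq_len(n)]
  fields <- strsplit(trimws(recs), "\\s+")
  bad <- which(vapply(fields, length, 0L) < 4L)
  if (length(bad)) {
    stop("XYZ parse error at line ", bad[1L] + 2L,
         ": expected 'element x y z'")
  }
  element <- vapply(fields, `[[`, "", 1L)
  xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  if (anyNA(xyz)) {
    stop("XYZ parse error: non-numeric coordinate at line ",
         which(apply(is.na(xyz), 1L, any))[1L] + 2L)
  }
  g <- geometry(element, xyz)
  attr(g, "comment") <- if (length(lines) >= 2L) lines[2L] else ""
  g
}

#' Write a geometry to an XYZ file
#'
#' Coordinates are written in fixed-width 6-decimal fields so that a
#' read/write cycle round-trips to identical text.
#'
#' @param g a [geometry()].
#' @param path output path.
#' @param comment comment line (line 2 of the file).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(g, path, comment = "") {
  rec <- sprintf("%-2s %13.6f %13.6f %13.6f",
                 g$element, g$xyz[, 1L], g$xyz[, 2L], g$xyz[, 3L])
  writeLines(c(as.character(n_atoms(g)), comment, rec), path)
  invisible(path)
}

# element symbol from PDB columns 77-78, falling back to the atom name
.pdb_element <- function(line, atom_name) {
  el <- trimws(substr(line, 77, 78))
  if (nzchar(el)) {
    return(paste0(toupper(substr(el, 1, 1)),
                  tolower(substr(el, 2, nchar(el)))))
  }
  nm <- gsub("[0-9']", "", trimws(atom_name))
  if (nchar(nm) >= 2 &&
      toupper(substr(nm, 1, 2)) %in% toupper(names(.ATOMIC_MASS))) {
    cand2 <- paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 2)))
    if (cand2 %in% names(.ATOMIC_MASS) && !cand2 %in% c("Ca", "Cl"))
      return(cand2)
  }
  substr(nm, 1, 1)
}

#' @rdname read_structure
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1L] - 1L)]
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (!length(sel)) stop("no ATOM/HETATM records in ", path)
  lines <- lines[sel]
  altloc <- substr(lines, 17, 17)
  lines <- lines[altloc %in% c(" ", "A", "")]
  atom <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  resid <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  icode <- substr(lines, 27, 27)
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54)))
  if (anyNA(xyz)) {
    stop("PDB parse error: bad coordinate field in record ",
         which(apply(is.na(xyz), 1L, any))[1L])
  }
  element <- mapply(.pdb_element, lines, atom, USE.NAMES = FALSE)
  rectype <- ifelse(grepl("^HETATM", lines), "HETATM", "ATOM")
  geometry(element, xyz,
           labels = data.frame(resname = resname, resid = resid,
                               atom = atom, icode = icode,
                               rectype = rectype,
                               stringsAsFactors = FALSE))
}

#' Write a geometry to a PDB file
#'
#' @param g a [geometry()]; labels are used when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(g, path) {
  n <- n_atoms(g)
  lb <- g$labels
  if (is.null(lb)) {
    lb <- data.frame(resname = "UNK", resid = 1L, atom = g$element,
                     icode = " ", rectype = "HETATM")
  }
  rec <- sprintf("%-6s%5d %-4s %-3s  %4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 lb$rectype, seq_len(n), substr(lb$atom, 1, 4), lb$resname,
                 lb$resid, substr(paste0(lb$icode, " "), 1, 1),
                 g$xyz[, 1L], g$xyz[, 2L], g$xyz[, 3L], 1, 0,
                 toupper(g$element))
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Read a per-residue charge table from CSV
#'
#' Expected columns: `residue` (label) and `value` (charge in e); extra
#' columns are kept.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_charge_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(df))) {
    stop("charge table needs columns 'residue' and 'value'")
  }
  df
}
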