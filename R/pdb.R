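# PDB reading and writing (fixed-column ATOM/HETATM records).

.emptyAtoms <- function() {
  data.frame(name = character(), element = character(),
             x = double(), y = double(), z = double(),
             chain = character(), res_seq = integer(), icode = character(),
             res_name = character(), is_backbone = logical(), het = logical(),
             stringsAsFactors = FALSE)
}

# Internal constructor from an atom table.
newStructure <- function(id, atoms) {
  rownames(atoms) <- NULL
  new("ProteinStructure", id = as.character(id), atoms = atoms)
}

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Water residues (HOH/WAT/DOD) are
#' dropped, hydrogens are kept but flagged by element, and when a file lists
#' alternate locations for an atom only the first-listed one is retained.
#' Residue numbering is taken as-is from the file (resSeq plus insertion
#' code); no renumbering is performed.
#'
#' @param path path to a PDB file containing at least one ATOM record.
#' @param id protein identifier; defaults to the file name without extension.
#' @return A [ProteinStructure-class].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDB(generateToyStructure(5, seed = 1), pdb)
#' s <- readPDB(pdb)
#' nrow(atoms(s))
#' @seealso [writePDB()], [generateToyStructure()]
#' @export
readPDB <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (!any(startsWith(trimws(rec), "ATOM")))
    stop("no ATOM records in ", path)
  if (length(keep) == 0L) stop("no ATOM records in ", path)

  ln <- lines[keep]
  parseNum <- function(s, what, field) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    bad <- which(is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s)))
    if (length(bad))
      stop("malformed ", field, " field at line ", keep[bad[1]], " of ", path)
    v
  }
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  res_name <- trimws(substr(ln, 18, 20))
  chain <- trimws(substr(ln, 22, 22))
  res_seq <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
  if (anyNA(res_seq))
    stop("malformed residue number at line ", keep[which(is.na(res_seq))[1]],
         " of ", path)
  icode <- trimws(substr(ln, 27, 27))
  x <- parseNum(substr(ln, 31, 38), ln, "x coordinate")
  y <- parseNum(substr(ln, 39, 46), ln, "y coordinate")
  z <- parseNum(substr(ln, 47, 54), ln, "z coordinate")
  element <- trimws(substr(ln, 77, 78))
  noel <- !nzchar(element)
  element[noel] <- substr(gsub("[0-9]", "", name[noel]), 1, 1)

  a <- data.frame(name = name, element = element, x = x, y = y, z = z,
                  chain = chain, res_seq = res_seq, icode = icode,
                  res_name = res_name,
                  is_backbone = name %in% BACKBONE_ATOMS,
                  het = substr(ln, 1, 6) == "HETATM",
                  stringsAsFactors = FALSE)

  a <- a[!a$res_name %in% WATER_RESNAMES, , drop = FALSE]
  if (nrow(a) == 0L) stop("no non-water atoms in ", path)

  # altloc: first occurrence of each (chain, res, icode, atom name) wins
  key <- paste(a$chain, a$res_seq, a$icode, a$name)
  a <- a[!duplicated(key), , drop = FALSE]

  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  newStructure(id, a)
}

#' Write a protein structure to a PDB file
#'
#' Emits standard fixed-column ATOM (or HETATM) records with coordinates at
#' 3-decimal precision. `readPDB(writePDB(s))` preserves atom names, residue
#' identity and coordinates to that precision.
#'
#' @param structure a [ProteinStructure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  stopifnot(is(structure, "ProteinStructure"))
  a <- atoms(structure)
  fmtName <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
  recs <- sprintf("%-6s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), fmtName,
                  a$res_name, ifelse(nzchar(a$chain), a$chain, " "),
                  a$res_seq, ifelse(nzchar(a$icode), a$icode, " "),
                  a$x, a$y, a$z, 1.00, 0.00, a$element)
  writeLines(c(recs, "END"), path)
  invisible(path)
}
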