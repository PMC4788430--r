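# Minimal fixed-width PDB reader/writer and a small atom-selection grammar,
# sufficient for the all-atom SASA/CSA analysis path.  Chain and residue
# identifiers are preserved verbatim (author numbering; no renumbering).

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL", "MSE", "ALY")
NUCLEIC_RES <- c("DA", "DC", "DG", "DT", "DI", "DU", "A", "C", "G", "U", "I",
                 "DA5", "DC5", "DG5", "DT5", "DA3", "DC3", "DG3", "DT3",
                 "ADE", "CYT", "GUA", "THY", "URA")

guess_element <- function(name, resname) {
  nm <- gsub("[0-9' ]", "", name)
  if (!nchar(nm)) return(NA_character_)
  # two-letter elements only when the raw name starts in column 13 with a
  # recognized symbol (FE, ZN, MG, ...); otherwise first letter wins
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR") &&
      !(resname %in% c(STANDARD_AA, NUCLEIC_RES)))
    return(two)
  toupper(substr(nm, 1, 1))
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (fixed columns) into an atom table plus one
#' coordinate set per MODEL.  Hydrogens are retained; downstream analyses
#' exclude them by element.
#'
#' @param path PDB file path
#' @param model_index which MODEL to make active (1-based)
#' @return an object of class `pdb_structure`: `atoms` (data.frame with
#'   serial, name, resname, chain, resid, element, occupancy), `models`
#'   (list of N x 3 matrices) and `model_index`
#' @export
read_pdb <- function(path, model_index = 1L) {
  if (!file.exists(path)) abort_config(sprintf("file not found: %s", path))
  ln <- readLines(path, warn = FALSE)
  rec <- substr(ln, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  n_models <- max(1L, length(model_starts))
  model_of <- rep(1L, length(ln))
  if (length(model_starts)) {
    model_of <- findInterval(seq_along(ln), model_starts)
    model_of[model_of == 0] <- 1L
  }
  idx1 <- which(is_atom & model_of == 1L)
  if (!length(idx1)) abort_config(sprintf("no ATOM/HETATM records in %s", path))
  parse_block <- function(idx) {
    l <- ln[idx]
    num <- function(from, to, what) {
      v <- suppressWarnings(as.numeric(substr(l, from, to)))
      bad <- which(!is.finite(v))
      if (length(bad))
        abort_config(sprintf("malformed %s in ATOM record at line %d of %s",
                             what, idx[bad[1]], path))
      v
    }
    data.frame(
      serial = suppressWarnings(as.integer(substr(l, 7, 11))),
      name = trimws(substr(l, 13, 16)),
      altloc = substr(l, 17, 17),
      resname = trimws(substr(l, 18, 20)),
      chain = substr(l, 22, 22),
      resid = suppressWarnings(as.integer(substr(l, 23, 26))),
      x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
      occupancy = suppressWarnings(as.numeric(substr(l, 55, 60))),
      element = trimws(substr(l, 77, 78)),
      stringsAsFactors = FALSE)
  }
  a <- parse_block(idx1)
  a$element <- toupper(a$element)
  miss <- !nzchar(a$element)
  if (any(miss))
    a$element[miss] <- mapply(guess_element, a$name[miss], a$resname[miss])
  if (anyNA(a$element))
    abort_config("element undeducible for some atoms")
  models <- list(as.matrix(a[, c("x", "y", "z")]))
  if (n_models > 1) {
    for (m in 2:n_models) {
      idx <- which(is_atom & model_of == m)
      if (length(idx) != length(idx1))
        abort_config(sprintf("MODEL %d atom count differs from MODEL 1", m))
      b <- parse_block(idx)
      models[[m]] <- as.matrix(b[, c("x", "y", "z")])
    }
  }
  if (model_index < 1 || model_index > length(models))
    abort_config(sprintf("model_index %d not in 1..%d", model_index,
                         length(models)), "model_index")
  a$x <- a$y <- a$z <- NULL
  structure(list(atoms = a, models = lapply(models, unname),
                 model_index = as.integer(model_index)),
            class = "pdb_structure")
}

#' Coordinates of the active model of a structure
#' @param structure a `pdb_structure`
#' @return an N x 3 matrix
#' @export
structure_coords <- function(structure) structure$models[[structure$model_index]]

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("<pdb_structure> %d atoms, %d model(s), chains: %s\n",
              nrow(x$atoms), length(x$models),
              paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

#' Write a structure back to PDB format
#' @param structure a `pdb_structure`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  xyz <- structure_coords(structure)
  lines <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$serial,
                   ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
                   a$resname, a$chain, a$resid,
                   xyz[, 1], xyz[, 2], xyz[, 3],
                   ifelse(is.finite(a$occupancy), a$occupancy, 1),
                   0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Select atoms with a small expression grammar
#'
#' Clauses joined by `and`:
#' \itemize{
#'   \item `chain A [B ...]` -- chain identifiers
#'   \item `resid 1-40` or `resid 3 7 12` -- residue numbers (author
#'     numbering, ranges allowed)
#'   \item `name NZ [NH1 ...]` -- atom names
#'   \item `resname LYS [ARG ...]` -- residue names
#'   \item `heavy` -- non-hydrogen atoms
#'   \item `protein` / `nucleic` -- standard amino-acid / nucleotide
#'     residues
#' }
#'
#' @param structure a `pdb_structure`
#' @param expression selection string, e.g.
#'   `"chain A and resid 1-40 and heavy"`
#' @return an object of class `atom_selection`: ordered unique `indices`
#'   into the atom table and the `expression` as provenance
#' @export
select_atoms <- function(structure, expression) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  clauses <- strsplit(expression, "\\s+and\\s+")[[1]]
  pos <- 1L
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    if (!length(toks) || !nzchar(toks[1]))
      abort_config(sprintf("empty clause at position %d in '%s'", pos, expression))
    kw <- toks[1]
    args <- toks[-1]
    keep <- keep & switch(kw,
      chain = {
        if (!length(args)) abort_config(sprintf("'chain' needs arguments at position %d", pos))
        a$chain %in% args
      },
      resid = {
        if (!length(args)) abort_config(sprintf("'resid' needs arguments at position %d", pos))
        ids <- unlist(lapply(args, function(t) {
          if (grepl("^-?[0-9]+--?[0-9]+$", t) || grepl("^[0-9]+-[0-9]+$", t)) {
            p <- regmatches(t, regexec("^(-?[0-9]+)-(-?[0-9]+)$", t))[[1]]
            seq(as.integer(p[2]), as.integer(p[3]))
          } else if (grepl("^-?[0-9]+$", t)) as.integer(t)
          else abort_config(sprintf("bad resid token '%s' at position %d", t, pos))
        }))
        a$resid %in% ids
      },
      name = {
        if (!length(args)) abort_config(sprintf("'name' needs arguments at position %d", pos))
        a$name %in% args
      },
      resname = {
        if (!length(args)) abort_config(sprintf("'resname' needs arguments at position %d", pos))
        a$resname %in% args
      },
      heavy = !(a$element %in% c("H", "D")),
      protein = a$resname %in% STANDARD_AA,
      nucleic = a$resname %in% NUCLEIC_RES,
      abort_config(sprintf("unknown selection keyword '%s' at position %d in '%s'",
                           kw, pos, expression)))
    pos <- pos + nchar(cl) + 5L  # + " and "
  }
  structure(list(indices = which(keep), expression = expression),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> %d atoms from '%s'\n",
              length(x$indices), x$expression))
  invisible(x)
}
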