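#' Read a PDB file
#'
#' Parses ATOM/HETATM records of a (possibly multi-model) PDB file into a
#' [new_structure()] `Structure`.  All models must share the same atom count
#' and ordering; coordinates are taken at face value in angstrom.
#'
#' @param path path to a PDB file.
#' @return a `Structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model_open <- startsWith(lines, "MODEL")
  is_model_close <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # assign a model id to every atom line
  model_id <- cumsum(is_model_open)
  if (!any(is_model_open)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  atom_lineno <- which(is_atom)

  fixed <- function(v, from, to) trimws(substr(v, from, to))
  num <- function(v, from, to, what) {
    txt <- fixed(v, from, to)
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.finite(out))
    if (length(bad))
      stop(sprintf("parse error at line %d: malformed %s field '%s'",
                   atom_lineno[bad[1L]], what, txt[bad[1L]]))
    out
  }

  models_split <- split(seq_along(atom_lines), atom_model)
  counts <- lengths(models_split)
  if (length(unique(counts)) != 1L)
    stop("topology error: models have inconsistent atom counts (",
         paste(counts, collapse = ", "), ")")

  first <- atom_lines[models_split[[1L]]]
  elem <- fixed(first, 77, 78)
  name <- fixed(first, 13, 16)
  # fall back to the first letter of the atom name when the element
  # column is blank (common in minimal files)
  elem[elem == ""] <- gsub("[^A-Za-z].*$", "", name[elem == ""])
  elem[elem == ""] <- substr(name[elem == ""], 1, 1)
  occ <- suppressWarnings(as.numeric(fixed(first, 55, 60)))
  bfac <- suppressWarnings(as.numeric(fixed(first, 61, 66)))
  atoms <- data.frame(
    serial = num(first, 7, 11, "serial"),
    name = name,
    element = toupper(elem),
    resno = as.integer(num(first, 23, 26, "residue number")),
    resname = fixed(first, 18, 20),
    chain = substr(first, 22, 22),
    occupancy = ifelse(is.finite(occ), occ, 1),
    b = ifelse(is.finite(bfac), bfac, 0),
    stringsAsFactors = FALSE)

  models <- lapply(models_split, function(ii) {
    v <- atom_lines[ii]
    cbind(num(v, 31, 38, "x coordinate"),
          num(v, 39, 46, "y coordinate"),
          num(v, 47, 54, "z coordinate"))
  })
  # atom ordering must agree across models
  for (m in models_split[-1L]) {
    if (!identical(fixed(atom_lines[m], 13, 16), atoms$name) ||
        !identical(as.integer(num(atom_lines[m], 23, 26, "residue number")),
                   atoms$resno))
      stop("topology error: atom ordering differs between models")
  }
  names(models) <- NULL
  new_structure(atoms, models)
}

#' Write a PDB file
#'
#' Emits all models of a `Structure` as fixed-width ATOM records (with
#' MODEL/ENDMDL framing when there is more than one model).  Coordinates
#' whose magnitude overflows the 8.3 coordinate field raise a range error.
#'
#' @param s a `Structure` (may have zero atoms).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_models(s) > 1L
  a <- s$atoms
  fmt_name <- function(nm) {
    # standard PDB alignment: 1-3 character names start in column 14
    ifelse(nchar(nm) >= 4L, substr(nm, 1, 4), sprintf(" %-3s", nm))
  }
  for (m in seq_len(n_models(s))) {
    xyz <- get_xyz(s, m)
    if (length(xyz) && (max(xyz) > 9999.999 + 5e-4 ||
                        min(xyz) < -999.999 - 5e-4))
      stop("range error: coordinate magnitude overflows the PDB ",
           "8.3 field (model ", m, ")")
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    if (nrow(a)) {
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a$serial %% 100000L, fmt_name(a$name), a$resname, a$chain, a$resno,
        xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, a$b, a$element), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
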