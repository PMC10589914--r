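# PDB fixed-column I/O. Column slices follow the wwPDB format description
# (v3.3): serial 7-11, name 13-16, altLoc 17, resName 18-20, chainID 22,
# resSeq 23-26, iCode 27, x/y/z 31-54, occupancy 55-60, tempFactor 61-66,
# element 77-78.

slice <- function(line, from, to) substr(line, from, to)

num_or_stop <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(trimws(txt)))
  if (any(is.na(v)))
    stop(sprintf("malformed %s field at line %d: '%s'",
                 what, lineno[is.na(v)][1], trimws(txt[is.na(v)][1])),
         call. = FALSE)
  v
}

#' Parse PDB-format text into a structure tibble
#'
#' Reads ATOM/HETATM/MODEL/ENDMDL records (TER and everything else is
#' ignored for coordinates). Alternate locations are resolved to a single
#' conformer: within each (chain, residue, atom name) group the highest
#' occupancy wins, ties broken alphabetically by alt-loc identifier.
#' Hydrogens are retained.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @param model Model number to keep; default the first model present.
#'   Models are never averaged.
#' @param entry_id Optional identifier stored on the result.
#' @return A structure tibble (see [as_structure()]).
#' @export
parse_pdb <- function(text, model = NULL, entry_id = "") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  rec <- substr(lines, 1, 6)
  cur_model <- 1L
  model_no <- integer(length(lines))
  for (i in seq_along(lines)) {
    if (startsWith(rec[i], "MODEL")) {
      m <- suppressWarnings(as.integer(trimws(substr(lines[i], 7, 80))))
      cur_model <- if (is.na(m)) cur_model + 1L else m
    }
    model_no[i] <- cur_model
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no atoms", call. = FALSE)
  keep <- which(is_atom)
  al <- lines[keep]
  lineno <- keep
  mdl <- model_no[keep]
  target <- if (is.null(model)) mdl[1] else as.integer(model)
  sel <- mdl == target
  if (!any(sel)) stop("model ", target, " not present", call. = FALSE)
  al <- al[sel]; lineno <- lineno[sel]; mdl <- mdl[sel]
  al <- formatC(al, width = 80, flag = "-")  # pad short lines

  a <- tibble::tibble(
    serial = as.integer(num_or_stop(slice(al, 7, 11), lineno, "serial")),
    atom = trimws(slice(al, 13, 16)),
    alt = trimws(slice(al, 17, 17)),
    resname = trimws(slice(al, 18, 20)),
    chain = trimws(slice(al, 22, 22)),
    resno = as.integer(num_or_stop(slice(al, 23, 26), lineno, "residue number")),
    ins = trimws(slice(al, 27, 27)),
    x = num_or_stop(slice(al, 31, 38), lineno, "coordinate"),
    y = num_or_stop(slice(al, 39, 46), lineno, "coordinate"),
    z = num_or_stop(slice(al, 47, 54), lineno, "coordinate"),
    occ = num_or_default(slice(al, 55, 60), 1),
    b = num_or_default(slice(al, 61, 66), 0),
    element = trimws(slice(al, 77, 78)),
    het = substr(al, 1, 6) == "HETATM",
    model = mdl
  )
  if (any(!nzchar(a$atom))) stop("empty atom name", call. = FALSE)
  a <- resolve_altlocs(a)
  as_structure(a, entry_id = entry_id)
}

num_or_default <- function(txt, default) {
  v <- suppressWarnings(as.numeric(trimws(txt)))
  v[is.na(v)] <- default
  v
}

#' Keep one conformer per atom: highest occupancy, tie -> alphabetical alt
#' @noRd
resolve_altlocs <- function(a) {
  if (all(a$alt == "")) return(a)
  key <- paste(a$chain, a$resno, a$ins, a$resname, a$atom, sep = "\r")
  ord <- order(match(key, unique(key)), -a$occ, a$alt)
  a2 <- a[ord, ]
  a2 <- a2[!duplicated(paste(a2$chain, a2$resno, a2$ins, a2$resname, a2$atom,
                             sep = "\r")), ]
  a2[order(match(paste(a2$chain, a2$resno, a2$ins, a2$resname, a2$atom,
                       sep = "\r"), unique(key))), ]
}

#' Read a PDB file
#' @param path Path to a PDB file.
#' @inheritParams parse_pdb
#' @return A structure tibble.
#' @export
read_pdb <- function(path, model = NULL) {
  parse_pdb(readLines(path, warn = FALSE), model = model,
            entry_id = sub("\\.(pdb|ent)$", "", basename(path)))
}

pdb_atom_name <- function(atom, element) {
  # names of <=3 chars whose element is a single letter start in column 14
  ifelse(nchar(atom) >= 4 | nchar(element) == 2,
         formatC(atom, width = -4),
         paste0(" ", formatC(atom, width = -3)))
}

#' Render a structure as PDB-format text
#'
#' Emits fixed-column ATOM/HETATM records with coordinates to 3 decimals,
#' a TER record after every chain and END at the end.
#' `parse_pdb(write_pdb(s))` reproduces the chain/residue/atom hierarchy and
#' coordinates to 1e-3 Angstrom.
#'
#' @param s A structure tibble.
#' @param path Optional file path; when given, lines are written there.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_pdb <- function(s, path = NULL) {
  if (any(nchar(s$chain) > 1))
    stop("chain_id longer than 1 character cannot be written to PDB",
         call. = FALSE)
  out <- character(0)
  serial <- 0L
  for (ch in unique(s$chain)) {
    cs <- s[s$chain == ch, ]
    serials <- serial + seq_len(nrow(cs))
    serial <- serial + nrow(cs) + 1L
    lines <- sprintf(
      "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(cs$het, "HETATM", "ATOM"),
      serials,
      pdb_atom_name(cs$atom, cs$element),
      cs$alt, cs$resname, cs$chain, cs$resno, cs$ins,
      cs$x, cs$y, cs$z, cs$occ, cs$b,
      formatC(cs$element, width = 2)
    )
    last <- cs[nrow(cs), ]
    ter <- sprintf("TER   %5d      %3s %1s%4d%1s",
                   serial, last$resname, last$chain, last$resno, last$ins)
    out <- c(out, lines, ter)
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
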