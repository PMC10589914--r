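# Minimal mmCIF reader/writer for the `_atom_site` loop. Author identifiers
# (auth_asym_id, auth_seq_id) are used for chain and residue identity so that
# PDB and mmCIF renderings of one entry parse to the same structure.

#' Tokenize one mmCIF data line
#'
#' Handles single- and double-quoted values (which may contain spaces) and
#' whitespace separation. `.` and `?` become empty strings.
#' @noRd
cif_tokens <- function(line) {
  toks <- character(0)
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch %in% c("'", '"')) {
      # a quote ends the value only when followed by whitespace or EOL
      j <- i + 1L
      repeat {
        j <- regexpr(ch, substr(line, j, n), fixed = TRUE) + j - 1L
        if (j < i + 1L) stop("unterminated quoted value", call. = FALSE)
        nxt <- substr(line, j + 1L, j + 1L)
        if (nxt == "" || nxt %in% c(" ", "\t")) break
        j <- j + 1L
      }
      toks <- c(toks, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- regexpr("[ \t]", substr(line, i, n))
      end <- if (j < 0) n else i + j - 2L
      toks <- c(toks, substr(line, i, end))
      i <- end + 1L
    }
  }
  toks[toks %in% c(".", "?")] <- ""
  toks
}

#' Parse mmCIF text into a structure tibble
#'
#' Only the `_atom_site` loop is read; the same alt-loc resolution and chain
#' typing as [parse_pdb()] apply, and the default model is the first
#' `pdbx_PDB_model_num` present.
#'
#' @inheritParams parse_pdb
#' @return A structure tibble.
#' @export
parse_mmcif <- function(text, model = NULL, entry_id = "") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  # locate the loop_ whose tags belong to _atom_site
  tag_start <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "loop_" && i < length(lines) &&
        startsWith(trimws(lines[i + 1L]), "_atom_site.")) {
      tag_start <- i + 1L
      break
    }
    i <- i + 1L
  }
  if (is.null(tag_start)) stop("no _atom_site loop found", call. = FALSE)
  tags <- character(0)
  i <- tag_start
  while (i <= length(lines) && startsWith(trimws(lines[i]), "_atom_site.")) {
    tags <- c(tags, sub("^_atom_site\\.", "", trimws(lines[i])))
    i <- i + 1L
  }
  vals <- character(0)
  rows <- list()
  row_i <- 0L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "loop_" || startsWith(ln, "_") || startsWith(ln, "data_")) break
    vals <- c(vals, cif_tokens(lines[i]))
    while (length(vals) >= length(tags)) {
      row_i <- row_i + 1L
      rows[[row_i]] <- vals[seq_along(tags)]
      vals <- vals[-seq_along(tags)]
    }
    i <- i + 1L
  }
  if (length(vals))
    stop("column count mismatch in _atom_site loop at row ", row_i + 1L,
         ": ", length(vals), " stray value(s)", call. = FALSE)
  if (!length(rows)) stop("no atoms", call. = FALSE)
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  getcol <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% tags) return(m[, nm])
    if (!is.null(alt) && alt %in% tags) return(m[, alt])
    rep(default, nrow(m))
  }
  a <- tibble::tibble(
    serial = as.integer(getcol("id", default = NA)),
    atom = getcol("auth_atom_id", "label_atom_id"),
    alt = getcol("label_alt_id", default = ""),
    resname = getcol("auth_comp_id", "label_comp_id"),
    chain = getcol("auth_asym_id", "label_asym_id"),
    resno = as.integer(getcol("auth_seq_id", "label_seq_id")),
    ins = getcol("pdbx_PDB_ins_code", default = ""),
    x = as.numeric(getcol("Cartn_x")),
    y = as.numeric(getcol("Cartn_y")),
    z = as.numeric(getcol("Cartn_z")),
    occ = as.numeric(getcol("occupancy", default = "1")),
    b = as.numeric(getcol("B_iso_or_equiv", default = "0")),
    element = getcol("type_symbol", default = ""),
    het = getcol("group_PDB", default = "ATOM") == "HETATM",
    model = as.integer(getcol("pdbx_PDB_model_num", default = "1"))
  )
  a$alt[is.na(a$alt)] <- ""
  a$ins[is.na(a$ins)] <- ""
  if (is.na(a$serial[1])) a$serial <- seq_len(nrow(a))
  if (any(is.na(a$x) | is.na(a$y) | is.na(a$z)))
    stop("malformed coordinate in _atom_site loop", call. = FALSE)
  target <- if (is.null(model)) a$model[1] else as.integer(model)
  a <- a[a$model == target, , drop = FALSE]
  if (!nrow(a)) stop("model ", target, " not present", call. = FALSE)
  a <- resolve_altlocs(a)
  as_structure(a, entry_id = entry_id)
}

#' Read an mmCIF file
#' @param path Path to an mmCIF file.
#' @inheritParams parse_mmcif
#' @return A structure tibble.
#' @export
read_mmcif <- function(path, model = NULL) {
  parse_mmcif(readLines(path, warn = FALSE), model = model,
              entry_id = sub("\\.cif$", "", basename(path)))
}

cif_quote <- function(x) {
  x[x == ""] <- "."
  needs <- grepl("[ \t']", x)
  x[needs] <- paste0('"', x[needs], '"')
  x
}

#' Render a structure as a minimal mmCIF file
#'
#' Writes a `data_` block with a single `_atom_site` loop carrying both
#' label_* and auth_* identifiers (set equal), so the output parses back
#' identically and is readable by standard mmCIF tools.
#'
#' @param s A structure tibble.
#' @param path Optional output file path.
#' @return Character vector of lines, invisibly when `path` is given.
#' @export
write_mmcif <- function(s, path = NULL) {
  eid <- attr(s, "entry_id")
  if (is.null(eid) || !nzchar(eid)) eid <- "structkit"
  tags <- c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
            "label_comp_id", "label_asym_id", "label_seq_id",
            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
            "occupancy", "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
            "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num")
  body <- paste(
    ifelse(s$het, "HETATM", "ATOM"),
    s$serial, cif_quote(s$element), cif_quote(s$atom), cif_quote(s$alt),
    cif_quote(s$resname), cif_quote(s$chain), s$resno, cif_quote(s$ins),
    sprintf("%.3f", s$x), sprintf("%.3f", s$y), sprintf("%.3f", s$z),
    sprintf("%.2f", s$occ), sprintf("%.2f", s$b),
    s$resno, cif_quote(s$resname), cif_quote(s$chain), cif_quote(s$atom),
    s$model
  )
  out <- c(paste0("data_", eid), "#", "loop_",
           paste0("_atom_site.", tags), body, "#")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
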