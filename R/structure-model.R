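#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Residue vocabulary. MSE (selenomethionine) is treated as protein and reads
# as "M" in sequences, the usual convention.
AA3 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

NUC1 <- c(DA = "A", DC = "C", DG = "G", DT = "T", DU = "U",
          A = "A", C = "C", G = "G", U = "U")

ATOM_COLS <- c("serial", "atom", "alt", "resname", "chain", "resno", "ins",
               "x", "y", "z", "occ", "b", "element", "het", "model")

classify_resname <- function(resname) {
  rn <- toupper(trimws(resname))
  dplyr::case_when(
    rn %in% names(AA3) ~ "protein",
    rn %in% names(NUC1) ~ "nucleic",
    TRUE ~ "hetero"
  )
}

#' Build a structure tibble from atom records
#'
#' The atom table is the package's working representation of a macromolecular
#' structure: one row per atom, chains and residues implied by the
#' `chain`/`resno`/`ins` columns in file order. `chain_type` is the majority
#' residue classification of each chain (protein / nucleic / hetero; ties
#' resolved protein > nucleic > hetero).
#'
#' @param atoms A data frame with at least `atom`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z` columns; missing bookkeeping columns are filled
#'   with defaults.
#' @param entry_id Optional entry identifier stored as an attribute.
#' @return A tibble of class `struct_tbl`.
#' @export
as_structure <- function(atoms, entry_id = "") {
  a <- tibble::as_tibble(atoms)
  if (!nrow(a)) stop("no atoms", call. = FALSE)
  defaults <- list(serial = seq_len(nrow(a)), alt = "", ins = "",
                   occ = 1, b = 0, element = "", het = FALSE, model = 1L)
  for (nm in names(defaults)) if (is.null(a[[nm]])) a[[nm]] <- defaults[[nm]]
  missing <- setdiff(ATOM_COLS, names(a))
  if (length(missing))
    stop("missing atom columns: ", paste(missing, collapse = ", "), call. = FALSE)
  a <- a[, ATOM_COLS]
  a$resno <- as.integer(a$resno)
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
    stop("non-finite coordinates", call. = FALSE)
  a$element <- ifelse(a$element == "", guess_element(a$atom), a$element)
  cls <- classify_resname(a$resname)
  type_by_chain <- tapply(cls, a$chain, function(v) {
    # one vote per residue, not per atom
    tab <- table(v)
    winners <- names(tab)[tab == max(tab)]
    for (cand in c("protein", "nucleic", "hetero"))
      if (cand %in% winners) return(cand)
  })
  a$chain_type <- as.character(type_by_chain[a$chain])
  attr(a, "entry_id") <- entry_id
  class(a) <- c("struct_tbl", class(a))
  a
}

guess_element <- function(atom) {
  nm <- sub("^[0-9]+", "", toupper(trimws(atom)))
  two <- substr(nm, 1, 2)
  el <- substr(nm, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "NA", "CL", "BR", "CU"),
         two, el)
}

#' @export
print.struct_tbl <- function(x, ...) {
  eid <- attr(x, "entry_id")
  cat(sprintf("# structure%s: %d atoms, %d chains\n",
              if (nzchar(eid)) paste0(" ", eid) else "",
              nrow(x), length(unique(x$chain))))
  NextMethod()
}

#' Residue keys "<chain>:<resno><ins>" in file order
#' @noRd
residue_keys <- function(s, unique = TRUE) {
  k <- paste0(s$chain, ":", s$resno, s$ins)
  if (unique) unique(k) else k
}

#' Per-chain summary of a structure
#'
#' @param s A structure tibble.
#' @return A tibble with one row per chain: `chain`, `chain_type`,
#'   `n_residues`, `n_atoms`.
#' @export
structure_info <- function(s) {
  s |>
    dplyr::group_by(.data$chain, .data$chain_type) |>
    dplyr::summarise(
      n_residues = length(unique(paste0(.data$resno, .data$ins))),
      n_atoms = dplyr::n(), .groups = "drop"
    )
}

#' Extract one chain from a structure
#'
#' @param s A structure tibble.
#' @param chain_id Chain identifier.
#' @return The chain's atoms as a tibble, file order preserved.
#' @export
get_chain <- function(s, chain_id) {
  out <- s[s$chain == chain_id, , drop = FALSE]
  if (!nrow(out)) stop("no such chain: ", chain_id, call. = FALSE)
  out
}

# ---- residue identifiers ----------------------------------------------------

#' Parse a residue identifier like "19" or "30A"
#'
#' Residue identity is (author number, insertion code); ranges are inclusive.
#' @noRd
parse_resid <- function(id) {
  id <- trimws(as.character(id))
  m <- regmatches(id, regexec("^(-?[0-9]+)([A-Za-z]?)$", id))[[1]]
  if (!length(m)) stop("malformed residue id: ", id, call. = FALSE)
  list(resno = as.integer(m[2]), ins = m[3])
}

resid_index <- function(chain_tbl, id) {
  r <- parse_resid(id)
  keys <- unique(paste0(chain_tbl$resno, "_", chain_tbl$ins))
  match(paste0(r$resno, "_", r$ins), keys)
}

#' Extract an inclusive residue range from a chain
#'
#' Endpoints are residue identifiers in author numbering, insertion code
#' appended (`"30"`, `"30A"`); the range is inclusive in file order, matching
#' the `19-38` convention used to name grafted loops.
#'
#' @param chain_tbl A single-chain structure tibble.
#' @param start,end Residue identifiers.
#' @return The atoms of the selected residues, order preserved.
#' @export
extract_range <- function(chain_tbl, start, end) {
  keys <- unique(paste0(chain_tbl$resno, "_", chain_tbl$ins))
  i <- resid_index(chain_tbl, start)
  j <- resid_index(chain_tbl, end)
  if (is.na(i)) stop("residue not found: ", start, call. = FALSE)
  if (is.na(j)) stop("residue not found: ", end, call. = FALSE)
  if (i > j) stop("start is after end in file order", call. = FALSE)
  wanted <- keys[i:j]
  chain_tbl[paste0(chain_tbl$resno, "_", chain_tbl$ins) %in% wanted, ,
            drop = FALSE]
}

#' One-letter sequence of a protein or nucleic chain
#'
#' Unknown residues become `"X"`; numbering gaps do not introduce gap
#' characters.
#'
#' @param chain_tbl A single-chain structure tibble.
#' @return A single string.
#' @export
chain_sequence <- function(chain_tbl) {
  type <- chain_tbl$chain_type[1]
  if (!type %in% c("protein", "nucleic"))
    stop("chain is not protein or nucleic (type: ", type, ")", call. = FALSE)
  res <- chain_tbl[!duplicated(paste0(chain_tbl$resno, "_", chain_tbl$ins)), ]
  rn <- toupper(trimws(res$resname))
  letters1 <- if (type == "protein") AA3[rn] else NUC1[rn]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}
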