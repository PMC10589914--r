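# Residue-contact interfaces between chain pairs. A contact is a residue
# pair from two different chains whose minimum selected-atom distance is at
# or below the cutoff; hydrogens and hetero residues (waters, ligands) never
# take part.

#' Compute the residue-contact interface between two chains
#'
#' One contact per residue pair, carrying the minimum atom-pair distance
#' under the chosen atom mode. Contact kind is derived from the residue
#' classes: PP (protein-protein), PN (protein-nucleic, either order) or NN.
#'
#' @param a,b Single-chain structure tibbles (different chains).
#' @param cutoff Contact distance cutoff, Angstrom (> 0). Default 5 for
#'   heavy/cb modes; 8 is the conventional choice for `ca` mode.
#' @param atom_mode `"heavy"` (all non-hydrogen atoms), `"ca"` or `"cb"`
#'   (C-beta, with C-alpha substituted for glycine).
#' @return A tibble of contacts, one row per residue pair within the cutoff:
#'   `chain_a`, `resno_a`, `ins_a`, `resname_a`, likewise for b, `distance`
#'   and `kind`; ordered by file order of (a, b). Attributes `chain_a`,
#'   `chain_b`, `cutoff`, `atom_mode` record the call.
#' @export
compute_interface <- function(a, b, cutoff = NULL,
                              atom_mode = c("heavy", "ca", "cb")) {
  atom_mode <- match.arg(atom_mode)
  if (is.null(cutoff)) cutoff <- if (atom_mode == "ca") 8 else 5
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (identical(a$chain[1], b$chain[1]) && nrow(a) == nrow(b) &&
      isTRUE(all.equal(a$x, b$x)))
    stop("interface requires two different chains", call. = FALSE)

  keep_poly <- function(s) s[classify_resname(s$resname) != "hetero", ,
                             drop = FALSE]
  a <- keep_poly(a); b <- keep_poly(b)
  empty <- tibble::tibble(chain_a = character(), resno_a = integer(),
                          ins_a = character(), resname_a = character(),
                          chain_b = character(), resno_b = integer(),
                          ins_b = character(), resname_b = character(),
                          distance = double(), kind = character())
  result_attrs <- function(x) {
    attr(x, "chain_a") <- if (nrow(a)) a$chain[1] else NA_character_
    attr(x, "chain_b") <- if (nrow(b)) b$chain[1] else NA_character_
    attr(x, "cutoff") <- cutoff
    attr(x, "atom_mode") <- atom_mode
    class(x) <- c("interface_tbl", class(x))
    x
  }
  if (!nrow(a) || !nrow(b)) return(result_attrs(empty))

  dm <- pairwise_min_distances(a, b, atom_mode)
  hit <- which(!is.na(dm) & dm <= cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(result_attrs(empty))
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]

  resa <- a[!duplicated(paste0(a$resno, "_", a$ins)), ]
  resb <- b[!duplicated(paste0(b$resno, "_", b$ins)), ]
  cls <- function(res, i) classify_resname(res$resname[i])
  kind <- vapply(seq_len(nrow(hit)), function(r) {
    ka <- cls(resa, hit[r, 1]); kb <- cls(resb, hit[r, 2])
    if (ka == "protein" && kb == "protein") "PP"
    else if (ka == "nucleic" && kb == "nucleic") "NN"
    else "PN"
  }, character(1))
  out <- tibble::tibble(
    chain_a = resa$chain[hit[, 1]], resno_a = resa$resno[hit[, 1]],
    ins_a = resa$ins[hit[, 1]], resname_a = resa$resname[hit[, 1]],
    chain_b = resb$chain[hit[, 2]], resno_b = resb$resno[hit[, 2]],
    ins_b = resb$ins[hit[, 2]], resname_b = resb$resname[hit[, 2]],
    distance = dm[hit], kind = kind
  )
  result_attrs(out)
}

#' Residues of one side of an interface
#'
#' @param interface A contact tibble from [compute_interface()].
#' @param side `"a"` or `"b"`.
#' @return Character vector of unique residue ids (`<resno><ins>`) of that
#'   side appearing in at least one contact, in chain order.
#' @export
interface_residues <- function(interface, side = c("a", "b")) {
  side <- match.arg(side)
  ids <- paste0(interface[[paste0("resno_", side)]],
                interface[[paste0("ins_", side)]])
  unique(ids[order(seq_along(ids))])
}

#' Interface contacts as TSV text
#'
#' @param interface A contact tibble from [compute_interface()].
#' @return Character vector: a header line then one TSV row per contact
#'   (`chain_a_res`, `chain_b_res`, `distance` to 3 decimals, `kind`),
#'   sorted by file order of (res_a, res_b).
#' @export
interface_summary <- function(interface) {
  header <- "chain_a_res\tchain_b_res\tdistance\tkind"
  if (!nrow(interface)) return(header)
  rows <- sprintf("%s:%s%s\t%s:%s%s\t%.3f\t%s",
                  interface$chain_a, interface$resno_a, interface$ins_a,
                  interface$chain_b, interface$resno_b, interface$ins_b,
                  interface$distance, interface$kind)
  c(header, rows)
}
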