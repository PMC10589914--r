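# Homology-search bookkeeping: BLAST tabular parsing, hit filtering
# (E-value / coverage / identity / the Rost significance curve) and PIR
# alignment output for comparative modeling.

BLAST12 <- c("query_id", "subject_id", "pct_identity", "aln_length",
             "mismatches", "gap_opens", "q_start", "q_end", "s_start",
             "s_end", "e_value", "bit_score")

#' Parse standard 12-column BLAST tabular output
#'
#' Comment lines beginning `#` are skipped; one record per data line, file
#' order preserved.
#'
#' @param text Character vector of lines (or one string with newlines).
#' @return A tibble with the standard columns: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `e_value`, `bit_score`.
#' @export
parse_blast_tabular <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(tibble::as_tibble(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), BLAST12)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad))
    stop(sprintf("expected 12 tab-separated columns, got %d at line %d",
                 lengths(parts)[bad[1]], lineno[bad[1]]), call. = FALSE)
  m <- do.call(rbind, parts)
  numcol <- function(k, what, integer = FALSE) {
    v <- suppressWarnings(as.numeric(m[, k]))
    if (anyNA(v))
      stop(sprintf("unparseable %s at line %d: '%s'", what,
                   lineno[which(is.na(v))[1]], m[which(is.na(v))[1], k]),
           call. = FALSE)
    if (integer) as.integer(v) else v
  }
  tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = numcol(3, "percent identity"),
    aln_length = numcol(4, "alignment length", TRUE),
    mismatches = numcol(5, "mismatch count", TRUE),
    gap_opens = numcol(6, "gap open count", TRUE),
    q_start = numcol(7, "query start", TRUE),
    q_end = numcol(8, "query end", TRUE),
    s_start = numcol(9, "subject start", TRUE),
    s_end = numcol(10, "subject end", TRUE),
    e_value = numcol(11, "E-value"),
    bit_score = numcol(12, "bit score")
  )
}

#' Read a BLAST tabular file
#' @param path File path.
#' @return A tibble of hits; see [parse_blast_tabular()].
#' @export
read_blast_tabular <- function(path) parse_blast_tabular(readLines(path))

#' Length-dependent sequence-identity significance threshold (Rost curve)
#'
#' `p(L) = n + 480 * L^(-0.32 * (1 + exp(-L / 1000)))`, in percent identity:
#' the curve above which sequence similarity implies homology, used to
#' select homology-modeling templates. `n` shifts the curve; n = 5 is the
#' conventional safe margin.
#'
#' @param aln_length Alignment length(s) L, >= 1.
#' @param n Curve offset in percent.
#' @return Percent identity threshold(s), same length as `aln_length`.
#' @export
rost_threshold <- function(aln_length, n = 5) {
  if (any(aln_length < 1)) stop("alignment length must be >= 1", call. = FALSE)
  L <- as.numeric(aln_length)
  n + 480 * L^(-0.32 * (1 + exp(-L / 1000)))
}

#' Construct a hit filter
#'
#' @param max_evalue Maximum E-value kept.
#' @param min_coverage Minimum query coverage, fraction in [0, 1]; coverage
#'   is `(q_end - q_start + 1) / query_length`.
#' @param min_identity Minimum percent identity in [0, 100].
#' @param use_rost Require `pct_identity >= rost_threshold(aln_length, rost_n)`.
#' @param rost_n Offset passed to [rost_threshold()].
#' @return A list of class `hit_filter`.
#' @export
hit_filter <- function(max_evalue = Inf, min_coverage = 0, min_identity = 0,
                       use_rost = FALSE, rost_n = 5) {
  stopifnot(max_evalue >= 0, min_coverage >= 0, min_coverage <= 1,
            min_identity >= 0, min_identity <= 100)
  structure(list(max_evalue = max_evalue, min_coverage = min_coverage,
                 min_identity = min_identity, use_rost = use_rost,
                 rost_n = rost_n), class = "hit_filter")
}

#' Filter BLAST hits on statistics and the Rost curve
#'
#' Keeps hits satisfying every enabled criterion; input order is preserved
#' and the operation is idempotent.
#'
#' @param hits Hit tibble from [parse_blast_tabular()].
#' @param query_length Length of the query sequence, >= 1.
#' @param filter A [hit_filter()].
#' @return The surviving hits.
#' @export
filter_hits <- function(hits, query_length, filter = hit_filter()) {
  stopifnot(inherits(filter, "hit_filter"), query_length >= 1)
  if (!nrow(hits)) return(hits)
  coverage <- (hits$q_end - hits$q_start + 1) / query_length
  keep <- hits$e_value <= filter$max_evalue &
    coverage >= filter$min_coverage &
    hits$pct_identity >= filter$min_identity
  if (filter$use_rost)
    keep <- keep &
      hits$pct_identity >= rost_threshold(hits$aln_length, filter$rost_n)
  hits[keep, , drop = FALSE]
}

wrap60 <- function(seq) {
  starts <- seq(1, nchar(seq), by = 60)
  substring(seq, starts, pmin(starts + 59, nchar(seq)))
}

#' Write a query/template alignment in PIR format
#'
#' Emits the MODELLER-compatible dialect: a `structureX` entry for the
#' template followed by a `sequence` entry for the query, sequences wrapped
#' at 60 characters and terminated by `*` (appended to the final line, or
#' alone on the next line when the final line is already 60 characters).
#'
#' @param query_id,template_id Entry identifiers.
#' @param query_seq,template_seq Aligned sequences of equal length, `-` for
#'   gaps; must not contain `*`.
#' @param template_chain Template chain id.
#' @param template_start,template_end First/last template residue ids.
#' @param path Optional output file.
#' @return Character vector of PIR lines (invisibly when `path` is given).
#' @export
write_pir <- function(query_id, query_seq, template_id, template_seq,
                      template_chain = "A", template_start = 1,
                      template_end = nchar(gsub("-", "", template_seq)),
                      path = NULL) {
  if (!nzchar(query_seq) || !nzchar(template_seq))
    stop("empty sequence", call. = FALSE)
  if (nchar(query_seq) != nchar(template_seq))
    stop("aligned sequences differ in length", call. = FALSE)
  if (grepl("*", query_seq, fixed = TRUE) ||
      grepl("*", template_seq, fixed = TRUE))
    stop("'*' is the PIR terminator and may not appear in a sequence",
         call. = FALSE)
  body <- function(seq) {
    lines <- wrap60(seq)
    if (nchar(lines[length(lines)]) < 60)
      lines[length(lines)] <- paste0(lines[length(lines)], "*")
    else lines <- c(lines, "*")
    lines
  }
  out <- c(
    paste0(">P1;", template_id),
    sprintf("structureX:%s:%s:%s:%s:%s::::", template_id, template_start,
            template_chain, template_end, template_chain),
    body(template_seq),
    paste0(">P1;", query_id),
    sprintf("sequence:%s::::::::", query_id),
    body(query_seq)
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
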