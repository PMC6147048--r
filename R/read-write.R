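hit_columns <- function() {
  c("query_id", "subject_id", "pident", "aln_length", "mismatches",
    "gap_opens", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

#' Read a 12-column tabular homology hit file
#'
#' Parses the common headerless tab-separated dialect of protein-vs-genome
#' searches (query, subject, percent identity, alignment length, mismatches,
#' gap opens, query start/end, subject start/end, e-value, bit score).
#' Coordinates are 1-based inclusive. Row order is preserved and identifiers
#' are taken verbatim.
#'
#' @param path Path to a hit file. An empty file yields a zero-row tibble.
#' @return A tibble with one row per hit and columns
#'   `query_id, subject_id, pident, aln_length, mismatches, gap_opens,
#'   qstart, qend, sstart, send, evalue, bitscore`.
#' @seealso [filter_hits()], [write_hit_table()]
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("hit file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(fields)
  bad <- which(nfld != 12)
  if (length(bad) > 0) {
    abort(sprintf("malformed hit table %s: row %d has %d columns (expected 12)",
                  path, bad[1], nfld[bad[1]]))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pident = as_num(m[, 3], "pident", path),
    aln_length = as_int(m[, 4], "aln_length", path),
    mismatches = as_int(m[, 5], "mismatches", path),
    gap_opens = as_int(m[, 6], "gap_opens", path),
    qstart = as_int(m[, 7], "qstart", path),
    qend = as_int(m[, 8], "qend", path),
    sstart = as_int(m[, 9], "sstart", path),
    send = as_int(m[, 10], "send", path),
    evalue = as_num(m[, 11], "evalue", path),
    bitscore = as_num(m[, 12], "bitscore", path)
  )
  out
}

empty_hit_table <- function() {
  tibble(query_id = character(), subject_id = character(), pident = numeric(),
         aln_length = integer(), mismatches = integer(), gap_opens = integer(),
         qstart = integer(), qend = integer(), sstart = integer(),
         send = integer(), evalue = numeric(), bitscore = numeric())
}

as_num <- function(x, field, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric %s in %s at row %d: '%s'",
                  field, path, bad[1], x[bad[1]]))
  }
  out
}

as_int <- function(x, field, path) {
  as.integer(as_num(x, field, path))
}

#' Write a hit table in the 12-column tabular dialect
#'
#' @param hits A hit tibble as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, hit_columns()], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-organism metadata
#'
#' Expects a tab-delimited file with named columns `organism_id`, `kingdom`,
#' `taxon_path` (ranks joined by `;`), `habitat` and `oxygen_req`. Habitat and
#' oxygen values are case-normalised; blank or out-of-vocabulary values map to
#' `"unknown"`. Duplicate organism ids and unknown kingdom tokens are errors.
#'
#' @param path Path to the metadata table.
#' @return A tibble with the five metadata columns, vocabularies enforced.
#' @export
read_metadata <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  validate_metadata(as_tibble(raw), source = path)
}

#' Validate and normalise a metadata table
#'
#' @param metadata A data frame with columns `organism_id`, `kingdom`,
#'   `taxon_path`, `habitat`, `oxygen_req`.
#' @param source Label used in error messages.
#' @return The normalised metadata tibble.
#' @export
validate_metadata <- function(metadata, source = "metadata") {
  need <- c("organism_id", "kingdom", "taxon_path", "habitat", "oxygen_req")
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s lacks required columns: %s", source,
                  paste(missing_cols, collapse = ", ")))
  }
  md <- as_tibble(metadata)[, need]
  md$organism_id <- trimws(md$organism_id)
  dup <- unique(md$organism_id[duplicated(md$organism_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate organism_id in %s: %s", source,
                  paste(dup, collapse = ", ")))
  }
  norm <- function(x) tolower(trimws(x))
  md$kingdom <- norm(md$kingdom)
  bad_k <- unique(md$kingdom[!md$kingdom %in% kingdom_levels()])
  if (length(bad_k) > 0) {
    abort(sprintf("unknown kingdom token in %s: %s", source,
                  paste(bad_k, collapse = ", ")))
  }
  md$habitat <- norm(md$habitat)
  md$habitat[!md$habitat %in% habitat_levels()] <- "unknown"
  md$oxygen_req <- norm(md$oxygen_req)
  md$oxygen_req[!md$oxygen_req %in% oxygen_levels()] <- "unknown"
  md
}

#' Write per-organism metadata
#' @param metadata Metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a domain-hit table
#'
#' Tab-delimited with header; required columns `protein_id`, `domain_id`,
#' `start`, `end`, `score`, `evalue`; an `organism_id` column is carried
#' through when present.
#'
#' @param path Path to the table.
#' @return A tibble of domain hits.
#' @export
read_domain_table <- function(path) {
  raw <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                     check.names = FALSE))
  need <- c("protein_id", "domain_id", "start", "end", "score", "evalue")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("domain table %s lacks columns: %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(raw$start > raw$end)
  if (length(bad) > 0) {
    abort(sprintf("domain table %s row %d: start > end", path, bad[1]))
  }
  raw
}

#' Write a domain-hit table
#' @param domains Domain-hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  utils::write.table(domains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA (equal-length sequences).
#' @return A named character vector of upper-case aligned sequences.
#' @export
read_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  out <- toupper(vapply(seqs, function(s) as.character(s)[1], character(1)))
  names(out) <- names(seqs)
  if (length(unique(nchar(out))) > 1) {
    abort(sprintf("alignment %s has unequal sequence lengths", path))
  }
  out
}

#' Write an aligned FASTA file
#' @param aln Named character vector of equal-length sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(unname(aln)), names = names(aln),
                      file.out = path, nbchar = 80)
  invisible(path)
}
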