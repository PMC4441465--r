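#' Construct a set of sequence records
#'
#' A sequence record collection is a data frame with one row per sequence and
#' columns `id`, `description`, `residues`, `original_length` and
#' `skipped_count`. Residues are always uppercase over the alphabet
#' \{A, C, G, T\}; `skipped_count` records how many non-ACGT symbols were
#' removed during cleaning, so that
#' `nchar(residues) + skipped_count == original_length`.
#'
#' @param id character vector of unique identifiers.
#' @param residues character vector of raw sequences; cleaned on construction
#'   (uppercased, `U` mapped to `T`, all other non-ACGT symbols removed).
#' @param description optional free-text descriptions (default empty).
#' @return A data frame of class `"seq_records"`.
#' @examples
#' seq_records(c("a", "b"), c("acgt", "ACNNGT"))
#' @export
seq_records <- function(id, residues, description = "") {
  id <- as.character(id)
  residues <- as.character(residues)
  if (length(id) != length(residues)) {
    stop("'id' and 'residues' must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  cleaned <- clean_residues(residues)
  empty <- !nzchar(cleaned$residues)
  if (any(empty)) {
    stop("entry '", id[which(empty)[1L]], "' has no A/C/G/T residues after cleaning")
  }
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    residues = cleaned$residues,
    original_length = cleaned$original_length,
    skipped_count = cleaned$skipped_count,
    stringsAsFactors = FALSE
  )
  class(out) <- c("seq_records", "data.frame")
  out
}

# Uppercase, map U->T (RNA-alphabet files), drop anything outside ACGT.
clean_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  original_length <- nchar(x)
  cleaned <- gsub("[^ACGT]", "", x)
  list(
    residues = cleaned,
    original_length = original_length,
    skipped_count = original_length - nchar(cleaned)
  )
}

#' Read DNA sequences from a FASTA file
#'
#' Parses a (multi-)FASTA file into a [seq_records] collection. The record id
#' is the first whitespace-delimited token of the header line; the remainder
#' is kept as the description. Sequences are cleaned deterministically:
#' lowercase letters are uppercased, `U` becomes `T`, and every other
#' non-ACGT symbol (`N`, IUPAC ambiguity codes, gaps, ...) is removed and
#' counted in `skipped_count`.
#'
#' @param path path to an existing FASTA file.
#' @return A `"seq_records"` data frame, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1L])
  }
  seq_records(ids, as.character(set), desc)
}

#' Write sequence records to a FASTA file
#'
#' Writes standard FASTA with 70-column line wrapping. Reading the file back
#' with [read_fasta()] reproduces the records exactly (records are already
#' clean, so cleaning is the identity).
#'
#' @param records a `"seq_records"` collection (or anything [seq_records()]
#'   accepts as a data frame with `id`, `residues`, optional `description`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- as_seq_records(records)
  if (nrow(records) == 0L) stop("no records to write")
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(
    nzchar(records$description),
    paste(records$id, records$description),
    records$id
  )
  Biostrings::writeXStringSet(set, filepath = path, width = 70L)
  invisible(path)
}

as_seq_records <- function(x) {
  if (inherits(x, "seq_records")) return(x)
  if (is.data.frame(x) && all(c("id", "residues") %in% names(x))) {
    return(seq_records(x$id, x$residues,
                       if ("description" %in% names(x)) x$description else ""))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(seq_records(ids, x))
  }
  stop("cannot interpret input as sequence records")
}

#' Read a sequence metadata table
#'
#' Tab-separated table with a header row and columns `id`, `name`, `group`,
#' used to label and colour points on a map.
#'
#' @param path path to the TSV file.
#' @return A data frame with columns `id`, `name`, `group`.
#' @export
read_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "name", "group")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("metadata table lacks column(s): ", paste(missing, collapse = ", "))
  }
  meta[, need]
}

# All 64 trinucleotides in lexicographic order (AAA, AAC, ..., TTT).
trinucleotide_alphabet <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(third = b, second = b, first = b,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  paste0(g$first, g$second, g$third)
}

#' Overlapping trinucleotide counts of a sequence
#'
#' Counts every length-3 window of the residues, so the counts sum to
#' `length - 2`. This is the profile that the trinucleotide-preserving
#' shuffle conserves exactly.
#'
#' @param x a single residue string, or a one-row `"seq_records"` entry.
#' @return Named integer vector of length 64 (all trinucleotides,
#'   lexicographic order).
#' @examples
#' trinucleotide_profile("ACGTACGT")
#' @export
trinucleotide_profile <- function(x) {
  residues <- residues_of(x)
  n <- nchar(residues)
  if (n < 3L) stop("sequence too short for order-3 profile (length ", n, ")")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(residues), width = 3L
  )
  counts <- counts[trinucleotide_alphabet()]
  storage.mode(counts) <- "integer"
  counts
}

# Accept a residue string, a one-row seq_records, or a list-like record.
residues_of <- function(x) {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) return(toupper(x))
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single sequence record")
    return(x$residues)
  }
  if (is.list(x) && !is.null(x$residues)) return(x$residues)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("cannot extract residues from input")
}

#' @export
print.seq_records <- function(x, ...) {
  cat("Sequence records: ", nrow(x), " sequence(s)\n", sep = "")
  df <- data.frame(
    id = x$id,
    length = nchar(x$residues),
    skipped = x$skipped_count,
    stringsAsFactors = FALSE
  )
  print(head(df, 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat("... and ", nrow(x) - 10L, " more\n", sep = "")
  invisible(x)
}
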