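#' Read a FASTA file into a sequence record table
#'
#' Records are returned in file order. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description. Sequences are case-normalized to upper case; no alphabet
#' check is performed here (see [validate_sequences()]).
#'
#' @param path Path to a FASTA text file. Multi-line sequences are allowed.
#' @return A data.frame with columns `id`, `desc`, `seq`, `length`.
#' @seealso [write_fasta()], [validate_sequences()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read FASTA file: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(empty_records())
  }
  headers <- names(set)
  if (any(!nzchar(trimws(headers)))) {
    stop("FASTA entry with empty header in ", path)
  }
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seq <- toupper(as.character(set))
  data.frame(id = id, desc = desc, seq = seq,
             length = nchar(seq), stringsAsFactors = FALSE)
}

empty_records <- function() {
  data.frame(id = character(), desc = character(), seq = character(),
             length = integer(), stringsAsFactors = FALSE)
}

as_records <- function(id, seq, desc = "") {
  data.frame(id = id, desc = desc, seq = toupper(seq),
             length = nchar(seq), stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records Record table as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- ifelse(nzchar(records$desc),
                       paste(records$id, records$desc),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

SEQ_ALPHABET <- c("A", "C", "G", "T", "U", "N")

#' Validate sequence records for pipeline use
#'
#' Applies the pipeline loading rules: sequences longer than `max_len`
#' nucleotides, sequences with characters outside A/C/G/T/U/N, empty
#' sequences, and duplicated ids (first occurrence kept) are excluded.
#' Validation never raises on content; every exclusion is reported.
#'
#' @param records Record table ([read_fasta()]).
#' @param max_len Maximum sequence length in nt. The miRNA identification
#'   pipeline uses 3000; the target pipeline accepts up to 20000.
#' @param allow_n Whether ambiguous N bases are tolerated (default TRUE).
#' @return A list with elements `kept` (record table) and `report`
#'   (list: `n_input`, `n_kept`, `n_excluded`, `exclusions` data.frame
#'   with columns `id`, `reason`).
#' @export
validate_sequences <- function(records, max_len = 3000L, allow_n = TRUE) {
  stopifnot(max_len > 0)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  allowed <- if (allow_n) SEQ_ALPHABET else setdiff(SEQ_ALPHABET, "N")
  bad_re <- paste0("[^", paste(allowed, collapse = ""), "]")
  for (i in seq_len(n)) {
    s <- records$seq[i]
    if (!nzchar(s)) {
      reason[i] <- "empty"
    } else if (nchar(s) > max_len) {
      reason[i] <- "too_long"
    } else if (grepl(bad_re, s)) {
      reason[i] <- "bad_alphabet"
    }
  }
  dup <- duplicated(records$id)
  reason[is.na(reason) & dup] <- "duplicate_id"
  keep <- is.na(reason)
  report <- list(
    n_input = n,
    n_kept = sum(keep),
    n_excluded = sum(!keep),
    exclusions = data.frame(id = records$id[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE)
  )
  list(kept = records[keep, , drop = FALSE], report = report)
}

#' Write a validation report to JSON or TSV
#'
#' @param report The `report` element of [validate_sequences()].
#' @param path Output path; format chosen by extension (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(report$exclusions, path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' Alphabet-preserving: if the input contains any U the complement of A is
#' U, otherwise T. N maps to N. Works on the A/C/G/T/U/N alphabet only.
#'
#' @param seq A nucleotide string.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  s <- toupper(seq)
  if (grepl(paste0("[^", paste(SEQ_ALPHABET, collapse = ""), "]"), s)) {
    stop("reverse_complement: sequence contains non-nucleotide characters")
  }
  a_to <- if (grepl("U", s, fixed = TRUE)) "U" else "T"
  comp <- chartr("ACGTUN", paste0(a_to, "GCAAN"), s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}
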