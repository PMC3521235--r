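#' Parse a miRBase-style miRNA identifier into family and species
#'
#' `ath-miR156a` yields family `miR156`, species `ath`. The species is
#' the leading 2-4 lowercase letters before the first dash; the family is
#' `miR` plus the leading integer of the remainder, with variant letters
#' and `-5p`/`-3p`/`.n` suffixes stripped. Identifiers without a
#' `miR<number>` token fall back to the remainder verbatim.
#'
#' @param mirna_id Character vector of identifiers.
#' @return data.frame with columns `family` and `species`.
#' @export
parse_family <- function(mirna_id) {
  stopifnot(all(nzchar(mirna_id)))
  species <- ifelse(grepl("^[a-z]{2,4}-", mirna_id),
                    sub("-.*$", "", mirna_id), "")
  rest <- ifelse(nzchar(species),
                 sub("^[a-z]{2,4}-", "", mirna_id), mirna_id)
  fam <- character(length(rest))
  for (i in seq_along(rest)) {
    mi <- regexpr("miR[0-9]+", rest[i], ignore.case = TRUE)
    fam[i] <- if (mi > 0) {
      paste0("miR", gsub("[^0-9]", "", regmatches(rest[i], mi)))
    } else {
      rest[i]
    }
  }
  data.frame(family = fam, species = species, stringsAsFactors = FALSE)
}

#' Read a mature miRNA reference from FASTA
#'
#' Headers are expected in miRBase style (`ath-miR156a ...`). Lengths
#' outside 18-26 nt draw a warning; outside 15-30 nt the entry is
#' rejected.
#'
#' @param path FASTA file of mature miRNAs.
#' @return data.frame: `id`, `family`, `species`, `seq`, `length`.
#' @export
read_mirna_fasta <- function(path) {
  rec <- read_fasta(path)
  mirna_table(rec$id, rec$seq)
}

#' Build a mature miRNA table from ids and sequences
#'
#' @param id,seq Character vectors of equal length.
#' @return data.frame: `id`, `family`, `species`, `seq`, `length`.
#' @export
mirna_table <- function(id, seq) {
  seq <- toupper(seq)
  len <- nchar(seq)
  if (any(len < 15 | len > 30)) {
    stop("mature miRNA length outside sanity bounds 15-30 nt: ",
         paste(id[len < 15 | len > 30], collapse = ", "))
  }
  if (any(len < 18 | len > 26)) {
    warning("mature miRNA length outside the usual 18-26 nt: ",
            paste(id[len < 18 | len > 26], collapse = ", "))
  }
  fam <- parse_family(id)
  data.frame(id = id, family = fam$family, species = fam$species,
             seq = seq, length = len, stringsAsFactors = FALSE)
}

#' Exhaustive mismatch-tolerant ungapped scan
#'
#' Reports every 1-based offset of `subject` where the Hamming distance
#' to `query` is at most `max_mismatch`. U and T compare equal; N in
#' either string always counts as a mismatch. Complete by construction.
#'
#' @param query,subject Nucleotide strings.
#' @param max_mismatch Maximum allowed mismatches.
#' @return data.frame with `start` (ascending) and `n_mismatch`.
#' @export
scan_exhaustive <- function(query, subject, max_mismatch = 4L) {
  stopifnot(max_mismatch >= 0)
  q <- encode_nt(query)
  s <- encode_nt(subject)
  m <- length(q); n <- length(s)
  if (m == 0L || m > n) {
    return(data.frame(start = integer(), n_mismatch = integer()))
  }
  noff <- n - m + 1L
  mm <- integer(noff)
  for (p in seq_len(m)) {
    col <- s[p:(p + noff - 1L)]
    mm <- mm + as.integer(col != q[p] | col == 0L | q[p] == 0L)
  }
  hit <- which(mm <= max_mismatch)
  data.frame(start = hit, n_mismatch = mm[hit])
}

#' Seeded (pigeonhole) mismatch-tolerant scan
#'
#' Splits the query into `max_mismatch + 1` contiguous seeds; any window
#' within the mismatch budget must contain at least one exact seed, so
#' verifying Hamming distance at seed-anchored offsets loses nothing.
#' Output is identical to [scan_exhaustive()] on every input; this is the
#' accelerated mode (word-seeded heuristics such as BLASTN can miss
#' matches, this scan cannot).
#'
#' @inheritParams scan_exhaustive
#' @return data.frame with `start` and `n_mismatch`.
#' @export
scan_seeded <- function(query, subject, max_mismatch = 4L) {
  stopifnot(max_mismatch >= 0)
  q <- encode_nt(query)
  s <- encode_nt(subject)
  m <- length(q); n <- length(s)
  if (m == 0L || m > n) {
    return(data.frame(start = integer(), n_mismatch = integer()))
  }
  nseed <- max_mismatch + 1L
  if (nseed > m) {
    return(scan_exhaustive(query, subject, max_mismatch))
  }
  bounds <- as.integer(floor(seq(0L, m, length.out = nseed + 1L)))
  cand <- integer(0)
  for (k in seq_len(nseed)) {
    a <- bounds[k] + 1L; b <- bounds[k + 1L]
    sl <- b - a + 1L
    noff2 <- n - sl + 1L
    ok <- rep(TRUE, noff2)
    for (p in seq_len(sl)) {
      col <- s[p:(p + noff2 - 1L)]
      qc <- q[a + p - 1L]
      ok <- ok & col == qc & col != 0L & qc != 0L
    }
    starts <- which(ok) - (a - 1L)
    cand <- c(cand, starts[starts >= 1L & starts <= n - m + 1L])
  }
  cand <- sort(unique(cand))
  if (!length(cand)) {
    return(data.frame(start = integer(), n_mismatch = integer()))
  }
  nm <- vapply(cand, function(st) {
    win <- s[st:(st + m - 1L)]
    sum(win != q | win == 0L | q == 0L)
  }, integer(1))
  keep <- nm <= max_mismatch
  data.frame(start = cand[keep], n_mismatch = as.integer(nm[keep]))
}

#' Scan input sequences for homologs of mature miRNAs
#'
#' The plus strand scans each mature miRNA against the forward sequence;
#' with `strands = "both"` the reverse strand is scanned against the
#' reverse complement and hits are mapped back to forward coordinates.
#' Overlapping hits of different miRNAs are all reported.
#'
#' @param records Validated sequence records.
#' @param mirnas Mature miRNA table ([read_mirna_fasta()]).
#' @param max_mismatch Maximum mismatches per hit (default 4).
#' @param strands `"plus_only"` (default, as in the reference runs) or
#'   `"both"`.
#' @param scanner `"seeded"` (default) or `"exhaustive"`; identical
#'   output, different speed.
#' @return data.frame of hits: `seq_id`, `mirna_id`, `family`, `start`,
#'   `end`, `strand`, `n_mismatch`, `matched_text`, sorted by
#'   `(seq_id, start, mirna_id)`. Coordinates are 1-based inclusive on
#'   the forward sequence.
#' @export
run_homolog_search <- function(records, mirnas, max_mismatch = 4L,
                               strands = c("plus_only", "both"),
                               scanner = c("seeded", "exhaustive")) {
  strands <- match.arg(strands)
  scanner <- match.arg(scanner)
  if (nrow(mirnas) == 0L) {
    stop("run_homolog_search: empty mature miRNA reference")
  }
  scan_fun <- if (scanner == "seeded") scan_seeded else scan_exhaustive
  out <- list()
  for (ri in seq_len(nrow(records))) {
    subj <- records$seq[ri]
    subj_rc <- if (strands == "both") reverse_complement(subj) else NULL
    n <- nchar(subj)
    for (mi in seq_len(nrow(mirnas))) {
      qlen <- mirnas$length[mi]
      hits <- scan_fun(mirnas$seq[mi], subj, max_mismatch)
      if (nrow(hits)) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = records$id[ri], mirna_id = mirnas$id[mi],
          family = mirnas$family[mi], start = hits$start,
          end = hits$start + qlen - 1L, strand = "+",
          n_mismatch = hits$n_mismatch,
          matched_text = substring(subj, hits$start, hits$start + qlen - 1L),
          stringsAsFactors = FALSE)
      }
      if (!is.null(subj_rc)) {
        hits <- scan_fun(mirnas$seq[mi], subj_rc, max_mismatch)
        if (nrow(hits)) {
          fstart <- n - (hits$start + qlen - 1L) + 1L
          out[[length(out) + 1L]] <- data.frame(
            seq_id = records$id[ri], mirna_id = mirnas$id[mi],
            family = mirnas$family[mi], start = fstart,
            end = fstart + qlen - 1L, strand = "-",
            n_mismatch = hits$n_mismatch,
            matched_text = substring(subj_rc, hits$start,
                                     hits$start + qlen - 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(), mirna_id = character(),
                      family = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_mismatch = integer(), matched_text = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$seq_id, res$start, res$mirna_id), , drop = FALSE]
}
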