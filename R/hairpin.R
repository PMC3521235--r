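#' Parse a dot-bracket structure into a pair table
#'
#' @param structure Dot-bracket text over `.`, `(`, `)`.
#' @return A list with `n` (length) and `partner` (integer vector; 0 means
#'   unpaired). `partner` is symmetric and pairs are nested.
#' @export
parse_dotbracket <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (length(chars) && any(!chars %in% c(".", "(", ")"))) {
    stop("parse_dotbracket: invalid character in structure")
  }
  n <- length(chars)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("parse_dotbracket: unbalanced brackets")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("parse_dotbracket: unbalanced brackets")
  list(n = n, partner = partner)
}

#' Render a pair table back to dot-bracket text
#'
#' @param pt A pair table from [parse_dotbracket()].
#' @return Dot-bracket string.
#' @export
render_dotbracket <- function(pt) {
  out <- rep(".", pt$n)
  paired <- which(pt$partner > 0)
  out[paired[pt$partner[paired] > paired]] <- "("
  out[paired[pt$partner[paired] < paired]] <- ")"
  paste(out, collapse = "")
}

#' Precursor hairpin statistics: GC%, AMFE and MFEI
#'
#' AMFE is the folding energy normalized per 100 nt; MFEI divides AMFE by
#' the GC percentage. MFEI is the classical index separating plant miRNA
#' precursors from other non-coding RNAs; it is stored signed (negative
#' for any paired structure).
#'
#' @param seq Precursor sequence.
#' @param fold Fold result for `seq` ([fold_sequence()]).
#' @return List with `gc_percent`, `amfe`, `mfei` (`NA` when GC is zero).
#' @export
compute_stats <- function(seq, fold) {
  len <- nchar(seq)
  if (len == 0L) stop("compute_stats: zero-length sequence")
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  gc <- 100 * sum(bases %in% c("G", "C")) / len
  amfe <- fold$mfe / len * 100
  mfei <- if (gc > 0) amfe / gc else NA_real_
  list(gc_percent = gc, amfe = amfe, mfei = mfei)
}

# hairpin (terminal) loops: pairs (i,j) with no paired position inside
hairpin_loop_pairs <- function(pt, region = c(1L, pt$n)) {
  loops <- list()
  for (i in seq(region[1], region[2])) {
    j <- pt$partner[i]
    if (j > i && j <= region[2]) {
      inside <- if (j - i > 1L) pt$partner[(i + 1L):(j - 1L)] else integer(0)
      if (all(inside == 0L)) loops[[length(loops) + 1L]] <- c(i, j)
    }
  }
  loops
}

#' Does a structure region contain a multi-loop?
#'
#' True when the region holds more than one terminal (hairpin) loop,
#' i.e. some closing pair encloses two or more helices. Valid plant
#' pre-miRNA stem-loops must be single-hairpin.
#'
#' @param pt Pair table.
#' @param region Two-element `(start, end)` span (default: whole
#'   structure).
#' @return Logical flag.
#' @export
is_multiloop <- function(pt, region = c(1L, pt$n)) {
  length(hairpin_loop_pairs(pt, region)) > 1L
}

#' Is the mature miRNA confined to one arm of the hairpin?
#'
#' The mature span must not touch the terminal-loop interior, and every
#' paired mature position must pair across the terminal loop into the
#' opposite arm.
#'
#' @param pt Pair table of the structure.
#' @param mature_span Two-element `(start, end)` 1-based span.
#' @return List with `one_arm` (flag) and `arm` (`"5p"`, `"3p"`, or `NA`).
#' @export
mature_in_one_arm <- function(pt, mature_span) {
  loops <- hairpin_loop_pairs(pt)
  if (length(loops) != 1L) {
    return(list(one_arm = FALSE, arm = NA_character_))
  }
  hi <- loops[[1]][1]; hj <- loops[[1]][2]
  ms <- mature_span[1]; me <- mature_span[2]
  pos <- ms:me
  if (any(pos > hi & pos < hj)) {
    return(list(one_arm = FALSE, arm = NA_character_))
  }
  arm <- if (me <= hi) "5p" else if (ms >= hj) "3p" else NA_character_
  if (is.na(arm)) return(list(one_arm = FALSE, arm = NA_character_))
  partners <- pt$partner[pos]
  partners <- partners[partners > 0]
  opposite <- if (arm == "5p") all(partners >= hj) else all(partners <= hi)
  if (!opposite) return(list(one_arm = FALSE, arm = NA_character_))
  list(one_arm = TRUE, arm = arm)
}

#' Locate the miRNA* span opposite a mature miRNA
#'
#' Reads the pair table of the (first-pass) structure: the star spans the
#' partners of the outermost paired mature positions, extended by the
#' two-nucleotide 3' overhang at its 3' end and clamped to the sequence.
#'
#' @param pt Pair table.
#' @param mature_span `(start, end)` of the mature hit, mature in one arm.
#' @return `(start, end)` span of the star, 1-based inclusive.
#' @export
locate_star <- function(pt, mature_span) {
  ms <- mature_span[1]; me <- mature_span[2]
  pos <- ms:me
  paired <- pos[pt$partner[pos] > 0]
  if (!length(paired)) {
    stop("locate_star: mature region entirely unpaired (no_duplex)")
  }
  i_prime <- min(paired)           # first paired position >= mature start
  j_prime <- max(paired)           # first paired position <= mature end
  lo <- min(pt$partner[i_prime], pt$partner[j_prime])
  hi <- max(pt$partner[i_prime], pt$partner[j_prime]) + 2L
  hi <- min(hi, pt$n)
  lo <- max(lo, 1L)
  c(lo, hi)
}

#' Excise a stem-loop precursor around a homolog hit (Auto mode)
#'
#' Cleaves from the start of the homologous mature miRNA to the end of
#' its miRNA* duplex partner with the two-nucleotide 3' overhang (either
#' arm orientation).
#'
#' @param record One sequence record (single row).
#' @param fold Fold result of the full (primary) sequence.
#' @param hit One homolog hit row with `start`, `end`.
#' @return List with `pre_span` on the source and `pre_seq`.
#' @export
excise_stemloop_auto <- function(record, fold, hit) {
  pt <- parse_dotbracket(fold$structure)
  mature_span <- c(hit$start, hit$end)
  star <- locate_star(pt, mature_span)
  span <- c(min(mature_span[1], star[1]), max(mature_span[2], star[2]))
  list(pre_span = span,
       pre_seq = substr(record$seq, span[1], span[2]))
}

#' Excise a precursor at user-supplied positions (Manual mode)
#'
#' @param record One sequence record.
#' @param start,stop 1-based inclusive cleavage positions.
#' @return List with `pre_span` and `pre_seq`.
#' @export
excise_stemloop_manual <- function(record, start, stop) {
  stopifnot(start >= 1, stop <= nchar(record$seq), start < stop)
  list(pre_span = c(start, stop),
       pre_seq = substr(record$seq, start, stop))
}

#' miRNA:miRNA* duplex statistics on a refolded precursor
#'
#' Walks the mature region 5' to 3'. Opposed unpaired positions flanked by
#' pairs count as duplex mismatches (one per opposed pair); an unpaired
#' run on one strand only is a bulge (count 1, size = run length); an
#' asymmetric interior loop contributes `min(r, g)` mismatches plus one
#' bulge of size `|r - g|`. G:U wobbles are pairs here, not mismatches.
#' `n_overhang2` counts duplex ends (0, 1 or 2) showing exactly a 2-nt 3'
#' overhang with a flush opposing 5' end.
#'
#' @param pt Pair table of the refolded precursor.
#' @param mature_span,star_span 1-based spans on the precursor.
#' @return List: `duplex_mismatches`, `n_bulges`, `max_bulge_size`,
#'   `n_overhang2`.
#' @export
duplex_stats <- function(pt, mature_span, star_span) {
  ms <- mature_span[1]; me <- mature_span[2]
  pos <- ms:me
  paired <- pos[pt$partner[pos] > 0]
  mism <- 0L; n_bulge <- 0L; max_bulge <- 0L
  if (length(paired) >= 2L) {
    for (idx in seq_len(length(paired) - 1L)) {
      a <- paired[idx]; b <- paired[idx + 1L]
      gap_m <- b - a - 1L
      gap_s <- abs(pt$partner[a] - pt$partner[b]) - 1L
      if (gap_m == 0L && gap_s == 0L) next
      mism <- mism + min(gap_m, gap_s)
      if (gap_m != gap_s) {
        n_bulge <- n_bulge + 1L
        max_bulge <- max(max_bulge, abs(gap_m - gap_s))
      }
    }
  }
  list(duplex_mismatches = mism, n_bulges = n_bulge,
       max_bulge_size = max_bulge,
       n_overhang2 = count_overhang2(pt, mature_span, star_span))
}

count_overhang2 <- function(pt, mature_span, star_span) {
  spans <- if (mature_span[1] < star_span[1]) {
    list(L = mature_span, R = star_span)
  } else {
    list(L = star_span, R = mature_span)
  }
  paired_in <- function(span) {
    pos <- span[1]:span[2]
    pos[pt$partner[pos] > 0]
  }
  pl <- paired_in(spans$L); pr <- paired_in(spans$R)
  if (!length(pl) || !length(pr)) return(0L)
  n <- 0L
  # outer end: R's 3' protrusion of exactly 2 nt, L's 5' end flush
  if ((spans$R[2] - max(pr)) == 2L && (min(pl) - spans$L[1]) == 0L) n <- n + 1L
  # loop end: L's 3' protrusion of exactly 2 nt, R's 5' end flush
  if ((spans$L[2] - max(pl)) == 2L && (min(pr) - spans$R[1]) == 0L) n <- n + 1L
  n
}

#' Default plant precursor validation thresholds
#'
#' Multi-loop structures and mature sequences not confined to one arm are
#' always rejected. The remaining knobs follow the conventional plant
#' miRNA precursor criteria: `|MFEI| >= 0.85`, at most 4 miRNA:miRNA*
#' duplex mismatches, at most 2 bulges of at most 2 nt each; 2-nt 3'
#' overhangs are reported but not required by default (excision clamping
#' at sequence ends can truncate them on partial transcripts).
#'
#' @param min_abs_mfei Minimum `|MFEI|`.
#' @param max_duplex_mismatches Maximum miRNA:miRNA* mismatches.
#' @param max_bulges Maximum number of bulges in the duplex.
#' @param max_bulge_size Maximum single-bulge size in nt.
#' @param require_overhangs Minimum count of exact 2-nt 3' overhangs
#'   (0, 1 or 2; default 0).
#' @return A list of class `precursor_filters`.
#' @export
precursor_filters <- function(min_abs_mfei = 0.85,
                              max_duplex_mismatches = 4L,
                              max_bulges = 2L,
                              max_bulge_size = 2L,
                              require_overhangs = 0L) {
  stopifnot(min_abs_mfei >= 0, max_duplex_mismatches >= 0,
            max_bulges >= 0, max_bulge_size >= 0,
            require_overhangs %in% 0:2)
  structure(list(min_abs_mfei = min_abs_mfei,
                 max_duplex_mismatches = max_duplex_mismatches,
                 max_bulges = max_bulges,
                 max_bulge_size = max_bulge_size,
                 require_overhangs = require_overhangs),
            class = "precursor_filters")
}

#' Apply precursor validation filters to hairpin candidates
#'
#' @param cands Candidate table from [hairpin_candidates()].
#' @param filters A [precursor_filters()] object.
#' @return List with `accepted` and `rejected` candidate tables; rejected
#'   rows carry the first failing `reason`.
#' @export
filter_precursors <- function(cands, filters = precursor_filters()) {
  reason <- rep(NA_character_, nrow(cands))
  for (i in seq_len(nrow(cands))) {
    r <- cands[i, ]
    reason[i] <-
      if (!is.na(r$reject_reason) && nzchar(r$reject_reason)) r$reject_reason
      else if (isTRUE(r$multiloop)) "multiloop"
      else if (!isTRUE(r$mature_one_arm)) "not_one_arm"
      else if (is.na(r$mfei)) "zero_gc"
      else if (abs(r$mfei) < filters$min_abs_mfei) "mfei"
      else if (r$duplex_mismatches > filters$max_duplex_mismatches) "duplex_mismatches"
      else if (r$n_bulges > filters$max_bulges) "bulges"
      else if (r$max_bulge_size > filters$max_bulge_size) "bulge_size"
      else if (r$n_overhang2 < filters$require_overhangs) "overhangs"
      else NA_character_
  }
  keep <- is.na(reason)
  rejected <- cands[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  list(accepted = cands[keep, , drop = FALSE], rejected = rejected)
}

#' Build validated hairpin candidates from homolog hits
#'
#' For each hit: fold the source (primary) sequence, excise the stem-loop
#' around the mature hit with its star partner (Auto mode), refold the
#' excised precursor, re-map the mature to precursor coordinates, relocate
#' the star on the refolded structure, and collect all validation
#' statistics. Candidates that fail structurally (unpaired mature, star
#' localization failure) are returned with a `reject_reason` so
#' [filter_precursors()] reports them.
#'
#' @param records Validated sequence records.
#' @param hits Homolog hits ([run_homolog_search()]).
#' @param params [fold_params()] used for both folding passes.
#' @param engine Folding engine (`"builtin"` or `"thermo"`).
#' @return One candidate data.frame row per hit.
#' @export
hairpin_candidates <- function(records, hits, params = fold_params(),
                               engine = "builtin") {
  fold_cache <- new.env(parent = emptyenv())
  fold_once <- function(id, seq) {
    if (is.null(fold_cache[[id]])) {
      fold_cache[[id]] <- fold_sequence(seq, params, engine)
    }
    fold_cache[[id]]
  }
  rows <- lapply(seq_len(nrow(hits)), function(k) {
    hit <- hits[k, ]
    rec <- records[records$id == hit$seq_id, , drop = FALSE][1, ]
    pri_fold <- fold_once(rec$id, rec$seq)
    base <- list(
      source_id = rec$id, mirna_id = hit$mirna_id,
      pre_seq = NA_character_, pre_structure = NA_character_,
      pre_start = NA_integer_, pre_end = NA_integer_,
      mature_start = NA_integer_, mature_end = NA_integer_,
      star_start = NA_integer_, star_end = NA_integer_,
      mfe = NA_real_, amfe = NA_real_, mfei = NA_real_,
      gc_percent = NA_real_, n_overhang2 = NA_integer_,
      duplex_mismatches = NA_integer_, n_bulges = NA_integer_,
      max_bulge_size = NA_integer_, multiloop = NA,
      mature_one_arm = NA, arm = NA_character_,
      reject_reason = NA_character_)
    exc <- tryCatch(excise_stemloop_auto(rec, pri_fold, hit),
                    error = function(e) NULL)
    if (is.null(exc)) {
      base$reject_reason <- "no_duplex"
      return(as.data.frame(base, stringsAsFactors = FALSE))
    }
    pre_seq <- exc$pre_seq
    pre_fold <- fold_sequence(pre_seq, params, engine)
    pt <- parse_dotbracket(pre_fold$structure)
    mature <- c(hit$start, hit$end) - exc$pre_span[1] + 1L
    stats <- compute_stats(pre_seq, pre_fold)
    one_arm <- mature_in_one_arm(pt, mature)
    base$pre_seq <- pre_seq
    base$pre_structure <- pre_fold$structure
    base$pre_start <- exc$pre_span[1]; base$pre_end <- exc$pre_span[2]
    base$mature_start <- mature[1]; base$mature_end <- mature[2]
    base$mfe <- pre_fold$mfe
    base$amfe <- stats$amfe; base$mfei <- stats$mfei
    base$gc_percent <- stats$gc_percent
    base$multiloop <- is_multiloop(pt)
    base$mature_one_arm <- one_arm$one_arm
    base$arm <- one_arm$arm
    if (one_arm$one_arm) {
      star <- tryCatch(locate_star(pt, mature), error = function(e) NULL)
      if (is.null(star)) {
        base$reject_reason <- "no_duplex"
      } else {
        ds <- duplex_stats(pt, mature, star)
        base$star_start <- star[1]; base$star_end <- star[2]
        base$n_overhang2 <- ds$n_overhang2
        base$duplex_mismatches <- ds$duplex_mismatches
        base$n_bulges <- ds$n_bulges
        base$max_bulge_size <- ds$max_bulge_size
      }
    }
    as.data.frame(base, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
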