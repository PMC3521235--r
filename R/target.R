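#' Target scanning configuration
#'
#' The binding score is a weighted count over the antiparallel
#' miRNA:site alignment: each mismatch costs 1.0, each G:U wobble 0.5
#' and each single-nucleotide gap 2.0 by default (the miRU/psRNATarget
#' convention). Sites scoring above `max_score` are dropped. The
#' positional rules (at most one mismatch in positions 1-9, no mismatch
#' at positions 10 or 11, no three consecutive mismatches, counting from
#' the miRNA 5' end) are applied by default and can be switched off.
#'
#' @param max_score Maximum binding score kept (default 4.0; the
#'   reference's customized runs use 6.0).
#' @param weights Named numeric vector `c(mismatch=, gu=, gap=)`.
#' @param max_gaps Maximum single-nt gaps per site (default 1).
#' @param position_rules_on Apply the positional mismatch rules
#'   (default TRUE).
#' @param strands `"plus_only"` (default) or `"both"`.
#' @return A list of class `target_scan_config`.
#' @export
target_scan_config <- function(max_score = 4.0,
                               weights = c(mismatch = 1.0, gu = 0.5,
                                           gap = 2.0),
                               max_gaps = 1L,
                               position_rules_on = TRUE,
                               strands = c("plus_only", "both")) {
  strands <- match.arg(strands)
  stopifnot(max_score >= 0, all(weights >= 0),
            all(c("mismatch", "gu", "gap") %in% names(weights)),
            max_gaps >= 0)
  structure(list(max_score = max_score, weights = weights,
                 max_gaps = max_gaps,
                 position_rules_on = position_rules_on,
                 strands = strands),
            class = "target_scan_config")
}

#' Classify aligned miRNA/site positions
#'
#' Position p (1 = miRNA 5' end) faces the site read 3' to 5'
#' (antiparallel). Watson-Crick oppositions are `match`; miRNA G against
#' site U/T or miRNA U/T against site G are `GU`; anything else
#' (including N) is `mismatch`.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param site Site sequence on the transcript, 5' to 3', equal length.
#' @return Character vector of labels along the miRNA.
#' @export
classify_positions <- function(mirna, site) {
  a <- encode_nt(mirna)
  b <- encode_nt(site)
  if (length(a) != length(b)) {
    stop("classify_positions: sequences must have equal length")
  }
  b <- rev(b)  # antiparallel: miRNA position p faces site position L-p+1
  classify_codes(a, b)
}

# a = miRNA codes 5'->3', b = opposed site codes (already reversed)
classify_codes <- function(a, b) {
  lab <- rep("mismatch", length(a))
  wc <- (a == 1L & b == 4L) | (a == 4L & b == 1L) |
        (a == 2L & b == 3L) | (a == 3L & b == 2L)
  gu <- (a == 3L & b == 4L) | (a == 4L & b == 3L)
  lab[gu] <- "GU"
  lab[wc] <- "match"
  lab
}

#' Score a classified site
#'
#' @param labels Labels from [classify_positions()]; `gap` entries mark
#'   gapped positions.
#' @param weights Named weights (`mismatch`, `gu`, `gap`).
#' @return List: `score`, `n_mismatch`, `n_gu`, `n_gap`,
#'   `mismatch_positions` (1-based on the miRNA).
#' @export
score_site <- function(labels, weights = c(mismatch = 1.0, gu = 0.5,
                                           gap = 2.0)) {
  n_mismatch <- sum(labels == "mismatch")
  n_gu <- sum(labels == "GU")
  n_gap <- sum(labels == "gap")
  list(score = n_mismatch * weights[["mismatch"]] +
         n_gu * weights[["gu"]] + n_gap * weights[["gap"]],
       n_mismatch = n_mismatch, n_gu = n_gu, n_gap = n_gap,
       mismatch_positions = which(labels == "mismatch"))
}

#' Positional mismatch rules for plant miRNA target sites
#'
#' Counting from the miRNA 5' end: fail when positions 1-9 hold more
#' than one mismatch, when position 10 or 11 holds any mismatch, or when
#' three or more mismatches run consecutively. G:U wobbles and gaps are
#' not mismatches for these rules.
#'
#' @param labels Position labels.
#' @return List: `pass` flag and `violated_rule`
#'   (`"max_one_in_1_9"`, `"none_at_10_11"`, `"no_3_consecutive"`, or
#'   `NA`). The first violated rule (in that order) is reported.
#' @export
position_rule_filter <- function(labels) {
  mm <- labels == "mismatch"
  L <- length(labels)
  if (sum(mm[seq_len(min(9L, L))]) > 1L) {
    return(list(pass = FALSE, violated_rule = "max_one_in_1_9"))
  }
  if (L >= 10L && any(mm[10:min(11L, L)])) {
    return(list(pass = FALSE, violated_rule = "none_at_10_11"))
  }
  r <- rle(mm)
  if (any(r$values & r$lengths >= 3L)) {
    return(list(pass = FALSE, violated_rule = "no_3_consecutive"))
  }
  list(pass = TRUE, violated_rule = NA_character_)
}

empty_sites <- function() {
  data.frame(target_id = character(), mirna_id = character(),
             family = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(),
             n_mismatch = integer(), n_gu = integer(), n_gap = integer(),
             mismatch_positions = character(), alignment = character(),
             duplex_mfe = numeric(), overlap_fraction = numeric(),
             stringsAsFactors = FALSE)
}

# Evaluate a candidate window at transcript offset `st` for one miRNA.
# Tries the ungapped alignment first; when it fails the score cutoff and
# gaps are allowed, evaluates every placement of one single-nt gap in
# either strand and keeps the best-scoring alignment (deterministic
# tie-break: fewer gaps, then site-gap before miRNA-gap, then smallest
# gap position). Returns NULL when nothing passes.
evaluate_site <- function(mirna_codes, subj_codes, st, cfg) {
  L <- length(mirna_codes)
  n <- length(subj_codes)
  best <- NULL
  consider <- function(labels, start, end) {
    sc <- score_site(labels, cfg$weights)
    if (sc$score > cfg$max_score) return(NULL)
    if (cfg$position_rules_on && !position_rule_filter(labels)$pass) {
      return(NULL)
    }
    c(sc, list(labels = labels, start = start, end = end))
  }
  if (st + L - 1L <= n) {
    win <- rev(subj_codes[st:(st + L - 1L)])
    cand <- consider(classify_codes(mirna_codes, win), st, st + L - 1L)
    if (!is.null(cand)) return(cand)
  }
  if (cfg$max_gaps < 1L) return(NULL)
  # gap in the site: one miRNA position faces no site base (window L-1)
  if (st + L - 2L <= n) {
    win <- rev(subj_codes[st:(st + L - 2L)])
    for (g in seq_len(L)) {
      labels <- classify_codes(mirna_codes[-g], win)
      full <- character(L)
      full[-g] <- labels
      full[g] <- "gap"
      cand <- consider(full, st, st + L - 2L)
      if (!is.null(cand) && (is.null(best) || cand$score < best$score)) {
        best <- cand
      }
    }
  }
  # gap in the miRNA: one extra site base is bulged out (window L+1)
  if (st + L <= n) {
    win_full <- rev(subj_codes[st:(st + L)])
    for (g in seq_len(L + 1L)) {
      opp <- win_full[-g]
      labels <- classify_codes(mirna_codes, opp)
      full <- c(labels, "gap")
      cand <- consider(full, st, st + L)
      if (!is.null(cand) && (is.null(best) || cand$score < best$score)) {
        best <- cand
      }
    }
  }
  best
}

#' Scan transcripts for miRNA complementary target sites
#'
#' For each mature miRNA the reverse complement is scanned against each
#' transcript with the lossless seeded scanner at a mismatch budget of
#' `floor(max_score / min positive weight)`, which cannot miss any
#' window scoring within `max_score` (every non-Watson-Crick opposition
#' costs at least the minimum weight). Candidate windows are then
#' classified position by position, scored, and kept when the score is
#' within `max_score` and (by default) the positional rules pass. When
#' gaps are allowed, additional candidates are seeded from the two query
#' halves so a one-gap site with one clean half is still found.
#'
#' @param records Validated transcript records (target pipeline length
#'   cap 20000 nt).
#' @param mirnas Mature miRNA table.
#' @param cfg A [target_scan_config()].
#' @return data.frame of target sites with per-site score decomposition;
#'   `duplex_mfe` and `overlap_fraction` are `NA` until
#'   [refine_with_duplex()].
#' @export
scan_targets <- function(records, mirnas, cfg = target_scan_config()) {
  if (nrow(mirnas) == 0L) {
    stop("scan_targets: empty mature miRNA reference")
  }
  min_w <- min(cfg$weights[cfg$weights > 0])
  budget <- as.integer(floor(cfg$max_score / min_w))
  out <- list()
  for (ri in seq_len(nrow(records))) {
    subj <- records$seq[ri]
    subj_codes <- encode_nt(subj)
    for (mi in seq_len(nrow(mirnas))) {
      mirna_seq <- mirnas$seq[mi]
      mirna_codes <- encode_nt(mirna_seq)
      query <- reverse_complement(mirna_seq)
      L <- nchar(query)
      starts <- scan_seeded(query, subj, budget)$start
      gap_w <- cfg$weights[["gap"]]
      if (cfg$max_gaps >= 1L && L >= 2L && gap_w <= cfg$max_score) {
        # a one-gap site keeps one gap-free half whose non-WC cost is
        # at most max_score - gap weight
        half_budget <- as.integer(floor((cfg$max_score - gap_w) / min_w))
        half <- L %/% 2L
        h1 <- substr(query, 1L, half)
        h2 <- substr(query, half + 1L, L)
        s1 <- scan_seeded(h1, subj, half_budget)$start
        s2 <- scan_seeded(h2, subj, half_budget)$start - half
        extra <- unique(c(s1, s2, s1 - 1L, s1 + 1L, s2 - 1L, s2 + 1L))
        starts <- sort(unique(c(starts, extra)))
        starts <- starts[starts >= 1L & starts <= nchar(subj)]
      }
      for (st in starts) {
        cand <- evaluate_site(mirna_codes, subj_codes, st, cfg)
        if (is.null(cand)) next
        out[[length(out) + 1L]] <- data.frame(
          target_id = records$id[ri], mirna_id = mirnas$id[mi],
          family = mirnas$family[mi],
          start = cand$start, end = cand$end, strand = "+",
          score = cand$score, n_mismatch = cand$n_mismatch,
          n_gu = cand$n_gu, n_gap = cand$n_gap,
          mismatch_positions = paste(cand$mismatch_positions,
                                     collapse = ","),
          alignment = paste(cand$labels, collapse = "|"),
          duplex_mfe = NA_real_, overlap_fraction = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_sites())
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[c("target_id", "mirna_id", "start", "end")]), ]
  res[order(res$target_id, res$start, res$mirna_id), , drop = FALSE]
}

#' Refine scanned target sites with miRNA:site duplex folding
#'
#' Annotates each site with the hybridization energy of the miRNA
#' against the site substring and the fraction of the scanned span
#' covered by duplex pairing positions. No site is removed; refinement
#' only annotates.
#'
#' @param sites Sites from [scan_targets()].
#' @param records The transcript records the sites were scanned on.
#' @param mirnas Mature miRNA table.
#' @param temperature Duplex folding temperature (default 37).
#' @param engine `"builtin"` or `"thermo"`.
#' @return `sites` with `duplex_mfe` and `overlap_fraction` filled in.
#' @export
refine_with_duplex <- function(sites, records, mirnas, temperature = 37,
                               engine = "builtin") {
  for (i in seq_len(nrow(sites))) {
    rec <- records[records$id == sites$target_id[i], , drop = FALSE][1, ]
    mir <- mirnas[mirnas$id == sites$mirna_id[i], , drop = FALSE][1, ]
    site_seq <- substr(rec$seq, sites$start[i], sites$end[i])
    dup <- fold_duplex(mir$seq, site_seq, temperature, engine)
    sites$duplex_mfe[i] <- dup$mfe
    span_len <- sites$end[i] - sites$start[i] + 1L
    covered <- unique(dup$pairing[, "site_pos"])
    sites$overlap_fraction[i] <- length(covered) / span_len
  }
  sites
}
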