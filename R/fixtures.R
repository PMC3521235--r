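# Seeded generators for planted ground-truth data: pri-miRNA hairpins,
# decoys, and transcripts with planted complementary sites. Every
# generator is a pure function of its seed and spec: the global RNG
# state is saved and restored.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

revcomp_dna <- function(seq) {
  chartr("U", "T", reverse_complement(chartr("U", "T", seq)))
}

# Mature miRNAs in plants are AU-rich; sample ~30% GC (clamped to 5-7 GC
# in 21 nt) so planted precursors clear the MFEI gate under the builtin
# -1/pair energy proxy. The three stem bases flanking the terminal loop
# are kept A/T-free of G and the three outer stem bases G/C-free of T
# (arm-dependent), so the all-C loop and all-A flanks cannot trade
# count-neutral pairs with the stem boundary: the designed stem is then
# the unique base-pair-maximal structure.
sample_mature <- function(len = 21L, arm = "5p") {
  repeat {
    s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.325, 0.175, 0.175, 0.325))
    head_ok <- s[1:3] %in% c("C", "G")
    tail_ok <- s[(len - 2):len] %in% c("A", "T")
    if (arm == "3p") {
      head_ok <- s[1:3] %in% c("A", "T")
      tail_ok <- s[(len - 2):len] %in% c("C", "G")
    }
    if (!all(head_ok) || !all(tail_ok)) next
    gc <- sum(s %in% c("G", "C"))
    if (gc >= 5L && gc <= 7L) return(paste(s, collapse = ""))
  }
}

sample_flank <- function(len) {
  strrep("A", len)
}

loop_seq <- function(len) {
  strrep("C", len)
}

# substitution that can neither Watson-Crick nor wobble pair with `base`
non_pairing_base <- function(base) {
  switch(chartr("U", "T", base),
         A = "C", C = "A", G = "A", T = "C")
}

#' Generate a pri-miRNA sequence with a planted hairpin
#'
#' The sequence is `flank5 + mature + loop + star + flank3` (arm order
#' swapped for `arm = "3p"`), where the star arm is the reverse
#' complement of the mature sequence with the requested stem
#' perturbations applied. The loop is all-C and the flanks poly-A (these
#' cannot pair with each other or themselves), and auto-sampled mature
#' sequences are rejection-sampled until the built-in fold reproduces
#' the designed stem exactly, so the recorded truth holds under folding.
#'
#' @param mature_seq Mature miRNA (DNA letters); `NULL` samples a 21-nt
#'   AU-rich one.
#' @param arm `"5p"` or `"3p"`: which arm carries the mature miRNA.
#' @param loop_len Terminal loop length (>= 4; default 8).
#' @param flank5_len,flank3_len Flank lengths (default 10; at least 2 on
#'   the star-overhang side).
#' @param perturbations List of `list(type, offset, size)` with type
#'   `"sym_mismatch"` or `"bulge"` (a bulge deletes `size` star bases so
#'   the opposed mature stretch bulges out); `offset` is a mature
#'   position, kept within 3..(L-2).
#' @param seed Integer seed.
#' @return List with `record` (one-row record table) and `truth`
#'   (mature/star/precursor spans on the source, expected duplex
#'   statistics and expected MFEI under the builtin energy proxy).
#' @export
make_hairpin <- function(mature_seq = NULL, arm = c("5p", "3p"),
                         loop_len = 8L, flank5_len = 10L,
                         flank3_len = 10L, perturbations = list(),
                         seed = 1L) {
  arm <- match.arg(arm)
  stopifnot(loop_len >= 4L)
  with_seed(seed, {
    fixed_mature <- !is.null(mature_seq)
    for (attempt in seq_len(50L)) {
      out <- hairpin_attempt(
        if (fixed_mature) chartr("U", "T", toupper(mature_seq))
        else sample_mature(arm = arm),
        arm, loop_len, flank5_len, flank3_len, perturbations, seed)
      if (!is.null(out)) return(out)
      if (fixed_mature) break
    }
    stop("make_hairpin: rejection-sampling bound exceeded")
  })
}

hairpin_attempt <- function(mature_seq, arm, loop_len, flank5_len,
                            flank3_len, perturbations, seed) {
  {
    L <- nchar(mature_seq)
    for (p in perturbations) {
      stopifnot(p$type %in% c("sym_mismatch", "bulge"),
                p$offset >= 3L, p$offset + (p$size %||% 1L) - 1L <= L - 2L)
    }
    mat_chars <- strsplit(mature_seq, "", fixed = TRUE)[[1]]
    star_chars <- strsplit(revcomp_dna(mature_seq), "", fixed = TRUE)[[1]]
    # star index i faces mature position L - i + 1
    star_partner_of <- function(p) L - p + 1L
    unpaired_mature <- integer(0)
    drop_star <- integer(0)
    n_mm <- 0L; n_bulge <- 0L; max_bulge <- 0L
    for (p in perturbations) {
      if (p$type == "sym_mismatch") {
        i <- star_partner_of(p$offset)
        star_chars[i] <- non_pairing_base(mat_chars[p$offset])
        unpaired_mature <- c(unpaired_mature, p$offset)
        n_mm <- n_mm + 1L
      } else {
        size <- p$size %||% 1L
        offs <- p$offset:(p$offset + size - 1L)
        drop_star <- c(drop_star, star_partner_of(offs))
        unpaired_mature <- c(unpaired_mature, offs)
        n_bulge <- n_bulge + 1L
        max_bulge <- max(max_bulge, size)
      }
    }
    if (length(drop_star)) star_chars <- star_chars[-drop_star]
    star_arm <- paste(star_chars, collapse = "")
    Ls <- nchar(star_arm)
    loop <- loop_seq(loop_len)

    build <- function(f5, f3) {
      if (arm == "5p") {
        paste0(f5, mature_seq, loop, star_arm, f3)
      } else {
        paste0(f5, star_arm, loop, mature_seq, f3)
      }
    }
    if (arm == "5p") {
      mature_span <- c(flank5_len + 1L, flank5_len + L)
      arm_span <- c(flank5_len + L + loop_len + 1L,
                    flank5_len + L + loop_len + Ls)
    } else {
      arm_span <- c(flank5_len + 1L, flank5_len + Ls)
      mature_span <- c(flank5_len + Ls + loop_len + 1L,
                       flank5_len + Ls + loop_len + L)
    }
    total_len <- flank5_len + L + loop_len + Ls + flank3_len
    star_span <- c(arm_span[1], min(arm_span[2] + 2L, total_len))
    pre_span <- c(min(mature_span[1], star_span[1]),
                  max(mature_span[2], star_span[2]))

    # designed partner map of the full sequence
    designed <- integer(total_len)
    m_off <- mature_span[1] - 1L
    star_keep <- sort(setdiff(seq_len(L), drop_star))  # orig star indices kept
    for (k in seq_along(star_keep)) {
      p <- star_partner_of(star_keep[k])
      if (p %in% unpaired_mature) next
      designed[m_off + p] <- arm_span[1] - 1L + k
      designed[arm_span[1] - 1L + k] <- m_off + p
    }

    seq_txt <- build(sample_flank(flank5_len), sample_flank(flank3_len))
    fold <- nussinov_fold(seq_txt)
    pt <- parse_dotbracket(fold$structure)
    if (!identical(pt$partner, designed)) {
      return(NULL)
    }

    pre_seq <- substr(seq_txt, pre_span[1], pre_span[2])
    pre_len <- nchar(pre_seq)
    n_pairs <- sum(designed[mature_span[1]:mature_span[2]] > 0)
    gc <- 100 * lengths(regmatches(pre_seq, gregexpr("[GC]", pre_seq))) / pre_len
    amfe <- -n_pairs / pre_len * 100
    rec <- as_records(sprintf("hp_seed%d", seed), seq_txt)
    list(record = rec,
         truth = list(mature_seq = mature_seq, arm = arm,
                      mature_span = mature_span, star_span = star_span,
                      pre_span = pre_span,
                      duplex_mismatches = n_mm, n_bulges = n_bulge,
                      max_bulge_size = max_bulge,
                      expected_mfei = amfe / gc,
                      expected_gc = gc))
  }
}

#' Generate a decoy sequence with no planted miRNA
#'
#' @param length Decoy length (>= 50) for `mode = "uniform"`.
#' @param seed Integer seed.
#' @param mode `"uniform"` (i.i.d. A/C/G/T) or `"dinucleotide_shuffle"`
#'   of `source` (preserves all 16 dinucleotide counts; Altschul-Erikson
#'   Eulerian-path shuffle).
#' @param source Source sequence for the shuffle mode.
#' @return One-row record table.
#' @export
make_decoy <- function(length = 500L, seed = 1L,
                       mode = c("uniform", "dinucleotide_shuffle"),
                       source = NULL) {
  mode <- match.arg(mode)
  with_seed(seed, {
    seq_txt <- if (mode == "uniform") {
      stopifnot(length >= 50L)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    } else {
      stopifnot(!is.null(source))
      dinucleotide_shuffle(chartr("U", "T", toupper(source)))
    }
    as_records(sprintf("decoy_seed%d", seed), seq_txt)
  })
}

# Altschul-Erikson shuffle: random Eulerian path over the dinucleotide
# transition multigraph, keeping the first and last base fixed.
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  verts <- unique(ch)
  edges <- split(ch[-1], factor(ch[-n], levels = verts))
  last <- ch[n]
  repeat {
    # pick a candidate last edge for every vertex except the final one
    last_edge <- vapply(verts, function(v) {
      if (v == last || !length(edges[[v]])) NA_character_
      else sample(edges[[v]], 1L)
    }, character(1))
    # the chosen last edges must lead every vertex to the final vertex
    ok <- TRUE
    for (v in verts) {
      if (v == last || !length(edges[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  adj <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (!length(e)) return(character(0))
    if (v == last) return(sample(e))
    le <- last_edge[[v]]
    rest <- e[-match(le, e)]
    c(if (length(rest)) sample(rest) else character(0), le)
  })
  names(adj) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- adj[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Generate a transcript with a planted miRNA-complementary site
#'
#' The reverse complement of the miRNA is planted at `site_offset` in a
#' uniform-random background, then edited: `mismatch` substitutes a
#' non-pairing base opposite the given miRNA position, `gu` turns the
#' opposition into a G:U wobble (miRNA position must hold G or U/T),
#' `gap` deletes the opposed site base. The binding score implied by the
#' edits is recorded.
#'
#' @param mirna_seq Mature miRNA sequence.
#' @param background_len Transcript length (default 500).
#' @param site_offset 1-based plant position; `NULL` picks a random
#'   valid offset.
#' @param edits List of `list(position, type)` with type `"mismatch"`,
#'   `"gu"` or `"gap"`; positions are on the miRNA (1 = 5' end) and must
#'   not repeat.
#' @param weights Binding-score weights used for the expected score.
#' @param seed Integer seed.
#' @return List with `record` and `truth` (`site_span`, `score`,
#'   `n_mismatch`, `n_gu`, `n_gap`).
#' @export
make_target_transcript <- function(mirna_seq, background_len = 500L,
                                   site_offset = NULL, edits = list(),
                                   weights = c(mismatch = 1.0, gu = 0.5,
                                               gap = 2.0),
                                   seed = 1L) {
  with_seed(seed, {
    mirna_seq <- toupper(mirna_seq)
    L <- nchar(mirna_seq)
    pos_used <- vapply(edits, function(e) e$position, numeric(1))
    if (anyDuplicated(pos_used)) {
      stop("make_target_transcript: overlapping edits")
    }
    site <- strsplit(revcomp_dna(mirna_seq), "", fixed = TRUE)[[1]]
    mat_chars <- strsplit(chartr("U", "T", mirna_seq), "",
                          fixed = TRUE)[[1]]
    n_mm <- 0L; n_gu <- 0L; n_gap <- 0L
    drop <- integer(0)
    for (e in edits) {
      p <- e$position
      stopifnot(p >= 1L, p <= L)
      i <- L - p + 1L  # site index opposite miRNA position p
      if (e$type == "mismatch") {
        site[i] <- non_pairing_base(mat_chars[p])
        n_mm <- n_mm + 1L
      } else if (e$type == "gu") {
        site[i] <- switch(mat_chars[p],
                          G = "T", T = "G",
                          stop("gu edit needs G or U at miRNA position ", p))
        n_gu <- n_gu + 1L
      } else if (e$type == "gap") {
        drop <- c(drop, i)
        n_gap <- n_gap + 1L
      } else {
        stop("unknown edit type: ", e$type)
      }
    }
    if (length(drop)) site <- site[-drop]
    site_txt <- paste(site, collapse = "")
    slen <- nchar(site_txt)
    stopifnot(background_len >= slen)
    if (is.null(site_offset)) {
      site_offset <- sample.int(background_len - slen + 1L, 1L)
    }
    bg <- sample(c("A", "C", "G", "T"), background_len, replace = TRUE)
    seq_txt <- paste0(
      paste(bg[seq_len(site_offset - 1L)], collapse = ""),
      site_txt,
      paste(bg[seq_len(background_len - slen - site_offset + 1L) +
                 site_offset + slen - 1L], collapse = ""))
    score <- n_mm * weights[["mismatch"]] + n_gu * weights[["gu"]] +
      n_gap * weights[["gap"]]
    list(record = as_records(sprintf("tx_seed%d", seed), seq_txt),
         truth = list(site_span = c(site_offset, site_offset + slen - 1L),
                      score = score, n_mismatch = n_mm, n_gu = n_gu,
                      n_gap = n_gap))
  })
}

#' Write a batch of fixtures with their truth tables
#'
#' Generates `n_hairpins` planted hairpins, `n_decoys` uniform decoys
#' and `n_targets` transcripts with planted sites (for a freshly sampled
#' 21-nt miRNA per transcript), writing FASTA files plus TSV truth
#' tables under `outdir`.
#'
#' @param n_hairpins,n_decoys,n_targets Batch sizes.
#' @param seed Base seed; item k uses `seed * 1000 + k`.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_fixture_batch <- function(n_hairpins = 10L, n_decoys = 10L,
                                n_targets = 10L, seed = 1L,
                                outdir = "fixtures") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- seed * 1000L
  if (n_hairpins > 0L) {
    hp <- lapply(seq_len(n_hairpins),
                 function(k) make_hairpin(seed = base + k))
    write_fasta(do.call(rbind, lapply(hp, `[[`, "record")),
                file.path(outdir, "hairpins.fasta"))
    truth <- do.call(rbind, lapply(hp, function(h) {
      t <- h$truth
      data.frame(id = h$record$id, mature_seq = t$mature_seq,
                 mature_start = t$mature_span[1],
                 mature_end = t$mature_span[2],
                 star_start = t$star_span[1], star_end = t$star_span[2],
                 stringsAsFactors = FALSE)
    }))
    write_tsv(truth, file.path(outdir, "hairpins_truth.tsv"))
    write_fasta(as_records(sprintf("hpm-miR%03d", seq_len(n_hairpins)),
                           chartr("T", "U", truth$mature_seq)),
                file.path(outdir, "hairpin_mirnas.fasta"))
  }
  if (n_decoys > 0L) {
    dc <- do.call(rbind, lapply(seq_len(n_decoys), function(k) {
      make_decoy(seed = base + 500L + k)
    }))
    dc$id <- paste0(dc$id, "_", seq_len(n_decoys))
    write_fasta(dc, file.path(outdir, "decoys.fasta"))
  }
  if (n_targets > 0L) {
    mir <- vapply(seq_len(n_targets), function(k) {
      with_seed(base + 700L + k, chartr("T", "U", sample_mature()))
    }, character(1))
    tx <- lapply(seq_len(n_targets), function(k) {
      make_target_transcript(mir[k], seed = base + 800L + k)
    })
    recs <- do.call(rbind, lapply(tx, `[[`, "record"))
    recs$id <- paste0(recs$id, "_", seq_len(n_targets))
    write_fasta(recs, file.path(outdir, "targets.fasta"))
    write_fasta(as_records(sprintf("mir-%03d", seq_len(n_targets)), mir),
                file.path(outdir, "target_mirnas.fasta"))
    truth <- do.call(rbind, lapply(seq_len(n_targets), function(k) {
      t <- tx[[k]]$truth
      data.frame(id = recs$id[k], mirna_id = sprintf("mir-%03d", k),
                 start = t$site_span[1], end = t$site_span[2],
                 score = t$score, stringsAsFactors = FALSE)
    }))
    write_tsv(truth, file.path(outdir, "targets_truth.tsv"))
  }
  invisible(outdir)
}
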