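test_that("dot-bracket parsing and rendering are inverse", {
  pt <- parse_dotbracket("((..))")
  expect_equal(pt$partner, c(6L, 5L, 0L, 0L, 2L, 1L))
  expect_equal(parse_dotbracket("......")$partner, rep(0L, 6))
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("())"), "unbalanced")
  expect_error(parse_dotbracket("(x)"), "invalid")

  set.seed(14)
  for (i in 1:30) {
    s <- random_structure(sample(20:60, 1))
    expect_equal(render_dotbracket(parse_dotbracket(s)), s)
    # partner symmetry
    pt <- parse_dotbracket(s)
    paired <- which(pt$partner > 0)
    expect_equal(pt$partner[pt$partner[paired]], paired)
  }
})

test_that("precursor statistics follow the MFEI arithmetic", {
  seq100 <- paste0(strrep("G", 20), strrep("C", 20), strrep("A", 60))
  st <- compute_stats(seq100, list(mfe = -40))
  expect_equal(st$gc_percent, 40)
  expect_equal(st$amfe, -40)
  expect_equal(st$mfei, -1)

  open <- compute_stats("ACGTACGTAC", list(mfe = 0))
  expect_equal(open$amfe, 0)
  expect_equal(open$mfei, 0)

  # zero GC: MFEI undefined
  expect_true(is.na(compute_stats("ATATATAT", list(mfe = -1))$mfei))
  expect_error(compute_stats("", list(mfe = 0)), "zero-length")
})

test_that("multi-loop detection agrees with terminal-loop counting", {
  expect_false(is_multiloop(parse_dotbracket("((((....))))")))
  expect_true(is_multiloop(parse_dotbracket("((..((...))..((...))..))")))
  set.seed(8)
  for (i in 1:40) {
    s <- random_structure(sample(25:70, 1))
    pt <- parse_dotbracket(s)
    expect_equal(is_multiloop(pt), oracle_terminal_loops(s) > 1)
  }
})

test_that("mature arm placement distinguishes 5p, 3p and straddling spans", {
  # 30-nt perfect hairpin: 12-pair stem, 6-nt loop
  s <- paste0(strrep("(", 12), "......", strrep(")", 12))
  pt <- parse_dotbracket(s)
  expect_equal(mature_in_one_arm(pt, c(1, 10)),
               list(one_arm = TRUE, arm = "5p"))
  expect_equal(mature_in_one_arm(pt, c(20, 30)),
               list(one_arm = TRUE, arm = "3p"))
  expect_false(mature_in_one_arm(pt, c(8, 20))$one_arm)
  # multi-hairpin structure never qualifies
  multi <- parse_dotbracket("((...))..((...))")
  expect_false(mature_in_one_arm(multi, c(1, 5))$one_arm)
})

test_that("star localization reads the duplex with the 2-nt 3' overhang", {
  # flank5 10 + mature 21 + loop 8 + revcomp(mature) 21 + flank3 10
  hp <- make_hairpin(seed = 1)
  rec <- hp$record
  fold <- fold_sequence(rec$seq)
  pt <- parse_dotbracket(fold$structure)
  expect_equal(locate_star(pt, c(11, 31)), c(40, 62))

  exc <- excise_stemloop_auto(rec, fold, list(start = 11, end = 31))
  expect_equal(exc$pre_span, c(11, 62))
  expect_equal(nchar(exc$pre_seq), 52)

  # clamping: without a 3' flank the star end stops at the sequence end
  trunc <- plantmir:::as_records("trunc", substr(rec$seq, 1, 60))
  ftr <- fold_sequence(trunc$seq)
  ptr <- parse_dotbracket(ftr$structure)
  expect_equal(locate_star(ptr, c(11, 31))[2], 60)

  # fully unpaired mature region cannot be localized
  open_pt <- parse_dotbracket(strrep(".", 70))
  expect_error(locate_star(open_pt, c(11, 31)), "no_duplex")

  # manual mode returns the requested substring verbatim
  man <- excise_stemloop_manual(rec, 5, 40)
  expect_equal(man$pre_seq, substr(rec$seq, 5, 40))
})

test_that("star and mature spans are disjoint across random fixtures", {
  for (k in 1:25) {
    arm <- if (k %% 2 == 0) "5p" else "3p"
    hp <- make_hairpin(seed = 3000 + k, arm = arm)
    t <- hp$truth
    expect_true(t$star_span[2] < t$mature_span[1] ||
                t$star_span[1] > t$mature_span[2])
    # excision inclusion: precursor covers the mature hit
    expect_true(t$pre_span[1] <= t$mature_span[1] &&
                t$pre_span[2] >= t$mature_span[2])
  }
})

test_that("duplex statistics count planted mismatches and bulges", {
  run_stats <- function(hp) {
    mir <- mirna_table("xxx-miR1", hp$truth$mature_seq)
    hits <- run_homolog_search(hp$record, mir, max_mismatch = 0)
    cands <- hairpin_candidates(hp$record, hits)
    cands[1, ]
  }
  clean <- run_stats(make_hairpin(seed = 61))
  expect_equal(clean$duplex_mismatches, 0L)
  expect_equal(clean$n_bulges, 0L)
  expect_equal(clean$max_bulge_size, 0L)
  expect_gte(clean$n_overhang2, 1L)

  mm <- run_stats(make_hairpin(
    seed = 62, perturbations = list(list(type = "sym_mismatch", offset = 9))))
  expect_equal(mm$duplex_mismatches, 1L)
  expect_equal(mm$n_bulges, 0L)

  bg <- run_stats(make_hairpin(
    seed = 63, perturbations = list(list(type = "bulge", offset = 10,
                                         size = 2))))
  expect_equal(bg$duplex_mismatches, 0L)
  expect_equal(bg$n_bulges, 1L)
  expect_equal(bg$max_bulge_size, 2L)
})

test_that("precursor filters reject in rule order and loosen monotonically", {
  mk <- function(...) {
    base <- list(source_id = "s", mirna_id = "m", pre_seq = "x",
                 pre_structure = ".", pre_start = 1L, pre_end = 60L,
                 mature_start = 1L, mature_end = 21L, star_start = 30L,
                 star_end = 52L, mfe = -20, amfe = -40, mfei = -1,
                 gc_percent = 40, n_overhang2 = 1L,
                 duplex_mismatches = 0L, n_bulges = 0L,
                 max_bulge_size = 0L, multiloop = FALSE,
                 mature_one_arm = TRUE, arm = "5p",
                 reject_reason = NA_character_)
    mod <- list(...)
    base[names(mod)] <- mod
    as.data.frame(base, stringsAsFactors = FALSE)
  }
  # multiloop rejected regardless of thresholds
  f_loose <- precursor_filters(min_abs_mfei = 0, max_duplex_mismatches = 99,
                               max_bulges = 99, max_bulge_size = 99)
  r <- filter_precursors(mk(multiloop = TRUE), f_loose)
  expect_equal(r$rejected$reason, "multiloop")
  r <- filter_precursors(mk(mature_one_arm = FALSE), f_loose)
  expect_equal(r$rejected$reason, "not_one_arm")

  # MFEI gate at the default 0.85
  expect_equal(nrow(filter_precursors(mk(mfei = -0.9))$accepted), 1L)
  expect_equal(filter_precursors(mk(mfei = -0.8))$rejected$reason, "mfei")

  expect_equal(filter_precursors(mk(duplex_mismatches = 5L))$rejected$reason,
               "duplex_mismatches")
  expect_equal(filter_precursors(mk(n_bulges = 3L))$rejected$reason, "bulges")
  expect_equal(filter_precursors(mk(max_bulge_size = 3L))$rejected$reason,
               "bulge_size")
  expect_equal(filter_precursors(
    mk(n_overhang2 = 0L),
    precursor_filters(require_overhangs = 1L))$rejected$reason, "overhangs")

  # monotonicity: loosening any threshold never shrinks the accepted set
  cands <- do.call(rbind, list(
    mk(), mk(mfei = -0.7), mk(duplex_mismatches = 3L),
    mk(n_bulges = 2L, max_bulge_size = 2L), mk(duplex_mismatches = 6L)))
  tight <- precursor_filters(min_abs_mfei = 0.85, max_duplex_mismatches = 2,
                             max_bulges = 1, max_bulge_size = 1)
  for (loose in list(
    precursor_filters(min_abs_mfei = 0.5, max_duplex_mismatches = 2,
                      max_bulges = 1, max_bulge_size = 1),
    precursor_filters(min_abs_mfei = 0.85, max_duplex_mismatches = 6,
                      max_bulges = 1, max_bulge_size = 1),
    precursor_filters(min_abs_mfei = 0.85, max_duplex_mismatches = 2,
                      max_bulges = 3, max_bulge_size = 3))) {
    a_tight <- filter_precursors(cands, tight)$accepted
    a_loose <- filter_precursors(cands, loose)$accepted
    expect_gte(nrow(a_loose), nrow(a_tight))
  }
})

test_that("stored AMFE and MFEI agree with recomputation from mfe/length/gc", {
  hp <- make_hairpin(seed = 77)
  mir <- mirna_table("xxx-miR2", hp$truth$mature_seq)
  hits <- run_homolog_search(hp$record, mir, max_mismatch = 0)
  cand <- hairpin_candidates(hp$record, hits)[1, ]
  len <- nchar(cand$pre_seq)
  expect_equal(cand$amfe, cand$mfe / len * 100, tolerance = 1e-9)
  expect_equal(cand$mfei, cand$amfe / cand$gc_percent, tolerance = 1e-9)
})
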