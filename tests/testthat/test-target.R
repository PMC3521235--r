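test_that("position classification matches the 16-combination truth table", {
  bases <- c("A", "C", "G", "U")
  for (a in bases) {
    for (b in bases) {
      # a 4-nt miRNA of base `a` against a site of base `b`: position p
      # of the miRNA faces site position L-p+1, all identical here
      lab <- classify_positions(strrep(a, 4), strrep(b, 4))
      expect_equal(lab, rep(oracle_pair_label(a, b), 4),
                   info = paste(a, b))
    }
  }
  mir <- "UGACAGAAGAGAGUGAGCAC"
  expect_equal(classify_positions(mir, reverse_complement(mir)),
               rep("match", 20))
  # one engineered miRNA-G : site-U wobble
  site <- reverse_complement(mir)
  gpos <- regexpr("G", chartr("U", "T", mir))[1]
  idx <- nchar(site) - gpos + 1
  substr(site, idx, idx) <- "T"
  lab <- classify_positions(mir, site)
  expect_equal(sum(lab == "GU"), 1)
  expect_equal(which(lab == "GU"), gpos)
  # N is always a mismatch
  expect_equal(classify_positions("N", "A"), "mismatch")
  expect_error(classify_positions("ACG", "AC"), "equal length")
})

test_that("binding score is the weighted sum of defects", {
  w <- c(mismatch = 1, gu = 0.5, gap = 2)
  expect_equal(score_site(rep("match", 20), w)$score, 0)
  sc <- score_site(c(rep("match", 17), "mismatch", "mismatch", "GU"), w)
  expect_equal(sc$score, 2.5)
  expect_equal(sc$n_mismatch, 2L)
  expect_equal(sc$mismatch_positions, c(18L, 19L))
  expect_equal(score_site(c(rep("match", 18), "gap", "GU"), w)$score, 2.5)
  # linear in the weights; zero weights give zero score
  labs <- c(rep("match", 10), "mismatch", "GU", "gap")
  expect_equal(score_site(labs, c(mismatch = 0, gu = 0, gap = 0))$score, 0)
  expect_equal(score_site(labs, 2 * w)$score, 2 * score_site(labs, w)$score)
})

test_that("positional rules fail on seed mismatches, 10/11, and triples", {
  L <- 21
  mk <- function(mm) {
    labs <- rep("match", L); labs[mm] <- "mismatch"; labs
  }
  expect_true(position_rule_filter(mk(integer(0)))$pass)
  r10 <- position_rule_filter(mk(10))
  expect_false(r10$pass)
  expect_equal(r10$violated_rule, "none_at_10_11")
  expect_false(position_rule_filter(mk(11))$pass)
  r19 <- position_rule_filter(mk(c(2, 5)))
  expect_false(r19$pass)
  expect_equal(r19$violated_rule, "max_one_in_1_9")
  expect_true(position_rule_filter(mk(c(15, 16)))$pass)
  r3 <- position_rule_filter(mk(c(15, 16, 17)))
  expect_false(r3$pass)
  expect_equal(r3$violated_rule, "no_3_consecutive")
  # G:U wobbles are not mismatches for the rules
  gu <- rep("match", L); gu[c(10, 11)] <- "GU"
  expect_true(position_rule_filter(gu)$pass)
})

test_that("positional rules match brute force on every <=3-mismatch pattern", {
  L <- 21
  oracle_rules <- function(mm) {
    if (sum(mm <= 9) > 1) return(FALSE)
    if (any(mm %in% c(10, 11))) return(FALSE)
    runs <- rle(seq_len(L) %in% mm)
    !any(runs$values & runs$lengths >= 3)
  }
  check <- function(mm) {
    labs <- rep("match", L); labs[mm] <- "mismatch"
    expect_equal(position_rule_filter(labs)$pass, oracle_rules(mm),
                 info = paste(mm, collapse = ","))
  }
  check(integer(0))
  for (a in 1:L) check(a)
  cmb2 <- utils::combn(L, 2)
  for (i in seq_len(ncol(cmb2))) check(cmb2[, i])
  cmb3 <- utils::combn(L, 3)
  for (i in seq_len(ncol(cmb3))) check(cmb3[, i])
})

test_that("target scan recovers planted sites with exact composition", {
  mir <- mirna_table("ath-miR398a", "UGUGUUCUCAGGUCACCCCUU")
  t0 <- make_target_transcript(mir$seq, seed = 201)
  s0 <- scan_targets(t0$record, mir)
  hit <- s0[s0$start == t0$truth$site_span[1], ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$score, 0)

  # boundary: score exactly at the cutoff is kept
  edits4 <- list(list(position = 13, type = "mismatch"),
                 list(position = 15, type = "mismatch"),
                 list(position = 18, type = "mismatch"),
                 list(position = 20, type = "mismatch"))
  t4 <- make_target_transcript(mir$seq, seed = 202, edits = edits4)
  s4 <- scan_targets(t4$record, mir)
  hit4 <- s4[s4$start == t4$truth$site_span[1], ]
  expect_equal(hit4$score, 4)
  expect_equal(hit4$n_mismatch, 4L)

  # a site violating the 10/11 rule is dropped unless rules are off
  tbad <- make_target_transcript(
    mir$seq, seed = 203, edits = list(list(position = 10, type = "mismatch")))
  sbad <- scan_targets(tbad$record, mir)
  expect_equal(nrow(sbad[sbad$start == tbad$truth$site_span[1], ]), 0L)
  soff <- scan_targets(tbad$record, mir,
                       target_scan_config(position_rules_on = FALSE))
  expect_equal(nrow(soff[soff$start == tbad$truth$site_span[1], ]), 1L)

  expect_error(scan_targets(t0$record, mir[0, ]), "empty")
})

test_that("gapped sites are found through the half-seeded path", {
  mir <- mirna_table("ath-miR398a", "UGUGUUCUCAGGUCACCCCUU")
  tg <- make_target_transcript(
    mir$seq, seed = 210, edits = list(list(position = 12, type = "gap")))
  sg <- scan_targets(tg$record, mir)
  hit <- sg[sg$start == tg$truth$site_span[1], ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$n_gap, 1L)
  expect_equal(hit$score, 2)
  expect_equal(hit$end - hit$start + 1L, mir$length - 1L)
})

test_that("raising max_score never removes a reported site", {
  mir <- mirna_table("ath-miR398a", "UGUGUUCUCAGGUCACCCCUU")
  set.seed(220)
  rec <- plantmir:::as_records("bg", random_seq(400))
  prev <- 0L
  for (ms in c(0, 2, 4, 6)) {
    cfg <- target_scan_config(max_score = ms, position_rules_on = FALSE)
    n <- nrow(scan_targets(rec, mir, cfg))
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("max_score 0 with rules off equals exact reverse-complement search", {
  set.seed(230)
  for (i in 1:5) {
    mirseq <- chartr("T", "U", random_seq(21))
    mir <- mirna_table("xxx-miR0", mirseq)
    t0 <- make_target_transcript(mirseq, seed = 230 + i)
    cfg <- target_scan_config(max_score = 0, position_rules_on = FALSE)
    got <- scan_targets(t0$record, mir, cfg)
    # string-search oracle
    pat <- chartr("U", "T", reverse_complement(mirseq))
    expected <- gregexpr(pat, t0$record$seq, fixed = TRUE)[[1]]
    expected <- expected[expected > 0]
    expect_equal(got$start, as.integer(expected))
  }
})

test_that("duplex refinement annotates without removing sites", {
  mir <- mirna_table("ath-miR398a", "UGUGUUCUCAGGUCACCCCUU")
  t0 <- make_target_transcript(mir$seq, seed = 240)
  t2 <- make_target_transcript(
    mir$seq, seed = 241, edits = list(list(position = 14, type = "mismatch"),
                                      list(position = 17, type = "mismatch")))
  s <- rbind(scan_targets(t0$record, mir), scan_targets(t2$record, mir))
  n_before <- nrow(s)
  recs <- rbind(t0$record, t2$record)
  s <- refine_with_duplex(s, recs, mir)
  expect_equal(nrow(s), n_before)
  perfect <- s[s$target_id == t0$record$id &
               s$start == t0$truth$site_span[1], ]
  expect_equal(perfect$overlap_fraction, 1)
  mism <- s[s$target_id == t2$record$id &
            s$start == t2$truth$site_span[1], ]
  # perfect complementarity hybridizes at least as strongly
  expect_lte(perfect$duplex_mfe, mism$duplex_mfe)
})
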