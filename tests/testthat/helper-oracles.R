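# Independent oracles used across the suite. These deliberately use
# naive per-case algorithms, not the package's vectorized code paths.

# per-offset Hamming scan, character by character (U==T, N mismatches)
oracle_hamming_scan <- function(query, subject, max_mismatch) {
  norm <- function(s) strsplit(chartr("U", "T", toupper(s)), "")[[1]]
  q <- norm(query); s <- norm(subject)
  m <- length(q); n <- length(s)
  out <- data.frame(start = integer(), n_mismatch = integer())
  if (m == 0 || m > n) return(out)
  for (st in 1:(n - m + 1)) {
    mm <- 0L
    for (p in 1:m) {
      a <- q[p]; b <- s[st + p - 1]
      if (a != b || a == "N" || b == "N") mm <- mm + 1L
    }
    if (mm <= max_mismatch) {
      out <- rbind(out, data.frame(start = st, n_mismatch = mm))
    }
  }
  out
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# exhaustive enumeration of nested structures (min loop 3) returning
# the maximum number of base pairs; exponential, for tiny n only
oracle_max_pairs <- function(seq) {
  pairs_ok <- function(a, b) {
    ab <- paste0(chartr("U", "T", a), chartr("U", "T", b))
    ab %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  ch <- strsplit(toupper(seq), "")[[1]]
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i + 1, j)  # i unpaired
    for (k in (i + 4):j) {
      if (pairs_ok(ch[i], ch[k])) {
        left <- if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0L
        right <- if (k + 1 <= j) rec(k + 1, j) else 0L
        best <- max(best, 1L + left + right)
      }
    }
    best
  }
  rec(1, length(ch))
}

# random valid nested dot-bracket structure of length n
random_structure <- function(n, p_pair = 0.3) {
  out <- rep(".", n)
  attempt <- 0
  while (attempt < n) {
    attempt <- attempt + 1
    i <- sample.int(n, 1)
    j <- sample.int(n, 1)
    if (abs(j - i) <= 3) next
    lo <- min(i, j); hi <- max(i, j)
    if (any(out[lo:hi] != ".")) next
    if (stats::runif(1) > p_pair) next
    out[lo] <- "("; out[hi] <- ")"
  }
  paste(out, collapse = "")
}

# count terminal loops by enumerating maximal unpaired runs flanked by
# a pair that closes around them
oracle_terminal_loops <- function(structure) {
  pt <- plantmir::parse_dotbracket(structure)
  n_loops <- 0
  for (i in seq_len(pt$n)) {
    j <- pt$partner[i]
    if (j > i) {
      inside <- if (j - i > 1) pt$partner[(i + 1):(j - 1)] else integer(0)
      if (length(inside) && all(inside == 0)) n_loops <- n_loops + 1
    }
  }
  n_loops
}

# truth-table classifier for one opposed base pair (miRNA base vs the
# site base it faces)
oracle_pair_label <- function(mir_base, site_base) {
  a <- chartr("U", "T", mir_base); b <- chartr("U", "T", site_base)
  wc <- list(A = "T", T = "A", C = "G", G = "C")
  if (a %in% c("A", "C", "G", "T") && identical(wc[[a]], b)) return("match")
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return("GU")
  "mismatch"
}

# a fresh AU-rich 21-nt mature miRNA (RNA letters) from a given seed
with_seed_free_mature <- function(seed) {
  plantmir:::with_seed(seed, chartr("T", "U", plantmir:::sample_mature()))
}
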