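# Built-in deterministic structure engines. These are energy *proxies*
# (base-pair maximization; weighted duplex offsets), not thermodynamic
# models: they exist so the full pipeline runs with no external engine.

# encode with U==T: A=1 C=2 G=3 T/U=4 N=0
encode_nt <- function(seq) {
  v <- strsplit(chartr("U", "T", toupper(seq)), "", fixed = TRUE)[[1]]
  m <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)
  out <- unname(m[v])
  if (anyNA(out)) stop("sequence contains non-nucleotide characters")
  out
}

# allowed pairs: AU/UA, GC/CG, GU/UG (N pairs with nothing)
can_pair_code <- function(a, b) {
  (a == 1L & b == 4L) | (a == 4L & b == 1L) |
  (a == 2L & b == 3L) | (a == 3L & b == 2L) |
  (a == 3L & b == 4L) | (a == 4L & b == 3L)
}

MIN_HAIRPIN_LOOP <- 3L

# Nussinov base-pair maximization with min loop 3. Traceback is
# deterministic: unpaired-i is taken when optimal, else the smallest
# pairing partner k achieving the optimum.
nussinov_fold <- function(seq, max_bp_distance = Inf) {
  enc <- encode_nt(seq)
  n <- length(enc)
  M <- matrix(0L, n, n)
  if (n > MIN_HAIRPIN_LOOP + 1L) {
    for (d in (MIN_HAIRPIN_LOOP + 1L):(n - 1L)) {
      for (i in seq_len(n - d)) {
        j <- i + d
        best <- M[i + 1L, j]
        ks <- (i + MIN_HAIRPIN_LOOP + 1L):j
        ks <- ks[can_pair_code(enc[i], enc[ks]) & (ks - i) <= max_bp_distance]
        if (length(ks)) {
          inner <- M[cbind(i + 1L, ks - 1L)]          # k-1 >= i+4 > i
          outer <- integer(length(ks))
          not_end <- ks < j
          outer[not_end] <- M[cbind(ks[not_end] + 1L, j)]
          best <- max(best, max(inner + outer + 1L))
        }
        M[i, j] <- best
      }
    }
  }
  partner <- integer(n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    while (i < j) {
      if (j - i <= MIN_HAIRPIN_LOOP) break
      if (M[i, j] == M[i + 1L, j]) { i <- i + 1L; next }
      ks <- (i + MIN_HAIRPIN_LOOP + 1L):j
      ks <- ks[can_pair_code(enc[i], enc[ks]) & (ks - i) <= max_bp_distance]
      found <- FALSE
      for (k in ks) {
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        outer <- if (k + 1L <= j) M[k + 1L, j] else 0L
        if (inner + outer + 1L == M[i, j]) {
          partner[i] <- k; partner[k] <- i
          if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L; i <- i + 1L
          found <- TRUE
          break
        }
      }
      if (!found) i <- i + 1L
    }
  }
  structure_txt <- render_dotbracket(list(n = n, partner = partner))
  list(seq = toupper(seq), structure = structure_txt,
       mfe = -sum(partner > 0) / 2)
}

DUPLEX_WEIGHTS <- c(GC = -3, AU = -2, GU = -1)

duplex_pair_weight <- function(a, b) {
  w <- numeric(length(a))
  gc <- (a == 2L & b == 3L) | (a == 3L & b == 2L)
  au <- (a == 1L & b == 4L) | (a == 4L & b == 1L)
  gu <- (a == 3L & b == 4L) | (a == 4L & b == 3L)
  w[gc] <- DUPLEX_WEIGHTS[["GC"]]
  w[au] <- DUPLEX_WEIGHTS[["AU"]]
  w[gu] <- DUPLEX_WEIGHTS[["GU"]]
  w
}

# Exhaustive ungapped antiparallel offset search. miRNA position p faces
# site position q = m - p + 1 + s at shift s; the best-scoring shift wins,
# ties going to the smaller |s| (then the smaller s).
duplex_builtin <- function(mirna, site) {
  a <- encode_nt(mirna)
  b <- encode_nt(site)
  m <- length(a); n <- length(b)
  shifts <- (1L - m):(n - 1L)
  shifts <- shifts[order(abs(shifts), shifts)]
  best <- NULL
  for (s in shifts) {
    p <- seq_len(m)
    q <- m - p + 1L + s
    ok <- q >= 1L & q <= n
    if (!any(ok)) next
    w <- duplex_pair_weight(a[p[ok]], b[q[ok]])
    sc <- sum(w)
    if (is.null(best) || sc < best$mfe) {
      paired <- w < 0
      best <- list(mfe = sc,
                   pairing = cbind(mirna_pos = p[ok][paired],
                                   site_pos = q[ok][paired]))
    }
  }
  best
}
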