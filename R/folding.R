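#' Folding parameters
#'
#' @param temperature Folding temperature in degrees Celsius (default 37).
#' @param max_bp_distance Maximum allowed base-pair span in nt, or `Inf`.
#' @param max_interior_loop Maximum bulge/interior loop size passed to the
#'   thermodynamic engine (default 30; ignored by the builtin engine).
#' @return A list of class `fold_params`.
#' @export
fold_params <- function(temperature = 37, max_bp_distance = Inf,
                        max_interior_loop = 30L) {
  stopifnot(temperature >= 0, temperature <= 100)
  structure(list(temperature = temperature,
                 max_bp_distance = max_bp_distance,
                 max_interior_loop = max_interior_loop),
            class = "fold_params")
}

#' Predict the secondary structure of a single sequence
#'
#' Two engines sit behind one contract. `engine = "thermo"` delegates to
#' the ViennaRNA `RNAfold` program (minimum-free-energy structure,
#' kcal/mol). `engine = "builtin"` runs deterministic Nussinov base-pair
#' maximization (minimum hairpin loop 3; AU/GC/GU pairs with U==T) and
#' reports the proxy energy -1.0 per pair; it requires no external
#' software and is the package default.
#'
#' @param seq Nucleotide sequence (length >= 10).
#' @param params A [fold_params()] object.
#' @param engine `"builtin"` or `"thermo"`.
#' @return A list with `seq`, `structure` (dot-bracket) and `mfe`.
#' @export
fold_sequence <- function(seq, params = fold_params(),
                          engine = c("builtin", "thermo")) {
  engine <- match.arg(engine)
  if (nchar(seq) < 10L) {
    stop("fold_sequence: sequence shorter than 10 nt")
  }
  if (engine == "builtin") {
    nussinov_fold(seq, max_bp_distance = params$max_bp_distance)
  } else {
    rnafold_run(seq, params)
  }
}

#' Hybridize a miRNA with a target site
#'
#' Intermolecular pairing only. The builtin engine scores every ungapped
#' antiparallel offset with proxy pair weights GC -3, AU -2, GU -1 and
#' returns the best offset (ties to the smaller absolute offset); the
#' thermo engine calls ViennaRNA `RNAduplex` and reports its
#' hybridization energy in kcal/mol.
#'
#' @param mirna,site Nucleotide strands, conventionally 15-30 nt.
#' @param temperature Temperature in degrees Celsius (default 37).
#' @param engine `"builtin"` or `"thermo"`.
#' @return A list with `mirna_seq`, `site_seq`, `mfe`, and `pairing` (a
#'   two-column matrix of 1-based miRNA/site positions, increasing on the
#'   miRNA and decreasing on the site).
#' @export
fold_duplex <- function(mirna, site, temperature = 37,
                        engine = c("builtin", "thermo")) {
  engine <- match.arg(engine)
  if (!nzchar(mirna) || !nzchar(site)) {
    stop("fold_duplex: empty strand")
  }
  res <- if (engine == "builtin") {
    duplex_builtin(mirna, site)
  } else {
    rnaduplex_run(mirna, site, temperature)
  }
  c(list(mirna_seq = toupper(mirna), site_seq = toupper(site)), res)
}

vienna_binary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    stop("thermodynamic engine unavailable: '", name, "' not found on PATH")
  }
  path
}

rnafold_run <- function(seq, params) {
  bin <- vienna_binary("RNAfold")
  out <- system2(bin, args = c("--noPS", "-T", params$temperature),
                 input = chartr("T", "U", toupper(seq)), stdout = TRUE)
  # last line: <structure> ( -12.30 )
  line <- out[length(out)]
  structure_txt <- sub("\\s.*$", "", line)
  mfe <- as.numeric(gsub("[()\\s]", "", sub("^\\S+\\s+", "", line), perl = TRUE))
  list(seq = toupper(seq), structure = structure_txt, mfe = mfe)
}

rnaduplex_run <- function(mirna, site, temperature) {
  bin <- vienna_binary("RNAduplex")
  inp <- paste(chartr("T", "U", toupper(mirna)),
               chartr("T", "U", toupper(site)), sep = "\n")
  out <- system2(bin, args = c("-T", temperature), input = inp, stdout = TRUE)
  line <- out[length(out)]
  # format: .((((&)))).   2,6   :   1,5  (-5.40)
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  db <- toks[1]
  span_a <- as.integer(strsplit(toks[2], ",")[[1]])
  span_b <- as.integer(strsplit(toks[4], ",")[[1]])
  mfe <- as.numeric(gsub("[()]", "", toks[5]))
  halves <- strsplit(db, "&", fixed = TRUE)[[1]]
  lefts <- which(strsplit(halves[1], "")[[1]] == "(")
  rights <- which(strsplit(halves[2], "")[[1]] == ")")
  stopifnot(length(lefts) == length(rights))
  pairing <- cbind(
    mirna_pos = span_a[1] - 1L + lefts,
    site_pos = span_b[1] - 1L + rev(rights)
  )
  list(mfe = mfe, pairing = pairing)
}

#' Write fold results as a Vienna-format structure file
#'
#' One block per result: `>id`, sequence line, then structure with the
#' energy in parentheses.
#'
#' @param ids Character vector of identifiers.
#' @param folds List of fold results ([fold_sequence()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(ids, folds, path) {
  lines <- unlist(lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    c(paste0(">", ids[i]), f$seq,
      sprintf("%s (%.2f)", f$structure, f$mfe))
  }))
  writeLines(lines, path)
  invisible(path)
}
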