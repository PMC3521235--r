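#' Confusion-matrix metrics
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return List with `ppv`, `npv`, `sensitivity`, `specificity`;
#'   a metric with a zero denominator is reported as `NA`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(ppv = safe_div(tp, tp + fp),
       npv = safe_div(tn, tn + fn),
       sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp))
}

#' Order-preserving parallel map
#'
#' Applies a pure per-item function with `parallel::mclapply`; results
#' are returned in input order so any thread count yields identical
#' output. On platforms without fork support it falls back to `lapply`.
#'
#' @param f Function of one item.
#' @param items List or vector of items.
#' @param n_threads Number of worker processes (default 1).
#' @return List of results, one per item, in input order.
#' @export
parallel_map <- function(f, items, n_threads = 1L) {
  if (n_threads <= 1L || .Platform$OS.type == "windows") {
    return(lapply(items, f))
  }
  res <- parallel::mclapply(items, f, mc.cores = n_threads,
                            mc.preschedule = TRUE)
  errs <- vapply(res, inherits, logical(1), "try-error")
  if (any(errs)) {
    stop("parallel_map: worker failure on item ", which(errs)[1])
  }
  res
}

step_report <- function(step_name, n_in, n_out, params_used = list()) {
  list(step_name = step_name, n_in = n_in, n_out = n_out,
       n_excluded = n_in - n_out, params_used = params_used)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param input Path to the input FASTA (cDNA/EST/GSS or transcripts).
#' @param mirnas Path to the mature miRNA reference FASTA (miRBase-style
#'   headers), or a miRNA table.
#' @param outdir Output directory for per-step artifacts.
#' @param max_mismatch Homolog-scan mismatch cap (default 4).
#' @param max_score Target-scan binding score cap (default 4).
#' @param strands `"plus_only"` or `"both"`.
#' @param engine Folding engine (`"builtin"` or `"thermo"`).
#' @param temperature Folding temperature, degrees Celsius.
#' @param n_threads Worker processes for per-sequence steps.
#' @param filters [precursor_filters()] for the miRNA pipeline.
#' @param screen_hook Optional screening hook: a function taking a
#'   record table and returning a logical vector (TRUE = hit, sequence
#'   dropped), used to remove protein-coding/ncRNA sequences when an
#'   external search tool is wired in. `NULL` skips the step.
#' @return A configuration list.
#' @export
pipeline_config <- function(input, mirnas, outdir = tempfile("plantmir_"),
                            max_mismatch = 4L, max_score = 4.0,
                            strands = "plus_only", engine = "builtin",
                            temperature = 37, n_threads = 1L,
                            filters = precursor_filters(),
                            screen_hook = NULL) {
  list(input = input, mirnas = mirnas, outdir = outdir,
       max_mismatch = max_mismatch, max_score = max_score,
       strands = strands, engine = engine, temperature = temperature,
       n_threads = n_threads, filters = filters,
       screen_hook = screen_hook)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; filter
#' thresholds may be given under a `filters:` block.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  f <- do.call(precursor_filters, y$filters %||% list())
  args <- y[setdiff(names(y), "filters")]
  args$filters <- f
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_mirnas <- function(mirnas) {
  if (is.character(mirnas)) read_mirna_fasta(mirnas) else mirnas
}

apply_screen <- function(records, hook) {
  if (is.null(hook) || nrow(records) == 0L) return(records)
  verdict <- hook(records)
  stopifnot(length(verdict) == nrow(records))
  records[!verdict, , drop = FALSE]
}

#' Run the miRNA identification pipeline
#'
#' Sequence validation (max 3000 nt), homolog search, optional external
#' screening, primary folding, stem-loop excision with star partner and
#' two-nucleotide 3' overhang, precursor refolding, statistics, and the
#' plant precursor validation filters. All intermediates are written
#' under `config$outdir`.
#'
#' @param config A [pipeline_config()] list.
#' @return List with `reports` (chained step reports), `accepted` and
#'   `rejected` candidate tables, `summary` (families/members tallies)
#'   and `outdir`.
#' @export
run_mirna_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  mirnas <- resolve_mirnas(config$mirnas)
  if (nrow(mirnas) == 0L) stop("configuration error: empty miRNA reference")
  records <- if (is.character(config$input)) read_fasta(config$input)
             else config$input

  val <- validate_sequences(records, max_len = 3000L)
  write_validation_report(val$report,
                          file.path(config$outdir, "validation.json"))
  reports <- list(step_report("sequence_loading", nrow(records),
                              nrow(val$kept),
                              list(max_len = 3000L)))

  hits <- run_homolog_search(val$kept, mirnas,
                             max_mismatch = config$max_mismatch,
                             strands = config$strands)
  write_tsv(hits, file.path(config$outdir, "homolog_hits.tsv"))
  with_hits <- val$kept[val$kept$id %in% hits$seq_id, , drop = FALSE]
  reports <- c(reports, list(step_report(
    "homolog_search", nrow(val$kept), nrow(with_hits),
    list(max_mismatch = config$max_mismatch, strands = config$strands))))

  screened <- apply_screen(with_hits, config$screen_hook)
  params <- fold_params(temperature = config$temperature)
  reports <- c(reports, list(step_report(
    "primary_folding", nrow(with_hits), nrow(screened),
    list(engine = config$engine, temperature = config$temperature))))

  hits2 <- hits[hits$seq_id %in% screened$id, , drop = FALSE]
  cands <- if (nrow(hits2)) {
    hairpin_candidates(screened, hits2, params, config$engine)
  } else {
    data.frame()
  }
  flt <- if (nrow(cands)) filter_precursors(cands, config$filters)
         else list(accepted = data.frame(), rejected = data.frame())
  acc_ids <- unique(flt$accepted$source_id)
  reports <- c(reports, list(step_report(
    "precursor_folding", nrow(screened), length(acc_ids),
    unclass(config$filters))))

  if (nrow(cands)) {
    write_tsv(cands[setdiff(names(cands), "pre_structure")],
              file.path(config$outdir, "hairpin_candidates.tsv"))
  }
  if (nrow(flt$accepted)) {
    acc <- flt$accepted
    write_fasta(as_records(paste0(acc$source_id, "_", acc$mirna_id,
                                  "_", acc$pre_start),
                           acc$pre_seq),
                file.path(config$outdir, "accepted_precursors.fasta"))
    folds <- lapply(seq_len(nrow(acc)), function(i) {
      list(seq = acc$pre_seq[i], structure = acc$pre_structure[i],
           mfe = acc$mfe[i])
    })
    write_vienna(paste0(acc$source_id, "_", acc$mirna_id),
                 folds, file.path(config$outdir, "accepted_structures.txt"))
  }
  summary <- list(
    n_sequences = length(acc_ids),
    n_families = length(unique(parse_family(flt$accepted$mirna_id)$family)),
    n_members = length(unique(flt$accepted$mirna_id)))
  result <- list(reports = reports, accepted = flt$accepted,
                 rejected = flt$rejected, summary = summary,
                 outdir = config$outdir)
  jsonlite::write_json(list(reports = reports, summary = summary),
                       file.path(config$outdir, "mirna_report.json"),
                       auto_unbox = TRUE, digits = NA)
  result
}

#' Run the target identification pipeline
#'
#' Sequence validation (max 20000 nt), complementary-site scanning under
#' the binding score, duplex-folding refinement, and an optional
#' annotation hook.
#'
#' @param config A [pipeline_config()] list; `config$mirnas` may also be
#'   the `accepted` table of a prior [run_mirna_pipeline()] run (its
#'   mature sequences are reused as queries).
#' @return List with `reports`, `sites` and `outdir`.
#' @export
run_target_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  mirnas <- config$mirnas
  if (is.character(mirnas)) {
    mirnas <- read_mirna_fasta(mirnas)
  } else if (!is.null(mirnas$pre_seq)) {
    # accepted hairpin candidates: reuse their mature sequences
    mature <- substr(mirnas$pre_seq,
                     mirnas$mature_start, mirnas$mature_end)
    mirnas <- mirna_table(mirnas$mirna_id, mature)
    mirnas <- mirnas[!duplicated(paste(mirnas$id, mirnas$seq)), ]
  }
  if (nrow(mirnas) == 0L) stop("configuration error: empty miRNA reference")
  records <- if (is.character(config$input)) read_fasta(config$input)
             else config$input

  val <- validate_sequences(records, max_len = 20000L)
  reports <- list(step_report("sequence_loading", nrow(records),
                              nrow(val$kept), list(max_len = 20000L)))

  cfg <- target_scan_config(max_score = config$max_score,
                            strands = config$strands)
  chunks <- parallel_map(function(i) {
    scan_targets(val$kept[i, , drop = FALSE], mirnas, cfg)
  }, seq_len(nrow(val$kept)), config$n_threads)
  sites <- do.call(rbind, c(list(empty_sites()), chunks))
  flagged <- unique(sites$target_id)
  reports <- c(reports, list(step_report(
    "target_scanning", nrow(val$kept), length(flagged),
    list(max_score = config$max_score, strands = config$strands))))

  sites <- refine_with_duplex(sites, val$kept, mirnas,
                              temperature = config$temperature,
                              engine = config$engine)
  reports <- c(reports, list(step_report(
    "duplex_folding", length(flagged), length(unique(sites$target_id)),
    list(temperature = config$temperature, engine = config$engine))))

  write_tsv(sites, file.path(config$outdir, "target_sites.tsv"))
  jsonlite::write_json(list(reports = reports),
                       file.path(config$outdir, "target_report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(reports = reports, sites = sites, outdir = config$outdir)
}
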