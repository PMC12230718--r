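# Top-level driver: FASTA in, prediction table out. Batch mode emits the
# one-row-per-prediction table; interactive mode keeps, per prediction, the
# itemized penalty ledger, the dot-bracket string and the display-bar
# summary, and enforces the per-submission length cap.

#' Read sequences from FASTA
#'
#' @param path FASTA file (DNA or RNA; single- or multi-record).
#' @return Named character vector of raw sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("unreadable FASTA '", path, "': ",
                                           conditionMessage(e)))
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
}

empty_predictions <- function() {
  data.frame(seq_id = character(0), motif_id = character(0),
             family = character(0), start = integer(0), end = integer(0),
             loop_start = integer(0), has_3prime_bulge = logical(0),
             score = numeric(0), category = character(0),
             pooled_tier = character(0), delta_g = numeric(0),
             concordance = numeric(0), core_seq = character(0),
             location = character(0), d5_ire_aug = integer(0),
             d_cap_5ire = integer(0), d_ter_3ire = integer(0),
             stringsAsFactors = FALSE)
}

#' Predict iron-responsive elements
#'
#' The main entry point: normalizes each input record, scans it for
#' apical-loop motifs, assembles and scores every structural interpretation,
#' folds each candidate in context, keeps the best-scoring interpretation
#' per site, and (when CDS coordinates are available) annotates transcript
#' location and distances.
#'
#' @param x Named character vector of sequences, or a FASTA path.
#' @param cds Optional transcript annotation: a named list of
#'   [transcript_context()] (see [read_cds_table()] / [cds_from_gff3()]).
#'   Records without an entry get `NA` location fields and a warning.
#' @param params Scanner limits, [scan_params()].
#' @param config Scoring scheme, [penalty_config()].
#' @param engine Folding engine, `"vienna"` or `"builtin"`.
#' @param flank Folding context per side (nt, default 15).
#' @param mode `"batch"` (table only) or `"interactive"` (adds per-
#'   prediction detail records and enforces the `params$max_len` input cap;
#'   the table itself is identical between modes).
#' @param min_category Drop predictions below this confidence category.
#' @param gene Optional named character vector mapping seq_id to gene label
#'   (enables [collapse_redundant()] downstream).
#' @return An object of class `ire_scan`: list with `predictions` (the
#'   table: one row per retained prediction, 1-based inclusive coordinates,
#'   sorted by seq_id then position), `details` (interactive mode only),
#'   `n_records`, `params`, `engine`, `config_hash`, `mode`.
#' @examples
#' fx <- plant_core(build_core("1", seed = 7), 80, 31, seed = 7)
#' res <- find_ires(setNames(fx$seq, "demo"), engine = "builtin")
#' res$predictions[, c("seq_id", "motif_id", "start", "end", "score")]
#' @export
find_ires <- function(x, cds = NULL, params = scan_params(),
                      config = penalty_config(),
                      engine = c("vienna", "builtin"), flank = 15L,
                      mode = c("batch", "interactive"),
                      min_category = "Very-low", gene = NULL) {
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  if (!min_category %in% CATEGORY_LEVELS) {
    stop("min_category must be one of: ",
         paste(CATEGORY_LEVELS, collapse = ", "))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x))) {
    x <- read_fasta(x)
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("input sequences must be named (seq_id)")
  }
  registry <- ire_motifs()
  max_cat_rank <- match(min_category, CATEGORY_LEVELS)
  rows <- list()
  details <- list()
  missing_cds <- character(0)
  for (id in names(x)) {
    norm <- normalize_sequence(x[[id]], max_len = params$max_len)
    cands <- scan_sequence(norm$seq, registry, params, seq_id = id)
    ctx <- if (!is.null(cds)) cds[[id]] else NULL
    if (!is.null(cds) && is.null(ctx)) missing_cds <- c(missing_cds, id)
    for (group in site_groups(cands)) {
      scored <- lapply(group, function(core) {
        score_candidate(core, fold_window(norm$seq, core, flank, engine),
                        config)
      })
      win <- pick_site_winner(scored)
      if (match(win$category, CATEGORY_LEVELS) > max_cat_rank) next
      core <- win$core
      mid <- ire_midpoint(core)
      loc <- NA_character_
      dist <- list(d5_ire_aug = NA_integer_, d_cap_5ire = NA_integer_,
                   d_ter_3ire = NA_integer_)
      if (!is.null(ctx)) {
        loc <- classify_location(mid, ctx)
        dist <- compute_distances(mid, loc, ctx)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = id, motif_id = core$motif_id, family = core$family,
        start = core$core_start, end = core$core_end,
        loop_start = core$loop_start,
        has_3prime_bulge = core$has_3prime_bulge,
        score = win$score, category = win$category,
        pooled_tier = win$pooled_tier,
        delta_g = win$fold$delta_g, concordance = win$fold$concordance,
        core_seq = core$core_seq, location = loc,
        d5_ire_aug = dist$d5_ire_aug, d_cap_5ire = dist$d_cap_5ire,
        d_ter_3ire = dist$d_ter_3ire, stringsAsFactors = FALSE)
      if (mode == "interactive") {
        details[[length(details) + 1L]] <- list(
          scored = win, penalties = win$penalties,
          dot_bracket = win$fold$dot_bracket,
          bars = summarize_quality(win, config))
      }
    }
  }
  if (length(missing_cds)) {
    warning("no CDS entry for record(s): ",
            paste(missing_cds, collapse = ", "),
            "; location fields reported as NA")
  }
  predictions <- if (length(rows)) do.call(rbind, rows) else
    empty_predictions()
  ord <- order(predictions$seq_id, predictions$start, predictions$loop_start)
  predictions <- predictions[ord, , drop = FALSE]
  rownames(predictions) <- NULL
  if (!is.null(gene)) predictions$gene <- unname(gene[predictions$seq_id])
  if (mode == "interactive") details <- details[ord]
  structure(list(predictions = predictions,
                 details = if (mode == "interactive") details else NULL,
                 n_records = length(x), params = params, engine = engine,
                 config_hash = config$hash, mode = mode),
            class = "ire_scan")
}

#' @export
print.ire_scan <- function(x, ...) {
  cat(sprintf("IRE scan (%s mode, %s engine): %d prediction(s) in %d record(s)\n",
              x$mode, x$engine, nrow(x$predictions), x$n_records))
  cat("scoring config:", x$config_hash, "\n")
  if (nrow(x$predictions)) {
    show <- x$predictions[, c("seq_id", "motif_id", "start", "end", "score",
                              "category", "delta_g", "location")]
    print(head(show, 20), row.names = FALSE)
    if (nrow(show) > 20) cat("... and", nrow(show) - 20, "more row(s)\n")
  }
  invisible(x)
}

#' @export
summary.ire_scan <- function(object, ...) {
  p <- object$predictions
  out <- list(
    n_records = object$n_records,
    n_predictions = nrow(p),
    by_category = table(factor(p$category, levels = CATEGORY_LEVELS)),
    by_location = table(factor(p$location, levels = LOCATION_LEVELS)),
    mean_score = if (nrow(p)) mean(p$score) else NA_real_,
    mean_delta_g = if (nrow(p)) mean(p$delta_g) else NA_real_)
  class(out) <- "summary.ire_scan"
  out
}

#' @export
print.summary.ire_scan <- function(x, ...) {
  cat(sprintf("%d prediction(s) in %d record(s); mean score %.2f, mean dG %.2f\n",
              x$n_predictions, x$n_records, x$mean_score, x$mean_delta_g))
  cat("by category:\n"); print(x$by_category)
  if (sum(x$by_location)) { cat("by location:\n"); print(x$by_location) }
  invisible(x)
}

#' @export
as.data.frame.ire_scan <- function(x, ...) x$predictions

#' Write a prediction table
#'
#' @param res An `ire_scan` result (or its prediction data.frame).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"json"` (one document per record,
#'   with the run's config hash).
#' @export
write_predictions <- function(res, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- if (inherits(res, "ire_scan")) res$predictions else res
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    doc <- list(predictions = df)
    if (inherits(res, "ire_scan")) {
      doc$config_hash <- res$config_hash
      doc$engine <- res$engine
    }
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}
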