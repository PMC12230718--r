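# Secondary-structure support: fold the candidate plus flanking context with
# a minimum-free-energy engine, then measure how much of the IRE structural
# model (five upper-stem pairs plus the N7.N25 closing pair) the predicted
# structure reproduces. The lower stem is not part of the motif model, but
# it sits in the folded window and so contributes to the free energy and to
# whether N7.N25 closes.

#' Is the external MFE engine available?
#'
#' @return TRUE when the `RNAfold` executable is on the PATH.
#' @export
vienna_available <- function() {
  nzchar(Sys.which("RNAfold"))
}

run_rnafold <- function(window_seq) {
  if (!vienna_available()) {
    stop("fold engine 'vienna' requires the RNAfold executable on the PATH; ",
         "none was found. Select engine = \"builtin\" for the approximate ",
         "internal folder.")
  }
  out <- system2("RNAfold", args = "--noPS", input = window_seq,
                 stdout = TRUE, stderr = FALSE)
  if (length(out) < 2L) stop("RNAfold produced no structure line")
  line <- out[2L]
  db <- sub("^([.()]+).*$", "\\1", line)
  en <- regmatches(line, regexpr("-?[0-9]+\\.?[0-9]*(?=\\s*\\)\\s*$)",
                                 line, perl = TRUE))
  if (!nchar(db) || !length(en)) {
    stop("could not parse RNAfold output line: ", line)
  }
  list(dot_bracket = db, delta_g = as.numeric(en))
}

# 2-column matrix of (i, j) pairs encoded by a dot-bracket string.
dot_bracket_pairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs <- rbind(pairs, c(j, i))
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pairs
}

# The candidate's six model pairs in sequence coordinates.
model_pairs <- function(core) {
  p <- core$positions
  rbind(
    t(vapply(1:5, function(j) {
      c(p[[STEM_PAIRS[j, "five"]]], p[[STEM_PAIRS[j, "three"]]])
    }, integer(2))),
    c(p[["N7"]], p[["N25"]])
  )
}

#' Fold a candidate with flanking context
#'
#' Extracts the candidate core plus `flank` nucleotides on each side
#' (truncated at sequence ends), predicts its minimum-free-energy structure,
#' and scores concordance: the fraction of the six model base pairs (five
#' upper-stem pairs and N7.N25) present in the predicted structure. Also
#' reports whether the apical loop is left open (no loop position paired,
#' except possibly the N14.N18 cross-loop interaction).
#'
#' The default engine shells out to ViennaRNA's `RNAfold` and reports the
#' true MFE of the folded window in kcal/mol. The `builtin` engine is an
#' approximate internal scorer of the candidate's own model helix (-1.0 per
#' Watson-Crick pair, -0.5 per wobble, additive) for use when no external
#' engine exists; its results are flagged `approximate`.
#'
#' @param seq Normalized RNA string the candidate was scanned from.
#' @param core An `ire_core` candidate.
#' @param flank Context nucleotides on each side of the core (default 15, so
#'   a centered candidate sees at least the recommended ~31-nt context).
#' @param engine `"vienna"` (external MFE) or `"builtin"` (approximate).
#' @return A list of class `ire_fold`: `window_start`, `window_end`,
#'   `window_seq`, `dot_bracket`, `delta_g` (kcal/mol, <= 0), `concordance`
#'   (k/6), `loop_open`, `engine`, `approximate`.
#' @export
fold_window <- function(seq, core, flank = 15L,
                        engine = c("vienna", "builtin")) {
  engine <- match.arg(engine)
  if (is.list(seq) && !is.null(seq$seq)) seq <- seq$seq
  stopifnot(flank >= 0L)
  n <- nchar(seq)
  ws <- max(1L, core$core_start - as.integer(flank))
  we <- min(n, core$core_end + as.integer(flank))
  window_seq <- substr(seq, ws, we)
  mp <- model_pairs(core)
  mp_w <- mp - ws + 1L
  if (engine == "vienna") {
    fr <- run_rnafold(window_seq)
    db <- fr$dot_bracket
    dg <- fr$delta_g
    approx <- FALSE
    pred <- dot_bracket_pairs(db)
    conc <- concordant_pairs(mp_w, pred) / 6
  } else {
    s <- function(i) substr(window_seq, i, i)
    types <- apply(mp_w, 1, function(ij) pair_type(s(ij[1]), s(ij[2])))
    formed <- types != "mismatch"
    dg <- -1.0 * sum(types == "watson_crick") - 0.5 * sum(types == "wobble")
    chars <- rep(".", nchar(window_seq))
    chars[mp_w[formed, 1]] <- "("
    chars[mp_w[formed, 2]] <- ")"
    db <- paste0(chars, collapse = "")
    pred <- mp_w[formed, , drop = FALSE]
    conc <- sum(formed) / 6
    approx <- TRUE
  }
  loop_pos <- core$positions[paste0("N", 14:19)] - ws + 1L
  partner <- rep(NA_integer_, nchar(window_seq))
  if (nrow(pred)) {
    partner[pred[, 1]] <- pred[, 2]
    partner[pred[, 2]] <- pred[, 1]
  }
  lp <- partner[loop_pos]
  n14 <- loop_pos[[1]]; n18 <- loop_pos[[5]]
  loop_open <- all(is.na(lp) |
                     (loop_pos %in% c(n14, n18) & lp %in% c(n14, n18)))
  structure(list(window_start = ws, window_end = we, window_seq = window_seq,
                 dot_bracket = db, delta_g = dg, concordance = conc,
                 loop_open = loop_open, engine = engine,
                 approximate = approx),
            class = "ire_fold")
}

concordant_pairs <- function(model, predicted) {
  if (!nrow(predicted)) return(0L)
  key <- function(m) paste(m[, 1], m[, 2], sep = ":")
  sum(key(model) %in% key(predicted))
}

#' @export
print.ire_fold <- function(x, ...) {
  cat(sprintf("MFE fold [%s%s] window %d-%d: dG %.2f kcal/mol, concordance %d/6%s\n",
              x$engine, if (x$approximate) ", approximate" else "",
              x$window_start, x$window_end, x$delta_g,
              round(x$concordance * 6),
              if (x$loop_open) ", loop open" else ""))
  cat(" ", x$window_seq, "\n ", x$dot_bracket, "\n")
  invisible(x)
}
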