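# Apical-loop motif registry: the curated table of degenerate 6-nt loop
# patterns (N14-N19), the N8 bulge identity each motif requires, the
# N14-N18 cross-loop pair, and the optional N19i-N19ii loop extension.

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Load the IRE motif registry
#'
#' Reads the bundled apical-loop motif table (or a user override in the same
#' format) and validates it. The registry is data, not code: each row defines
#' one degenerate loop pattern over positions N14-N19 together with the N8
#' bulge base the motif requires, the N14-N18 cross-loop pair, and, for the
#' loop-extended motif, the two extra loop nucleotides N19i-N19ii. Motif
#' family 9 is stored as two rows (9a/9b) that partition the allowed N19
#' base, so the registry holds 23 pattern rows for 22 distinct motifs.
#'
#' @param file Optional path to a registry override: tab-separated text with
#'   columns `motif_id`, `family`, `version`, `n8`, `loop_pattern`
#'   (IUPAC, 6 characters), `cross_pair` (e.g. `"C-G"`), `extension`
#'   (`"-"` for none). Lines starting with `#` are ignored.
#' @return A data.frame with one row per loop pattern, in registry order,
#'   with columns `row` (stable row number used for tie-breaking),
#'   `motif_id`, `family`, `version`, `n8`, `loop_pattern`, `cross_pair`,
#'   `extension` (`NA` when absent) and `loop_len` (6 or 8).
#' @examples
#' reg <- ire_motifs()
#' nrow(reg)                       # 23 pattern rows
#' length(unique(reg$family))      # 22 motif families
#' @export
ire_motifs <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "ire_motifs.tsv", package = "irescan")
  }
  if (!file.exists(file)) {
    stop("motif registry file not found: ", file)
  }
  reg <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("motif_id", "family", "version", "n8", "loop_pattern",
              "cross_pair", "extension")
  missing <- setdiff(needed, names(reg))
  if (length(missing)) {
    stop("motif registry is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  reg$extension[reg$extension %in% c("-", "")] <- NA_character_
  reg$row <- seq_len(nrow(reg))
  reg$loop_len <- 6L + 2L * !is.na(reg$extension)
  validate_registry(reg)
  reg[, c("row", "motif_id", "family", "version", "n8", "loop_pattern",
          "cross_pair", "extension", "loop_len")]
}

validate_registry <- function(reg) {
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    where <- sprintf("registry row %d (motif %s)", i, r$motif_id)
    if (nchar(r$loop_pattern) != 6L ||
        !all(strsplit(r$loop_pattern, "")[[1]] %in% names(IUPAC_RNA))) {
      stop(where, ": loop_pattern must be 6 IUPAC RNA characters, got '",
           r$loop_pattern, "'")
    }
    if (!r$n8 %in% c("A", "C", "G", "U")) {
      stop(where, ": n8 must be a single RNA base, got '", r$n8, "'")
    }
    cp <- strsplit(r$cross_pair, "-", fixed = TRUE)[[1]]
    if (length(cp) != 2L || !all(cp %in% c("A", "C", "G", "U"))) {
      stop(where, ": cross_pair must look like 'C-G', got '", r$cross_pair, "'")
    }
    pat <- strsplit(r$loop_pattern, "")[[1]]
    # Table consistency: N14 (pattern position 1) and N18 (position 5) must
    # restate the cross-loop pair.
    if (pat[1] != cp[1] || pat[5] != cp[2]) {
      stop(where, ": loop_pattern positions 1/5 ('", pat[1], "','", pat[5],
           "') disagree with cross_pair '", r$cross_pair, "'")
    }
    if (!r$version %in% c("legacy_v1_2", "new_v3")) {
      stop(where, ": unknown version tag '", r$version, "'")
    }
    if (!is.na(r$extension) &&
        !all(strsplit(r$extension, "")[[1]] %in% c("A", "C", "G", "U"))) {
      stop(where, ": extension must be RNA bases, got '", r$extension, "'")
    }
  }
  if (anyDuplicated(reg$motif_id)) {
    stop("registry motif_id values must be unique")
  }
  invisible(reg)
}

# Character vector of bases allowed at one IUPAC position.
iupac_bases <- function(code) {
  b <- IUPAC_RNA[[code]]
  if (is.null(b)) stop("unknown IUPAC code '", code, "'")
  b
}

# Translate a 6-character IUPAC loop pattern into a plain regular
# expression over {A,C,G,U}. Ambiguity codes in the *sequence* are never
# matched: the character classes contain concrete bases only.
loop_pattern_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  paste0(vapply(chars, function(ch) {
    b <- iupac_bases(ch)
    if (length(b) == 1L) b else paste0("[", paste0(b, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Match apical-loop motifs at one sequence position
#'
#' Tests the 6-mer starting at `pos` against every degenerate loop pattern in
#' the registry. Patterns are not mutually exclusive, so several motifs can
#' match the same site; all matches are returned and the per-site winner is
#' chosen only after scoring. The loop-extended motif additionally requires
#' its two extension bases immediately after the 6-mer and reports an 8-nt
#' loop.
#'
#' @param seq A normalized RNA string (see [normalize_sequence()]).
#' @param pos 1-based offset of the first loop position (N14);
#'   `pos + 5 <= nchar(seq)` is required.
#' @param registry A registry from [ire_motifs()].
#' @return A data.frame of matching registry rows with an extra column
#'   `loop_seq`, the matched loop including any extension. Zero rows when
#'   nothing matches.
#' @examples
#' reg <- ire_motifs()
#' match_loop("CAGUGC", 1, reg)$motif_id   # "1" and "20" (not "22": no CA)
#' @export
match_loop <- function(seq, pos, registry = ire_motifs()) {
  n <- nchar(seq)
  if (pos < 1L || pos + 5L > n) {
    stop("loop position out of range: pos=", pos, ", length=", n)
  }
  if (grepl("[^ACGUN]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGUN]", seq))
    stop("sequence contains non-RNA character '", bad,
         "'; normalize_sequence() it first")
  }
  six <- substr(seq, pos, pos + 5L)
  hit <- logical(nrow(registry))
  loop_seq <- character(nrow(registry))
  for (i in seq_len(nrow(registry))) {
    if (!grepl(paste0("^", loop_pattern_regex(registry$loop_pattern[i]), "$"),
               six)) next
    ext <- registry$extension[i]
    if (!is.na(ext)) {
      end <- pos + 5L + nchar(ext)
      if (end > n || substr(seq, pos + 6L, end) != ext) next
      loop_seq[i] <- substr(seq, pos, end)
    } else {
      loop_seq[i] <- six
    }
    hit[i] <- TRUE
  }
  out <- registry[hit, , drop = FALSE]
  out$loop_seq <- loop_seq[hit]
  rownames(out) <- NULL
  out
}
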