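# Candidate assembly: around every apical-loop hit, build the full IRE core
# (5-bp upper stem, N8 bulge, N7.N25 closing pair, optional single bulged
# nucleotide in either stem arm or on the 3' strand before N25), recording
# every structural defect for the scorer.

#' Scanner parameters
#'
#' Structural-defect limits used by [scan_sequence()]. The model tolerates
#' near-perfect stems only: by default at most one mismatched upper-stem pair
#' and at most one single-nucleotide stem bulge per candidate, with G.U
#' wobbles accepted as paired (they carry their own small penalty at scoring
#' time, not a defect count here).
#'
#' @param max_mismatches Maximum mismatched upper-stem pairs (default 1).
#' @param max_stem_bulges Maximum single-nucleotide insertions across the two
#'   upper-stem arms (default 1).
#' @param allow_wobble Accept G.U as a paired (wobble) upper-stem position
#'   rather than a mismatch (default TRUE).
#' @param allow_3prime_bulge Allow one unpaired nucleotide between N24 and
#'   N25 on the 3' strand, as in the EPAS1 and SLC11A2 IREs (default TRUE).
#' @param max_len Maximum accepted sequence length for normalization
#'   (default 50000).
#' @return A named list of class `ire_scan_params`.
#' @export
scan_params <- function(max_mismatches = 1L, max_stem_bulges = 1L,
                        allow_wobble = TRUE, allow_3prime_bulge = TRUE,
                        max_len = 50000L) {
  stopifnot(max_mismatches >= 0L, max_stem_bulges >= 0L, max_len >= 1L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 max_stem_bulges = as.integer(max_stem_bulges),
                 allow_wobble = isTRUE(allow_wobble),
                 allow_3prime_bulge = isTRUE(allow_3prime_bulge),
                 max_len = as.integer(max_len)),
            class = "ire_scan_params")
}

#' Normalize an input sequence to RNA
#'
#' Uppercases and converts T to U so DNA and RNA inputs share one code path.
#' IUPAC ambiguity codes are preserved but never matched by motif patterns
#' or counted as paired. No positions are dropped, so reported coordinates
#' always refer to the input as given (the offset map is the identity).
#'
#' @param raw Input sequence, DNA or RNA, any case.
#' @param max_len Length cap; inputs longer than this are rejected
#'   (default 50000).
#' @return A list with `seq` (normalized RNA string) and `offset_map`
#'   (integer vector mapping normalized to input positions; identity).
#' @examples
#' normalize_sequence("acgt")$seq  # "ACGU"
#' @export
normalize_sequence <- function(raw, max_len = 50000L) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("empty input sequence")
  }
  n <- nchar(raw)
  if (n > max_len) {
    stop("input sequence has ", n, " residues, over the per-submission cap of ",
         max_len)
  }
  seq <- chartr("t", "u", toupper(raw))
  seq <- chartr("T", "U", seq)
  if (grepl("[^ACGURYSWKMBDHVN]", seq)) {
    bad <- regmatches(seq, regexpr("[^ACGURYSWKMBDHVN]", seq))
    stop("sequence contains non-nucleotide character '", bad, "'")
  }
  list(seq = seq, offset_map = seq_len(n))
}

#' Classify a base pair
#'
#' @param a,b Single RNA bases.
#' @param allow_wobble Report G.U/U.G as `"wobble"`; otherwise they are
#'   mismatches.
#' @return `"watson_crick"`, `"wobble"` or `"mismatch"`.
#' @export
pair_type <- function(a, b, allow_wobble = TRUE) {
  ab <- paste0(a, b)
  if (ab %in% c("AU", "UA", "GC", "CG")) return("watson_crick")
  if (ab %in% c("GU", "UG") && allow_wobble) return("wobble")
  "mismatch"
}

# Upper-stem pairing scheme: pair index j = 1..5 pairs N(8+j) with N(25-j),
# i.e. (N9,N24) (N10,N23) (N11,N22) (N12,N21) (N13,N20).
STEM_PAIRS <- cbind(five = paste0("N", 9:13), three = paste0("N", 24:20))

#' Scan a sequence for IRE candidates
#'
#' For every apical-loop motif hit at every offset, attempts all stem
#' assemblies consistent with the defect limits: the 5' arm N9-N13
#' immediately 5' of the loop and the 3' arm N20-N24 immediately 3' of it
#' (after the loop extension when present), each arm optionally carrying one
#' single-nucleotide insertion; N8 must equal the motif's bulge base and sit
#' immediately 5' of N9; N7.N25 is evaluated as a pair (its status is
#' recorded, never filtered on); optionally one bulged nucleotide between
#' N24 and N25. Candidates whose core would run off either sequence end are
#' skipped silently, so a bare 19-nt perfect core is detectable with zero
#' flanking sequence.
#'
#' @param seq Normalized RNA string (or the list from
#'   [normalize_sequence()]).
#' @param registry Motif registry from [ire_motifs()].
#' @param params Limits from [scan_params()].
#' @param seq_id Identifier stored on each candidate.
#' @return A list of `ire_core` candidate records (possibly empty). Each has
#'   `positions`, a named vector of 1-based offsets for N7..N25 (plus
#'   `N19i`/`N19ii` and bulge positions when present), and `defects`
#'   itemizing mismatched pairs, wobble pairs, stem bulges and the N7.N25
#'   status.
#' @export
scan_sequence <- function(seq, registry = ire_motifs(),
                          params = scan_params(), seq_id = "seq") {
  if (is.list(seq)) seq <- seq$seq
  n <- nchar(seq)
  out <- list()
  if (n < 19L) return(out)
  for (i in seq_len(nrow(registry))) {
    row <- registry[i, ]
    rx <- paste0("(?=", loop_pattern_regex(row$loop_pattern), ")")
    hits <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    for (loop_start in as.integer(hits)) {
      ext <- row$extension
      if (!is.na(ext)) {
        end <- loop_start + 5L + nchar(ext)
        if (end > n || substr(seq, loop_start + 6L, end) != ext) next
      }
      out <- c(out, assemble_candidates(seq, loop_start, row, params, seq_id))
    }
  }
  # stable order: by loop position, then registry row
  if (length(out) > 1L) {
    ord <- order(vapply(out, `[[`, 1L, "loop_start"),
                 vapply(out, `[[`, 1L, "row"))
    out <- out[ord]
  }
  out
}

# All stem assemblies for one (loop position, motif) combination.
assemble_candidates <- function(seq, loop_start, row, params, seq_id) {
  n <- nchar(seq)
  s <- function(i) substr(seq, i, i)
  loop_len <- row$loop_len
  loop_end <- loop_start + loop_len - 1L
  cands <- list()
  b3p_options <- if (params$allow_3prime_bulge) c(FALSE, TRUE) else FALSE
  for (b5 in 0:4) {
    for (b3 in 0:4) {
      if ((b5 > 0L) + (b3 > 0L) > params$max_stem_bulges) next
      # 5' arm, N13 down to N9; gap k sits between N(14-k) and N(13-k)
      off <- loop_start - 1L
      pos5 <- c(N13 = off)
      bulge5_off <- NA_integer_
      for (k in 1:4) {
        off <- off - 1L
        if (b5 == k) { bulge5_off <- off; off <- off - 1L }
        pos5[paste0("N", 13L - k)] <- off
      }
      n9 <- pos5[["N9"]]
      n8 <- n9 - 1L
      n7 <- n8 - 1L
      # 3' arm, N20 up to N24; gap k sits between N(19+k) and N(20+k)
      off <- loop_end + 1L
      pos3 <- c(N20 = off)
      bulge3_off <- NA_integer_
      for (k in 1:4) {
        off <- off + 1L
        if (b3 == k) { bulge3_off <- off; off <- off + 1L }
        pos3[paste0("N", 20L + k)] <- off
      }
      n24 <- pos3[["N24"]]
      for (b3p in b3p_options) {
        n25 <- n24 + 1L + b3p
        if (n7 < 1L || n25 > n) next
        if (s(n8) != row$n8) next
        types <- vapply(1:5, function(j) {
          a <- s(c(pos5, N7 = n7)[[STEM_PAIRS[j, "five"]]])
          b <- s(pos3[[STEM_PAIRS[j, "three"]]])
          pair_type(a, b, params$allow_wobble)
        }, character(1))
        mism <- which(types == "mismatch")
        if (length(mism) > params$max_mismatches) next
        wob <- which(types == "wobble")
        n7_n25 <- pair_type(s(n7), s(n25), allow_wobble = TRUE)
        positions <- c(N7 = n7, N8 = n8, sort(pos5))
        loop_named <- setNames(loop_start:(loop_start + 5L), paste0("N", 14:19))
        positions <- c(positions, loop_named)
        if (!is.na(row$extension)) {
          positions <- c(positions,
                         N19i = loop_start + 6L, N19ii = loop_start + 7L)
        }
        positions <- c(positions, sort(pos3))
        if (b3p) positions <- c(positions, B3p = n24 + 1L)
        positions <- c(positions, N25 = n25)
        stem_bulges <- c(bulge5_off, bulge3_off)
        stem_bulges <- stem_bulges[!is.na(stem_bulges)]
        cands[[length(cands) + 1L]] <- structure(list(
          seq_id = seq_id,
          loop_start = loop_start,
          motif_id = row$motif_id,
          family = row$family,
          row = row$row,
          loop_len = loop_len,
          positions = positions,
          has_3prime_bulge = b3p,
          defects = list(mismatch_pairs = mism,
                         wobble_pairs = wob,
                         stem_bulges = stem_bulges,
                         n7_n25 = n7_n25),
          core_start = n7,
          core_end = n25,
          core_seq = substr(seq, n7, n25)
        ), class = "ire_core")
      }
    }
  }
  cands
}

# Total structural defects, used as the last tie-break at winner selection.
n_defects <- function(core) {
  d <- core$defects
  length(d$mismatch_pairs) + length(d$wobble_pairs) + length(d$stem_bulges) +
    (d$n7_n25 != "watson_crick")
}

#' Group candidate interpretations by site
#'
#' Candidates sharing one apical-loop offset are alternative structural
#' interpretations of the same site. All are retained through scoring; the
#' per-site winner is chosen afterwards with [pick_site_winner()].
#'
#' @param cands List of `ire_core` candidates from one sequence.
#' @return A list of candidate groups, one per distinct loop offset, in
#'   sequence order.
#' @export
site_groups <- function(cands) {
  if (!length(cands)) return(list())
  starts <- vapply(cands, `[[`, 1L, "loop_start")
  groups <- split(cands, starts)
  groups[order(as.integer(names(groups)))]
}

#' @export
print.ire_core <- function(x, ...) {
  d <- x$defects
  cat(sprintf(
    "IRE candidate [%s] motif %s: core %d-%d, loop at %d%s\n",
    x$seq_id, x$motif_id, x$core_start, x$core_end, x$loop_start,
    if (x$has_3prime_bulge) ", 3' bulge" else ""))
  cat(sprintf("  defects: %d mismatch, %d wobble, %d stem bulge; N7.N25 %s\n",
              length(d$mismatch_pairs), length(d$wobble_pairs),
              length(d$stem_bulges), d$n7_n25))
  invisible(x)
}
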