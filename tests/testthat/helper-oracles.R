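# Independent oracles for the motif matcher and the scanner. These
# re-transcribe the motif table as explicit per-position base sets and
# re-implement matching/assembly by direct enumeration, sharing no code
# with the package paths they check.

ACGU <- c("A", "C", "G", "U")

oracle_motifs <- local({
  p <- function(...) lapply(list(...), function(x) strsplit(x, "")[[1]])
  list(
    list(id = "1",  n8 = "C", pos = p("C", "A", "G", "U", "G", "ACGU")),
    list(id = "2",  n8 = "C", pos = p("C", "A", "G", "A", "G", "ACU")),
    list(id = "3",  n8 = "C", pos = p("C", "U", "G", "U", "G", "CU")),
    list(id = "4",  n8 = "C", pos = p("C", "C", "G", "U", "G", "ACU")),
    list(id = "5",  n8 = "C", pos = p("C", "C", "G", "A", "G", "A")),
    list(id = "6",  n8 = "C", pos = p("C", "U", "U", "A", "G", "C")),
    list(id = "7",  n8 = "C", pos = p("C", "A", "A", "U", "G", "C")),
    list(id = "8",  n8 = "C", pos = p("C", "A", "G", "G", "G", "ACGU")),
    list(id = "9a", n8 = "C", pos = p("U", "A", "G", "U", "A", "CU")),
    list(id = "9b", n8 = "C", pos = p("U", "A", "G", "U", "A", "AG")),
    list(id = "10", n8 = "C", pos = p("U", "A", "G", "G", "A", "U")),
    list(id = "11", n8 = "C", pos = p("U", "A", "G", "A", "A", "CU")),
    list(id = "12", n8 = "C", pos = p("U", "A", "G", "C", "A", "G")),
    list(id = "13", n8 = "C", pos = p("G", "A", "G", "U", "C", "AG")),
    list(id = "14", n8 = "C", pos = p("G", "A", "G", "C", "C", "AG")),
    list(id = "15", n8 = "C", pos = p("G", "A", "G", "A", "G", "GU")),
    list(id = "16", n8 = "C", pos = p("G", "G", "G", "A", "G", "ACGU")),
    list(id = "17", n8 = "C", pos = p("G", "A", "G", "U", "G", "AU")),
    list(id = "18", n8 = "G", pos = p("C", "A", "G", "U", "G", "A")),
    list(id = "19", n8 = "C", pos = p("A", "A", "G", "U", "U", "ACGU")),
    list(id = "20", n8 = "U", pos = p("C", "A", "G", "U", "G", "ACGU")),
    list(id = "21", n8 = "U", pos = p("C", "A", "G", "A", "G", "ACGU")),
    list(id = "22", n8 = "U", pos = p("C", "A", "G", "U", "G", "ACGU"),
         ext = "CA")
  )
})

# Motif ids whose loop pattern admits `loop6`, given the two characters
# that follow it (for the extension-bearing motif).
oracle_match <- function(loop6, after = "") {
  chars <- strsplit(loop6, "")[[1]]
  ids <- character(0)
  for (m in oracle_motifs) {
    ok <- all(vapply(1:6, function(i) chars[i] %in% m$pos[[i]], logical(1)))
    if (ok && !is.null(m$ext)) ok <- identical(substr(after, 1, 2), m$ext)
    if (ok) ids <- c(ids, m$id)
  }
  ids
}

oracle_is_paired <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

# Defect-free scanner by direct enumeration: every offset against every
# motif, exact contiguous arms, all five upper-stem pairs paired
# (Watson-Crick or wobble), N8 identity enforced, N7/N25 unconstrained.
oracle_scan <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  out <- data.frame(loop_start = integer(0), motif_id = character(0))
  for (s in seq_len(max(0, n - 5))) {
    loop6 <- paste0(chars[s:(s + 5)], collapse = "")
    after <- if (s + 7 <= n) paste0(chars[(s + 6):(s + 7)], collapse = "") else ""
    for (id in oracle_match(loop6, after)) {
      m <- oracle_motifs[[which(vapply(oracle_motifs, `[[`, "", "id") == id)]]
      ext_len <- if (is.null(m$ext)) 0L else nchar(m$ext)
      e <- s + 5L + ext_len
      if (s - 7L < 1L || e + 6L > n) next
      if (chars[s - 6L] != m$n8) next
      arm5 <- chars[(s - 5L):(s - 1L)]              # N9..N13
      arm3 <- chars[(e + 1L):(e + 5L)]              # N20..N24
      paired <- vapply(1:5, function(j) {
        oracle_is_paired(arm5[j], arm3[6L - j])
      }, logical(1))
      if (all(paired)) {
        out <- rbind(out, data.frame(loop_start = s, motif_id = id))
      }
    }
  }
  out
}

# Fabricated fold record for scoring tests that hold folding evidence fixed.
make_fold <- function(concordance = 1, delta_g = -5) {
  structure(list(window_start = 1L, window_end = 19L, window_seq = "",
                 dot_bracket = "", delta_g = delta_g,
                 concordance = concordance, loop_open = TRUE,
                 engine = "stub", approximate = TRUE),
            class = "ire_fold")
}

all_sixmers <- function() {
  g <- expand.grid(ACGU, ACGU, ACGU, ACGU, ACGU, ACGU,
                   stringsAsFactors = FALSE)
  apply(g, 1, paste0, collapse = "")
}
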