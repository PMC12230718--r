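# Deterministic synthetic fixtures: IRE cores built exactly on the
# structural model (optionally with requested defects), planted in random
# backgrounds that are rejection-sampled so no spurious perfect loop motif
# appears by chance. These are the test and calibration substrate; they do
# not attempt to mimic real UTR base composition.

RNA_BASES <- c("A", "C", "G", "U")
WC_PARTNER <- c(A = "U", U = "A", C = "G", G = "C")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched. NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

# A base that pairs with `a` neither canonically nor as a wobble.
non_pairing_base <- function(a) {
  bad <- c(WC_PARTNER[[a]], if (a == "G") "U", if (a == "U") "G")
  sample(setdiff(RNA_BASES, bad), 1)
}

#' Build a synthetic IRE core
#'
#' Emits a sequence satisfying the structural model exactly, except for the
#' requested defects: `mismatches` broken upper-stem pairs, `stem_bulges`
#' single-nucleotide insertions (placed in the 3' arm), the N7.N25 status,
#' and optionally the single 3' bulged nucleotide between N24 and N25.
#' `lower_stem` adds that many Watson-Crick lower-stem pairs flanking the
#' core, giving the fold a lower stem to close N7.N25 against (natural IREs
#' carry one of variable length). Deterministic given `seed`.
#'
#' @param motif_id Registry motif identifier (e.g. `"1"`, `"9b"`, `"22"`).
#' @param mismatches,stem_bulges Defect counts (each at most 1, the scanner
#'   caps).
#' @param n7_n25 `"pair"`, `"wobble"` or `"mismatch"`.
#' @param with_3prime_bulge Insert a bulged nucleotide before N25.
#' @param lower_stem Number of flanking lower-stem base pairs (default 0:
#'   bare core).
#' @param seed Integer seed.
#' @param registry Motif registry.
#' @return A list of class `ire_fixture`: `seq` (the emitted string),
#'   `core_start`, `core_end`, `loop_start` (all 1-based in `seq`),
#'   `motif_id`, `family`, `row`, `defects` (the requested spec),
#'   `has_3prime_bulge`.
#' @examples
#' fx <- build_core("1", seed = 7)
#' nchar(fx$seq)  # 19: the bare perfect core
#' @export
build_core <- function(motif_id, mismatches = 0L, stem_bulges = 0L,
                       n7_n25 = c("pair", "wobble", "mismatch"),
                       with_3prime_bulge = FALSE, lower_stem = 0L,
                       seed = NULL, registry = ire_motifs()) {
  n7_n25 <- match.arg(n7_n25)
  row <- registry[registry$motif_id == as.character(motif_id), ]
  if (nrow(row) != 1L) stop("unknown motif_id '", motif_id, "'")
  if (mismatches > 1L || stem_bulges > 1L) {
    stop("unsatisfiable defect spec: the scanner caps allow at most 1 ",
         "mismatch and 1 stem bulge per candidate")
  }
  with_seed(seed, {
    loop <- vapply(strsplit(row$loop_pattern, "")[[1]],
                   function(ch) sample(iupac_bases(ch), 1), character(1))
    ext <- if (is.na(row$extension)) character(0) else
      strsplit(row$extension, "")[[1]]
    arm5 <- sample(RNA_BASES, 5, replace = TRUE)            # N9..N13
    arm3 <- rev(WC_PARTNER[arm5])                           # N20..N24
    if (mismatches == 1L) {
      j <- sample(1:5, 1)              # pair index: (N9,N24) ... (N13,N20)
      arm3[6L - j] <- non_pairing_base(arm5[j])
    }
    n7 <- sample(RNA_BASES, 1)
    if (n7_n25 != "pair") {
      # keep the requested closing-pair defect identifiable: if N7 (or N9)
      # could read as the motif's bulge base, the scanner can slide the
      # frame into the lower stem and recast the defect as a stem bulge
      n7 <- sample(setdiff(RNA_BASES, row$n8), 1)
      while (arm5[1] == row$n8) arm5[1] <- sample(RNA_BASES, 1)
    }
    n25 <- switch(n7_n25,
                  pair = WC_PARTNER[[n7]],
                  wobble = { n7 <- if (row$n8 == "G") "U" else "G"
                             if (n7 == "G") "U" else "G" },
                  mismatch = non_pairing_base(n7))
    arm3_full <- as.character(arm3)
    if (stem_bulges == 1L) {
      gap <- sample(1:4, 1)            # insertion between N(19+gap), N(20+gap)
      arm3_full <- append(arm3_full, sample(RNA_BASES, 1), after = gap)
    }
    tail3 <- if (with_3prime_bulge) c(sample(RNA_BASES, 1), n25) else n25
    core <- c(n7, row$n8, arm5, loop, ext, arm3_full, tail3)
    stem5 <- if (lower_stem > 0L) sample(RNA_BASES, lower_stem, replace = TRUE)
             else character(0)
    if (lower_stem > 0L && n7_n25 != "pair") {
      # keep the requested closing-pair defect identifiable: the lower-stem
      # base abutting N25 must not offer N7 an alternative (3'-bulge) pairing
      while (pair_type(n7, WC_PARTNER[[stem5[lower_stem]]]) != "mismatch") {
        stem5[lower_stem] <- sample(RNA_BASES, 1)
      }
    }
    stem3 <- rev(WC_PARTNER[stem5])
    seq <- paste0(c(stem5, core, stem3), collapse = "")
    structure(list(seq = seq,
                   core_start = lower_stem + 1L,
                   core_end = lower_stem + length(core),
                   loop_start = lower_stem + 8L,
                   motif_id = row$motif_id, family = row$family,
                   row = row$row,
                   defects = list(mismatches = as.integer(mismatches),
                                  stem_bulges = as.integer(stem_bulges),
                                  n7_n25 = n7_n25),
                   has_3prime_bulge = isTRUE(with_3prime_bulge)),
              class = "ire_fixture")
  })
}

# Loop-motif hit offsets anywhere in `seq`, across the whole registry.
loop_hits <- function(seq, registry) {
  hits <- integer(0)
  for (i in seq_len(nrow(registry))) {
    rx <- paste0("(?=", loop_pattern_regex(registry$loop_pattern[i]), ")")
    h <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (h[1] != -1L) hits <- c(hits, as.integer(h))
  }
  sort(unique(hits))
}

#' Plant a core in a random background
#'
#' Splices the fixture core into a uniform-random background so the final
#' record has length `background_len` with the core starting at `position`.
#' The background is rejection-sampled: if any exact loop-motif hit occurs
#' wholly outside the planted insert the background is redrawn, so no
#' perfect loop arises in the background by chance. Hits overlapping the
#' insert (the planted loop itself, or a junction 6-mer borrowing core
#' bases) are left alone: junction hits cannot always be avoided -- some
#' cores end in the first five bases of a loop pattern whose last position
#' accepts any base -- and, like spurious partial hits, they exercise the
#' stem filter.
#'
#' @param fixture A [build_core()] result (or plain core string).
#' @param background_len Total record length.
#' @param position 1-based start of the core in the record.
#' @param seed Integer seed.
#' @param seq_id Record identifier.
#' @param registry Motif registry.
#' @return A list of class `ire_fixture`: `seq`, `seq_id`, plus the fixture
#'   truth fields shifted to record coordinates.
#' @export
plant_core <- function(fixture, background_len, position, seed = NULL,
                       seq_id = "planted", registry = ire_motifs()) {
  if (is.character(fixture)) {
    fixture <- list(seq = fixture, core_start = 1L,
                    core_end = nchar(fixture), loop_start = 8L,
                    motif_id = NA_character_, family = NA_character_,
                    row = NA_integer_, defects = NULL,
                    has_3prime_bulge = FALSE)
  }
  core <- fixture$seq
  core_len <- nchar(core)
  if (position < 1L || position + core_len - 1L > background_len) {
    stop("core of ", core_len, " nt cannot start at ", position,
         " in a record of ", background_len, " nt")
  }
  with_seed(seed, {
    insert_start <- position
    insert_end <- position + core_len - 1L
    for (try in 1:200) {
      bg <- sample(RNA_BASES, background_len - core_len, replace = TRUE)
      seq <- paste0(c(head(bg, position - 1L), strsplit(core, "")[[1]],
                      bg[seq_len(length(bg)) >= position]), collapse = "")
      hits <- loop_hits(seq, registry)
      spurious <- hits[hits + 5L < insert_start | hits > insert_end]
      if (!length(spurious)) {
        return(structure(list(seq = seq, seq_id = seq_id,
                              core_start = position + fixture$core_start - 1L,
                              core_end = position + fixture$core_end - 1L,
                              loop_start = position + fixture$loop_start - 1L,
                              motif_id = fixture$motif_id,
                              family = fixture$family, row = fixture$row,
                              defects = fixture$defects,
                              has_3prime_bulge = fixture$has_3prime_bulge),
                         class = "ire_fixture"))
      }
    }
    stop("could not sample a background free of spurious loop motifs in ",
         "200 draws (background_len = ", background_len, ")")
  })
}

#' Synthetic labelled control set
#'
#' Builds a labelled positive/negative sequence set for benchmarking
#' exercises: positives are random-background records with one planted IRE
#' core (random motif family, optionally with defects), negatives are plain
#' uniform-random records that may or may not contain chance partial motifs.
#'
#' @param n_pos,n_neg Record counts.
#' @param len Record length (default 120).
#' @param defect_rate Fraction of positives carrying one random structural
#'   defect (default 0.3).
#' @param seed Integer seed.
#' @param registry Motif registry.
#' @return A list: `seqs` (named character vector), `labels` (data.frame
#'   `seq_id`, `label`), `truth` (list of planted fixtures for positives).
#' @export
synthetic_controls <- function(n_pos, n_neg, len = 120L, defect_rate = 0.3,
                               seed = NULL, registry = ire_motifs()) {
  with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    for (i in seq_len(n_pos)) {
      id <- sprintf("pos_%03d", i)
      motif <- sample(registry$motif_id, 1)
      defect <- runif(1) < defect_rate
      fx <- build_core(motif,
                       mismatches = if (defect && runif(1) < 0.5) 1L else 0L,
                       stem_bulges = if (defect && runif(1) < 0.5) 1L else 0L,
                       lower_stem = 4L,
                       seed = NULL, registry = registry)
      core_len <- nchar(fx$seq)
      pos <- sample.int(len - core_len + 1L, 1)
      pl <- plant_core(fx, len, pos, seed = NULL, seq_id = id,
                       registry = registry)
      seqs[id] <- pl$seq
      truth[[id]] <- pl
    }
    for (i in seq_len(n_neg)) {
      id <- sprintf("neg_%03d", i)
      seqs[id] <- paste0(sample(RNA_BASES, len, replace = TRUE),
                         collapse = "")
    }
    labels <- data.frame(seq_id = names(seqs),
                         label = rep(c("pos", "neg"), c(n_pos, n_neg)),
                         stringsAsFactors = FALSE)
    list(seqs = seqs, labels = labels, truth = truth)
  })
}
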