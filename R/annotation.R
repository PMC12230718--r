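# Transcript-context annotation: where a predicted IRE sits on its
# transcript (5'UTR, boundary classes, CDS, 3'UTR) and how far its midpoint
# lies from the cap, the start codon and the stop codon. IRP binding at a
# 5'UTR IRE represses translation while a 3'UTR IRE stabilizes the mRNA, so
# location determines the element's functional reading.

LOCATION_LEVELS <- c("5UTR", "5UTR-CDS", "CDS", "CDS-3UTR", "3UTR")
BOUNDARY_WINDOW <- 15L  # |midpoint - junction| < 15 -> boundary class

#' Transcript context
#'
#' CDS coordinates on one transcript, 1-based inclusive: `cds_start` is the
#' first nucleotide of the start codon (the A of AUG, position A+1 in most
#' transcripts) and `cds_end` the last nucleotide of the stop codon.
#'
#' @param transcript_id Identifier matching the FASTA record.
#' @param cds_start,cds_end 1-based CDS bounds.
#' @param length Transcript length in nt.
#' @return A list of class `transcript_context`.
#' @export
transcript_context <- function(transcript_id, cds_start, cds_end, length) {
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  length <- as.integer(length)
  if (!(1L <= cds_start && cds_start < cds_end && cds_end <= length)) {
    stop("invalid CDS bounds for ", transcript_id, ": need 1 <= cds_start < ",
         "cds_end <= length, got ", cds_start, ", ", cds_end, ", ", length)
  }
  if ((cds_end - cds_start + 1L) %% 3L != 0L) {
    stop("CDS length for ", transcript_id, " (", cds_end - cds_start + 1L,
         " nt) is not a multiple of 3")
  }
  structure(list(transcript_id = transcript_id, cds_start = cds_start,
                 cds_end = cds_end, length = length),
            class = "transcript_context")
}

#' Read a CDS coordinate table
#'
#' Delimited text with columns `transcript_id`, `cds_start`, `cds_end`,
#' `length` (1-based inclusive).
#'
#' @param file Path to the table.
#' @return A named list of [transcript_context()] objects keyed by
#'   transcript_id.
#' @export
read_cds_table <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  needed <- c("transcript_id", "cds_start", "cds_end", "length")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("CDS table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    transcript_context(tab$transcript_id[i], tab$cds_start[i],
                       tab$cds_end[i], tab$length[i])
  })
  setNames(out, tab$transcript_id)
}

#' Extract CDS contexts from a GFF3 file
#'
#' Reads `CDS` features in transcript coordinates from a GFF3 annotation and
#' builds one [transcript_context()] per sequence region, spanning the first
#' to the last CDS nucleotide. `lengths` supplies transcript lengths (named
#' integer vector); missing lengths default to the end of the last feature
#' on the transcript.
#'
#' @param file GFF3 path.
#' @param lengths Optional named integer vector of transcript lengths.
#' @return Named list of contexts, as [read_cds_table()].
#' @export
cds_from_gff3 <- function(file, lengths = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("cds_from_gff3 needs the rtracklayer package")
  }
  gr <- rtracklayer::import(file, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (!length(cds)) stop("no CDS features in ", file)
  ids <- as.character(GenomicRanges::seqnames(cds))
  out <- list()
  for (id in unique(ids)) {
    sel <- cds[ids == id]
    len <- if (!is.null(lengths) && id %in% names(lengths)) {
      lengths[[id]]
    } else {
      max(GenomicRanges::end(gr[as.character(GenomicRanges::seqnames(gr)) == id]))
    }
    out[[id]] <- transcript_context(id, min(GenomicRanges::start(sel)),
                                    max(GenomicRanges::end(sel)), len)
  }
  out
}

#' IRE midpoint position
#'
#' The middle position of the element: N16 for a core without a 3' bulged
#' nucleotide, N17 for one with it; 1-based in transcript coordinates.
#'
#' @param core An `ire_core`.
#' @return Integer position.
#' @export
ire_midpoint <- function(core) {
  key <- if (core$has_3prime_bulge) "N17" else "N16"
  unname(core$positions[[key]])
}

#' Classify an IRE location on its transcript
#'
#' Five classes. A midpoint within strictly fewer than 15 nt of the first
#' nucleotide of the start codon is `5UTR-CDS`; within strictly fewer than
#' 15 nt of the last nucleotide of the stop codon, `CDS-3UTR` (the start
#' boundary wins if both windows cover the midpoint, possible only for a CDS
#' under 30 nt); otherwise plain `5UTR`, `CDS` or `3UTR` by position.
#'
#' @param mid 1-based midpoint position.
#' @param ctx A [transcript_context()].
#' @return One of `"5UTR"`, `"5UTR-CDS"`, `"CDS"`, `"CDS-3UTR"`, `"3UTR"`.
#' @export
classify_location <- function(mid, ctx) {
  if (mid < 1L || mid > ctx$length) {
    stop("midpoint ", mid, " outside transcript ", ctx$transcript_id,
         " (length ", ctx$length, ")")
  }
  dA <- mid - ctx$cds_start
  dT <- mid - ctx$cds_end
  if (abs(dA) < BOUNDARY_WINDOW) return("5UTR-CDS")
  if (abs(dT) < BOUNDARY_WINDOW) return("CDS-3UTR")
  if (mid < ctx$cds_start) return("5UTR")
  if (mid <= ctx$cds_end) return("CDS")
  "3UTR"
}

#' Distances from the IRE midpoint to key transcript elements
#'
#' For a 5'UTR or 5'UTR-CDS element: distance to the translational start
#' site (`d5_ire_aug = cds_start - mid`; negative when the midpoint lies
#' inside the CDS) and to the m7G cap (`d_cap_5ire = mid - 1`, the cap
#' abutting transcript position 1). For a 3'UTR or CDS-3'UTR element:
#' distance from the terminal codon (`d_ter_3ire = mid - cds_end`). CDS
#' elements get no distances.
#'
#' @param mid Midpoint position.
#' @param location Class from [classify_location()].
#' @param ctx A [transcript_context()].
#' @return List with `d5_ire_aug`, `d_cap_5ire`, `d_ter_3ire` (NA when not
#'   applicable).
#' @export
compute_distances <- function(mid, location, ctx) {
  out <- list(d5_ire_aug = NA_integer_, d_cap_5ire = NA_integer_,
              d_ter_3ire = NA_integer_)
  if (location %in% c("5UTR", "5UTR-CDS")) {
    out$d5_ire_aug <- ctx$cds_start - mid
    out$d_cap_5ire <- mid - 1L
  } else if (location %in% c("3UTR", "CDS-3UTR")) {
    out$d_ter_3ire <- mid - ctx$cds_end
  }
  out
}

#' Collapse redundant IREs within genes
#'
#' When the same element is predicted in multiple transcripts of one gene
#' (isoform redundancy), a single occurrence is retained; distinct elements
#' within the same gene are all kept. Identity is (core sequence, motif,
#' location) within one gene. Input order is preserved; the first occurrence
#' of each identity survives.
#'
#' @param df A prediction data.frame carrying columns `gene`, `core_seq`,
#'   `motif_id`, `location`.
#' @return The non-redundant subset, original order.
#' @export
collapse_redundant <- function(df) {
  stopifnot(all(c("gene", "core_seq", "motif_id", "location") %in% names(df)))
  key <- paste(df$gene, df$core_seq, df$motif_id, df$location, sep = "\r")
  df[!duplicated(key), , drop = FALSE]
}

#' Per-region counts and densities
#'
#' Counts predictions per location class, and normalizes by the total length
#' of each region class across the supplied transcripts: 5'UTR
#' (`cds_start - 1` nt), CDS, 3'UTR (`length - cds_end` nt); the two
#' boundary classes are normalized by their 29-nt midpoint windows (the
#' strictly-within-15 rule admits 29 midpoints around each junction),
#' truncated at transcript ends. Length-normalized density exposes
#' enrichment that raw counts hide: the 5'UTR is short, so even modest
#' counts there can be the highest density.
#'
#' @param df Prediction data.frame with a `location` column (NA rows are
#'   ignored) and a `seq_id` column naming the transcript.
#' @param contexts Named list of [transcript_context()] covering every
#'   annotated record.
#' @return data.frame with `location`, `count`, `region_nt`, `density`
#'   (count per nt).
#' @export
region_enrichment <- function(df, contexts) {
  located <- df[!is.na(df$location), , drop = FALSE]
  counts <- table(factor(located$location, levels = LOCATION_LEVELS))
  nt <- c("5UTR" = 0, "5UTR-CDS" = 0, "CDS" = 0, "CDS-3UTR" = 0, "3UTR" = 0)
  for (ctx in contexts) {
    nt[["5UTR"]] <- nt[["5UTR"]] + (ctx$cds_start - 1L)
    nt[["CDS"]] <- nt[["CDS"]] + (ctx$cds_end - ctx$cds_start + 1L)
    nt[["3UTR"]] <- nt[["3UTR"]] + (ctx$length - ctx$cds_end)
    nt[["5UTR-CDS"]] <- nt[["5UTR-CDS"]] +
      sum(abs(seq_len(ctx$length) - ctx$cds_start) < BOUNDARY_WINDOW)
    nt[["CDS-3UTR"]] <- nt[["CDS-3UTR"]] +
      sum(abs(seq_len(ctx$length) - ctx$cds_end) < BOUNDARY_WINDOW)
  }
  data.frame(location = LOCATION_LEVELS,
             count = as.integer(counts[LOCATION_LEVELS]),
             region_nt = as.numeric(nt[LOCATION_LEVELS]),
             density = ifelse(nt[LOCATION_LEVELS] > 0,
                              as.integer(counts[LOCATION_LEVELS]) /
                                as.numeric(nt[LOCATION_LEVELS]), NA_real_),
             row.names = NULL)
}
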