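# Penalty-based quality scoring: a candidate starts from the maximum score
# of 8 and loses points for every structural defect, for belonging to a
# motif class without in-vivo gold-standard support, for discordance with
# the predicted secondary structure, and for a non-negative free energy.
# The score maps onto six confidence categories, pooled pairwise into
# high/medium/low tiers for benchmarking.

CATEGORY_LEVELS <- c("High", "High-medium", "Medium", "Medium-low",
                     "Low", "Very-low")
POOLED_TIER <- c(High = "high", `High-medium` = "high",
                 Medium = "medium", `Medium-low` = "medium",
                 Low = "low", `Very-low` = "low")

#' Scoring configuration
#'
#' Penalty magnitudes, category thresholds and display ranges. All penalties
#' subtract from the base score of 8. The N7.N25 penalties exceed the
#' ordinary stem penalties: mutations of that closing pair are the ones
#' observed in IRE-linked disease (ALAS2, FTL), so a defect there must cost
#' strictly more than an upper-stem mismatch.
#'
#' @param file Optional YAML file of `key: number` overrides for any field
#'   below.
#' @param ... Named overrides taking precedence over `file`.
#' @return A list of class `ire_config` with fields: `base_score` (8),
#'   `stem_mismatch` (1.5), `stem_bulge` (1.5), `wobble` (0.5),
#'   `noncanonical_motif` (1.0, waived for families in
#'   `canonical_families`, default 1/2/19), `n7_n25_mismatch` (3.0),
#'   `n7_n25_wobble` (1.5), `discordance_weight` (2.5, applied as
#'   `weight * (1 - concordance)`), `positive_dg` (2.0, applied when
#'   `delta_g >= 0`), `thresholds` (category cut-points 7/6/5/3.5/1.5),
#'   `bar_min` (-4) and `energy_min` (-15) for display bars.
#' @export
penalty_config <- function(file = NULL, ...) {
  cfg <- list(
    base_score = 8,
    stem_mismatch = 1.5,
    stem_bulge = 1.5,
    wobble = 0.5,
    noncanonical_motif = 1.0,
    canonical_families = c("1", "2", "19"),
    n7_n25_mismatch = 3.0,
    n7_n25_wobble = 1.5,
    discordance_weight = 2.5,
    positive_dg = 2.0,
    thresholds = c(High = 7, `High-medium` = 6, Medium = 5,
                   `Medium-low` = 3.5, Low = 1.5, `Very-low` = -Inf),
    bar_min = -4,
    energy_min = -15
  )
  if (!is.null(file)) {
    if (!file.exists(file)) stop("scoring config file not found: ", file)
    over <- yaml::read_yaml(file)
    cfg <- apply_config_overrides(cfg, over, file)
  }
  dots <- list(...)
  if (length(dots)) cfg <- apply_config_overrides(cfg, dots, "argument")
  validate_config(cfg)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "ire_config")
}

apply_config_overrides <- function(cfg, over, src) {
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown scoring config key(s) in ", src, ": ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(over$thresholds)) {
    th <- unlist(over$thresholds)
    if (!all(names(th) %in% CATEGORY_LEVELS)) {
      stop("threshold names must be the six category labels")
    }
    cfg$thresholds[names(th)] <- th
    over$thresholds <- NULL
  }
  modifyList(cfg, over)
}

validate_config <- function(cfg) {
  pens <- c("stem_mismatch", "stem_bulge", "wobble", "noncanonical_motif",
            "n7_n25_mismatch", "n7_n25_wobble", "discordance_weight",
            "positive_dg")
  for (p in pens) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0) {
      stop("penalty '", p, "' must be a non-negative number")
    }
  }
  th <- cfg$thresholds[CATEGORY_LEVELS]
  if (any(is.na(th)) || any(diff(th) >= 0)) {
    stop("category thresholds must be strictly decreasing High -> Very-low")
  }
  if (cfg$n7_n25_mismatch <= cfg$stem_mismatch) {
    stop("n7_n25_mismatch must exceed stem_mismatch (the closing-pair ",
         "refinement)")
  }
  invisible(cfg)
}

# Stable hash of the active configuration, logged with every run so that
# outputs are attributable to the exact scoring scheme that produced them.
config_hash <- function(cfg) {
  cfg$hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' Score one candidate
#'
#' Computes `score = 8 - sum(penalties)` from the candidate's structural
#' defects, motif class and folding evidence, and assigns the confidence
#' category. Every contributing penalty term is itemized in the returned
#' record.
#'
#' @param core An `ire_core` candidate.
#' @param fold The `ire_fold` result for that candidate.
#' @param cfg A [penalty_config()].
#' @return A list of class `scored_ire`: `core`, `fold`, `penalties` (named
#'   numeric vector of the non-zero terms), `score`, `category`,
#'   `pooled_tier`.
#' @export
score_candidate <- function(core, fold, cfg = penalty_config()) {
  d <- core$defects
  pen <- c(
    stem_mismatch = length(d$mismatch_pairs) * cfg$stem_mismatch,
    stem_bulge = length(d$stem_bulges) * cfg$stem_bulge,
    wobble = length(d$wobble_pairs) * cfg$wobble,
    noncanonical_motif =
      if (core$family %in% cfg$canonical_families) 0 else cfg$noncanonical_motif,
    n7_n25 = switch(d$n7_n25, watson_crick = 0,
                    wobble = cfg$n7_n25_wobble,
                    mismatch = cfg$n7_n25_mismatch),
    discordance = cfg$discordance_weight * (1 - fold$concordance),
    positive_dg = if (fold$delta_g >= 0) cfg$positive_dg else 0
  )
  score <- cfg$base_score - sum(pen)
  category <- categorize(score, cfg)
  structure(list(core = core, fold = fold,
                 penalties = pen[pen > 0],
                 score = score,
                 category = category,
                 pooled_tier = unname(POOLED_TIER[category])),
            class = "scored_ire")
}

#' Map a score to its confidence category
#'
#' The first threshold the score meets, scanning from High down to Very-low;
#' the scale runs over negative values up to the maximum of 8.
#'
#' @param score Numeric score.
#' @param cfg A [penalty_config()].
#' @return One of `"High"`, `"High-medium"`, `"Medium"`, `"Medium-low"`,
#'   `"Low"`, `"Very-low"`.
#' @export
categorize <- function(score, cfg = penalty_config()) {
  th <- cfg$thresholds[CATEGORY_LEVELS]
  CATEGORY_LEVELS[which(score >= th)[1]]
}

#' Choose the winning interpretation at one site
#'
#' Among scored candidates sharing one loop offset: highest score wins, ties
#' broken by lower registry row number, then by fewer structural defects.
#'
#' @param group Non-empty list of `scored_ire` sharing `loop_start`.
#' @return The winning `scored_ire`.
#' @export
pick_site_winner <- function(group) {
  stopifnot(length(group) >= 1L)
  score <- vapply(group, `[[`, numeric(1), "score")
  row <- vapply(group, function(g) g$core$row, integer(1))
  defects <- vapply(group, function(g) n_defects(g$core), numeric(1))
  group[[order(-score, row, defects)[1]]]
}

#' Display summary of a scored prediction
#'
#' Normalized positions for the two report bars: the quality bar spans
#' `[bar_min, 8]` and the free-energy bar spans `[energy_min, 0]`, with 0
#' the worst possible free energy. Positions are clamped to `[0, 1]`, 1
#' being the favourable (green) end of each bar.
#'
#' @param scored A `scored_ire`.
#' @param cfg The [penalty_config()] used to score it.
#' @return A list: `score`, `category`, `delta_g`, `score_bar`,
#'   `energy_bar`.
#' @export
summarize_quality <- function(scored, cfg = penalty_config()) {
  clamp01 <- function(x) min(1, max(0, x))
  list(score = scored$score,
       category = scored$category,
       delta_g = scored$fold$delta_g,
       score_bar = clamp01((scored$score - cfg$bar_min) /
                             (cfg$base_score - cfg$bar_min)),
       energy_bar = clamp01((0 - scored$fold$delta_g) / (0 - cfg$energy_min)))
}

#' @export
print.scored_ire <- function(x, ...) {
  cat(sprintf("Scored IRE [%s] motif %s @ %d-%d: %.2f/8 (%s, %s tier), dG %.2f\n",
              x$core$seq_id, x$core$motif_id, x$core$core_start,
              x$core$core_end, x$score, x$category, x$pooled_tier,
              x$fold$delta_g))
  if (length(x$penalties)) {
    cat("  penalties:",
        paste(sprintf("%s %.2f", names(x$penalties), x$penalties),
              collapse = ", "), "\n")
  }
  invisible(x)
}
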