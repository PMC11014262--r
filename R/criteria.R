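# Round-1 screening and the three criteria sets with the >= 2-of-3
# bona fide verdict.
#
# The three shipped sets render the community annotation standards:
# an animal-style set (precise processing, 2-nt 3' overhangs at both duplex
# ends, compact precursor), a plant-style set (longer precursors allowed,
# duplex quality and replicated expression), and a combined set (structural
# plus read-evidence minimum with structured-ncRNA exclusion). Every
# threshold is overridable from a YAML config.

# registry of predicate ids -> feature the comparator applies to
PREDICATE_FEATURES <- c(
  modal_support_5p = "modal_support_5p",
  modal_support_3p = "modal_support_3p",
  precision_5p = "precision_5p",
  precision_3p = "precision_3p",
  overhang_lower = "overhang3p_lower",
  overhang_upper = "overhang3p_upper",
  loop_len = "loop_len",
  paired_fraction = "paired_fraction",
  precursor_len = "precursor_len",
  n_mismatch = "n_mismatch",
  asymmetric_bulge_nt = "asymmetric_bulge_nt",
  duplex_read_fraction = "duplex_read_fraction",
  expressed_reps = "expressed_reps",
  single_stem_loop = "single_stem_loop",
  both_arms_mapped = "both_arms_mapped",
  ncrna_overlap = "ncrna_overlap"
)

#' Default criteria-set configuration
#'
#' @return named list of three criteria sets (`animal_style`, `plant_style`,
#'   `combined`), each an ordered list of `(predicate, comparator,
#'   threshold)` triples.
#' @export
default_criteria_config <- function() {
  p <- function(predicate, comparator, threshold) {
    list(predicate = predicate, comparator = comparator,
         threshold = threshold)
  }
  list(
    animal_style = list(
      p("modal_support_5p", "ge", 2),
      p("modal_support_3p", "ge", 2),
      p("precision_5p", "ge", 0.5),
      p("precision_3p", "ge", 0.5),
      p("overhang_lower", "between", c(1, 3)),
      p("overhang_upper", "between", c(1, 3)),
      p("loop_len", "ge", 8),
      p("paired_fraction", "ge", 0.6),
      p("precursor_len", "le", 150)
    ),
    plant_style = list(
      p("precursor_len", "le", 300),
      p("n_mismatch", "le", 5),
      p("asymmetric_bulge_nt", "le", 3),
      p("duplex_read_fraction", "ge", 0.75),
      p("overhang_lower", "between", c(1, 3)),
      p("expressed_reps", "ge", 2)
    ),
    combined = list(
      p("single_stem_loop", "is_true", TRUE),
      p("both_arms_mapped", "is_true", TRUE),
      p("precision_5p", "ge", 0.5),
      p("precision_3p", "ge", 0.5),
      p("duplex_read_fraction", "ge", 0.5),
      p("ncrna_overlap", "is_false", FALSE)
    )
  )
}

#' Load (or save) a criteria configuration
#'
#' @param path YAML file; `NULL` returns the shipped defaults.
#' @return criteria configuration list.
#' @export
criteria_config <- function(path = NULL) {
  if (is.null(path)) return(default_criteria_config())
  raw <- yaml::read_yaml(path)
  lapply(raw, function(set) lapply(set, function(pr) {
    pr$threshold <- unlist(pr$threshold)
    pr
  }))
}

#' @rdname criteria_config
#' @param cfg configuration list to write.
#' @export
write_criteria_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

apply_comparator <- function(value, comparator, threshold) {
  switch(comparator,
         ge = value >= threshold,
         le = value <= threshold,
         eq = value == threshold,
         between = value >= threshold[1] & value <= threshold[2],
         is_true = isTRUE(value),
         is_false = isFALSE(value),
         stop("unknown comparator: ", comparator))
}

#' Round-1 candidate screen
#'
#' Keep a cluster if it folds into a hairpin and both arms reach the
#' minimum 5' processing precision (default 30%).
#'
#' @param features named list with `hairpin_found`, `precision_5p`,
#'   `precision_3p`.
#' @param min_precision precision threshold.
#' @return logical.
#' @export
screen_round1 <- function(features, min_precision = 0.30) {
  isTRUE(features$hairpin_found) &&
    !is.na(features$precision_5p) && !is.na(features$precision_3p) &&
    features$precision_5p >= min_precision &&
    features$precision_3p >= min_precision
}

#' Evaluate one criteria set
#'
#' Every predicate is evaluated and recorded; the set passes iff all its
#' predicates pass. Evaluation never short-circuits, so the report names
#' every failing predicate.
#'
#' @param features named feature list for one candidate.
#' @param set_cfg one element of a criteria configuration.
#' @param set_name label recorded in the report.
#' @return list with `pass` and a per-predicate `report` data.table.
#' @export
evaluate_criteria_set <- function(features, set_cfg, set_name = "set") {
  rows <- lapply(set_cfg, function(pr) {
    feat <- PREDICATE_FEATURES[[pr$predicate]]
    if (is.null(feat)) stop("unknown predicate: ", pr$predicate)
    if (!feat %in% names(features) || is.null(features[[feat]]) ||
        (length(features[[feat]]) == 1 && is.na(features[[feat]]))) {
      stop("missing feature for criteria evaluation: ", feat)
    }
    val <- features[[feat]]
    data.table::data.table(
      set = set_name, predicate = pr$predicate,
      value = as.numeric(val),
      comparator = pr$comparator,
      threshold = paste(pr$threshold, collapse = ","),
      pass = apply_comparator(val, pr$comparator, pr$threshold))
  })
  report <- data.table::rbindlist(rows)
  list(pass = all(report$pass), report = report)
}

#' Final two-out-of-three verdict
#'
#' @param set_results named list of exactly three [evaluate_criteria_set()]
#'   results.
#' @param candidate_id identifier recorded in the verdict.
#' @return a `candidate_verdict` list with `n_sets_passed`, `bona_fide`
#'   (`>= 2` sets passed), `all_three` and `rejection_reasons`.
#' @export
final_verdict <- function(set_results, candidate_id = NA_character_) {
  stopifnot(length(set_results) == 3L)
  passed <- vapply(set_results, `[[`, TRUE, "pass")
  failed_sets <- names(passed)[!passed] %||% character(0)
  reasons <- unlist(lapply(set_results[!passed], function(sr) {
    sr$report$predicate[!sr$report$pass]
  }))
  structure(list(candidate_id = candidate_id,
                 set_pass = passed,
                 n_sets_passed = sum(passed),
                 bona_fide = sum(passed) >= 2L,
                 all_three = all(passed),
                 rejection_reasons = unique(unname(reasons)),
                 report = data.table::rbindlist(
                   lapply(set_results, `[[`, "report"))),
            class = "candidate_verdict")
}

#' Assemble candidate features for the criteria engine
#'
#' @param profile,call,geometry,hairpin pieces computed by the hairpin
#'   module (`hairpin` may be `NULL`).
#' @param drf value of [duplex_read_fraction()] at slack 2.
#' @param precision_5p,precision_3p [arm_precision()] results.
#' @param ncrna_overlap logical from the context module (default `FALSE`).
#' @return named feature list.
#' @export
candidate_features <- function(profile, call, geometry, hairpin,
                               drf, precision_5p, precision_3p,
                               ncrna_overlap = FALSE) {
  arm_reads_rep <- function(arm) {
    r <- profile$reads
    ok <- r$lstart >= arm[["start"]] - 2L & (r$lstart + r$len) <= arm[["end"]] + 2L
    vapply(profile$replicates,
           function(rp) sum(ok & r$replicate == rp), 1.0)
  }
  expressed <- arm_reads_rep(call$mir5p) + arm_reads_rep(call$mir3p)
  list(
    hairpin_found = !is.null(hairpin),
    single_stem_loop = !is.null(hairpin),
    both_arms_mapped = inherits(call, "duplex_call"),
    precision_5p = precision_5p$precision,
    precision_3p = precision_3p$precision,
    modal_support_5p = sum(call$modal_counts_5p >= 2),
    modal_support_3p = sum(call$modal_counts_3p >= 2),
    duplex_read_fraction = drf,
    expressed_reps = sum(expressed >= 1),
    ncrna_overlap = ncrna_overlap,
    paired_fraction = geometry$paired_fraction,
    n_mismatch = geometry$n_mismatch,
    asymmetric_bulge_nt = geometry$asymmetric_bulge_nt,
    overhang3p_lower = geometry$overhang3p_lower,
    overhang3p_upper = geometry$overhang3p_upper,
    loop_len = geometry$loop_len,
    precursor_len = geometry$precursor_len
  )
}

#' Evaluate all three criteria sets and return the verdict
#'
#' @param features from [candidate_features()].
#' @param cfg criteria configuration (default [default_criteria_config()]).
#' @param candidate_id identifier.
#' @return a `candidate_verdict`.
#' @export
evaluate_candidate <- function(features, cfg = default_criteria_config(),
                               candidate_id = NA_character_) {
  res <- lapply(names(cfg), function(nm) {
    evaluate_criteria_set(features, cfg[[nm]], nm)
  })
  names(res) <- names(cfg)
  final_verdict(res, candidate_id)
}
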