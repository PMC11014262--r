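# End-to-end discovery: preprocess -> contaminant filter -> align ->
# fractional weights -> clusters -> per-cluster fold + duplex analysis ->
# round-1 screen -> three criteria sets -> >=2-of-3 verdict -> annotation
# exclusion and context labels.

as_read_table <- function(reads) {
  if (data.table::is.data.table(reads) && "replicate" %in% names(reads)) {
    return(reads)
  }
  if (is.list(reads) && all(vapply(reads, is.data.frame, TRUE))) {
    reps <- names(reads) %||% paste0("rep", seq_along(reads))
    return(data.table::rbindlist(lapply(seq_along(reads), function(i) {
      data.table::data.table(read_id = reads[[i]]$read_id,
                             seq = reads[[i]]$seq, replicate = reps[i])
    })))
  }
  read_records(reads)
}

# map a local (transcript-oriented, 0-based half-open) interval back to
# genome coordinates
local_to_genome <- function(profile, ls, le) {
  if (profile$strand == "+") {
    c(profile$window_start + ls, profile$window_start + le)
  } else {
    c(profile$window_end - le, profile$window_end - ls)
  }
}

#' Discover bona fide miRNAs from small RNA libraries
#'
#' Runs the full curation pipeline. A candidate is called *bona fide* when
#' it passes at least two of the three criteria sets and is not derived
#' from an annotated structured ncRNA.
#'
#' @param reads per-replicate read sets: a named list of character vectors /
#'   DNAStringSets / `data.table(read_id, seq)`, or a single read table
#'   with a `replicate` column.
#' @param genome named character vector of contig sequences.
#' @param align_cfg an [align_config()].
#' @param fold_cfg a [fold_config()].
#' @param criteria criteria configuration (see [criteria_config()]).
#' @param annotations optional `annotation_set`.
#' @param contaminants optional named character vector of contaminant
#'   genomes.
#' @param merge_gap cluster merge gap in bp (must exceed the longest
#'   expected precursor loop so that both arms fall in one cluster).
#' @param min_weighted_depth minimum weighted cluster depth.
#' @param weight_window neighbourhood for multimapper weighting.
#' @param round1_min_precision round-1 5' precision threshold (both arms).
#' @param min_overlap_frac ncRNA overlap fraction triggering exclusion.
#' @param preprocess set FALSE when reads are already trimmed and length-
#'   selected.
#' @return list with `candidates` (one row per analyzed cluster),
#'   `details` (per-candidate profile/fold/call/verdict), `clusters`,
#'   `placements`, `criteria_report` and `read_lengths`.
#' @export
discover_mirnas <- function(reads, genome,
                            align_cfg = align_config(),
                            fold_cfg = fold_config(),
                            criteria = default_criteria_config(),
                            annotations = NULL,
                            contaminants = NULL,
                            merge_gap = 100L,
                            min_weighted_depth = 5.0,
                            weight_window = 50L,
                            round1_min_precision = 0.30,
                            min_overlap_frac = 0.5,
                            preprocess = TRUE) {
  rt <- as_read_table(reads)
  if (preprocess) rt <- preprocess_reads(rt, align_cfg)
  read_lengths <- nchar(rt$seq)
  if (!is.null(contaminants)) {
    rt <- filter_contaminants(rt, contaminants, align_cfg)
  }
  pl <- align_reads(rt, genome, align_cfg)
  pl <- weight_multimappers(pl, window = weight_window)
  cl <- call_clusters(pl, merge_gap = merge_gap,
                      min_weighted_depth = min_weighted_depth)
  clusters <- cl$clusters
  n_cl <- if (is.null(clusters) || nrow(clusters) == 0) 0L else nrow(clusters)
  message(sprintf("discover_mirnas: %d clusters to analyze", n_cl))

  details <- list()
  rows <- list()
  if (n_cl > 0) {
    # placements were assigned to clusters during merging; profiling each
    # cluster from its own subset avoids rescanning the full placement table
    pl_split <- split(cl$placements[!is.na(cl$placements$cluster_id)],
                      by = "cluster_id")
    profiles <- lapply(seq_len(n_cl), function(i) {
      sub <- pl_split[[clusters$cluster_id[i]]]
      if (is.null(sub)) sub <- cl$placements[0]
      build_cluster_profile(sub, clusters[i], genome,
                            flank = fold_cfg$flank)
    })
    foldable <- vapply(profiles, function(p) {
      !isTRUE(p$empty) && p$L >= 30 && p$L <= 1000
    }, TRUE)
    seqs <- vapply(profiles[foldable], `[[`, "", "seq")
    names(seqs) <- clusters$cluster_id[foldable]
    folds_df <- fold_sequences(seqs, temperature = fold_cfg$temperature)

    for (i in seq_len(n_cl)) {
      cid <- clusters$cluster_id[i]
      prof <- profiles[[i]]
      rec <- list(cluster_id = cid, contig = clusters$contig[i],
                  strand = clusters$strand[i],
                  cluster_start = clusters$start[i],
                  cluster_end = clusters$end[i],
                  weighted_depth = clusters$weighted_depth[i])
      det <- list(profile = prof)
      finish <- function(stage, extra = list()) {
        rows[[length(rows) + 1L]] <<- c(rec, list(stage = stage),
                                        extra)
        details[[cid]] <<- det
      }
      if (!foldable[i]) { finish("unfoldable"); next }
      fidx <- match(cid, folds_df$id)
      fold <- as_fold_result(folds_df$seq[fidx], folds_df$structure[fidx],
                             folds_df$mfe[fidx])
      det$fold <- fold
      hairpin <- find_hairpin(fold, prof)
      det$hairpin <- hairpin
      if (is.null(hairpin)) { finish("no_hairpin"); next }
      call <- call_duplex(prof, hairpin, fold)
      det$call <- call
      if (inherits(call, "duplex_rejection")) {
        finish("duplex_rejected", list(reason = call$reason)); next
      }
      p5 <- arm_precision(prof, call$mir5p, "5p")
      p3 <- arm_precision(prof, call$mir3p, "3p")
      geom <- tryCatch(duplex_geometry(fold, call),
                       degenerate_duplex = function(e) NULL)
      if (is.null(geom)) {
        finish("degenerate_duplex",
               list(precision_5p = p5$precision, precision_3p = p3$precision))
        next
      }
      drf <- duplex_read_fraction(prof, call, slack = 2L)
      feats <- candidate_features(prof, call, geom, hairpin, drf, p5, p3)
      det$geometry <- geom
      det$features <- feats
      # precursor = outer span of the called arms
      s5 <- call$mir5p[["start"]]; e3 <- call$mir3p[["end"]]
      det$precursor_seq <- substr(prof$seq, s5 + 1L, e3)
      det$precursor_structure <- substr(fold$structure, s5 + 1L, e3)
      gpre <- local_to_genome(prof, s5, e3)
      g5 <- local_to_genome(prof, call$mir5p[["start"]], call$mir5p[["end"]])
      g3 <- local_to_genome(prof, call$mir3p[["start"]], call$mir3p[["end"]])
      finish("evaluated", list(
        precision_5p = p5$precision, precision_3p = p3$precision,
        duplex_read_fraction = drf,
        precursor_start = gpre[1], precursor_end = gpre[2],
        arm5p_start = g5[1], arm5p_end = g5[2],
        arm3p_start = g3[1], arm3p_end = g3[2]))
    }
  }
  candidates <- data.table::rbindlist(rows, fill = TRUE)
  if (nrow(candidates) == 0) {
    return(list(candidates = candidates, details = details,
                clusters = clusters, placements = cl$placements,
                criteria_report = data.table::data.table(),
                read_lengths = read_lengths))
  }

  # structured-ncRNA exclusion + context labels (annotation inputs)
  candidates[, ncrna_overlap := FALSE]
  candidates[, transposon_flag := FALSE]
  candidates[, context := NA_character_]
  candidates[, excluded_class := NA_character_]
  ev <- which(candidates$stage == "evaluated")
  if (!is.null(annotations) && length(ev) > 0) {
    gr <- granges0(candidates$contig[ev], candidates$precursor_start[ev],
                   candidates$precursor_end[ev], candidates$strand[ev])
    names(gr) <- candidates$cluster_id[ev]
    part <- exclude_structured_overlap(gr, annotations,
                                       min_overlap_frac = min_overlap_frac)
    rej_ids <- names(part$rejected)
    candidates[cluster_id %in% rej_ids, ncrna_overlap := TRUE]
    if (length(rej_ids) > 0) {
      candidates[match(rej_ids, cluster_id),
                 excluded_class := part$rejected$reason]
    }
    kept_ids <- names(part$kept)
    candidates[match(kept_ids, cluster_id),
               transposon_flag := part$transposon_flag]
    for (k in ev) {
      ctx <- classify_context(granges0(candidates$contig[k],
                                       candidates$precursor_start[k],
                                       candidates$precursor_end[k],
                                       candidates$strand[k]), annotations)
      candidates$context[k] <- ctx$label
    }
  }

  # round-1 screen + criteria verdicts
  candidates[, round1_pass := FALSE]
  candidates[, n_sets_passed := NA_integer_]
  candidates[, bona_fide := FALSE]
  candidates[, all_three := FALSE]
  reports <- list()
  for (k in ev) {
    cid <- candidates$cluster_id[k]
    feats <- details[[cid]]$features
    feats$ncrna_overlap <- candidates$ncrna_overlap[k]
    r1 <- screen_round1(list(hairpin_found = feats$hairpin_found,
                             precision_5p = feats$precision_5p,
                             precision_3p = feats$precision_3p),
                        min_precision = round1_min_precision)
    candidates$round1_pass[k] <- r1
    if (!r1) next
    verdict <- evaluate_candidate(feats, criteria, candidate_id = cid)
    details[[cid]]$verdict <- verdict
    candidates$n_sets_passed[k] <- verdict$n_sets_passed
    candidates$all_three[k] <- verdict$all_three
    candidates$bona_fide[k] <- verdict$bona_fide &&
      !isTRUE(candidates$ncrna_overlap[k])
    rep_k <- data.table::copy(verdict$report)
    rep_k[, cluster_id := cid]
    reports[[length(reports) + 1L]] <- rep_k
  }
  message(sprintf("discover_mirnas: %d bona fide miRNA(s) of %d candidates",
                  sum(candidates$bona_fide), nrow(candidates)))
  list(candidates = candidates[], details = details, clusters = clusters,
       placements = cl$placements,
       criteria_report = data.table::rbindlist(reports),
       read_lengths = read_lengths)
}

#' Match bona fide calls against a simulation truth table
#'
#' A planted miRNA counts as recovered when a bona fide candidate's
#' precursor overlaps the planted locus on the same strand. Bona fide calls
#' are attributed to the overlapping planted locus class, or `background`.
#'
#' @param candidates candidate table from [discover_mirnas()].
#' @param truth truth records from the simulator.
#' @return list with `recovered` (named logical per planted miRNA),
#'   `calls_by_class` (table of bona fide calls by truth class) and
#'   `call_class` (per bona fide candidate).
#' @export
score_recovery <- function(candidates, truth) {
  mir <- truth[vapply(truth, function(r) r$plan$locus_class == "mirna", TRUE)]
  bona <- candidates[candidates$bona_fide %in% TRUE &
                       candidates$stage == "evaluated", ]
  recovered <- setNames(rep(FALSE, length(mir)), names(mir))
  call_class <- rep("background", nrow(bona))
  if (nrow(bona) > 0) {
    for (j in seq_len(nrow(bona))) {
      for (r in truth) {
        same <- r$plan$contig == bona$contig[j] &&
          r$plan$strand == bona$strand[j] &&
          bona$precursor_start[j] < r$plan$end &&
          bona$precursor_end[j] > r$plan$start
        if (same) {
          call_class[j] <- r$plan$locus_class
          if (r$plan$locus_class == "mirna") recovered[r$locus_id] <- TRUE
          break
        }
      }
    }
  }
  list(recovered = recovered,
       calls_by_class = table(factor(call_class,
                                     levels = c("mirna", "sirna",
                                                "ncrna_decoy", "transposon",
                                                "background"))),
       call_class = call_class)
}
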