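window_qualifies <- function(seg, params) {
  len <- seg$end - seg$start + 1
  list(
    low_ccf = min(seg$cell_fraction) < params$min_segment_ccf,
    nonuniform_sizes = max(len) / min(len) > params$uniformity_max_ratio,
    discordant_tracks = !isTRUE(as.logical(track_concordance(seg)))
  )
}

# Longest (leftmost) window of >= min_panel_run consecutive run members that
# passes the CCF, size-uniformity and track-concordance filters. The
# published rule reads "five consecutive oscillating uniformly sized
# segments": uniformity applies to the consecutive segments called, not to
# the whole maximal run, so a long run with one outlier segment can still
# contain a qualifying stretch.
best_qualifying_window <- function(segments, run, params) {
  members <- run$member_indices
  n <- length(members)
  if (n < params$min_panel_run) return(NULL)
  for (w in seq(n, params$min_panel_run)) {
    for (s in seq_len(n - w + 1L)) {
      idx <- members[s:(s + w - 1L)]
      seg <- segments[idx, , drop = FALSE]
      fail <- window_qualifies(seg, params)
      if (!any(unlist(fail))) {
        sub <- list(first = idx[1], last = idx[w],
                    deviants = intersect(run$deviant_indices,
                                         seq(idx[1], idx[w])),
                    states = run$states)
        return(annotate_run(segments, sub))
      }
    }
  }
  NULL
}

#' Targeted-panel chromothripsis caller
#'
#' Applies the oscillating copy-number rule used for targeted-panel (tNGS)
#' data: a chromosome is `suggestive_positive` when it carries at least
#' `min_panel_run` (default 5) consecutive segments oscillating between two
#' total-CN states, uniformly sized (longest/shortest length ratio at most
#' `uniformity_max_ratio`), every segment with cellular fraction at least
#' `min_segment_ccf` (default 0.5), and with concordant log-ratio /
#' integer-CN (and, when present, allelic log-odds) tracks. Segments whose
#' total CN exceeds `amp_baseline_factor` times the chromosomal baseline
#' are bridged as deviations before rule evaluation, since ecDNA
#' amplification spikes sit inside chromothriptic regions and would
#' otherwise break the alternation. Verdicts are per chromosome; the
#' qualifying run's coordinates are reported.
#'
#' @param segments A `chrom_segments` data frame (one sample), or a plain
#'   data frame/path accepted by [as_chrom_segments()]/[read_segments()].
#' @param params A [detector_params()] object.
#' @param sample Sample label carried into the report.
#' @return An object of class `panel_calls`: a list with `calls` (one
#'   `panel_call` per chromosome, each holding `verdict`, `best_run`,
#'   `reasons`) and `report` (flat data frame, one row per chromosome).
#' @export
call_panel <- function(segments, params = detector_params(),
                       sample = "sample") {
  params <- as_detector_params(params)
  if (is.character(segments) && length(segments) == 1L) {
    segments <- read_segments(segments)
  }
  if (!inherits(segments, "chrom_segments")) {
    segments <- as_chrom_segments(segments)
  }
  ccf_assumed <- isTRUE(attr(segments, "ccf_assumed"))
  chroms <- unique(segments$chrom)
  calls <- list()
  rows <- list()
  for (ch in chroms) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    rownames(seg) <- NULL
    amp <- flag_amplified_segments(seg, params)
    runs <- find_oscillation_runs(seg, params, bridgeable = amp$flagged)
    best <- NULL
    for (r in runs) {
      w <- best_qualifying_window(seg, r, params)
      if (!is.null(w) &&
          (is.null(best) || w$run_length > best$run_length)) {
        best <- w
      }
    }
    reasons <- character(0)
    if (is.null(best)) {
      if (!length(runs)) {
        reasons <- "no_oscillation"
      } else {
        lens <- vapply(runs, `[[`, integer(1), "run_length")
        longest <- runs[[which.max(lens)]]
        if (longest$run_length < params$min_panel_run) {
          reasons <- "run_too_short"
        } else {
          seg_run <- seg[longest$member_indices, , drop = FALSE]
          fail <- window_qualifies(seg_run, params)
          reasons <- names(fail)[unlist(fail)]
          if (!length(reasons)) reasons <- "no_qualifying_window"
        }
      }
    }
    verdict <- if (is.null(best)) "negative" else "suggestive_positive"
    call <- structure(
      list(chrom = ch, verdict = verdict, best_run = best,
           reasons = reasons, ccf_assumed = ccf_assumed),
      class = "panel_call"
    )
    calls[[ch]] <- call
    rows[[ch]] <- data.frame(
      sample = sample, chrom = ch,
      start = if (is.null(best)) min(seg$start) else
        seg$start[best$first_index],
      end = if (is.null(best)) max(seg$end) else seg$end[best$last_index],
      verdict = verdict,
      n_intra_interleaved = NA_integer_, n_inter = NA_integer_,
      n_sv_total = NA_integer_,
      max_osc2 = max_oscillating_segments(runs),
      p_joins = NA_real_, p_enrich = NA_real_, p_exp = NA_real_,
      criteria_passed = "",
      reasons = paste(reasons, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  report <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    as_report(data.frame())
  }
  structure(list(calls = calls, report = report, params = params,
                 ccf_assumed = ccf_assumed),
            class = "panel_calls")
}

#' @export
print.panel_calls <- function(x, ...) {
  pos <- vapply(x$calls, function(cl) cl$verdict == "suggestive_positive",
                logical(1))
  cat("Targeted-panel chromothripsis calls:", length(x$calls),
      "chromosome(s),", sum(pos), "suggestive of chromothripsis\n")
  if (any(pos)) {
    for (cl in x$calls[pos]) {
      cat(sprintf("  chr%s: run of %d segments (CN %s)\n", cl$chrom,
                  cl$best_run$run_length,
                  paste(cl$best_run$states, collapse = "/")))
    }
  }
  if (isTRUE(x$ccf_assumed)) {
    cat("  note: segment cellular fractions were missing and assumed 1.0\n")
  }
  invisible(x)
}

#' @export
summary.panel_calls <- function(object, ...) {
  print(object)
  invisible(object$report)
}

#' Detector concordance against ground-truth labels
#'
#' Chromosome-level sensitivity and specificity of a set of calls against
#' known labels, with exact (Clopper-Pearson) binomial 95\% intervals and
#' the per-chromosome confusion table. A call is counted positive when its
#' verdict is one of `positive_verdicts`.
#'
#' @param calls `panel_calls`, `chromothripsis_calls`, or a data frame with
#'   `chrom` and `verdict` columns.
#' @param truth Named logical vector (names = chromosomes) or a data frame
#'   with `chrom` and `label` columns; must cover every called chromosome.
#' @param positive_verdicts Verdicts counted as positive calls.
#' @return List with `sensitivity`, `specificity` (NA when the class is
#'   empty), `sens_ci`, `spec_ci`, and `confusion` (per-chromosome table).
#' @export
concordance_vs_truth <- function(calls, truth,
                                 positive_verdicts = c("suggestive_positive",
                                                       "positive",
                                                       "low_density")) {
  rep <- as_report(calls)
  if (is.data.frame(truth)) {
    labels <- as.logical(truth$label)
    names(labels) <- normalize_chrom(truth$chrom)
  } else {
    labels <- as.logical(truth)
    names(labels) <- normalize_chrom(names(truth))
  }
  rep$chrom <- normalize_chrom(rep$chrom)
  missing_lab <- setdiff(rep$chrom, names(labels))
  if (length(missing_lab)) {
    stop("truth labels missing for chromosome(s): ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  called_pos <- rep$verdict %in% positive_verdicts
  is_pos <- labels[rep$chrom]
  tp <- sum(called_pos & is_pos)
  fn <- sum(!called_pos & is_pos)
  tn <- sum(!called_pos & !is_pos)
  fp <- sum(called_pos & !is_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  sens_ci <- if (!is.na(sens)) {
    as.numeric(stats::binom.test(tp, tp + fn)$conf.int)
  } else c(NA_real_, NA_real_)
  spec_ci <- if (!is.na(spec)) {
    as.numeric(stats::binom.test(tn, tn + fp)$conf.int)
  } else c(NA_real_, NA_real_)
  confusion <- data.frame(
    chrom = rep$chrom, called = called_pos, truth = unname(is_pos),
    outcome = ifelse(called_pos & is_pos, "TP",
              ifelse(called_pos & !is_pos, "FP",
              ifelse(!called_pos & is_pos, "FN", "TN"))),
    stringsAsFactors = FALSE
  )
  list(sensitivity = sens, specificity = spec,
       sens_ci = sens_ci, spec_ci = spec_ci,
       counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       confusion = confusion)
}
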