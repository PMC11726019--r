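#' Copy-number track concordance across a run of segments
#'
#' Checks that the continuous and integer copy-number tracks tell the same
#' story at every internal boundary of a segment run: the sign of the
#' log-ratio change must match the sign of the integer total-CN change, and,
#' where the allelic log-odds and minor CN are available on both sides of a
#' boundary, the change in allelic-imbalance magnitude `|logOR|` must match
#' the sign of the change in `total_cn - 2 * minor_cn`. The log-odds
#' magnitude is used because its sign is phase-arbitrary in allele-specific
#' CN output. Boundaries where the integer track does not change are skipped
#' (the continuous track carries no sign to agree with); missing tracks are
#' skipped and the result records which tracks were checked via the
#' `"tracks_checked"` attribute.
#'
#' @param segments A `chrom_segments` data frame (the segments of one run,
#'   in order).
#' @return `TRUE`/`FALSE` with attribute `tracks_checked`.
#' @export
track_concordance <- function(segments) {
  n <- nrow(segments)
  tracks <- "log_ratio"
  if (n < 2L) {
    return(structure(TRUE, tracks_checked = tracks))
  }
  dlr <- diff(segments$log_ratio)
  dtcn <- diff(segments$total_cn)
  chk <- dtcn != 0 & !is.na(dlr)
  ok <- all(sign(dlr[chk]) == sign(dtcn[chk]))
  lo <- segments$log_odds
  mc <- segments$minor_cn
  have <- !is.na(lo[-n]) & !is.na(lo[-1]) & !is.na(mc[-n]) & !is.na(mc[-1])
  if (any(have)) {
    tracks <- c(tracks, "log_odds")
    imb <- segments$total_cn - 2 * segments$minor_cn
    dimb <- diff(imb)
    dlo <- diff(abs(lo))
    chk2 <- have & dimb != 0
    ok <- ok && all(sign(dlo[chk2]) == sign(dimb[chk2]))
  }
  structure(isTRUE(ok), tracks_checked = tracks)
}

# Longest run starting at index i under the two-state alternation rule with
# bridged deviations. Returns NULL or list(first, last, deviants, states).
.scan_run <- function(cn, i, d, bridgeable) {
  n <- length(cn)
  if (i >= n) return(NULL)
  s1 <- cn[i]
  s2 <- NA
  last_state <- s1
  dev_used <- 0L
  deviants <- integer(0)
  prev_bridge <- FALSE
  last <- i
  j <- i + 1L
  while (j <= n) {
    cj <- cn[j]
    if (is.na(s2)) {
      if (cj == s1) {
        break
      } else if (bridgeable[j]) {
        deviants <- c(deviants, j)
        prev_bridge <- TRUE
      } else {
        s2 <- cj
        last_state <- cj
        prev_bridge <- FALSE
      }
    } else if (cj == s1 || cj == s2) {
      if (cj != last_state || prev_bridge) {
        last_state <- cj
        prev_bridge <- FALSE
      } else {
        break
      }
    } else if (bridgeable[j]) {
      deviants <- c(deviants, j)
      prev_bridge <- TRUE
    } else if (dev_used < d) {
      dev_used <- dev_used + 1L
      deviants <- c(deviants, j)
      prev_bridge <- TRUE
    } else {
      break
    }
    last <- j
    j <- j + 1L
  }
  # deviations must be interior: trim trailing bridges
  while (last %in% deviants) {
    deviants <- setdiff(deviants, last)
    last <- last - 1L
  }
  if (is.na(s2) || last <= i) return(NULL)
  list(first = i, last = last, deviants = deviants,
       states = sort(c(s1, s2)))
}

annotate_run <- function(segments, run) {
  idx <- setdiff(seq(run$first, run$last), run$deviants)
  seg <- segments[idx, , drop = FALSE]
  len <- seg$end - seg$start + 1
  conc <- track_concordance(seg)
  structure(
    list(chrom = segments$chrom[1],
         first_index = run$first,
         last_index = run$last,
         deviant_indices = run$deviants,
         member_indices = idx,
         states = run$states,
         run_length = length(idx),
         size_ratio = max(len) / min(len),
         min_cell_fraction = min(seg$cell_fraction),
         track_concordant = as.logical(conc),
         tracks_checked = attr(conc, "tracks_checked")),
    class = "oscillation_run"
  )
}

#' Find maximal oscillation runs on one chromosome
#'
#' Scans a sorted, non-overlapping segment list for maximal runs of
#' segments whose total copy number strictly alternates between two states
#' `{s1, s2}`. "Predominantly two states" is realized as an allowed number
#' of interior deviations (`params$max_deviations`, default 0): a deviation
#' is a segment whose CN lies outside the two states, bridged without
#' breaking the run and excluded from the run-length count. Additional
#' segments may be declared freely bridgeable via `bridgeable` (used to
#' bridge high-level amplification spikes that sit inside chromothriptic
#' regions). Maximal runs that overlap an earlier-starting selected run are
#' dropped, so the returned runs are disjoint; ties resolve toward the
#' leftmost run.
#'
#' @param segments `chrom_segments` data frame for a single chromosome.
#' @param params A [detector_params()] object.
#' @param bridgeable Optional logical vector (length `nrow(segments)`)
#'   marking segments that may be bridged without consuming the deviation
#'   budget.
#' @return List of `oscillation_run` objects (possibly empty), each with
#'   `first_index`, `last_index`, `states`, `run_length`, `size_ratio`,
#'   `min_cell_fraction`, `track_concordant`.
#' @examples
#' seg <- as_chrom_segments(data.frame(
#'   chrom = "1", start = c(0, 10, 20, 30) * 1e6 + 1,
#'   end = c(10, 20, 30, 40) * 1e6,
#'   n_marks = 50, log_ratio = c(0, -0.6, 0, -0.6), total_cn = c(2, 1, 2, 1)
#' ))
#' runs <- find_oscillation_runs(seg)
#' runs[[1]]$run_length
#' @export
find_oscillation_runs <- function(segments, params = detector_params(),
                                  bridgeable = NULL) {
  params <- as_detector_params(params)
  n <- nrow(segments)
  if (n == 0L) return(list())
  if (length(unique(segments$chrom)) > 1L) {
    stop("find_oscillation_runs expects segments of a single chromosome",
         call. = FALSE)
  }
  if (is.unsorted(segments$start)) {
    stop("segments must be sorted by start", call. = FALSE)
  }
  if (is.null(bridgeable)) bridgeable <- rep(FALSE, n)
  cn <- segments$total_cn
  cand <- list()
  for (i in seq_len(n - 1L)) {
    if (bridgeable[i]) next  # a run cannot start on a bridgeable spike
    r <- .scan_run(cn, i, params$max_deviations, bridgeable)
    if (!is.null(r)) cand[[length(cand) + 1L]] <- r
  }
  if (!length(cand)) return(list())
  # drop runs contained in another candidate's span
  keep <- vapply(seq_along(cand), function(k) {
    a <- cand[[k]]
    !any(vapply(seq_along(cand), function(m) {
      if (m == k) return(FALSE)
      b <- cand[[m]]
      b$first <= a$first && b$last >= a$last &&
        (b$last - b$first) > (a$last - a$first)
    }, logical(1)))
  }, logical(1))
  cand <- cand[keep]
  # disjoint selection, longest run first (ties toward the leftmost run)
  nondev <- vapply(cand, function(r) {
    (r$last - r$first + 1L) - length(r$deviants)
  }, integer(1))
  firsts <- vapply(cand, `[[`, numeric(1), "first")
  cand <- cand[order(-nondev, firsts)]
  sel <- list()
  for (r in cand) {
    clash <- any(vapply(sel, function(s) {
      r$first <= s$last && r$last >= s$first
    }, logical(1)))
    if (!clash) sel[[length(sel) + 1L]] <- r
  }
  sel <- sel[order(vapply(sel, `[[`, numeric(1), "first"))]
  lapply(sel, function(r) annotate_run(segments, r))
}

#' Maximum oscillating run length
#'
#' @param runs List of `oscillation_run` objects from
#'   [find_oscillation_runs()].
#' @return Largest `run_length`, or 0 for an empty list.
#' @export
max_oscillating_segments <- function(runs) {
  if (!length(runs)) return(0L)
  max(vapply(runs, `[[`, integer(1), "run_length"))
}

#' @export
print.oscillation_run <- function(x, ...) {
  cat(sprintf(
    "Oscillation run chr%s [%d..%d]: %d segments between CN %s, size ratio %.2f, min CCF %.2f, tracks %s\n",
    x$chrom, x$first_index, x$last_index, x$run_length,
    paste(x$states, collapse = "/"), x$size_ratio, x$min_cell_fraction,
    if (x$track_concordant) "concordant" else "DISCORDANT"))
  invisible(x)
}
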