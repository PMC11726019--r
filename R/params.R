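#' Detection parameters
#'
#' Collects every numeric threshold used by the panel and WGS chromothripsis
#' callers into one validated list, so that a run can be audited and the
#' thresholds explored around their defaults.
#'
#' The defaults encode the published rule set: a panel call requires at least
#' five consecutive oscillating, uniformly sized segments with segment CCF
#' >= 50\% and concordant copy-number tracks; the WGS criteria use the
#' interleaved-SV counts (6, 3, 40), the interchromosomal count (4), the
#' total-SV count (100) and the oscillation run lengths (7 and 5, with 4-6
#' defining the "low density" band); clonality of a mutation is called at
#' CCF >= 0.8; amplification is flagged above 5 times the chromosomal
#' baseline copy number.
#'
#' @param min_panel_run Minimum number of consecutive oscillating segments
#'   for a panel call (default 5).
#' @param min_segment_ccf Minimum cellular fraction of every segment in a
#'   qualifying panel run (default 0.5).
#' @param uniformity_max_ratio Maximum longest/shortest segment-length ratio
#'   for a run to count as uniformly sized (default 10).
#' @param clonal_ccf_cutoff CCF at or above which a mutation is classed
#'   clonal or near-clonal (default 0.8).
#' @param alpha_joins,alpha_enrich,alpha_exp Significance levels of the
#'   fragment joins, chromosomal enrichment and breakpoint exponentiality
#'   tests (default 0.05 each).
#' @param intra6,intra3,inter4,intra40,total100 SV-count thresholds of the
#'   WGS criteria (defaults 6, 3, 4, 40, 100).
#' @param osc7,osc5 Oscillating-segment thresholds of the WGS criteria
#'   (defaults 7 and 5).
#' @param osc_low_min,osc_low_max Oscillation run-length band of the
#'   low-density criterion (defaults 4 and 6).
#' @param amp_baseline_factor Amplification flag: segment total CN must
#'   exceed this multiple of the chromosomal baseline (default 5).
#' @param max_deviations Interior segments with copy number outside the two
#'   oscillation states that may be bridged per run (default 0, i.e. strict
#'   two-state alternation).
#' @param cluster_gap_bp Maximum distance between consecutive intrachromosomal
#'   breakends within one candidate region (default 10 Mb).
#'
#' @return An object of class `detector_params`.
#' @examples
#' p <- detector_params()
#' p$min_panel_run
#' detector_params(min_panel_run = 4)$min_panel_run
#' @export
detector_params <- function(min_panel_run = 5L,
                            min_segment_ccf = 0.5,
                            uniformity_max_ratio = 10,
                            clonal_ccf_cutoff = 0.8,
                            alpha_joins = 0.05,
                            alpha_enrich = 0.05,
                            alpha_exp = 0.05,
                            intra6 = 6L,
                            intra3 = 3L,
                            inter4 = 4L,
                            intra40 = 40L,
                            total100 = 100L,
                            osc7 = 7L,
                            osc5 = 5L,
                            osc_low_min = 4L,
                            osc_low_max = 6L,
                            amp_baseline_factor = 5,
                            max_deviations = 0L,
                            cluster_gap_bp = 1e7) {
  p <- list(
    min_panel_run = as.integer(min_panel_run),
    min_segment_ccf = min_segment_ccf,
    uniformity_max_ratio = uniformity_max_ratio,
    clonal_ccf_cutoff = clonal_ccf_cutoff,
    alpha_joins = alpha_joins,
    alpha_enrich = alpha_enrich,
    alpha_exp = alpha_exp,
    intra6 = as.integer(intra6),
    intra3 = as.integer(intra3),
    inter4 = as.integer(inter4),
    intra40 = as.integer(intra40),
    total100 = as.integer(total100),
    osc7 = as.integer(osc7),
    osc5 = as.integer(osc5),
    osc_low_min = as.integer(osc_low_min),
    osc_low_max = as.integer(osc_low_max),
    amp_baseline_factor = amp_baseline_factor,
    max_deviations = as.integer(max_deviations),
    cluster_gap_bp = cluster_gap_bp
  )
  thresholds <- c(
    "min_panel_run", "uniformity_max_ratio", "intra6", "intra3", "inter4",
    "intra40", "total100", "osc7", "osc5", "osc_low_min", "osc_low_max",
    "amp_baseline_factor", "cluster_gap_bp"
  )
  for (nm in thresholds) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("detector_params: '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  for (nm in c("alpha_joins", "alpha_enrich", "alpha_exp")) {
    a <- p[[nm]]
    if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0 || a >= 1) {
      stop("detector_params: '", nm, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  for (nm in c("min_segment_ccf", "clonal_ccf_cutoff")) {
    a <- p[[nm]]
    if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0 || a > 1) {
      stop("detector_params: '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$max_deviations < 0L) {
    stop("detector_params: 'max_deviations' must be >= 0", call. = FALSE)
  }
  if (p$osc_low_min > p$osc_low_max) {
    stop("detector_params: 'osc_low_min' must not exceed 'osc_low_max'",
         call. = FALSE)
  }
  structure(p, class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat("Chromothripsis detector parameters\n")
  cat("  panel rule : run >=", x$min_panel_run,
      "| segment CCF >=", x$min_segment_ccf,
      "| size ratio <=", x$uniformity_max_ratio, "\n")
  cat("  WGS counts : intra >=", x$intra6, "/", x$intra3, "/", x$intra40,
      "| inter >=", x$inter4, "| total >=", x$total100, "\n")
  cat("  oscillation: osc7 =", x$osc7, "| osc5 =", x$osc5,
      "| low-density band", x$osc_low_min, "-", x$osc_low_max, "\n")
  cat("  test alphas: joins", x$alpha_joins, "| enrichment", x$alpha_enrich,
      "| exponential", x$alpha_exp, "\n")
  cat("  clonal CCF >=", x$clonal_ccf_cutoff,
      "| amplification >", x$amp_baseline_factor, "x baseline\n")
  invisible(x)
}

as_detector_params <- function(params) {
  if (inherits(params, "detector_params")) return(params)
  if (is.null(params)) return(detector_params())
  if (is.list(params)) return(do.call(detector_params, params))
  stop("'params' must be NULL, a list, or a detector_params object",
       call. = FALSE)
}
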