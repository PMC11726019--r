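#' Expected variant allele frequency at a given cancer cell fraction
#'
#' Maps a cancer cell fraction (CCF) to the variant allele frequency
#' expected in a bulk sample of purity `p`, given the local tumor copy
#' number and the copy number contributed by admixed normal cells:
#'
#' \deqn{VAF(CCF) = \frac{p \cdot CCF}{CN_{diploid} (1 - p) + CN_{mut} \, p}}
#'
#' The numerator carries one mutant copy per mutated cell; callers that know
#' the mutant multiplicity can fold it into `ccf` upstream.
#'
#' @param purity Tumor purity `p` in (0, 1].
#' @param ccf Cancer cell fraction in \[0, 1\].
#' @param cn_mut Local total copy number in tumor cells (integer >= 1).
#' @param cn_diploid Copy number in normal cells at the locus (default 2).
#' @return Expected VAF in \[0, 1\].
#' @examples
#' expected_vaf(1, 1, 2)       # 0.5: pure tumor, heterozygous diploid locus
#' expected_vaf(0.5, 1, 2)     # 0.25
#' @export
expected_vaf <- function(purity, ccf, cn_mut, cn_diploid = 2) {
  if (any(purity <= 0 | purity > 1)) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  if (any(ccf < 0 | ccf > 1)) {
    stop("ccf must lie in [0, 1]", call. = FALSE)
  }
  if (any(cn_mut < 1) || any(cn_diploid < 0)) {
    stop("cn_mut must be >= 1 and cn_diploid >= 0", call. = FALSE)
  }
  denom <- cn_diploid * (1 - purity) + cn_mut * purity
  if (any(denom <= 0)) stop("non-positive denominator", call. = FALSE)
  purity * ccf / denom
}

#' Estimate the cancer cell fraction of a mutation
#'
#' Binomial maximum-likelihood estimation of the CCF from alt-read count,
#' depth, purity and local copy number: the likelihood
#' `Binomial(alt_reads | depth, expected_vaf(CCF))` is evaluated on a CCF
#' grid over \[0, 1\] (step 0.01), normalized with a uniform prior to a
#' posterior, and summarized by the grid argmax and a central 95\% credible
#' interval. Estimates that would want CCF > 1 are clamped at 1 and flagged.
#' A CCF at or above `clonal_ccf_cutoff` (default 0.8) is classed clonal or
#' near-clonal, otherwise subclonal.
#'
#' @param alt_reads Variant-supporting read count (integer >= 0).
#' @param depth Total read depth (integer >= `alt_reads`, >= 1).
#' @param purity Tumor purity in (0, 1].
#' @param cn_mut Local total copy number in tumor (integer >= 1). When the
#'   mutant multiplicity is unknown this is the local total CN.
#' @param cn_diploid Normal-cell copy number at the locus (default 2).
#' @param params A [detector_params()] object (supplies the clonality
#'   cutoff).
#' @param grid_step CCF grid resolution (default 0.01).
#' @return A `ccf_estimate` list with `ccf_point`, `ccf_low`, `ccf_high`,
#'   `clonality_class` (`"clonal_or_near_clonal"` or `"subclonal"`),
#'   `clamped`, and the posterior grid.
#' @examples
#' estimate_ccf(30, 100, purity = 0.8, cn_mut = 2)  # point estimate 0.75
#' @export
estimate_ccf <- function(alt_reads, depth, purity, cn_mut, cn_diploid = 2,
                         params = detector_params(), grid_step = 0.01) {
  params <- as_detector_params(params)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (alt_reads < 0 || alt_reads > depth) {
    stop("alt_reads must lie in [0, depth]", call. = FALSE)
  }
  grid <- seq(0, 1, by = grid_step)
  vaf <- expected_vaf(purity, grid, cn_mut, cn_diploid)
  if (all(vaf == 0)) {
    if (alt_reads > 0) {
      stop("degenerate input: expected VAF is zero for every CCF but ",
           "alt_reads > 0", call. = FALSE)
    }
  }
  loglik <- stats::dbinom(alt_reads, depth, vaf, log = TRUE)
  loglik[!is.finite(loglik)] <- -Inf
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  # raw MLE may sit above the grid top; detect wanting CCF > 1 by checking
  # whether the unconstrained VAF inversion exceeds the grid maximum
  vaf_hat <- alt_reads / depth
  denom <- cn_diploid * (1 - purity) + cn_mut * purity
  ccf_raw <- vaf_hat * denom / purity
  clamped <- ccf_raw > 1 + 1e-12
  ccf_point <- grid[which.max(post)]
  cum <- cumsum(post)
  ccf_low <- grid[which(cum >= 0.025)[1]]
  ccf_high <- grid[which(cum >= 0.975)[1]]
  ccf_low <- min(ccf_low, ccf_point)
  ccf_high <- max(ccf_high, ccf_point)
  cls <- if (ccf_point >= params$clonal_ccf_cutoff) {
    "clonal_or_near_clonal"
  } else {
    "subclonal"
  }
  structure(
    list(ccf_point = ccf_point, ccf_low = ccf_low, ccf_high = ccf_high,
         clonality_class = cls, clamped = clamped,
         grid = grid, posterior = post),
    class = "ccf_estimate"
  )
}

#' @export
print.ccf_estimate <- function(x, ...) {
  cat(sprintf("CCF %.2f (95%% CI %.2f-%.2f), %s%s\n",
              x$ccf_point, x$ccf_low, x$ccf_high, x$clonality_class,
              if (isTRUE(x$clamped)) " [clamped at 1]" else ""))
  invisible(x)
}

#' Estimate CCFs for a mutation table
#'
#' Applies [estimate_ccf()] row-wise to a mutation observation table
#' (columns `alt_reads`, `depth`, `purity`, `cn_mut`, optional
#' `cn_diploid`) and appends `ccf_point`, `ccf_low`, `ccf_high`,
#' `clonality`.
#'
#' @param mutations Data frame of mutation observations; a path to a
#'   tab-separated file is also accepted.
#' @param params A [detector_params()] object.
#' @return The input data frame with four appended columns.
#' @export
estimate_ccf_table <- function(mutations, params = detector_params()) {
  if (is.character(mutations) && length(mutations) == 1L) {
    mutations <- utils::read.delim(mutations, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(mutations))
  need <- c("alt_reads", "depth", "purity", "cn_mut")
  miss <- setdiff(need, names(mutations))
  if (length(miss)) {
    stop("mutation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cnd <- if ("cn_diploid" %in% names(mutations)) mutations$cn_diploid else
    rep(2, nrow(mutations))
  res <- lapply(seq_len(nrow(mutations)), function(i) {
    estimate_ccf(mutations$alt_reads[i], mutations$depth[i],
                 mutations$purity[i], mutations$cn_mut[i], cnd[i],
                 params = params)
  })
  mutations$ccf_point <- vapply(res, `[[`, numeric(1), "ccf_point")
  mutations$ccf_low <- vapply(res, `[[`, numeric(1), "ccf_low")
  mutations$ccf_high <- vapply(res, `[[`, numeric(1), "ccf_high")
  mutations$clonality <- vapply(res, `[[`, character(1), "clonality_class")
  mutations
}
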