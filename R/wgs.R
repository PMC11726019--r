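#' Flag high-level amplified segments
#'
#' The chromosomal baseline is the length-weighted modal total copy number;
#' segments whose total CN strictly exceeds `amp_baseline_factor` times the
#' baseline are flagged as high-level amplifications (the copy-number
#' plateau left by ecDNA).
#'
#' @param segments `chrom_segments` of one chromosome.
#' @param params A [detector_params()] object.
#' @return List with `flagged` (logical per segment) and `baseline`.
#' @export
flag_amplified_segments <- function(segments, params = detector_params()) {
  params <- as_detector_params(params)
  if (!nrow(segments)) {
    return(list(flagged = logical(0), baseline = NA_real_))
  }
  len <- segments$end - segments$start + 1
  w <- tapply(len, segments$total_cn, sum)
  cn_levels <- as.numeric(names(w))
  baseline <- min(cn_levels[w == max(w)])  # tie toward the lower state
  list(flagged = segments$total_cn > params$amp_baseline_factor * baseline,
       baseline = baseline)
}

#' Cluster intrachromosomal breakends into candidate regions
#'
#' Sorted intrachromosomal breakend positions are grouped into maximal
#' stretches where consecutive breakends are at most `gap_bp` apart; each
#' region is extended to cover both ends of its member junctions. The whole
#' chromosome is always appended as an additional candidate, matching the
#' frequent whole-chromosome involvement of chromothripsis.
#'
#' @param junctions `sv_junctions` restricted to one chromosome.
#' @param gap_bp Maximum within-cluster breakend gap (default 10 Mb).
#' @param chrom_length Chromosome length for the whole-chromosome candidate
#'   (defaults to the maximum observed position).
#' @return Data frame with `start`, `end`, `whole_chrom` per region.
#' @export
cluster_regions <- function(junctions, gap_bp = 1e7, chrom_length = NULL) {
  intra <- junctions[junctions$chrom1 == junctions$chrom2, , drop = FALSE]
  if (is.null(chrom_length)) {
    chrom_length <- max(1, junctions$pos1, junctions$pos2)
  }
  regions <- NULL
  if (nrow(intra)) {
    pos <- sort(c(intra$pos1, intra$pos2))
    grp <- cumsum(c(1, diff(pos) > gap_bp))
    pieces <- lapply(split(pos, grp), range)
    regions <- do.call(rbind, lapply(pieces, function(r) {
      inside <- intra$pos1 >= r[1] & intra$pos1 <= r[2] |
        intra$pos2 >= r[1] & intra$pos2 <= r[2]
      data.frame(start = min(r[1], intra$pos1[inside]),
                 end = max(r[2], intra$pos2[inside]),
                 whole_chrom = FALSE)
    }))
  }
  regions <- rbind(regions,
                   data.frame(start = 1, end = chrom_length,
                              whole_chrom = TRUE))
  rownames(regions) <- NULL
  regions
}

#' Count interleaved intrachromosomal junctions
#'
#' Two junctions interleave when their spans overlap without nesting:
#' `a.pos1 < b.pos1 < a.pos2 < b.pos2` (or symmetrically). The returned
#' count is the size of the largest connected component of the interleave
#' graph; a junction with no interleaving partner does not count.
#'
#' @param junctions `sv_junctions` (intrachromosomal rows are used; each
#'   must satisfy `pos1 < pos2`).
#' @return Integer count (0 when no pair interleaves).
#' @export
count_interleaved <- function(junctions) {
  intra <- junctions[junctions$chrom1 == junctions$chrom2, , drop = FALSE]
  n <- nrow(intra)
  if (n < 2L) return(0L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  linked <- rep(FALSE, n)
  a1 <- intra$pos1; a2 <- intra$pos2
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      il <- (a1[i] < a1[j] & a1[j] < a2[i] & a2[i] < a2[j]) ||
            (a1[j] < a1[i] & a1[i] < a2[j] & a2[j] < a2[i])
      if (il) {
        linked[i] <- linked[j] <- TRUE
        parent[find(i)] <- find(j)
      }
    }
  }
  if (!any(linked)) return(0L)
  roots <- vapply(which(linked), find, integer(1))
  max(table(roots))
}

#' Fragment joins test
#'
#' Goodness-of-fit test of the random-ligation hypothesis: under one-off
#' shattering and random re-joining, the four intrachromosomal junction
#' orientation classes (deletion-like, duplication-like, head-to-head and
#' tail-to-tail inversion) occur with equal probability 1/4. With 20 or
#' more junctions a chi-square statistic on 3 df is used; below that, the
#' exact multinomial p-value is computed by full enumeration of outcomes
#' whose probability does not exceed that of the observed counts. The
#' region is consistent with random ligation (the test "passes") when the
#' p-value is at least `alpha_joins`.
#'
#' @param junctions `sv_junctions`, or a length-4 numeric vector of
#'   orientation-class counts.
#' @return The p-value.
#' @export
fragment_joins_test <- function(junctions) {
  classes <- c("deletion_like", "duplication_like",
               "h2h_inversion", "t2t_inversion")
  if (is.numeric(junctions)) {
    if (length(junctions) != 4L) {
      stop("counts must have length 4", call. = FALSE)
    }
    counts <- as.integer(junctions)
  } else {
    intra <- junctions[junctions$chrom1 == junctions$chrom2, , drop = FALSE]
    counts <- as.integer(table(factor(intra$orientation_class,
                                      levels = classes)))
  }
  n <- sum(counts)
  if (n == 0L) stop("fragment joins test needs at least one junction",
                    call. = FALSE)
  if (n >= 20L) {
    e <- n / 4
    x2 <- sum((counts - e)^2 / e)
    return(stats::pchisq(x2, df = 3, lower.tail = FALSE))
  }
  # exact multinomial: sum the probability of every outcome at most as
  # probable as the observed one
  obs_lp <- stats::dmultinom(counts, prob = rep(0.25, 4), log = TRUE)
  p <- 0
  for (c1 in 0:n) for (c2 in 0:(n - c1)) for (c3 in 0:(n - c1 - c2)) {
    c4 <- n - c1 - c2 - c3
    lp <- stats::dmultinom(c(c1, c2, c3, c4), prob = rep(0.25, 4),
                           log = TRUE)
    if (lp <= obs_lp + 1e-9) p <- p + exp(lp)
  }
  min(p, 1)
}

#' Breakpoint exponentiality test
#'
#' One-sample Kolmogorov-Smirnov test of breakend positions against the
#' uniform distribution on the region (equivalently, of breakpoint spacings
#' against the exponential distribution). One-off shattering scatters
#' breakpoints uniformly, so the test passes (is consistent with
#' chromothripsis) when the p-value is at least `alpha_exp`.
#'
#' @param positions Numeric breakend positions within the region.
#' @param region_start,region_end Region bounds (1-based inclusive).
#' @return The p-value.
#' @export
breakpoint_exponential_test <- function(positions, region_start,
                                        region_end) {
  if (region_end <= region_start) {
    stop("region length must be positive", call. = FALSE)
  }
  pos <- positions[positions >= region_start & positions <= region_end]
  if (length(unique(pos)) < 5L) {
    stop("breakpoint exponentiality test needs >= 5 distinct positions",
         call. = FALSE)
  }
  suppressWarnings(
    stats::ks.test(pos, "punif", min = region_start,
                   max = region_end)$p.value
  )
}

#' Chromosomal enrichment test
#'
#' One-sided binomial test of whether a chromosome carries more breakends
#' than expected from its share of the genome: with `n_genome` breakends
#' genome-wide, the chromosome's count is compared against
#' `Binomial(n_genome, chrom_length / genome_length)` and the upper tail
#' probability `P[X >= n_chrom]` is returned. The chromosome is enriched
#' (the test passes) when the p-value is at most `alpha_enrich`.
#'
#' @param n_chrom Breakend count on the chromosome.
#' @param chrom_length Chromosome length in bp.
#' @param n_genome Genome-wide breakend count (>= `n_chrom`).
#' @param genome_length Genome length in bp.
#' @return The p-value.
#' @export
chromosomal_enrichment_test <- function(n_chrom, chrom_length, n_genome,
                                        genome_length) {
  if (n_genome < 1) {
    stop("enrichment test needs at least one genome-wide breakend",
         call. = FALSE)
  }
  if (n_chrom > n_genome) {
    stop("chromosome breakend count exceeds genome-wide count",
         call. = FALSE)
  }
  stats::pbinom(n_chrom - 1, n_genome, chrom_length / genome_length,
                lower.tail = FALSE)
}

#' Evaluate the combined WGS chromothripsis criteria
#'
#' Applies the five combined criteria over the per-region summary
#' statistics. Writing `joins`, `exp` and `enrich` for the three tests
#' passing at their alpha levels (`joins`/`exp` pass when *not* rejected,
#' `enrich` passes when rejected toward excess):
#' \itemize{
#'   \item i: >= 6 interleaved intrachromosomal SVs, >= 7 contiguous
#'     oscillating segments, `joins`, and (`enrich` or `exp`);
#'   \item ii: >= 3 interleaved intrachromosomal SVs and >= 4
#'     interchromosomal SVs, >= 7 contiguous oscillating segments, and
#'     `joins`;
#'   \item iii: >= 40 interleaved intrachromosomal SVs and `joins`;
#'   \item iv: >= 100 SVs in total and >= 5 contiguous oscillating
#'     segments;
#'   \item v: >= 6 interleaved intrachromosomal SVs, 4-6 adjacent
#'     oscillating segments, `joins`, and (`enrich` or `exp`).
#' }
#' A region passing any of i-iv is `positive`; a region passing only v is
#' `low_density`; otherwise `negative`. Missing p-values count as failing
#' the corresponding test.
#'
#' @param n_intra_interleaved Largest interleaved-SV component size.
#' @param n_inter Interchromosomal junction count.
#' @param n_sv_total Total SV count in the region.
#' @param max_osc2 Longest two-state oscillating segment run.
#' @param p_joins,p_enrich,p_exp Test p-values (NA allowed).
#' @param params A [detector_params()] object.
#' @param chrom,region_start,region_end Optional bookkeeping carried into
#'   the call.
#' @param sample Sample label.
#' @return A `chromothripsis_call` list with counts, p-values,
#'   `criteria_passed` (subset of `c("i","ii","iii","iv","v")`) and
#'   `verdict`.
#' @export
evaluate_criteria <- function(n_intra_interleaved, n_inter, n_sv_total,
                              max_osc2, p_joins, p_enrich, p_exp,
                              params = detector_params(),
                              chrom = NA_character_, region_start = NA_real_,
                              region_end = NA_real_, sample = "sample") {
  params <- as_detector_params(params)
  joins_ok <- !is.na(p_joins) && p_joins >= params$alpha_joins
  exp_ok <- !is.na(p_exp) && p_exp >= params$alpha_exp
  enrich_ok <- !is.na(p_enrich) && p_enrich <= params$alpha_enrich
  crit <- c(
    i = n_intra_interleaved >= params$intra6 && max_osc2 >= params$osc7 &&
      joins_ok && (enrich_ok || exp_ok),
    ii = n_intra_interleaved >= params$intra3 && n_inter >= params$inter4 &&
      max_osc2 >= params$osc7 && joins_ok,
    iii = n_intra_interleaved >= params$intra40 && joins_ok,
    iv = n_sv_total >= params$total100 && max_osc2 >= params$osc5,
    v = n_intra_interleaved >= params$intra6 &&
      max_osc2 >= params$osc_low_min && max_osc2 <= params$osc_low_max &&
      joins_ok && (enrich_ok || exp_ok)
  )
  passed <- names(crit)[crit]
  verdict <- if (any(crit[c("i", "ii", "iii", "iv")])) {
    "positive"
  } else if (identical(passed, "v")) {
    "low_density"
  } else {
    "negative"
  }
  structure(
    list(sample = sample, chrom = chrom,
         region = c(region_start, region_end),
         n_intra_interleaved = as.integer(n_intra_interleaved),
         n_inter = as.integer(n_inter),
         n_sv_total = as.integer(n_sv_total),
         max_osc2 = as.integer(max_osc2),
         p_joins = p_joins, p_enrich = p_enrich, p_exp = p_exp,
         criteria_passed = passed, verdict = verdict),
    class = "chromothripsis_call"
  )
}

#' @export
print.chromothripsis_call <- function(x, ...) {
  cat(sprintf(
    "chr%s [%s-%s]: %s (criteria %s)\n  intra interleaved %d, inter %d, total SV %d, osc %d\n  p: joins %s, enrich %s, exp %s\n",
    x$chrom, format(x$region[1], big.mark = ","),
    format(x$region[2], big.mark = ","), x$verdict,
    if (length(x$criteria_passed)) paste(x$criteria_passed, collapse = ",")
    else "none",
    x$n_intra_interleaved, x$n_inter, x$n_sv_total, x$max_osc2,
    format(x$p_joins, digits = 3), format(x$p_enrich, digits = 3),
    format(x$p_exp, digits = 3)))
  invisible(x)
}

call_to_row <- function(x, reasons = "") {
  data.frame(
    sample = x$sample, chrom = x$chrom,
    start = x$region[1], end = x$region[2], verdict = x$verdict,
    n_intra_interleaved = x$n_intra_interleaved, n_inter = x$n_inter,
    n_sv_total = x$n_sv_total, max_osc2 = x$max_osc2,
    p_joins = x$p_joins, p_enrich = x$p_enrich, p_exp = x$p_exp,
    criteria_passed = paste(x$criteria_passed, collapse = ","),
    reasons = reasons, stringsAsFactors = FALSE
  )
}

#' WGS chromothripsis caller
#'
#' Full whole-genome calling pipeline: per chromosome, candidate regions
#' are formed by breakend-density clustering (plus the whole chromosome),
#' the interleaved-SV count, oscillating-CN run length and the three
#' statistical tests are computed for each region, the combined criteria
#' are evaluated with [evaluate_criteria()], and the best region verdict
#' (`positive` > `low_density` > `negative`) is kept for the chromosome.
#' The chromosomal enrichment test compares each chromosome's breakend
#' count against its length share of the genome, so `genome_length` should
#' reflect the full genome even when only a few chromosomes carry data
#' (default: the GRCh37 autosomal total).
#'
#' @param segments `chrom_segments` (or coercible) for the sample.
#' @param junctions `sv_junctions` (or coercible) for the sample.
#' @param params A [detector_params()] object.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   defaults to the maximum observed coordinate per chromosome.
#' @param genome_length Genome length used by the enrichment test
#'   (default `sum(grch37_autosome_lengths())`).
#' @param sample Sample label.
#' @return Object of class `chromothripsis_calls`: `calls` (best
#'   `chromothripsis_call` per chromosome) and `report` (flat data frame).
#' @export
call_wgs <- function(segments, junctions, params = detector_params(),
                     chrom_lengths = NULL,
                     genome_length = sum(grch37_autosome_lengths()),
                     sample = "sample") {
  params <- as_detector_params(params)
  if (is.character(segments) && length(segments) == 1L) {
    segments <- read_segments(segments)
  }
  if (!inherits(segments, "chrom_segments")) {
    segments <- as_chrom_segments(segments)
  }
  if (is.character(junctions) && length(junctions) == 1L) {
    junctions <- read_bedpe(junctions)
  }
  if (!inherits(junctions, "sv_junctions")) {
    junctions <- as_sv_junctions(junctions)
  }
  chroms <- unique(c(segments$chrom, junctions$chrom1, junctions$chrom2))
  get_len <- function(ch) {
    if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      return(as.numeric(chrom_lengths[[ch]]))
    }
    max(1, segments$end[segments$chrom == ch],
        junctions$pos1[junctions$chrom1 == ch],
        junctions$pos2[junctions$chrom2 == ch])
  }
  n_genome_breakends <- 2L * nrow(junctions)
  calls <- list()
  rows <- list()
  for (ch in chroms) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    rownames(seg) <- NULL
    j_ch <- junctions[junctions$chrom1 == ch | junctions$chrom2 == ch, ,
                      drop = FALSE]
    intra <- j_ch[j_ch$chrom1 == ch & j_ch$chrom2 == ch, , drop = FALSE]
    inter <- j_ch[xor(j_ch$chrom1 == ch, j_ch$chrom2 == ch), , drop = FALSE]
    chrom_len <- get_len(ch)
    n_chrom_breakends <- 2L * nrow(intra) + nrow(inter)
    p_enrich <- if (n_genome_breakends > 0) {
      chromosomal_enrichment_test(n_chrom_breakends, chrom_len,
                                  n_genome_breakends, genome_length)
    } else NA_real_
    amp <- flag_amplified_segments(seg, params)
    regions <- cluster_regions(j_ch, gap_bp = params$cluster_gap_bp,
                               chrom_length = chrom_len)
    best <- NULL
    for (k in seq_len(nrow(regions))) {
      rs <- regions$start[k]; re <- regions$end[k]
      in_reg <- intra$pos1 >= rs & intra$pos1 <= re &
        intra$pos2 >= rs & intra$pos2 <= re
      intra_r <- intra[in_reg, , drop = FALSE]
      inter_pos <- ifelse(inter$chrom1 == ch, inter$pos1, inter$pos2)
      inter_r <- inter[inter_pos >= rs & inter_pos <= re, , drop = FALSE]
      seg_keep <- seg$end >= rs & seg$start <= re
      seg_r <- seg[seg_keep, , drop = FALSE]
      rownames(seg_r) <- NULL
      runs <- find_oscillation_runs(seg_r, params,
                                    bridgeable = amp$flagged[seg_keep])
      max_osc2 <- max_oscillating_segments(runs)
      p_joins <- if (nrow(intra_r) > 0) fragment_joins_test(intra_r) else
        NA_real_
      bp <- c(intra_r$pos1, intra_r$pos2,
              ifelse(inter_r$chrom1 == ch, inter_r$pos1, inter_r$pos2))
      p_exp <- if (length(unique(bp)) >= 5L && re > rs) {
        breakpoint_exponential_test(bp, rs, re)
      } else NA_real_
      cl <- evaluate_criteria(
        n_intra_interleaved = count_interleaved(intra_r),
        n_inter = nrow(inter_r),
        n_sv_total = nrow(intra_r) + nrow(inter_r),
        max_osc2 = max_osc2,
        p_joins = p_joins, p_enrich = p_enrich, p_exp = p_exp,
        params = params, chrom = ch, region_start = rs, region_end = re,
        sample = sample
      )
      rank <- function(x) {
        base <- c(negative = 0, low_density = 1, positive = 2)[x$verdict]
        base * 1e6 + length(x$criteria_passed) * 1e3 +
          min(x$n_sv_total, 999)
      }
      if (is.null(best) || rank(cl) > rank(best)) best <- cl
    }
    calls[[ch]] <- best
    rows[[ch]] <- call_to_row(best)
  }
  report <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    as_report(data.frame())
  }
  structure(list(calls = calls, report = report, params = params),
            class = "chromothripsis_calls")
}

#' @export
print.chromothripsis_calls <- function(x, ...) {
  v <- vapply(x$calls, `[[`, character(1), "verdict")
  cat("WGS chromothripsis calls:", length(v), "chromosome(s);",
      sum(v == "positive"), "positive,",
      sum(v == "low_density"), "low density\n")
  for (cl in x$calls[v != "negative"]) print(cl)
  invisible(x)
}

#' @export
summary.chromothripsis_calls <- function(object, ...) {
  print(object)
  invisible(object$report)
}
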