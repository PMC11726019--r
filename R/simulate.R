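#' GRCh37 autosome lengths
#'
#' Approximate lengths (bp) of the 22 human autosomes on GRCh37, used to
#' place panel targets genome-wide and to give the chromosomal enrichment
#' test a whole-genome denominator.
#'
#' @return Named numeric vector, names `"1"` to `"22"`.
#' @export
grch37_autosome_lengths <- function() {
  c(`1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
    `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
    `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
    `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
    `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
    `21` = 48129895, `22` = 51304566)
}

#' Simulation configuration for chromosome shattering
#'
#' Collects the generative parameters of the shatter-religate model: `K`
#' breakpoints drawn uniformly on the region shatter one homolog of a
#' diploid chromosome; each fragment is retained with probability `r`,
#' retained fragments are permuted and flipped at random and re-ligated; an
#' optional subset of retained fragments is circularized into ecDNA
#' amplified to `A` copies (one fragment optionally duplicated within the
#' circle, reaching `2A`). Readouts mix tumor and normal at purity `p` and
#' add Gaussian noise of sd `noise_sd` to the segment log-ratios.
#'
#' Defaults model the recurrent scenario in atypical small-cell lung
#' carcinoma: shattering of a chr11-sized chromosome (135 Mb) with ~30
#' breakpoints, half the fragments lost, purity 0.8, and (when enabled)
#' ecDNA at 60 copies, so a duplicated oncogene fragment reaches
#' `2 - 1 + 2A = 121` total copies — the >100-copy regime seen for
#' ecDNA-amplified cyclin genes.
#'
#' @param chrom Chromosome label (default `"11"`).
#' @param chrom_length Chromosome length in bp.
#' @param region_start,region_end Shattered region (defaults: whole
#'   chromosome).
#' @param n_breakpoints `K >= 2`, number of shatter breakpoints.
#' @param retention_prob `r` in (0, 1], per-fragment retention probability.
#' @param purity `p` in (0, 1].
#' @param ecdna Whether to circularize part of the shattered material.
#' @param ecdna_fragments Number of fragments in the ecDNA circle.
#' @param ecdna_copies `A >= 6`, copy number of the circle.
#' @param oncogene_duplicated If `TRUE`, one ecDNA fragment is duplicated
#'   within the circle (reaching `2A` extrachromosomal copies).
#' @param noise_sd Standard deviation of log-ratio noise.
#' @param control_events Number of scattered simple SVs in control genomes.
#' @param seed Optional integer seed applied at simulation entry.
#' @return Object of class `shatter_config`.
#' @export
shatter_config <- function(chrom = "11",
                           chrom_length = 135006516,
                           region_start = 1,
                           region_end = chrom_length,
                           n_breakpoints = 30L,
                           retention_prob = 0.5,
                           purity = 0.8,
                           ecdna = FALSE,
                           ecdna_fragments = 3L,
                           ecdna_copies = 60L,
                           oncogene_duplicated = FALSE,
                           noise_sd = 0.1,
                           control_events = 3L,
                           seed = NULL) {
  cfg <- list(chrom = as.character(chrom), chrom_length = chrom_length,
              region_start = region_start, region_end = region_end,
              n_breakpoints = as.integer(n_breakpoints),
              retention_prob = retention_prob, purity = purity,
              ecdna = isTRUE(ecdna),
              ecdna_fragments = as.integer(ecdna_fragments),
              ecdna_copies = as.integer(ecdna_copies),
              oncogene_duplicated = isTRUE(oncogene_duplicated),
              noise_sd = noise_sd,
              control_events = as.integer(control_events),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$n_breakpoints < 2L) {
    stop("shatter_config: 'n_breakpoints' must be >= 2", call. = FALSE)
  }
  if (cfg$retention_prob <= 0 || cfg$retention_prob > 1) {
    stop("shatter_config: 'retention_prob' must lie in (0, 1]",
         call. = FALSE)
  }
  if (cfg$purity <= 0 || cfg$purity > 1) {
    stop("shatter_config: 'purity' must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$region_start < 1 || cfg$region_end > cfg$chrom_length ||
      cfg$region_end <= cfg$region_start) {
    stop("shatter_config: region must be a non-empty interval within the ",
         "chromosome", call. = FALSE)
  }
  if (cfg$ecdna && cfg$ecdna_copies < 6L) {
    stop("shatter_config: 'ecdna_copies' must be >= 6 (amplification)",
         call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("shatter_config: 'noise_sd' must be >= 0", call. = FALSE)
  }
  if (cfg$control_events < 0) {
    stop("shatter_config: 'control_events' must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "shatter_config")
}

merge_cn_steps <- function(df) {
  if (nrow(df) < 2L) return(df)
  grp <- cumsum(c(1, diff(df$total_cn) != 0 | df$start[-1] != df$end[-nrow(df)] + 1))
  out <- do.call(rbind, lapply(split(df, grp), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               total_cn = g$total_cn[1], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Breakends of a ligation between fragment `a` followed by fragment `b` in
# the derivative, each with its own orientation. The retained side of a
# breakend is encoded in the strand, so random orientations yield a uniform
# strand-pair (hence orientation-class) distribution.
ligation_junction <- function(a, b, flip_a, flip_b, chrom, id) {
  p1 <- if (flip_a) a["start"] else a["end"]
  s1 <- if (flip_a) "-" else "+"
  p2 <- if (flip_b) b["end"] else b["start"]
  s2 <- if (flip_b) "+" else "-"
  data.frame(id = id, chrom1 = chrom, pos1 = unname(p1), strand1 = s1,
             chrom2 = chrom, pos2 = unname(p2), strand2 = s2,
             n_support = NA_integer_, stringsAsFactors = FALSE)
}

new_shatter_truth <- function(config, fragments, junctions, label) {
  frag_in <- fragments
  cn <- ifelse(!frag_in$retained, 1L,
               ifelse(frag_in$ecdna,
                      1L + ifelse(frag_in$ecdna_dup,
                                  2L * config$ecdna_copies,
                                  config$ecdna_copies),
                      2L))
  frag_in$total_cn <- as.integer(cn)
  prof <- data.frame(chrom = config$chrom, start = frag_in$start,
                     end = frag_in$end, total_cn = frag_in$total_cn,
                     stringsAsFactors = FALSE)
  # flanks outside the shattered region stay diploid
  if (min(prof$start) > 1) {
    prof <- rbind(data.frame(chrom = config$chrom, start = 1,
                             end = min(prof$start) - 1, total_cn = 2L), prof)
  }
  if (max(prof$end) < config$chrom_length) {
    prof <- rbind(prof, data.frame(chrom = config$chrom,
                                   start = max(prof$end) + 1,
                                   end = config$chrom_length, total_cn = 2L))
  }
  prof <- prof[order(prof$start), , drop = FALSE]
  structure(
    list(config = config, fragments = frag_in,
         junctions = junctions, cn_profile = merge_cn_steps(prof),
         label = label),
    class = "shatter_truth"
  )
}

#' Simulate one chromothripsis event
#'
#' Generative model: `K` breakpoints are drawn uniformly on the region,
#' producing `K + 1` fragments of one homolog; each fragment is retained
#' with probability `r`; retained fragments are permuted uniformly and each
#' flipped with probability 1/2; adjacent ligated ends emit junctions whose
#' strand pair reflects the chosen orientations (orientation classes are
#' therefore uniform under random ligation). If ecDNA is enabled, a subset
#' of retained fragments is removed from the derivative chromosome,
#' circularized (emitting circular junctions) and amplified to `A` copies.
#' The resulting per-bp copy number is 2 on unshattered material, 1 on lost
#' fragments (the intact homolog remains), 2 on retained fragments, and
#' `2 - 1 + A` on ecDNA fragments (`2 - 1 + 2A` for a duplicated oncogene
#' fragment).
#'
#' @param config A [shatter_config()].
#' @return Object of class `shatter_truth`: `fragments` (with retention,
#'   ecDNA flags and true total CN), `junctions` (`sv_junctions`),
#'   `cn_profile` (merged step function) and `label = TRUE`.
#' @export
simulate_chromothripsis <- function(config = shatter_config()) {
  stopifnot(inherits(config, "shatter_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$n_breakpoints
  repeat {
    bp <- sort(round(stats::runif(K, config$region_start,
                                  config$region_end - 1)))
    if (length(unique(bp)) == K) break
  }
  starts <- c(config$region_start, bp + 1)
  ends <- c(bp, config$region_end)
  n_frag <- K + 1L
  retained <- stats::rbinom(n_frag, 1, config$retention_prob) == 1
  frag <- data.frame(start = starts, end = ends, retained = retained,
                     ecdna = FALSE, ecdna_dup = FALSE)
  idx_ret <- which(retained)
  if (config$ecdna) {
    if (config$ecdna_fragments > length(idx_ret)) {
      stop("ecdna_fragments exceeds the number of retained fragments",
           call. = FALSE)
    }
    ec <- sample(idx_ret, config$ecdna_fragments)
    frag$ecdna[ec] <- TRUE
    if (config$oncogene_duplicated) {
      frag$ecdna_dup[sample(ec, 1)] <- TRUE
    }
  }
  jl <- list()
  make_chain <- function(idx, circular) {
    if (!length(idx)) return(invisible(NULL))
    ord <- if (length(idx) > 1) sample(idx) else idx
    flips <- stats::runif(length(ord)) < 0.5
    pairs <- if (circular) {
      cbind(seq_along(ord), c(seq_along(ord)[-1], 1L))
    } else if (length(ord) > 1) {
      cbind(seq_len(length(ord) - 1L), seq(2L, length(ord)))
    } else {
      NULL
    }
    for (k in seq_len(NROW(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      jl[[length(jl) + 1L]] <<- ligation_junction(
        c(start = frag$start[ord[a]], end = frag$end[ord[a]]),
        c(start = frag$start[ord[b]], end = frag$end[ord[b]]),
        flips[a], flips[b], config$chrom,
        sprintf("j%04d", length(jl) + 1L))
    }
  }
  make_chain(setdiff(idx_ret, which(frag$ecdna)), circular = FALSE)
  make_chain(which(frag$ecdna), circular = TRUE)
  junctions <- if (length(jl)) {
    as_sv_junctions(do.call(rbind, jl))
  } else {
    as_sv_junctions(data.frame(chrom1 = character(0), pos1 = numeric(0),
                               strand1 = character(0), chrom2 = character(0),
                               pos2 = numeric(0), strand2 = character(0)))
  }
  new_shatter_truth(config, frag, junctions, label = TRUE)
}

#' Simulate a non-chromothriptic control genome
#'
#' Scatters `control_events` independent simple events (deletions or
#' tandem duplications, chosen at random) across the chromosome, spaced so
#' that no two events are adjacent, each emitting the deterministic
#' junction orientation of its type (deletion-like or duplication-like).
#' The construction is re-drawn if it ever produces four or more contiguous
#' alternating segments, so control genomes never satisfy the weakest
#' oscillation criterion.
#'
#' @param config A [shatter_config()]; only the chromosome geometry,
#'   `control_events` and `seed` are used.
#' @return A `shatter_truth` with `label = FALSE`.
#' @export
simulate_control <- function(config = shatter_config()) {
  stopifnot(inherits(config, "shatter_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- config$control_events
  L <- config$chrom_length
  for (try in 1:100) {
    if (m == 0L) {
      frag <- data.frame(start = 1, end = L, retained = TRUE,
                         ecdna = FALSE, ecdna_dup = FALSE)
      truth <- new_shatter_truth(config, frag,
                                 as_sv_junctions(data.frame(
                                   chrom1 = character(0), pos1 = numeric(0),
                                   strand1 = character(0),
                                   chrom2 = character(0), pos2 = numeric(0),
                                   strand2 = character(0))),
                                 label = FALSE)
      return(truth)
    }
    size <- round(stats::runif(m, 1e6, 5e6))
    gap <- 10e6
    starts <- sort(round(stats::runif(m, gap, L - gap - max(size))))
    if (m > 1 && any(diff(starts) < max(size) + gap)) next
    ends <- starts + size - 1
    is_del <- stats::runif(m) < 0.5
    seg_start <- c(1, sort(c(starts, ends + 1)))
    seg_end <- c(sort(c(starts - 1, ends)), L)
    cn <- rep(2L, length(seg_start))
    event_of <- match(seg_start, starts)
    cn[!is.na(event_of)] <- ifelse(is_del[event_of[!is.na(event_of)]], 1L, 3L)
    frag <- data.frame(start = seg_start, end = seg_end,
                       retained = TRUE, ecdna = FALSE, ecdna_dup = FALSE)
    jl <- lapply(seq_len(m), function(k) {
      if (is_del[k]) {
        data.frame(id = sprintf("c%03d", k), chrom1 = config$chrom,
                   pos1 = starts[k] - 1, strand1 = "+",
                   chrom2 = config$chrom, pos2 = ends[k] + 1, strand2 = "-",
                   n_support = NA_integer_)
      } else {
        data.frame(id = sprintf("c%03d", k), chrom1 = config$chrom,
                   pos1 = starts[k], strand1 = "-",
                   chrom2 = config$chrom, pos2 = ends[k], strand2 = "+",
                   n_support = NA_integer_)
      }
    })
    truth <- new_shatter_truth(config, frag,
                               as_sv_junctions(do.call(rbind, jl)),
                               label = FALSE)
    truth$fragments$total_cn <- as.integer(cn)
    prof <- data.frame(chrom = config$chrom, start = seg_start,
                       end = seg_end, total_cn = as.integer(cn),
                       stringsAsFactors = FALSE)
    truth$cn_profile <- merge_cn_steps(prof)
    runs <- find_oscillation_runs(
      as_chrom_segments(data.frame(
        chrom = truth$cn_profile$chrom, start = truth$cn_profile$start,
        end = truth$cn_profile$end, n_marks = 10, log_ratio = 0,
        total_cn = truth$cn_profile$total_cn)))
    if (max_oscillating_segments(runs) < 4L) return(truth)
  }
  stop("failed to draw a control genome without oscillation", call. = FALSE)
}

#' @export
print.shatter_truth <- function(x, ...) {
  cat(sprintf(
    "Simulated %s genome: chr%s, %d fragments (%d retained%s), %d junctions\n",
    if (x$label) "chromothriptic" else "control",
    x$config$chrom, nrow(x$fragments), sum(x$fragments$retained),
    if (any(x$fragments$ecdna))
      sprintf(", %d on ecDNA", sum(x$fragments$ecdna)) else "",
    nrow(x$junctions)))
  invisible(x)
}

cn_to_segments <- function(profile, purity, noise_sd, marks_per_bp = 2e-5) {
  cn <- profile$total_cn
  minor <- as.integer(pmin(pmax(cn - 1L, 0L), 1L))
  major <- cn - minor
  mix <- pmax((purity * cn + 2 * (1 - purity)) / 2, 1e-6)
  lr <- log2(mix) + stats::rnorm(nrow(profile), 0, noise_sd)
  lo <- abs(log((purity * major + (1 - purity)) /
                  (purity * minor + (1 - purity))))
  as_chrom_segments(data.frame(
    chrom = profile$chrom, start = profile$start, end = profile$end,
    n_marks = pmax(1L, round((profile$end - profile$start + 1) * marks_per_bp)),
    log_ratio = lr, log_odds = lo, total_cn = cn, minor_cn = minor,
    cell_fraction = 1.0, stringsAsFactors = FALSE))
}

#' Render a simulated genome as WGS output
#'
#' Converts the true copy-number step function into a segment table with
#' purity-mixed, noisy log-ratios (`log2((p * cn + 2 (1 - p)) / 2)` plus
#' Gaussian noise), allelic log-odds derived from major/minor copy number,
#' and cellular fraction 1 for all somatic segments; junctions are passed
#' through with positional jitter of at most 100 bp (detectors use
#' midpoints, so calls are jitter-invariant).
#'
#' @param truth A `shatter_truth`.
#' @param config Optional [shatter_config()] overriding the truth's
#'   rendering parameters (purity, noise_sd).
#' @return List with `segments` (`chrom_segments`) and `junctions`
#'   (`sv_junctions`).
#' @export
render_wgs <- function(truth, config = truth$config) {
  segments <- cn_to_segments(truth$cn_profile, config$purity,
                             config$noise_sd)
  j <- truth$junctions
  if (nrow(j)) {
    j$pos1 <- pmin(pmax(j$pos1 + sample(-100:100, nrow(j), TRUE), 1),
                   config$chrom_length)
    j$pos2 <- pmin(pmax(j$pos2 + sample(-100:100, nrow(j), TRUE), 1),
                   config$chrom_length)
    j <- as_sv_junctions(j)
  }
  list(segments = segments, junctions = j)
}

#' Generate a synthetic targeted-panel design
#'
#' Places `n_targets` non-overlapping gene-footprint-like intervals
#' (10-100 kb) across the genome, allocated to chromosomes in proportion to
#' length and locally clustered the way gene panels cluster in gene-dense
#' regions. Deterministic for a given seed. The default count matches a
#' 505-gene clinical panel.
#'
#' @param n_targets Number of target intervals (default 505).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param seed Optional seed.
#' @return A `panel_design` data frame with `chrom`, `start`, `end`.
#' @export
default_panel <- function(n_targets = 505L,
                          chrom_lengths = grch37_autosome_lengths(),
                          seed = NULL) {
  if (n_targets < 1L) stop("n_targets must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  alloc <- round(n_targets * chrom_lengths / sum(chrom_lengths))
  # fix rounding so the total is exact
  while (sum(alloc) != n_targets) {
    k <- if (sum(alloc) < n_targets) which.max(chrom_lengths) else
      which.max(alloc)
    alloc[k] <- alloc[k] + sign(n_targets - sum(alloc))
  }
  rows <- list()
  for (ch in names(chrom_lengths)) {
    n_ch <- alloc[[ch]]
    if (n_ch == 0L) next
    L <- chrom_lengths[[ch]]
    n_clust <- max(1L, ceiling(n_ch / 5))
    centers <- stats::runif(n_clust, 0.02 * L, 0.98 * L)
    pos <- centers[1 + (seq_len(n_ch) - 1) %% n_clust] +
      stats::rnorm(n_ch, 0, 2e6)
    width <- round(stats::runif(n_ch, 1e4, 1e5))
    start <- pmin(pmax(round(pos), 1), L - max(width))
    ord <- order(start)
    start <- start[ord]; width <- width[ord]
    for (k in seq_len(n_ch)) {
      if (k > 1L) {
        prev_end <- rows[[length(rows)]]$end
        if (start[k] <= prev_end) start[k] <- prev_end + 1
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = normalize_chrom(ch), start = start[k],
        end = min(start[k] + width[k] - 1, L), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("panel_design", "data.frame")
  out
}

#' Render a simulated genome at targeted-panel resolution
#'
#' The panel observes copy number only at its target intervals: each target
#' takes the CN of the profile step it overlaps most, consecutive targets
#' with equal integer CN are merged into one segment spanning first to last
#' target (`n_marks` = number of merged targets), junctions are dropped
#' (panels yield few direct SV observations), and log-ratio noise is added
#' as in [render_wgs()]. Oscillating runs shorter at panel resolution than
#' in truth are the mechanism behind the reduced sensitivity of targeted
#' sequencing for chromothripsis.
#'
#' @param truth A `shatter_truth`.
#' @param panel A `panel_design` (e.g. [default_panel()]).
#' @param config Optional [shatter_config()] override for rendering.
#' @return List with `segments` (`chrom_segments`; junctions are not
#'   rendered).
#' @export
render_panel <- function(truth, panel, config = truth$config) {
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("panel design is empty", call. = FALSE)
  }
  targets <- panel[normalize_chrom(panel$chrom) ==
                     normalize_chrom(truth$config$chrom), , drop = FALSE]
  targets <- targets[order(targets$start), , drop = FALSE]
  prof <- truth$cn_profile
  if (!nrow(targets)) {
    return(list(segments = as_chrom_segments(data.frame(
      chrom = character(0), start = numeric(0), end = numeric(0),
      n_marks = integer(0), log_ratio = numeric(0), total_cn = integer(0)))))
  }
  cn_of_target <- vapply(seq_len(nrow(targets)), function(k) {
    ovl <- pmin(prof$end, targets$end[k]) - pmax(prof$start, targets$start[k]) + 1
    ovl[ovl < 0] <- 0
    if (all(ovl == 0)) return(NA_integer_)
    prof$total_cn[which.max(ovl)]
  }, integer(1))
  keep <- !is.na(cn_of_target)
  targets <- targets[keep, , drop = FALSE]
  cn_of_target <- cn_of_target[keep]
  if (!nrow(targets)) {
    return(list(segments = as_chrom_segments(data.frame(
      chrom = character(0), start = numeric(0), end = numeric(0),
      n_marks = integer(0), log_ratio = numeric(0), total_cn = integer(0)))))
  }
  grp <- cumsum(c(1, diff(cn_of_target) != 0))
  merged <- do.call(rbind, lapply(split(seq_along(grp), grp), function(ix) {
    data.frame(chrom = normalize_chrom(truth$config$chrom),
               start = targets$start[ix[1]],
               end = targets$end[ix[length(ix)]],
               total_cn = cn_of_target[ix[1]],
               n_targets = length(ix), stringsAsFactors = FALSE)
  }))
  cn <- merged$total_cn
  minor <- as.integer(pmin(pmax(cn - 1L, 0L), 1L))
  major <- cn - minor
  p <- config$purity
  mix <- pmax((p * cn + 2 * (1 - p)) / 2, 1e-6)
  lr <- log2(mix) + stats::rnorm(nrow(merged), 0, config$noise_sd)
  lo <- abs(log((p * major + (1 - p)) / (p * minor + (1 - p))))
  seg <- as_chrom_segments(data.frame(
    chrom = merged$chrom, start = merged$start, end = merged$end,
    n_marks = merged$n_targets, log_ratio = lr, log_odds = lo,
    total_cn = cn, minor_cn = minor, cell_fraction = 1.0,
    stringsAsFactors = FALSE))
  list(segments = seg)
}
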