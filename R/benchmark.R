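#' Benchmark both detectors on simulated genomes
#'
#' The concordance experiment on simulated data: for each of `n` seeds, one
#' chromothriptic genome and one control genome are simulated, rendered
#' both as WGS (segments + junctions) and at targeted-panel resolution
#' (segments at gene targets only), and both callers are run on the paired
#' renderings. Chromosome-level sensitivity and specificity per mode are
#' tabulated with exact binomial 95\% intervals. Deterministic for a given
#' seed.
#'
#' @param n Number of replicate seeds (>= 1).
#' @param config A [shatter_config()] giving the generative conditions.
#' @param params A [detector_params()].
#' @param panel A `panel_design`; by default a 505-target genome-wide
#'   panel built from the benchmark seed.
#' @param genome_length Genome length for the enrichment test.
#' @param seed Master seed; every source of randomness derives from it.
#' @return Object of class `shatter_benchmark`: `table` (one row per mode
#'   with sensitivity/specificity and CIs), `replicates` (per-seed calls)
#'   and `manifest` (config, params, seed, package version).
#' @export
run_benchmark <- function(n = 200L, config = shatter_config(),
                          params = detector_params(), panel = NULL,
                          genome_length = sum(grch37_autosome_lengths()),
                          seed = 1L) {
  if (n < 1L) stop("run_benchmark: 'n' must be >= 1", call. = FALSE)
  params <- as_detector_params(params)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
  if (is.null(panel)) {
    panel <- default_panel(seed = sample.int(.Machine$integer.max - 1L, 1))
  }
  ch <- normalize_chrom(config$chrom)
  one_side <- function(s, positive) {
    cfg <- config
    cfg$seed <- s
    truth <- if (positive) simulate_chromothripsis(cfg) else
      simulate_control(cfg)
    wgs <- render_wgs(truth, cfg)
    pan <- render_panel(truth, panel, cfg)
    wgs_call <- call_wgs(wgs$segments, wgs$junctions, params,
                         chrom_lengths = stats::setNames(cfg$chrom_length, ch),
                         genome_length = genome_length)
    wgs_pos <- !is.null(wgs_call$calls[[ch]]) &&
      wgs_call$calls[[ch]]$verdict != "negative"
    pan_pos <- FALSE
    if (nrow(pan$segments)) {
      pan_call <- call_panel(pan$segments, params)
      pan_pos <- !is.null(pan_call$calls[[ch]]) &&
        pan_call$calls[[ch]]$verdict == "suggestive_positive"
    }
    c(wgs = wgs_pos, panel = pan_pos)
  }
  res <- t(vapply(seq_len(n), function(i) {
    c(one_side(seeds[2 * i - 1L], TRUE), one_side(seeds[2 * i], FALSE))
  }, c(wgs_tp = FALSE, panel_tp = FALSE, wgs_fp = FALSE, panel_fp = FALSE)))
  replicates <- as.data.frame(res)
  replicates$seed_pos <- seeds[seq(1, 2 * n, by = 2)]
  replicates$seed_neg <- seeds[seq(2, 2 * n, by = 2)]
  row_for <- function(mode, tp, fp) {
    sens_ci <- as.numeric(stats::binom.test(sum(tp), n)$conf.int)
    spec_ci <- as.numeric(stats::binom.test(n - sum(fp), n)$conf.int)
    data.frame(mode = mode, n = n,
               sensitivity = mean(tp), sens_low = sens_ci[1],
               sens_high = sens_ci[2],
               specificity = mean(!fp), spec_low = spec_ci[1],
               spec_high = spec_ci[2], stringsAsFactors = FALSE)
  }
  tab <- rbind(row_for("wgs", replicates$wgs_tp, replicates$wgs_fp),
               row_for("panel", replicates$panel_tp, replicates$panel_fp))
  manifest <- list(seed = seed, n = n, config = unclass(config),
                   params = unclass(params),
                   package_version = as.character(
                     utils::packageVersion("chromoshatter")))
  structure(list(table = tab, replicates = replicates, manifest = manifest),
            class = "shatter_benchmark")
}

#' @export
print.shatter_benchmark <- function(x, ...) {
  cat("Detector operating characteristics over", x$table$n[1],
      "simulated genome pairs:\n")
  for (k in seq_len(nrow(x$table))) {
    r <- x$table[k, ]
    cat(sprintf(
      "  %-5s sensitivity %.3f [%.3f, %.3f]  specificity %.3f [%.3f, %.3f]\n",
      r$mode, r$sensitivity, r$sens_low, r$sens_high,
      r$specificity, r$spec_low, r$spec_high))
  }
  invisible(x)
}

.config_aliases <- c(min_run = "min_panel_run", k = "n_breakpoints",
                     noise = "noise_sd", retention = "retention_prob")

#' Validate a run configuration
#'
#' Parses and validates a configuration given as a YAML/JSON file path,
#' YAML text, or a list. Keys are split between the simulator
#' ([shatter_config()] fields) and detector ([detector_params()] fields);
#' the aliases `min_run`, `k`, `noise` and `retention` are mapped to their
#' canonical names; run-level keys `n`, `seed` and `out` are passed
#' through. Unknown keys are an error listing them; out-of-range values are
#' rejected by the constructors with field-level messages.
#'
#' @param raw File path, YAML text, or list.
#' @return List with `sim` (a `shatter_config`), `params`
#'   (`detector_params`), `n`, `seed`, `out`.
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1L) {
    cfg <- if (file.exists(raw)) yaml::read_yaml(raw) else
      yaml::yaml.load(raw)
    if (is.null(cfg)) cfg <- list()
  } else if (is.list(raw)) {
    cfg <- raw
  } else {
    stop("config must be a file path, YAML text, or a list", call. = FALSE)
  }
  nm <- names(cfg)
  hit <- nm %in% names(.config_aliases)
  nm[hit] <- .config_aliases[nm[hit]]
  names(cfg) <- nm
  sim_keys <- setdiff(names(formals(shatter_config)), "seed")
  par_keys <- names(formals(detector_params))
  run_keys <- c("n", "seed", "out")
  unknown <- setdiff(nm, c(sim_keys, par_keys, run_keys))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim <- do.call(shatter_config,
                 c(cfg[intersect(nm, sim_keys)],
                   if ("seed" %in% nm) list(seed = cfg$seed)))
  params <- do.call(detector_params, cfg[intersect(nm, par_keys)])
  list(sim = sim, params = params,
       n = if ("n" %in% nm) as.integer(cfg$n) else 200L,
       seed = if ("seed" %in% nm) as.integer(cfg$seed) else 1L,
       out = if ("out" %in% nm) cfg$out else NULL)
}
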