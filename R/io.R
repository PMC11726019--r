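# Column aliases accepted in segment tables. Left: canonical internal name;
# right: header spellings seen in allele-specific CN caller output.
.seg_aliases <- list(
  chrom         = c("chrom", "chromosome", "chr"),
  start         = c("start", "loc.start", "loc_start"),
  end           = c("end", "loc.end", "loc_end"),
  n_marks       = c("num_mark", "num.mark", "n_marks", "nummark"),
  log_ratio     = c("cnlr", "cnlr.median", "cnlr_median", "log_ratio", "seg.mean"),
  log_odds      = c("logor", "mafr", "log_odds"),
  total_cn      = c("tcn", "tcn.em", "tcn_em", "total_cn"),
  minor_cn      = c("lcn", "lcn.em", "lcn_em", "minor_cn"),
  cell_fraction = c("cf", "cf.em", "cf_em", "cell_fraction", "ccf")
)

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix so that mixed-dialect inputs
#' (`"chr1"` vs `"1"`) compare equal.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector without the `"chr"` prefix.
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX"))
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

new_chrom_segments <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("chrom_segments", "data.frame")
  df
}

#' Validate and canonicalize a segment table
#'
#' Coerces a data frame of copy-number segments to the internal
#' representation: 1-based inclusive coordinates, chromosomes normalized,
#' rows sorted by (chrom, start), non-overlap enforced within chromosome.
#' Missing `cell_fraction` is filled with 1.0 and flagged via the
#' `"ccf_assumed"` attribute, so a downstream CCF filter never rejects but
#' the report can disclose the assumption.
#'
#' @param df Data frame with columns `chrom`, `start`, `end`, `n_marks`,
#'   `log_ratio`, `total_cn` and optionally `log_odds`, `minor_cn`,
#'   `cell_fraction`.
#' @return A `chrom_segments` data frame.
#' @export
as_chrom_segments <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end", "n_marks", "log_ratio", "total_cn")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("segment table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    chrom = normalize_chrom(df$chrom),
    start = as.numeric(df$start),
    end = as.numeric(df$end),
    n_marks = as.integer(df$n_marks),
    log_ratio = as.numeric(df$log_ratio),
    log_odds = if ("log_odds" %in% names(df)) as.numeric(df$log_odds) else
      rep(NA_real_, nrow(df)),
    total_cn = as.integer(df$total_cn),
    minor_cn = if ("minor_cn" %in% names(df)) as.integer(df$minor_cn) else
      rep(NA_integer_, nrow(df)),
    cell_fraction = if ("cell_fraction" %in% names(df))
      as.numeric(df$cell_fraction) else rep(NA_real_, nrow(df)),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(out$start) | !is.finite(out$end))
  if (length(bad)) {
    stop("segment row ", bad[1], ": non-numeric position", call. = FALSE)
  }
  bad <- which(out$end < out$start)
  if (length(bad)) {
    stop("segment row ", bad[1], ": end < start", call. = FALSE)
  }
  if (any(out$n_marks < 1L, na.rm = TRUE)) {
    stop("segment row ", which(out$n_marks < 1L)[1], ": n_marks < 1",
         call. = FALSE)
  }
  if (any(out$total_cn < 0L, na.rm = TRUE)) {
    stop("negative total_cn in segment table", call. = FALSE)
  }
  both <- !is.na(out$minor_cn) & !is.na(out$total_cn)
  if (any(out$minor_cn[both] > out$total_cn[both] - out$minor_cn[both])) {
    stop("minor_cn exceeds the major allele copy number; the minor allele ",
         "must be the lesser", call. = FALSE)
  }
  ccf_assumed <- anyNA(out$cell_fraction)
  out$cell_fraction[is.na(out$cell_fraction)] <- 1.0
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  for (ch in unique(out$chrom)) {
    s <- out[out$chrom == ch, , drop = FALSE]
    if (nrow(s) > 1L) {
      ovl <- which(s$start[-1] <= s$end[-nrow(s)])
      if (length(ovl)) {
        stop("overlapping segments on chromosome ", ch, " near position ",
             s$start[ovl[1] + 1L],
             " (input must be a segmentation, not an interval set)",
             call. = FALSE)
      }
    }
  }
  out <- new_chrom_segments(out)
  attr(out, "ccf_assumed") <- ccf_assumed
  out
}

#' Read an allele-specific copy-number segment table
#'
#' Reads a tab-separated segmentation in the style of allele-specific CN
#' callers (columns `chrom, start, end, num_mark, cnlr, logOR, tcn, lcn, cf`;
#' common header aliases are mapped automatically). Positions are 1-based
#' inclusive. Segments are sorted per chromosome and must not overlap.
#'
#' @param path Path to the tab-separated file (UTF-8, with header).
#' @return A `chrom_segments` data frame; attributes `n_read` and
#'   `n_dropped` count data rows read and rows dropped (rows with
#'   missing total copy number), and `ccf_assumed` records whether a missing
#'   cellular-fraction column was defaulted to 1.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(raw))
  cols <- list()
  for (nm in names(.seg_aliases)) {
    hit <- which(lc %in% .seg_aliases[[nm]])
    if (length(hit)) cols[[nm]] <- raw[[hit[1]]]
  }
  need <- c("chrom", "start", "end", "n_marks", "log_ratio", "total_cn")
  miss <- setdiff(need, names(cols))
  if (length(miss)) {
    stop("segment table header lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  n_read <- nrow(df)
  # rows without an integer CN fit carry no usable state
  keep <- !is.na(suppressWarnings(as.numeric(df$total_cn)))
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  suppressWarnings({
    pos_bad <- which(is.na(as.numeric(df$start)) | is.na(as.numeric(df$end)))
  })
  if (length(pos_bad)) {
    stop("malformed segment row at line ", pos_bad[1] + 1L,
         " of ", path, call. = FALSE)
  }
  endlt <- which(as.numeric(df$end) < as.numeric(df$start))
  if (length(endlt)) {
    stop("malformed segment row at line ", endlt[1] + 1L, " of ", path,
         ": end < start", call. = FALSE)
  }
  out <- as_chrom_segments(df)
  attr(out, "n_read") <- n_read
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Classify the orientation of a structural-variant junction
#'
#' A pure function of chromosome equality and the two breakend strands.
#' For intrachromosomal junctions (breakends ordered so `pos1 < pos2`):
#' `(+,-)` is deletion-like, `(-,+)` duplication-like, `(+,+)` a
#' head-to-head inversion and `(-,-)` a tail-to-tail inversion. Junctions
#' with breakends on different chromosomes are interchromosomal.
#'
#' @param chrom1,chrom2 Chromosome labels of the two breakends.
#' @param strand1,strand2 Strands (`"+"` or `"-"`).
#' @return Character vector of orientation classes.
#' @examples
#' classify_orientation("1", "1", "+", "-")
#' classify_orientation("1", "2", "+", "-")
#' @export
classify_orientation <- function(chrom1, chrom2, strand1, strand2) {
  if (!all(c(strand1, strand2) %in% c("+", "-"))) {
    stop("strands must be '+' or '-'", call. = FALSE)
  }
  inter <- normalize_chrom(chrom1) != normalize_chrom(chrom2)
  key <- paste0(strand1, strand2)
  cls <- c("++" = "h2h_inversion", "--" = "t2t_inversion",
           "+-" = "deletion_like", "-+" = "duplication_like")[key]
  cls <- unname(cls)
  cls[inter] <- "interchromosomal"
  cls
}

new_sv_junctions <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("sv_junctions", "data.frame")
  df
}

#' Canonicalize a junction table
#'
#' Normalizes chromosome labels, orders intrachromosomal breakends so
#' `pos1 < pos2` (swapping strands along with positions) and assigns the
#' orientation class. Idempotent: re-normalizing changes nothing.
#'
#' @param df Data frame with columns `chrom1, pos1, strand1, chrom2, pos2,
#'   strand2` and optionally `id`, `n_support`.
#' @return An `sv_junctions` data frame with an `orientation_class` column.
#' @export
as_sv_junctions <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("junction table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    id = if ("id" %in% names(df)) as.character(df$id) else
      sprintf("sv%05d", seq_len(nrow(df))),
    chrom1 = normalize_chrom(df$chrom1),
    pos1 = as.numeric(df$pos1),
    strand1 = as.character(df$strand1),
    chrom2 = normalize_chrom(df$chrom2),
    pos2 = as.numeric(df$pos2),
    strand2 = as.character(df$strand2),
    n_support = if ("n_support" %in% names(df)) as.integer(df$n_support) else
      rep(NA_integer_, nrow(df)),
    stringsAsFactors = FALSE
  )
  if (!all(c(out$strand1, out$strand2) %in% c("+", "-"))) {
    stop("junction strands must be '+' or '-' (orientation is required)",
         call. = FALSE)
  }
  flip <- out$chrom1 == out$chrom2 & out$pos2 < out$pos1
  if (any(flip)) {
    tmp_pos <- out$pos1[flip]; tmp_str <- out$strand1[flip]
    out$pos1[flip] <- out$pos2[flip]; out$strand1[flip] <- out$strand2[flip]
    out$pos2[flip] <- tmp_pos; out$strand2[flip] <- tmp_str
  }
  out$orientation_class <- classify_orientation(out$chrom1, out$chrom2,
                                                out$strand1, out$strand2)
  new_sv_junctions(out)
}

#' Read structural-variant junctions from BEDPE
#'
#' Expects the 10-column BEDPE layout
#' `chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2`
#' with 0-based half-open intervals. Each breakend is collapsed to a 1-based
#' point position at the interval midpoint (rounded down); intrachromosomal
#' junctions are normalized so `pos1 < pos2` with strands swapped
#' accordingly, and the orientation class is assigned.
#'
#' @param path Path to a BEDPE file (plain text, tab-separated, optional
#'   `#`-prefixed header).
#' @return An `sv_junctions` data frame.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 10L) {
    stop("BEDPE must have 10 columns incl. strand1/strand2 ",
         "(orientation is required by the fragment joins test); got ",
         ncol(raw), call. = FALSE)
  }
  names(raw)[1:10] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                        "name", "score", "strand1", "strand2")
  # midpoint of [start, end) in 1-based coordinates, rounded down
  mid <- function(s0, e0) floor((s0 + 1 + e0) / 2)
  df <- data.frame(
    id = as.character(raw$name),
    chrom1 = raw$chrom1, pos1 = mid(as.numeric(raw$start1), as.numeric(raw$end1)),
    strand1 = raw$strand1,
    chrom2 = raw$chrom2, pos2 = mid(as.numeric(raw$start2), as.numeric(raw$end2)),
    strand2 = raw$strand2,
    n_support = suppressWarnings(as.integer(raw$score)),
    stringsAsFactors = FALSE
  )
  as_sv_junctions(df)
}

#' Write junctions to BEDPE
#'
#' Inverse of [read_bedpe()]: point breakends become 1-bp intervals in
#' 0-based half-open coordinates.
#'
#' @param junctions An `sv_junctions` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedpe <- function(junctions, path) {
  j <- as_sv_junctions(junctions)
  score <- ifelse(is.na(j$n_support), 0L, j$n_support)
  out <- data.frame(j$chrom1, j$pos1 - 1, j$pos1, j$chrom2, j$pos2 - 1, j$pos2,
                    j$id, score, j$strand1, j$strand2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.report_cols <- c("sample", "chrom", "start", "end", "verdict",
                  "n_intra_interleaved", "n_inter", "n_sv_total", "max_osc2",
                  "p_joins", "p_enrich", "p_exp", "criteria_passed", "reasons")

#' Write a chromothripsis call report
#'
#' Writes one row per (sample, chromosome, region) as a tab-separated table,
#' plus a JSON sidecar (`<path>.json`) that round-trips losslessly through
#' [read_report()]. Rows are sorted by (sample, chrom, start).
#'
#' @param calls A data frame of calls (e.g. from [call_wgs()] or
#'   [call_panel()] via [as_report()]), or an object with an `$report`
#'   component.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(calls, path) {
  df <- as_report(calls)
  df <- df[order(df$sample, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  con <- try(file(path, open = "wb"), silent = TRUE)
  if (inherits(con, "try-error")) {
    stop("cannot write report to ", path, call. = FALSE)
  }
  close(con)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(df, paste0(path, ".json"), digits = NA, na = "null")
  invisible(path)
}

#' Read back a chromothripsis call report
#'
#' @param path Path to the JSON sidecar (or the TSV path; `.json` is
#'   appended if missing).
#' @return The report data frame as written by [write_report()].
#' @export
read_report <- function(path) {
  if (!grepl("\\.json$", path)) path <- paste0(path, ".json")
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L || is.null(dim(df))) {
    df <- as.data.frame(matrix(nrow = 0, ncol = length(.report_cols),
                               dimnames = list(NULL, .report_cols)))
  }
  for (nm in c("start", "end", "p_joins", "p_enrich", "p_exp")) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  for (nm in c("n_intra_interleaved", "n_inter", "n_sv_total", "max_osc2")) {
    df[[nm]] <- as.integer(df[[nm]])
  }
  for (nm in c("sample", "chrom", "verdict", "criteria_passed", "reasons")) {
    df[[nm]] <- as.character(df[[nm]])
  }
  df
}

#' Coerce calls to the flat report schema
#'
#' @param calls A call object (`chromothripsis_calls`, `panel_calls`) or an
#'   already-flat data frame.
#' @return Data frame with the report columns.
#' @export
as_report <- function(calls) {
  if (!is.null(attr(calls, "report"))) calls <- attr(calls, "report")
  if (is.list(calls) && !is.data.frame(calls) && !is.null(calls$report)) {
    calls <- calls$report
  }
  if (!is.data.frame(calls)) {
    stop("'calls' must be a report data frame or carry one", call. = FALSE)
  }
  df <- calls
  defaults <- list(sample = "sample", chrom = NA_character_, start = NA_real_,
                   end = NA_real_, verdict = NA_character_,
                   n_intra_interleaved = NA_integer_, n_inter = NA_integer_,
                   n_sv_total = NA_integer_, max_osc2 = NA_integer_,
                   p_joins = NA_real_, p_enrich = NA_real_, p_exp = NA_real_,
                   criteria_passed = "", reasons = "")
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], length.out = nrow(df))
  }
  df[, .report_cols, drop = FALSE]
}
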