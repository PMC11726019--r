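# Build a segment table from a total-CN sequence with adjustable geometry.
# Default: adjacent 10-Mb segments, log-ratios consistent with the CN track,
# cellular fraction 1.
make_segments <- function(cn, chrom = "1", len = 1e7, cf = 1,
                          log_ratio = NULL, log_odds = NULL,
                          minor_cn = NULL) {
  n <- length(cn)
  len <- rep(len, length.out = n)
  start <- if (n == 0L) numeric(0) else cumsum(c(1, len[-n]))
  if (is.null(log_ratio)) log_ratio <- log2(pmax(cn, 1e-6) / 2)
  df <- data.frame(chrom = rep(chrom, length.out = n), start = start,
                   end = start + len - 1, n_marks = rep(20L, n),
                   log_ratio = log_ratio, total_cn = cn,
                   cell_fraction = rep(cf, length.out = n))
  if (!is.null(log_odds)) df$log_odds <- log_odds
  if (!is.null(minor_cn)) df$minor_cn <- minor_cn
  as_chrom_segments(df)
}

# Intrachromosomal junction set from span endpoints.
make_junctions <- function(pos1, pos2, chrom = "1",
                           strand1 = "+", strand2 = "-") {
  n <- length(pos1)
  as_sv_junctions(data.frame(
    chrom1 = rep(chrom, length.out = n), pos1 = pos1,
    strand1 = rep(strand1, length.out = n),
    chrom2 = rep(chrom, length.out = n), pos2 = pos2,
    strand2 = rep(strand2, length.out = n)))
}
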