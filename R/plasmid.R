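#' Estimate plasmid copy number from sequencing depth
#'
#' The point estimate is the mean per-base depth over plasmid-specific
#' sequence (the complement of the shared mask) divided by the genome-wide
#' mean depth — copies per haploid genome. Shared bases are ignored
#' entirely, so depth changes inside shared intervals can never move the
#' estimate. The confidence interval is a seeded nonparametric percentile
#' bootstrap over bins of plasmid-specific bases, resampled at bin (not
#' base) level to respect local depth autocorrelation.
#'
#' @param track a [depth_track()] over the plasmid; positions absent from
#'   the track count as depth 0
#' @param spec a [plasmid_spec()]
#' @param genome_mean positive scalar from [genome_mean_depth()]
#' @param n_boot bootstrap resamples (default 1,000)
#' @param conf confidence level (default 0.95)
#' @param bin_size bootstrap bin width; defaults to the track's recorded
#'   bin size, else 100 bp
#' @param seed integer seed for the bootstrap
#' @return a `cn_estimate`: `point`, `ci_low`, `ci_high`, `n_bases_used`,
#'   `genome_mean_used`, `n_boot`, `seed`
#' @export
estimate_plasmid_cn <- function(track, spec, genome_mean, n_boot = 1000,
                                conf = 0.95, bin_size = NULL, seed = NULL) {
  stopifnot(inherits(spec, "plasmid_spec"), genome_mean > 0)
  if (is.null(bin_size))
    bin_size <- if (!is.null(attr(track, "bin_size"))) attr(track, "bin_size") else 100L
  specific <- mask_complement(spec$shared, spec$name, spec$length)
  n_spec <- mask_width(specific)
  if (n_spec == 0) stop("plasmid has no plasmid-specific bases")
  # dense depth over specific bases (absent positions are 0)
  depth <- numeric(spec$length)
  sub <- track[track$seqname == spec$name, , drop = FALSE]
  if (nrow(sub) > 0) {
    if (max(sub$pos) > spec$length) stop("track positions exceed plasmid length")
    depth[sub$pos] <- sub$depth
  }
  pos0 <- unlist(mapply(function(s, e) s:(e - 1L), specific$start,
                        specific$end, SIMPLIFY = FALSE))
  d <- depth[pos0 + 1L]
  point <- mean(d) / genome_mean
  if (all(d == 0)) {
    est <- list(point = 0, ci_low = 0, ci_high = 0, n_bases_used = n_spec,
                genome_mean_used = genome_mean, n_boot = 0L, seed = seed)
    class(est) <- "cn_estimate"
    return(est)
  }
  bins <- pos0 %/% as.integer(bin_size)
  sums <- rowsum(d, bins)[, 1]
  cnts <- rowsum(rep(1, length(d)), bins)[, 1]
  nb <- length(sums)
  boots <- .with_seed(seed, {
    idx <- matrix(sample.int(nb, nb * n_boot, replace = TRUE), nrow = nb)
    colSums(matrix(sums[idx], nrow = nb)) /
      colSums(matrix(cnts[idx], nrow = nb)) / genome_mean
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  est <- list(point = point, ci_low = ci[1], ci_high = ci[2],
              n_bases_used = as.integer(n_spec),
              genome_mean_used = genome_mean,
              n_boot = as.integer(n_boot), seed = seed)
  class(est) <- "cn_estimate"
  est
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf("plasmid copy number: %.3g (95%% CI %.3g-%.3g, %d specific bases)\n",
              x$point, x$ci_low, x$ci_high, x$n_bases_used))
  invisible(x)
}

#' Whole-plasmid amplification uniformity diagnostic
#'
#' Distinguishes amplification of the entire plasmid (every part of the
#' backbone elevated in concert, as expected when copy number of the whole
#' episome rises) from intra-plasmid structural events such as a tandem
#' duplication of one region. Each feature's normalized depth ratio is
#' computed over its plasmid-specific bases only; the verdict is
#' `"whole-plasmid"` iff the max/min feature ratio is at most
#' `fold_threshold` (default 2: a single extra tandem copy of any part
#' creates at least a 2-fold internal contrast).
#'
#' Features wholly inside shared sequence are reported with `NA` ratios and
#' excluded from the verdict. Without declared features, equal-width
#' quarters of the plasmid-specific set are used. A single usable feature
#' yields a vacuous `"whole-plasmid"` verdict with a warning.
#'
#' @inheritParams estimate_plasmid_cn
#' @param fold_threshold maximum internal fold contrast compatible with
#'   whole-plasmid amplification
#' @return a `uniformity_report`: per-feature table, `max_min_ratio`,
#'   `verdict`
#' @export
uniformity <- function(track, spec, genome_mean, fold_threshold = 2.0) {
  stopifnot(inherits(spec, "plasmid_spec"), genome_mean > 0)
  specific <- mask_complement(spec$shared, spec$name, spec$length)
  feats <- spec$features
  if (is.null(feats) || nrow(feats) == 0) {
    # quarters of the specific set, by cumulative specific-base count
    pos0 <- unlist(mapply(function(s, e) s:(e - 1L), specific$start,
                          specific$end, SIMPLIFY = FALSE))
    qs <- split(pos0, cut(seq_along(pos0), 4, labels = FALSE))
    feats <- data.frame(seqname = spec$name,
                        start = vapply(qs, min, numeric(1)),
                        end = vapply(qs, max, numeric(1)) + 1L,
                        name = paste0("quarter", 1:4),
                        stringsAsFactors = FALSE)
  }
  depth <- numeric(spec$length)
  sub <- track[track$seqname == spec$name, , drop = FALSE]
  if (nrow(sub) > 0) depth[sub$pos] <- sub$depth
  spec_flag <- logical(spec$length)
  for (i in seq_len(nrow(specific)))
    spec_flag[(specific$start[i] + 1L):specific$end[i]] <- TRUE
  ratio <- n_used <- numeric(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    sel <- (feats$start[i] + 1L):feats$end[i]
    sel <- sel[spec_flag[sel]]
    n_used[i] <- length(sel)
    ratio[i] <- if (length(sel) == 0) NA_real_ else mean(depth[sel]) / genome_mean
  }
  tab <- data.frame(feature = if ("name" %in% names(feats)) feats$name else
                      paste0("f", seq_len(nrow(feats))),
                    start = feats$start, end = feats$end,
                    n_specific_bases = n_used, ratio = ratio,
                    stringsAsFactors = FALSE)
  usable <- ratio[!is.na(ratio) & ratio > 0]
  if (length(usable) <= 1) {
    warning("fewer than two usable features; uniformity verdict is vacuous")
    mm <- 1
  } else {
    mm <- max(usable) / min(usable)
  }
  rep <- list(features = tab, max_min_ratio = mm,
              fold_threshold = fold_threshold,
              verdict = if (mm <= fold_threshold) "whole-plasmid" else "non-uniform")
  class(rep) <- "uniformity_report"
  rep
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat("plasmid uniformity:", x$verdict,
      sprintf("(max/min feature ratio %.2f, threshold %.2f)\n",
              x$max_min_ratio, x$fold_threshold))
  print(x$features, row.names = FALSE)
  invisible(x)
}
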