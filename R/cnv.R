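#' Call whole-chromosome disomy from normalized coverage
#'
#' A haploid chromosome present in two copies shows normalized coverage
#' near 2. The call uses the per-chromosome median (robust to focal
#' events): euploid if median < 1.25, disomic if median >= 1.75, ambiguous
#' in between. The band midpoints guard against the upward bias of the
#' genome mean when a disomic chromosome is itself included in it.
#'
#' @param profile normalized `binned_track` restricted to one sequence
#'   (or pass `sequence` to select one)
#' @param sequence optional sequence name to subset
#' @param euploid_max,disomic_min thresholds on the median (defaults
#'   1.25 / 1.75)
#' @param min_bins minimum bins required (default 20)
#' @return a `disomy_call`: `seqname`, `median`, `status`, thresholds used
#' @export
call_disomy <- function(profile, sequence = NULL, euploid_max = 1.25,
                        disomic_min = 1.75, min_bins = 20L) {
  df <- as.data.frame(profile)
  if (!is.null(sequence)) df <- df[df$seqname == sequence, , drop = FALSE]
  if (length(unique(df$seqname)) != 1)
    stop("profile must cover exactly one sequence (use `sequence=`)")
  if (nrow(df) < min_bins)
    stop("too few bins (", nrow(df), " < ", min_bins, ") on ", df$seqname[1])
  m <- stats::median(df$depth)
  status <- if (m < euploid_max) "euploid" else
    if (m >= disomic_min) "disomic" else "ambiguous"
  structure(list(seqname = df$seqname[1], median = m, status = status,
                 euploid_max = euploid_max, disomic_min = disomic_min,
                 n_bins = nrow(df)),
            class = "disomy_call")
}

#' @export
print.disomy_call <- function(x, ...) {
  cat(sprintf("%s: %s (median normalized coverage %.3f, thresholds %.2f/%.2f)\n",
              x$seqname, x$status, x$median, x$euploid_max, x$disomic_min))
  invisible(x)
}

# best split of y into [1,k] | (k, n]: two-sample t statistic, pooled variance
.best_split <- function(y, min_bins) {
  n <- length(y)
  if (n < 2 * min_bins) return(NULL)
  cs <- cumsum(y); css <- cumsum(y * y)
  k <- seq.int(min_bins, n - min_bins)
  nl <- k; nr <- n - k
  ml <- cs[k] / nl; mr <- (cs[n] - cs[k]) / nr
  ssl <- css[k] - cs[k]^2 / nl
  ssr <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / nr
  # cumulative sums leave ~1e-12 residue on constant stretches; clamp so a
  # clean step registers as zero pooled variance
  tol <- css[n] * 1e-10
  ssl[ssl < tol] <- 0
  ssr[ssr < tol] <- 0
  s2 <- (ssl + ssr) / pmax(n - 2L, 1L)
  se <- sqrt(s2 * (1 / nl + 1 / nr))
  tt <- (ml - mr) / se
  # a clean step in noiseless data has pooled variance 0: infinitely strong
  tt[se == 0 & ml != mr] <- Inf
  tt[!is.finite(tt) & !is.infinite(tt)] <- 0
  i <- which.max(abs(tt))
  list(k = k[i], t = abs(tt[i]), dlog2 = abs(ml[i] - mr[i]))
}

# permutation p-value of the max-|t| split statistic; stops early once the
# exceedance count guarantees p >= alpha (the accept/reject decision is
# identical to the full test, the returned p is then only a lower bound on
# the permutations actually run)
.perm_split_p <- function(y, t_obs, min_bins, n_perm, alpha = 1) {
  ge <- 0L
  ge_stop <- ceiling(alpha * (1 + n_perm))
  for (b in seq_len(n_perm)) {
    st <- .best_split(sample(y), min_bins)
    if (!is.null(st) && st$t >= t_obs) {
      ge <- ge + 1L
      if (ge >= ge_stop) return((1 + ge) / (1 + b))
    }
  }
  (1 + ge) / (1 + n_perm)
}

# Boundary refinement. The global max-t split locates a boundary noisily;
# given the two flanking segments, re-place the cut at the argmax of the
# cumulative log-likelihood ratio between the two segment models. Depth is
# negative-binomial-like, and with a common dispersion the per-bin NB LLR
# is LINEAR in the counts, so heavy-tailed outlier bins cannot yank the
# cut the way a Gaussian LLR does. `scale` converts normalized values back
# to approximate counts; dispersion is moment-estimated from the segments
# (Poisson limit when no overdispersion is visible, incl. noiseless data).
.refine_boundaries <- function(x, starts, ends, scale = 1, min_bins = 5L) {
  if (length(starts) < 2) return(list(starts = starts, ends = ends))
  for (i in seq_len(length(starts) - 1L)) {
    lo <- starts[i]; hi <- ends[i + 1L]
    cl <- x[starts[i]:ends[i]] * scale
    cr <- x[starts[i + 1L]:ends[i + 1L]] * scale
    mu_l <- mean(cl); mu_r <- mean(cr)
    if (mu_l == mu_r || mu_l <= 0 || mu_r <= 0) next
    phi_inv <- function(v, mu, n) if (n >= 2) max(0, (v - mu) / mu^2) else 0
    nl <- length(cl); nr <- length(cr)
    pin <- (nl * phi_inv(stats::var(cl), mu_l, nl) +
            nr * phi_inv(stats::var(cr), mu_r, nr)) / (nl + nr)
    w <- x[lo:hi] * scale
    if (pin > 0) {
      size <- 1 / pin
      llr <- size * log((size + mu_r) / (size + mu_l)) +
        w * (log(mu_l / (size + mu_l)) - log(mu_r / (size + mu_r)))
    } else {
      llr <- w * log(mu_l / mu_r) - (mu_l - mu_r)  # Poisson limit
    }
    cum <- cumsum(llr)
    # never create segments shorter than the split stage could have made
    lo_k <- min(min_bins, nl)
    hi_k <- length(w) - min(min_bins, nr)
    if (hi_k < lo_k) next
    k <- (lo_k:hi_k)[which.max(cum[lo_k:hi_k])]
    if (k < length(w)) {
      cut <- lo + k - 1L
      ends[i] <- cut
      starts[i + 1L] <- cut + 1L
    }
  }
  list(starts = starts, ends = ends)
}

#' Segment a normalized coverage profile
#'
#' Recursive binary segmentation on `log2(normalized coverage + eps)`.
#' Each candidate split is the maximizing two-sample t statistic along the
#' chromosome, accepted when a seeded permutation test of the max-|t|
#' statistic (default 1,000 permutations) gives p < `alpha`, and recursed
#' on both sides. Adjacent final segments whose |delta log2| contrast
#' falls short of `min_abs_log2` are merged back (weakest boundary first),
#' as are any segments shorter than `min_bins` — so a split survives only
#' when the segments it separates differ by at least `min_abs_log2`.
#' The call set returned comprises gain segments only (mean copy factor >=
#' `min_factor`); symmetric losses (factor <= 1/`min_factor`) are detected
#' by the same logic but only *reported*, never interpreted, in the
#' `"losses"` attribute of the result.
#'
#' @param profile normalized `binned_track` for one sequence
#' @param sequence optional sequence name to subset
#' @param min_bins minimum segment length in bins (default 5)
#' @param min_abs_log2 minimum |delta log2| between flanking segments to
#'   accept a split (default 0.4)
#' @param n_perm permutations for the split test (default 1,000)
#' @param alpha permutation significance level (default 0.01)
#' @param min_factor copy factor for reporting a gain (default 1.5)
#' @param eps pseudo-count before log2, in normalized units; default
#'   1/30 (one read at 30x)
#' @param seed integer seed for the permutation test
#' @return data frame of gain segment calls: `seqname`, `start_bin`,
#'   `end_bin` (0-based, half-open, bin units), `start`, `end` (bp),
#'   `n_bins`, `mean_norm`, `copy_factor`, `direction`; zero rows when
#'   nothing is called; loss segments in `attr(, "losses")`. All-zero
#'   profiles return zero rows with a warning.
#' @export
segment <- function(profile, sequence = NULL, min_bins = 5L,
                    min_abs_log2 = 0.4, n_perm = 1000L, alpha = 0.01,
                    min_factor = 1.5, eps = 1 / 30, seed = NULL) {
  df <- as.data.frame(profile)
  if (!is.null(sequence)) df <- df[df$seqname == sequence, , drop = FALSE]
  if (length(unique(df$seqname)) != 1)
    stop("profile must cover exactly one sequence (use `sequence=`)")
  if (is.unsorted(df$start, strictly = TRUE)) stop("bins must be strictly ordered")
  empty <- data.frame(seqname = character(), start_bin = integer(),
                      end_bin = integer(), start = integer(), end = integer(),
                      n_bins = integer(), mean_norm = numeric(),
                      copy_factor = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  if (all(df$depth == 0)) {
    warning("all-zero coverage on ", df$seqname[1], "; no segment calls")
    return(empty)
  }
  y <- log2(df$depth + eps)
  n <- length(y)
  .with_seed(seed, {
    breaks <- integer()
    recurse <- function(lo, hi) {
      st <- .best_split(y[lo:hi], min_bins)
      if (is.null(st)) return(invisible())
      p <- .perm_split_p(y[lo:hi], st$t, min_bins, n_perm, alpha)
      if (p >= alpha) return(invisible())
      cut <- lo + st$k - 1L   # last index of the left side
      breaks <<- c(breaks, cut)
      recurse(lo, cut)
      recurse(cut + 1L, hi)
    }
    recurse(1L, n)
    bks <- sort(unique(breaks))
    starts <- c(1L, bks + 1L)
    ends <- c(bks, n)
    # prune: merge adjacent segments whose log2 contrast is below
    # min_abs_log2, weakest pair first, then any sub-min_bins leftovers
    repeat {
      if (length(starts) <= 1) break
      mlog <- vapply(seq_along(starts),
                     function(i) mean(y[starts[i]:ends[i]]), numeric(1))
      gaps <- abs(diff(mlog))
      short <- which(ends - starts + 1L < min_bins)
      if (length(short) > 0) {
        i <- short[1]
        j <- if (i == 1) 1L else if (i == length(starts)) i - 1L else
          if (gaps[i - 1] < gaps[i]) i - 1L else i
      } else if (any(gaps < min_abs_log2)) {
        j <- which.min(gaps)
      } else break
      ends[j] <- ends[j + 1L]
      starts <- starts[-(j + 1L)]; ends <- ends[-(j + 1L)]
    }
    gm <- attr(profile, "genome_mean")
    rf <- .refine_boundaries(df$depth, starts, ends,
                             scale = if (is.null(gm) || is.na(gm)) 1 else gm,
                             min_bins = min_bins)
    starts <- rf$starts; ends <- rf$ends
    mean_norm <- vapply(seq_along(starts),
                        function(i) mean(df$depth[starts[i]:ends[i]]), numeric(1))
    keep_gain <- mean_norm >= min_factor
    keep_loss <- mean_norm <= 1 / min_factor
    as_calls <- function(keep, direction) {
      if (!any(keep)) {
        out <- empty
      } else {
        out <- data.frame(seqname = df$seqname[1],
                          start_bin = starts[keep] - 1L,
                          end_bin = ends[keep],
                          start = df$start[starts[keep]],
                          end = df$end[ends[keep]],
                          n_bins = ends[keep] - starts[keep] + 1L,
                          mean_norm = mean_norm[keep],
                          copy_factor = mean_norm[keep],
                          direction = direction,
                          stringsAsFactors = FALSE)
        rownames(out) <- NULL
      }
      out
    }
    gains <- as_calls(keep_gain, "gain")
    attr(gains, "losses") <- as_calls(keep_loss, "loss")
    gains
  })
}

#' Write segment calls as BED
#'
#' Name column carries direction and copy factor; score column the copy
#' factor scaled x100.
#' @param segments segment-call data frame from [segment()] or [call_cnv()]
#' @param path output path
#' @export
write_segments_bed <- function(segments, path) {
  df <- data.frame(segments$seqname, segments$start, segments$end,
                   sprintf("%s_cf%.2f", segments$direction,
                           segments$copy_factor),
                   as.integer(round(segments$copy_factor * 100)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Compare duplication boundaries between two segment calls
#'
#' Two calls agree when both start and end differ by at most `tol_bins`
#' bins. Calls on different sequences return `FALSE` with a warning.
#'
#' @param a,b single-row segment-call data frames (from [segment()])
#' @param tol_bins tolerance in bins (default 2)
#' @export
compare_boundaries <- function(a, b, tol_bins = 2L) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$seqname != b$seqname) {
    warning("segment calls are on different sequences")
    return(FALSE)
  }
  abs(a$start_bin - b$start_bin) <= tol_bins &&
    abs(a$end_bin - b$end_bin) <= tol_bins
}

#' Genome-wide CNV calling
#'
#' Runs [call_disomy()] on every chromosome with enough bins, then
#' [segment()] only on chromosomes not called disomic — a whole-chromosome
#' duplication is a disomy call, never a chromosome-spanning segment.
#'
#' @param profile normalized `binned_track` over the genome
#' @param exclude_sequences sequences to skip entirely (e.g., chrM,
#'   plasmids)
#' @param ... passed to [segment()]
#' @inheritParams call_disomy
#' @return list with `disomy` (data frame: `seqname`, `median`, `status`),
#'   `segments` (gain calls from non-disomic chromosomes) and `losses`
#'   (reported-only loss segments)
#' @export
call_cnv <- function(profile, exclude_sequences = character(),
                     euploid_max = 1.25, disomic_min = 1.75,
                     min_bins_disomy = 20L, ...) {
  seqs <- setdiff(unique(profile$seqname), exclude_sequences)
  dis <- list(); seg <- list(); los <- list()
  for (sq in seqs) {
    sub <- .new_binned(as.data.frame(profile[profile$seqname == sq, , drop = FALSE]),
                       bin_size = attr(profile, "bin_size"),
                       normalized = isTRUE(attr(profile, "normalized")),
                       genome_mean = attr(profile, "genome_mean"))
    if (nrow(sub) < min_bins_disomy) next
    d <- call_disomy(sub, euploid_max = euploid_max,
                     disomic_min = disomic_min, min_bins = min_bins_disomy)
    dis[[sq]] <- data.frame(seqname = sq, median = d$median,
                            status = d$status, stringsAsFactors = FALSE)
    if (d$status != "disomic") {
      s <- segment(sub, ...)
      l <- attr(s, "losses")
      if (nrow(s) > 0) seg[[sq]] <- s
      if (!is.null(l) && nrow(l) > 0) los[[sq]] <- l
    }
  }
  list(disomy = if (length(dis)) do.call(rbind, c(dis, make.row.names = FALSE))
       else NULL,
       segments = if (length(seg)) do.call(rbind, c(seg, make.row.names = FALSE))
       else NULL,
       losses = if (length(los)) do.call(rbind, c(los, make.row.names = FALSE))
       else NULL)
}
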