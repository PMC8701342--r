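#' Read a qPCR plate CSV
#'
#' Expected columns: `sample`, `target`, `role` (`target`/`reference`),
#' `replicate`, `ct`. Each `sample` row group is one biological replicate;
#' a separate design table maps samples to strain groups.
#' @param path CSV path
#' @export
read_qpcr_plate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "role", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("plate CSV must have columns ", paste(need, collapse = ", "))
  if (any(!df$role %in% c("target", "reference")))
    stop("role must be 'target' or 'reference'")
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  df
}

#' Write a qPCR plate CSV
#' @param plate plate data frame
#' @param path output path
#' @export
write_qpcr_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse technical replicates to a mean Ct
#'
#' Arithmetic mean of the replicate Ct values; the spread flag is raised
#' when max - min exceeds `max_spread` cycles (default 0.5), the usual
#' bench rule for a failed triplicate.
#'
#' @param ct numeric vector of replicate Ct values (>= 1 value)
#' @param max_spread flag threshold in cycles
#' @return list(`mean_ct`, `flagged`, `spread`)
#' @export
collapse_triplicates <- function(ct, max_spread = 0.5) {
  if (length(ct) < 1) stop("at least one Ct value required")
  spread <- if (length(ct) == 1) 0 else max(ct) - min(ct)
  list(mean_ct = mean(ct), flagged = spread > max_spread, spread = spread)
}

#' Relative quantity by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_reference` within each sample;
#' `ddCt = dCt_sample - dCt_calibrator`; `quantity = 2^-ddCt` (perfect
#' amplification efficiency). Adding a constant to every Ct leaves the
#' quantity unchanged, and `log2(quantity) = -ddCt` exactly.
#'
#' @param target_ct,reference_ct sample mean Ct for target and reference
#'   gene
#' @param calibrator_target_ct,calibrator_reference_ct same for the
#'   calibrator sample
#' @return list(`dct`, `ddct`, `quantity`)
#' @export
ddct <- function(target_ct, reference_ct, calibrator_target_ct,
                 calibrator_reference_ct) {
  stopifnot(is.finite(target_ct), is.finite(reference_ct),
            is.finite(calibrator_target_ct), is.finite(calibrator_reference_ct))
  dct <- target_ct - reference_ct
  ddct <- dct - (calibrator_target_ct - calibrator_reference_ct)
  list(dct = dct, ddct = ddct, quantity = 2^-ddct)
}

#' Quantify every sample on a plate against a calibrator
#'
#' Technical replicates are collapsed per sample and role; the calibrator
#' delta-Ct is the mean over the calibrator sample(s). The calibrator's
#' own quantity is 1 by construction (up to averaging when several
#' calibrator samples are given).
#'
#' @param plate plate data frame (see [read_qpcr_plate()])
#' @param calibrator sample id(s) serving as calibrator
#' @return data frame: `sample`, `dct`, `ddct`, `quantity`,
#'   `spread_flagged`
#' @export
quantify_plate <- function(plate, calibrator) {
  if (!all(calibrator %in% plate$sample))
    stop("calibrator sample(s) absent from plate")
  samples <- unique(plate$sample)
  per <- lapply(samples, function(s) {
    sub <- plate[plate$sample == s, ]
    tc <- collapse_triplicates(sub$ct[sub$role == "target"])
    rc <- collapse_triplicates(sub$ct[sub$role == "reference"])
    data.frame(sample = s, dct = tc$mean_ct - rc$mean_ct,
               spread_flagged = tc$flagged || rc$flagged,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  cal_dct <- mean(per$dct[per$sample %in% calibrator])
  per$ddct <- per$dct - cal_dct
  per$quantity <- 2^-per$ddct
  per[, c("sample", "dct", "ddct", "quantity", "spread_flagged")]
}

#' Rank-based comparison of two groups of quantities
#'
#' Two-sided Wilcoxon rank-sum test: exact distribution when both groups
#' have at most 10 values and no ties, otherwise the normal approximation
#' with tie and continuity correction. Biological replicates, not
#' technical replicates, are the exchangeable units here.
#'
#' @param a,b numeric vectors of relative quantities
#' @return two-sided p-value
#' @export
compare_groups <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (length(a) < 3 || length(b) < 3)
    warning("fewer than 3 values in a group; the rank test has little power")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- max(length(a), length(b)) <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  unname(res$p.value)
}

#' Multiplicity adjustment for a family of p-values
#'
#' Benjamini-Hochberg step-up by default (the "adjusted p-value < 0.05"
#' convention); Holm available for strict family-wise control.
#'
#' @param pvals numeric vector in \[0, 1\]
#' @param method `"BH"` or `"holm"`
#' @export
adjust <- function(pvals, method = c("BH", "holm")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}
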