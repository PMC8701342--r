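#' Concordance between WGS- and qPCR-derived copy-number estimates
#'
#' Pairs strains by id, computes the Pearson correlation and an ordinary
#' least-squares fit (qPCR on WGS), and reports per-strain residuals.
#' Strains missing from either map are listed, never imputed. OLS rather
#' than an errors-in-variables fit: both axes carry noise, but the
#' target statistic is the plain correlation/regression of the
#' validation scatterplot.
#'
#' @param wgs named numeric vector: strain -> WGS copy-number estimate
#' @param qpcr named numeric vector: strain -> qPCR relative quantity
#' @return a `concordance` list: `n`, `r`, `r2`, `slope`, `intercept`,
#'   `residuals` (named), `missing_wgs`, `missing_qpcr`
#' @export
concord <- function(wgs, qpcr) {
  if (is.null(names(wgs)) || is.null(names(qpcr)))
    stop("wgs and qpcr must be named by strain")
  common <- intersect(names(wgs), names(qpcr))
  if (length(common) < 3) stop("need at least 3 strains present in both maps")
  x <- unname(wgs[common]); y <- unname(qpcr[common])
  if (stats::var(x) == 0) stop("zero variance in wgs estimates")
  if (stats::var(y) == 0) stop("zero variance in qpcr estimates")
  r <- stats::cor(x, y)
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- structure(list(n = length(common), r = r, r2 = r * r,
                        slope = unname(fit$coefficients[2]),
                        intercept = unname(fit$coefficients[1]),
                        residuals = stats::setNames(fit$residuals, common),
                        missing_wgs = setdiff(names(qpcr), names(wgs)),
                        missing_qpcr = setdiff(names(wgs), names(qpcr))),
                   class = "concordance")
  res
}

#' Simulated WGS/qPCR concordance experiment
#'
#' The validation analog of plotting sequencing-derived plasmid copy number
#' against qPCR-derived relative quantity across strains. For each strain a
#' true plasmid copy number is drawn uniformly on `cn_range`; the WGS
#' estimate comes from a simulated euploid genome (for the genome mean) and
#' a simulated plasmid depth track at the stated noise; the qPCR estimate
#' from a simulated plate with `n_bio_reps` biological replicates per
#' strain, quantified by delta-delta-Ct against a copy-number-1 calibrator
#' strain. Pearson r-squared is computed over the strain pairs, once per
#' repetition.
#'
#' @param n_strains strains per repetition (default 20)
#' @param n_reps repetitions (default 50)
#' @param cn_range range of true copy numbers (default 1-12)
#' @param mean_depth,dispersion depth model (default 30x, NB size 10)
#' @param ct_noise_sd qPCR noise (default 0.1 cycles)
#' @param n_bio_reps biological replicates per strain (default 6)
#' @param seed integer seed for the whole experiment
#' @return numeric vector of r-squared values, one per repetition
#' @export
concordance_experiment <- function(n_strains = 20, n_reps = 50,
                                   cn_range = c(1, 12), mean_depth = 30,
                                   dispersion = 10, ct_noise_sd = 0.1,
                                   n_bio_reps = 6, seed = NULL) {
  lay <- yeast_layout()
  spec <- default_plasmid_spec()
  .with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      cn <- stats::runif(n_strains, cn_range[1], cn_range[2])
      names(cn) <- sprintf("strain%02d", seq_len(n_strains))
      wgs <- vapply(seq_along(cn), function(i) {
        g <- simulate_depth(lay, event_set(),
                            noise_model(mean_depth, dispersion))
        gm <- genome_mean_depth(g$track, exclude = lay$excluded)
        tr <- simulate_plasmid_depth(spec, cn[i], mean_depth,
                                     noise_model(mean_depth, dispersion))
        estimate_plasmid_cn(tr, spec, gm, n_boot = 2)$point
      }, numeric(1))
      qsamples <- stats::setNames(
        rep(c(1, cn), each = n_bio_reps),
        paste0(rep(c("cal", names(cn)), each = n_bio_reps), "_r",
               seq_len(n_bio_reps)))
      plate <- simulate_qpcr_plate(qsamples, ct_noise_sd = ct_noise_sd)$plate
      q <- quantify_plate(plate, calibrator = paste0("cal_r",
                                                     seq_len(n_bio_reps)))
      strain_of <- sub("_r[0-9]+$", "", q$sample)
      qpcr <- tapply(q$quantity, strain_of, mean)[names(cn)]
      concord(stats::setNames(wgs, names(cn)),
              stats::setNames(as.numeric(qpcr), names(cn)))$r2
    }, numeric(1))
  })
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance over %d strains: r^2 = %.3f (r = %.3f), fit qpcr = %.3f * wgs + %.3f\n",
              x$n, x$r2, x$r, x$slope, x$intercept))
  if (length(x$missing_wgs) || length(x$missing_qpcr))
    cat("unpaired strains:",
        paste(c(x$missing_wgs, x$missing_qpcr), collapse = ", "), "\n")
  invisible(x)
}
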