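#' Simulate binned genome coverage with planted copy-number events
#'
#' Each bin's depth is drawn from a negative binomial with mean
#' `mean_depth * ploidy factor`; factors multiply over overlapping events
#' (a duplicated segment on a disomic chromosome would sit at 4x). A bin's
#' factor is determined by its midpoint. In deterministic mode every bin
#' equals its expectation exactly, so noiseless recovery tests are exact.
#'
#' @param layout a [genome_layout()]
#' @param events an [event_set()]
#' @param noise a [noise_model()]
#' @param bin_size bin width, bp (default 1,000); must not exceed the
#'   shortest sequence
#' @return list with `track` (a `binned_track` over all sequences) and
#'   `truth` (the planted events plus simulation parameters)
#' @export
simulate_depth <- function(layout, events = event_set(), noise = noise_model(),
                           bin_size = 1000L) {
  stopifnot(inherits(layout, "genome_layout"), inherits(events, "event_set"),
            inherits(noise, "noise_model"))
  if (any(layout$sequences$length < 1)) stop("zero-length sequence in layout")
  if (bin_size > min(layout$sequences$length))
    stop("bin_size exceeds the shortest sequence")
  segs <- events$segments
  if (nrow(segs) > 0) {
    len <- stats::setNames(layout$sequences$length, layout$sequences$name)
    if (!all(segs$seqname %in% names(len)))
      stop("segment events name unknown sequences")
    if (any(segs$end > len[segs$seqname]) || any(segs$start < 0))
      stop("segment events outside sequence bounds")
  }
  .with_seed(noise$seed, {
    pieces <- lapply(seq_len(nrow(layout$sequences)), function(i) {
      sq <- layout$sequences$name[i]
      len <- layout$sequences$length[i]
      nb <- ceiling(len / bin_size)
      starts <- (seq_len(nb) - 1L) * bin_size
      ends <- pmin(starts + bin_size, len)
      mid <- (starts + ends) / 2
      fac <- rep(1, nb)
      if (sq %in% events$disomies) fac <- fac * 2
      if (nrow(segs) > 0) {
        for (j in which(segs$seqname == sq)) {
          hit <- mid >= segs$start[j] & mid < segs$end[j]
          fac[hit] <- fac[hit] * segs$factor[j]
        }
      }
      mu <- noise$mean_depth * fac
      dep <- if (noise$deterministic) mu else
        stats::rnbinom(nb, size = noise$dispersion, mu = mu)
      data.frame(seqname = sq, start = starts, end = ends,
                 width = ends - starts, depth = as.numeric(dep),
                 stringsAsFactors = FALSE)
    })
    track <- .new_binned(do.call(rbind, pieces), bin_size = as.integer(bin_size))
    truth <- list(plasmid_cn = events$plasmid_cn,
                  disomies = events$disomies,
                  segments = events$segments,
                  mean_depth = noise$mean_depth,
                  dispersion = noise$dispersion,
                  deterministic = noise$deterministic,
                  bin_size = as.integer(bin_size),
                  seed = noise$seed)
    list(track = track, truth = truth)
  })
}

#' Simulate per-base plasmid coverage
#'
#' Expected depth is `genome_mean * plasmid_cn` on plasmid-specific bases
#' and `genome_mean * (plasmid_cn + 1)` on bases shared with the genome:
#' the single genomic locus contributes its own reads on top of every
#' plasmid copy. Noise is drawn per bin (default 50 bp — roughly the scale
#' at which short-read depth decorrelates) and expanded per base.
#'
#' @param spec a [plasmid_spec()]
#' @param plasmid_cn copies per haploid genome (>= 0; fractional values
#'   represent population averages)
#' @param genome_mean haploid genome mean depth
#' @param noise a [noise_model()] (its `mean_depth` is ignored; dispersion,
#'   seed and deterministic switch apply)
#' @param bin_size noise bin width, bp
#' @return a [depth_track()] over the plasmid, with the bin size recorded in
#'   attribute `bin_size`
#' @export
simulate_plasmid_depth <- function(spec, plasmid_cn, genome_mean,
                                   noise = noise_model(), bin_size = 50L) {
  stopifnot(inherits(spec, "plasmid_spec"))
  if (plasmid_cn < 0) stop("plasmid_cn must be non-negative")
  stopifnot(genome_mean > 0)
  len <- spec$length
  pos <- seq_len(len)
  shared <- in_mask(spec$shared, rep(spec$name, len), pos)
  e_base <- genome_mean * (plasmid_cn + as.numeric(shared))
  bin <- (pos - 1L) %/% as.integer(bin_size)
  counts <- as.vector(rowsum(rep(1, len), bin))  # rowsum sorts bins ascending
  mu_bin <- as.vector(rowsum(e_base, bin)) / counts
  dep_bin <- .with_seed(noise$seed, {
    if (noise$deterministic) mu_bin else
      stats::rnbinom(length(mu_bin), size = noise$dispersion, mu = mu_bin)
  })
  tr <- depth_track(rep(spec$name, len), pos, dep_bin[bin + 1L])
  attr(tr, "bin_size") <- as.integer(bin_size)
  tr
}

#' Simulate per-sample small-variant call sets
#'
#' Plants three classes of calls with recorded truth: recurrent
#' heterozygous artifacts confined to plasmid/genome shared sequence
#' (mapping ambiguity mimics), sample-private homozygous true variants
#' outside the shared mask, and introduced alleles present in designated
#' samples only.
#'
#' @param n_samples number of strains
#' @param shared_mask [region_mask()] of shared plasmid/genome sequence
#' @param artifact_rate probability a given sample carries each artifact site
#' @param unique_rate expected number (Poisson) of private true variants
#'   per sample
#' @param introduced optional data frame (`seqname`, `pos`, `ref`, `alt`,
#'   `samples` — comma-separated sample ids) of engineered alleles
#' @param n_artifact_sites number of recurrent artifact sites
#' @param layout a [genome_layout()] providing coordinates for private
#'   variants
#' @param seed integer seed
#' @return list with `calls` (data frame: `sample`, `seqname`, `pos`, `ref`,
#'   `alt`, `zygosity`) and `truth` (artifact/private/introduced keys)
#' @export
simulate_variant_calls <- function(n_samples, shared_mask, artifact_rate = 0.9,
                                   unique_rate = 2, introduced = NULL,
                                   n_artifact_sites = 3,
                                   layout = yeast_layout(), seed = NULL) {
  if (artifact_rate < 0 || artifact_rate > 1 || unique_rate < 0)
    stop("rates must lie in [0, 1] (artifact) and be non-negative (unique)")
  if (n_artifact_sites > 0 && artifact_rate > 0 && mask_width(shared_mask) == 0)
    stop("artifact_rate > 0 requires a non-empty shared mask")
  samples <- sprintf("S%02d", seq_len(n_samples))
  bases <- c("A", "C", "G", "T")
  .with_seed(seed, {
    rows <- list()
    # recurrent heterozygous artifacts inside the shared mask
    art <- NULL
    if (n_artifact_sites > 0 && artifact_rate > 0) {
      widths <- shared_mask$end - shared_mask$start
      iv <- sample.int(nrow(shared_mask), n_artifact_sites, replace = TRUE,
                       prob = widths)
      offs <- vapply(iv, function(i) sample.int(widths[i], 1), integer(1))
      pos <- shared_mask$start[iv] + offs  # 1-based position inside interval
      ref <- sample(bases, n_artifact_sites, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      art <- data.frame(seqname = shared_mask$seqname[iv], pos = pos,
                        ref = ref, alt = alt, stringsAsFactors = FALSE)
      art <- unique(art)
      for (k in seq_len(nrow(art))) {
        carriers <- samples[stats::runif(n_samples) < artifact_rate]
        if (length(carriers) > 0)
          rows[[length(rows) + 1]] <- data.frame(
            sample = carriers, seqname = art$seqname[k], pos = art$pos[k],
            ref = art$ref[k], alt = art$alt[k], zygosity = "het",
            stringsAsFactors = FALSE)
      }
    }
    # sample-private homozygous variants outside the mask
    lens <- stats::setNames(layout$sequences$length, layout$sequences$name)
    priv <- list()
    for (s in samples) {
      n_priv <- stats::rpois(1, unique_rate)
      made <- 0
      while (made < n_priv) {
        sq <- sample(names(lens), 1, prob = lens)
        p <- sample.int(lens[[sq]], 1)
        if (in_mask(shared_mask, sq, p)) next
        r <- sample(bases, 1); a <- sample(setdiff(bases, r), 1)
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, seqname = sq, pos = p, ref = r, alt = a,
          zygosity = "hom", stringsAsFactors = FALSE)
        priv[[length(priv) + 1]] <- data.frame(sample = s, seqname = sq,
                                               pos = p, ref = r, alt = a,
                                               stringsAsFactors = FALSE)
        made <- made + 1
      }
    }
    # introduced alleles in designated samples (homozygous: single locus)
    if (!is.null(introduced) && nrow(introduced) > 0) {
      for (k in seq_len(nrow(introduced))) {
        carriers <- intersect(strsplit(introduced$samples[k], ",")[[1]], samples)
        if (length(carriers) > 0)
          rows[[length(rows) + 1]] <- data.frame(
            sample = carriers, seqname = introduced$seqname[k],
            pos = introduced$pos[k], ref = introduced$ref[k],
            alt = introduced$alt[k], zygosity = "hom",
            stringsAsFactors = FALSE)
      }
    }
    calls <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(sample = character(), seqname = character(), pos = integer(),
                 ref = character(), alt = character(), zygosity = character(),
                 stringsAsFactors = FALSE)
    calls <- calls[order(calls$sample, calls$seqname, calls$pos), , drop = FALSE]
    rownames(calls) <- NULL
    list(calls = calls,
         truth = list(samples = samples,
                      artifacts = art,
                      private = if (length(priv)) do.call(rbind, priv) else NULL,
                      introduced = introduced))
  })
}

#' Simulate a qPCR plate with known relative quantities
#'
#' Perfect-efficiency model: each cycle doubles the product, so the target
#' quantitation cycle is `reference_ct - log2(quantity)` plus Gaussian
#' noise; the reference gene sits at `reference_ct`. Technical replicates
#' are independent. An efficiency parameter is accepted (doubling factor
#' `1 + efficiency` per cycle) but defaults to 1.
#'
#' @param quantities named numeric vector: true relative quantity per sample
#'   (one sample = one biological replicate); all > 0
#' @param reference_ct baseline quantitation cycle (default 20)
#' @param ct_noise_sd Gaussian Ct noise, cycles
#' @param n_triplicates technical replicates per well group (default 3)
#' @param target,reference_gene gene labels written to the plate
#' @param efficiency amplification efficiency (1 = perfect doubling)
#' @param seed integer seed
#' @return list with `plate` (data frame: `sample`, `target`, `role`,
#'   `replicate`, `ct`) and `truth` (the quantity map)
#' @export
simulate_qpcr_plate <- function(quantities, reference_ct = 20,
                                ct_noise_sd = 0.1, n_triplicates = 3,
                                target = "bla", reference_gene = "ACT1",
                                efficiency = 1, seed = NULL) {
  if (any(quantities <= 0)) stop("true quantities must be positive")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be non-negative")
  if (is.null(names(quantities)))
    names(quantities) <- sprintf("S%02d", seq_along(quantities))
  base <- log(2) / log(1 + efficiency)  # cycles per doubling
  .with_seed(seed, {
    rows <- lapply(names(quantities), function(s) {
      tct <- reference_ct - base * log2(quantities[[s]]) +
        stats::rnorm(n_triplicates, 0, ct_noise_sd)
      rct <- reference_ct + stats::rnorm(n_triplicates, 0, ct_noise_sd)
      data.frame(sample = s,
                 target = c(rep(target, n_triplicates),
                            rep(reference_gene, n_triplicates)),
                 role = rep(c("target", "reference"), each = n_triplicates),
                 replicate = rep(seq_len(n_triplicates), 2),
                 ct = c(tct, rct), stringsAsFactors = FALSE)
    })
    list(plate = do.call(rbind, rows), truth = quantities)
  })
}

#' Serialize / restore a simulation truth record
#' @param truth truth list from a simulator
#' @param path JSON path
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
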