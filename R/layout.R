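#' Genome layout for simulation and masking
#'
#' Declares the sequences of a (haploid) reference genome and any intervals
#' excluded from the genome-mean computation (typically the mitochondrial
#' contig, whose copy number is unrelated to nuclear ploidy).
#'
#' @param sequences data frame with columns `name`, `length` (bp)
#' @param excluded a [region_mask()] of intervals omitted from the genome mean
#' @export
genome_layout <- function(sequences, excluded = region_mask()) {
  stopifnot(is.data.frame(sequences), all(c("name", "length") %in% names(sequences)))
  if (anyDuplicated(sequences$name)) stop("sequence names must be unique")
  if (any(sequences$length < 1)) stop("sequence lengths must be >= 1")
  if (nrow(excluded) > 0) {
    len <- stats::setNames(sequences$length, sequences$name)
    if (!all(excluded$seqname %in% sequences$name))
      stop("excluded intervals name unknown sequences")
    if (any(excluded$end > len[excluded$seqname]))
      stop("excluded intervals extend beyond sequence bounds")
  }
  structure(list(sequences = data.frame(name = as.character(sequences$name),
                                        length = as.integer(sequences$length),
                                        stringsAsFactors = FALSE),
                 excluded = excluded),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$sequences), "sequences,",
      format(sum(as.numeric(x$sequences$length)), big.mark = ","), "bp total;",
      nrow(x$excluded), "excluded interval(s)\n")
  invisible(x)
}

#' Default haploid yeast-like genome layout
#'
#' Sixteen nuclear chromosomes with approximate S. cerevisiae lengths plus a
#' mitochondrial contig that is excluded from the genome-mean computation.
#' @export
yeast_layout <- function() {
  chr <- data.frame(
    name = c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrVI", "chrVII",
             "chrVIII", "chrIX", "chrX", "chrXI", "chrXII", "chrXIII",
             "chrXIV", "chrXV", "chrXVI", "chrM"),
    length = c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
               1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
               924431L, 784333L, 1091291L, 948066L, 85779L),
    stringsAsFactors = FALSE)
  genome_layout(chr, excluded = region_mask("chrM", 0L, 85779L))
}

#' Planted copy-number events for simulation
#'
#' @param plasmid_cn plasmid copies per haploid genome (non-negative real)
#' @param disomies character vector of chromosome names at ploidy 2
#' @param segments data frame (`seqname`, `start`, `end`, `factor`) of local
#'   duplications, 0-based half-open bp coordinates; factors multiply over
#'   overlapping events
#' @export
event_set <- function(plasmid_cn = 0, disomies = character(),
                      segments = NULL) {
  if (plasmid_cn < 0) stop("plasmid_cn must be non-negative")
  if (is.null(segments))
    segments <- data.frame(seqname = character(), start = integer(),
                           end = integer(), factor = numeric(),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("seqname", "start", "end", "factor") %in% names(segments)))
  if (nrow(segments) > 0 && any(segments$factor <= 0))
    stop("segment factors must be > 0")
  structure(list(plasmid_cn = plasmid_cn,
                 disomies = as.character(disomies),
                 segments = segments),
            class = "event_set")
}

#' Per-bin depth noise model
#'
#' Bin depths are drawn from a negative binomial with mean
#' `mean_depth * ploidy factor` and size (dispersion) parameter `dispersion`,
#' so Var = mu + mu^2/dispersion. With `deterministic = TRUE` noise is
#' disabled and every bin equals its expectation exactly — the switch used by
#' exact tests.
#'
#' @param mean_depth haploid mean coverage (default 30x)
#' @param dispersion negative-binomial size parameter
#' @param seed integer seed; `NULL` uses the current RNG stream
#' @param deterministic disable noise entirely?
#' @export
noise_model <- function(mean_depth = 30, dispersion = 10, seed = NULL,
                        deterministic = FALSE) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 seed = seed, deterministic = isTRUE(deterministic)),
            class = "noise_model")
}

#' Plasmid geometry: length, shared sequence, features
#'
#' `shared` marks plasmid coordinates whose sequence is also present in the
#' genome (marker gene, CEN/ARS, the cloned insert); reads from those bases
#' accumulate depth from both the genomic locus and every plasmid copy.
#' The plasmid-specific set — the complement of `shared` — is what the
#' copy-number estimator averages over.
#'
#' @param name plasmid sequence name
#' @param length plasmid length, bp
#' @param shared a [region_mask()] in plasmid coordinates
#' @param features optional named intervals (data frame with `start`,
#'   `end`, `name`; 0-based half-open) used by the uniformity diagnostic.
#'   Unlike a [region_mask()], adjacent features are kept distinct.
#' @export
plasmid_spec <- function(name, length, shared = region_mask(),
                         features = NULL) {
  stopifnot(length >= 1)
  if (nrow(shared) > 0) {
    if (!all(shared$seqname == name)) stop("shared intervals must be on the plasmid")
    if (any(shared$end > length)) stop("shared intervals exceed plasmid length")
    if (mask_width(shared) >= length)
      stop("plasmid-specific set is empty: shared mask covers the whole plasmid")
  }
  structure(list(name = name, length = as.integer(length), shared = shared,
                 features = features),
            class = "plasmid_spec")
}

#' Default centromeric-plasmid geometry
#'
#' An 8.5-kb pRS315-like shuttle vector carrying a 2.5-kb insert. Shared
#' sequence: the selection marker, the CEN/ARS cassette and the insert gene
#' (all have genomic homologs). Plasmid-specific sequence: bacterial
#' backbone (bla, ori, polylinker), 3,800 bp in total.
#' @export
default_plasmid_spec <- function() {
  nm <- "plasmid"
  shared <- region_mask(rep(nm, 3),
                        start = c(1500L, 3500L, 6000L),
                        end   = c(3100L, 4100L, 8500L),
                        name  = c("LEU2", "CEN-ARS", "insert"))
  features <- data.frame(seqname = nm,
                         start = c(0L, 1500L, 3100L, 3500L, 4100L, 6000L),
                         end   = c(1500L, 3100L, 3500L, 4100L, 6000L, 8500L),
                         name  = c("bla", "LEU2", "polylinker", "CEN-ARS",
                                   "ori", "insert"),
                         stringsAsFactors = FALSE)
  plasmid_spec(nm, 8500L, shared = shared, features = features)
}

# evaluate expr with a local, restorable RNG state; seed NULL = current stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
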