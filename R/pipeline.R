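#' Run a full simulation from a key-value config file
#'
#' The config is a DCF-style `key: value` file. Recognized keys (all
#' optional): `seed`, `mean_depth` (default 30), `dispersion` (10),
#' `bin_size` (1000), `deterministic` (`yes`/`no`), `plasmid_cn` (0),
#' `plasmid_bin_size` (50), `disomies` (comma-separated chromosome names),
#' `segments` (comma-separated `chr:start-endxFactor`, 0-based half-open).
#' The genome is the built-in yeast-like layout; the plasmid the built-in
#' centromeric spec.
#'
#' Outputs in `out_dir`: `genome.bedgraph` (binned genome coverage),
#' `plasmid.depth.tsv` (per-base plasmid coverage), `shared.bed` (shared
#' plasmid/genome mask) and `truth.json`.
#'
#' @param config_path path to the key-value config
#' @param out_dir output directory (created if needed)
#' @return invisible list with the simulated objects and truth
#' @export
simulate_from_config <- function(config_path, out_dir) {
  raw <- read.dcf(config_path)
  get <- function(key, default) {
    if (key %in% colnames(raw)) raw[1, key] else default
  }
  num <- function(key, default) as.numeric(get(key, default))
  seed <- get("seed", NA)
  seed <- if (is.na(seed)) NULL else as.integer(seed)
  noise <- noise_model(mean_depth = num("mean_depth", 30),
                       dispersion = num("dispersion", 10),
                       seed = seed,
                       deterministic = tolower(get("deterministic", "no")) %in%
                         c("yes", "true", "1"))
  disomies <- get("disomies", "")
  disomies <- if (nzchar(disomies)) trimws(strsplit(disomies, ",")[[1]]) else character()
  segs <- get("segments", "")
  seg_df <- NULL
  if (nzchar(segs)) {
    parts <- trimws(strsplit(segs, ",")[[1]])
    m <- regmatches(parts, regexec("^([^:]+):([0-9]+)-([0-9]+)x([0-9.]+)$", parts))
    if (any(lengths(m) != 5)) stop("cannot parse segments spec: ", segs)
    seg_df <- data.frame(seqname = vapply(m, `[[`, "", 2),
                         start = as.integer(vapply(m, `[[`, "", 3)),
                         end = as.integer(vapply(m, `[[`, "", 4)),
                         factor = as.numeric(vapply(m, `[[`, "", 5)),
                         stringsAsFactors = FALSE)
  }
  events <- event_set(plasmid_cn = num("plasmid_cn", 0), disomies = disomies,
                      segments = seg_df)
  layout <- yeast_layout()
  spec <- default_plasmid_spec()
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_depth(layout, events, noise,
                        bin_size = as.integer(num("bin_size", 1000)))
  write_depth(sim$track, file.path(out_dir, "genome.bedgraph"), "bedgraph")
  if (events$plasmid_cn > 0) {
    pl_noise <- noise_model(noise$mean_depth, noise$dispersion,
                            seed = if (is.null(seed)) NULL else seed + 1L,
                            deterministic = noise$deterministic)
    pl <- simulate_plasmid_depth(spec, events$plasmid_cn, noise$mean_depth,
                                 pl_noise,
                                 bin_size = as.integer(num("plasmid_bin_size", 50)))
    write_depth(pl, file.path(out_dir, "plasmid.depth.tsv"), "depth-tsv")
  } else pl <- NULL
  write_bed_mask(spec$shared, file.path(out_dir, "shared.bed"))
  write_truth(sim$truth, file.path(out_dir, "truth.json"))
  invisible(list(track = sim$track, plasmid = pl, truth = sim$truth,
                 layout = layout, plasmid_spec = spec))
}

#' Write per-strain copy-number results as CSV
#'
#' @param results data frame with at least `strain`, `cn`, `ci_low`,
#'   `ci_high` (extra columns such as `allele`, `selection_route`,
#'   `verdict` pass through)
#' @param path output path
#' @export
write_cn_table <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
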