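# Shared fixtures: everything is built in code, nothing is read from disk.

# a small genome for fast unit tests (acceptance tests use yeast_layout())
tiny_layout <- function() {
  genome_layout(data.frame(name = c("chrA", "chrB", "chrC"),
                           length = c(100000L, 60000L, 40000L)))
}

# 1-kb plasmid with a 400-bp shared block in the middle
tiny_plasmid <- function() {
  plasmid_spec("plas", 1000L,
               shared = region_mask("plas", 300L, 700L),
               features = data.frame(seqname = "plas",
                                     start = c(0L, 700L),
                                     end = c(300L, 1000L),
                                     name = c("left", "right"),
                                     stringsAsFactors = FALSE))
}

# constant-depth per-base track over one sequence
flat_track <- function(seqname, length, depth) {
  depth_track(rep(seqname, length), seq_len(length), rep(depth, length))
}

# write lines to a temp file, return path
write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# normalized binned track straight from a vector of per-bin values
profile_from_values <- function(values, seqname = "chrT", bin_size = 1000L,
                                genome_mean = 30) {
  n <- length(values)
  tr <- structure(
    data.frame(seqname = seqname,
               start = (seq_len(n) - 1L) * bin_size,
               end = seq_len(n) * bin_size,
               width = bin_size, depth = values,
               stringsAsFactors = FALSE),
    bin_size = bin_size, normalized = TRUE, genome_mean = genome_mean,
    class = c("binned_track", "data.frame"))
  tr
}
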