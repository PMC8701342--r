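#' Depth tracks and binned tracks
#'
#' A `depth_track` holds per-base depth as (`seqname`, `pos`, `depth`) with
#' 1-based positions, the dialect of `samtools depth`. Positions absent from
#' a track are depth 0. A `binned_track` holds fixed-width bins in 0-based
#' half-open coordinates (a trailing partial bin keeps its true width) with
#' the mean depth per bin.
#'
#' @name coverage-tracks
NULL

#' Construct a per-base depth track
#' @param seqname,pos,depth parallel vectors; `pos` 1-based, strictly
#'   increasing within each sequence; `depth >= 0`
#' @export
depth_track <- function(seqname, pos, depth) {
  df <- data.frame(seqname = as.character(seqname), pos = as.integer(pos),
                   depth = as.numeric(depth), stringsAsFactors = FALSE)
  if (any(df$depth < 0)) stop("depth must be non-negative")
  if (any(df$pos < 1)) stop("positions are 1-based and must be >= 1")
  for (sq in unique(df$seqname)) {
    p <- df$pos[df$seqname == sq]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within sequence ", sq)
  }
  class(df) <- c("depth_track", "data.frame")
  df
}

.new_binned <- function(df, bin_size, normalized = FALSE, genome_mean = NA_real_) {
  structure(df, bin_size = bin_size, normalized = normalized,
            genome_mean = genome_mean,
            class = c("binned_track", "data.frame"))
}

#' Read a depth file
#'
#' Supports the `samtools depth` TSV dialect (sequence, 1-based position,
#' depth) and bedGraph (sequence, 0-based start, end, value; expanded
#' per base). `#`-prefixed headers, `track` lines and CRLF endings are
#' tolerated. Malformed rows raise an error naming the line number.
#'
#' @param path input file
#' @param format `"auto"` (by extension/shape), `"depth-tsv"` or `"bedgraph"`
#' @return a [depth_track()]; empty file gives an empty track with a warning
#' @export
read_depth <- function(path, format = c("auto", "depth-tsv", "bedgraph")) {
  format <- match.arg(format)
  ln <- .read_clean_lines(path)
  keep <- !grepl("^(#|track|browser)", ln) & nzchar(ln)
  lineno <- which(keep)
  ln <- ln[keep]
  if (length(ln) == 0) {
    warning("no depth records in ", path)
    return(depth_track(character(), integer(), numeric()))
  }
  parts <- strsplit(ln, "\t")
  nf <- lengths(parts)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bdg|bg)$", path, ignore.case = TRUE) ||
                  all(nf == 4)) "bedgraph" else "depth-tsv"
  }
  want <- if (format == "bedgraph") 4L else 3L
  if (any(nf != want))
    stop("malformed row at line ", lineno[which(nf != want)[1]],
         ": expected ", want, " fields")
  sq <- vapply(parts, `[[`, "", 1)
  num <- function(k) suppressWarnings(as.numeric(vapply(parts, `[[`, "", k)))
  if (format == "depth-tsv") {
    pos <- num(2); dep <- num(3)
    bad <- is.na(pos) | is.na(dep)
    if (any(bad)) stop("non-numeric field at line ", lineno[which(bad)[1]])
    if (any(dep < 0)) stop("negative depth at line ", lineno[which(dep < 0)[1]])
    for (s in unique(sq)) {
      p <- pos[sq == s]
      if (is.unsorted(p, strictly = TRUE)) {
        i <- which(sq == s)[which(diff(p) <= 0)[1] + 1L]
        stop("non-monotone position at line ", lineno[i], " (sequence ", s, ")")
      }
    }
    return(depth_track(sq, pos, dep))
  }
  st <- num(2); en <- num(3); dep <- num(4)
  bad <- is.na(st) | is.na(en) | is.na(dep)
  if (any(bad)) stop("non-numeric field at line ", lineno[which(bad)[1]])
  if (any(en <= st)) stop("empty interval at line ", lineno[which(en <= st)[1]])
  if (any(dep < 0)) stop("negative depth at line ", lineno[which(dep < 0)[1]])
  w <- as.integer(en - st)
  depth_track(rep(sq, w),
              unlist(mapply(function(s, e) (s + 1L):e, as.integer(st),
                            as.integer(en), SIMPLIFY = FALSE)),
              rep(dep, w))
}

#' Write a depth or binned track
#'
#' Binned tracks written as depth-TSV are emitted at bin midpoints;
#' written as bedGraph they keep exact bin intervals (lossless at bin
#' resolution).
#' @param x a [depth_track()] or binned track
#' @param path output file
#' @param format `"depth-tsv"` or `"bedgraph"`
#' @export
write_depth <- function(x, path, format = c("depth-tsv", "bedgraph")) {
  format <- match.arg(format)
  if (inherits(x, "binned_track")) {
    if (format == "bedgraph") {
      df <- data.frame(x$seqname, x$start, x$end, x$depth)
    } else {
      mid <- x$start + pmax(1L, (x$end - x$start) %/% 2L)  # 1-based midpoint
      df <- data.frame(x$seqname, mid, x$depth)
    }
  } else {
    if (format == "bedgraph") {
      df <- data.frame(x$seqname, x$pos - 1L, x$pos, x$depth)
    } else {
      df <- data.frame(x$seqname, x$pos, x$depth)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Bin a per-base track into fixed-width bins
#'
#' Bin mean = sum of depths over the bin / bin width; positions absent from
#' the track count as depth 0. The trailing bin may be partial and carries
#' its true width.
#'
#' @param track a [depth_track()] (one or several sequences)
#' @param bin_size bin width in bp (>= 1)
#' @param sequence_lengths named vector of sequence lengths; defaults to the
#'   maximum observed position per sequence
#' @return a `binned_track` data frame (`seqname`, `start`, `end`, `width`,
#'   `depth`)
#' @export
bin_track <- function(track, bin_size, sequence_lengths = NULL) {
  stopifnot(bin_size >= 1)
  bin_size <- as.integer(bin_size)
  seqs <- unique(track$seqname)
  if (is.null(sequence_lengths)) {
    sequence_lengths <- vapply(seqs, function(s) max(track$pos[track$seqname == s]),
                               numeric(1))
  }
  out <- lapply(seqs, function(sq) {
    len <- sequence_lengths[[sq]]
    if (is.null(len) || is.na(len)) stop("no length given for sequence ", sq)
    sub <- track[track$seqname == sq, ]
    if (nrow(sub) > 0 && max(sub$pos) > len)
      stop("sequence_length ", len, " smaller than max observed position on ", sq)
    nb <- ceiling(len / bin_size)
    starts <- (seq_len(nb) - 1L) * bin_size
    ends <- pmin(starts + bin_size, as.integer(len))
    idx <- (sub$pos - 1L) %/% bin_size + 1L
    sums <- numeric(nb)
    if (nrow(sub) > 0) {
      agg <- rowsum(sub$depth, idx)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    data.frame(seqname = sq, start = starts, end = ends,
               width = ends - starts, depth = sums / (ends - starts),
               stringsAsFactors = FALSE)
  })
  .new_binned(do.call(rbind, out), bin_size = bin_size)
}

#' Genome-wide mean depth
#'
#' Width-weighted mean of bin means across genomic sequences, after removing
#' excluded intervals (partial overlaps reduce a bin's weight
#' proportionally). Plasmid sequences must be named so they never
#' contribute. Disomic chromosomes are not excluded: this mirrors the naive
#' genome-wide mean that anchors the copy-number ratio, and the resulting
#' upward bias (fraction of genome that is disomic) is documented rather
#' than corrected.
#'
#' @param binned a `binned_track` covering the genome
#' @param exclude optional [region_mask()] removed before averaging
#' @param plasmid_sequences sequence names dropped entirely (plasmids)
#' @export
genome_mean_depth <- function(binned, exclude = NULL,
                              plasmid_sequences = character()) {
  df <- binned[!(binned$seqname %in% plasmid_sequences), , drop = FALSE]
  if (nrow(df) == 0) stop("no genomic bins available")
  w <- as.numeric(df$width)
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (sq in unique(exclude$seqname)) {
      rows <- df$seqname == sq
      if (!any(rows)) next
      m <- exclude[exclude$seqname == sq, ]
      ov <- .overlap_widths(df$start[rows], df$end[rows], m$start, m$end)
      w[rows] <- w[rows] - ov
    }
  }
  if (sum(w) <= 0) stop("all bins are masked; genome mean undefined")
  sum(df$depth * w) / sum(w)
}

#' Normalize a binned track to the genome mean
#'
#' Divides every bin mean by `genome_mean`, so euploid expectation is 1.0
#' and a disomic chromosome sits near 2.0.
#' @param binned a `binned_track`
#' @param genome_mean positive scalar, from [genome_mean_depth()]
#' @export
normalize_track <- function(binned, genome_mean) {
  stopifnot(genome_mean > 0)
  out <- binned
  out$depth <- binned$depth / genome_mean
  .new_binned(as.data.frame(out), bin_size = attr(binned, "bin_size"),
              normalized = TRUE, genome_mean = genome_mean)
}
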