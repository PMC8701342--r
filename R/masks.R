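#' Region masks (0-based, half-open intervals)
#'
#' A `region_mask` is a set of genomic intervals in 0-based half-open
#' coordinates, stored merged and sorted. Masks mark sequence shared between
#' plasmid and genome, regions excluded from the genome mean, or annotation
#' such as plasmid backbone elements.
#'
#' @param seqname character vector of sequence names
#' @param start,end integer vectors; `0 <= start < end`
#' @param name optional interval labels (kept through merging only when
#'   intervals do not merge)
#' @return a `region_mask` data frame with columns `seqname`, `start`, `end`
#'   and optionally `name`
#' @examples
#' region_mask("chrI", c(10, 5), c(20, 12))  # merged to [5, 20)
#' @export
region_mask <- function(seqname = character(), start = integer(),
                        end = integer(), name = NULL) {
  if (length(seqname) == 0) {
    m <- data.frame(seqname = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
    class(m) <- c("region_mask", "data.frame")
    return(m)
  }
  stopifnot(length(seqname) == length(start), length(start) == length(end))
  if (any(start < 0)) stop("mask start must be >= 0")
  if (any(end <= start)) stop("mask intervals must satisfy end > start")
  df <- data.frame(seqname = as.character(seqname),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  df <- df[order(df$seqname, df$start, df$end), , drop = FALSE]
  out <- do.call(rbind, lapply(split(df, df$seqname), .merge_intervals))
  rownames(out) <- NULL
  class(out) <- c("region_mask", "data.frame")
  out
}

# merge overlapping/adjacent intervals within one sequence (already sorted)
.merge_intervals <- function(df) {
  if (nrow(df) <= 1) return(df)
  keep_name <- "name" %in% names(df)
  s <- df$start; e <- df$end
  os <- s[1]; oe <- e[1]; starts <- integer(); ends <- integer()
  nms <- character(); cur_nm <- if (keep_name) df$name[1] else NA_character_
  for (i in seq_len(nrow(df))[-1]) {
    if (s[i] <= oe) {
      oe <- max(oe, e[i])
      if (keep_name && !identical(df$name[i], cur_nm)) cur_nm <- NA_character_
    } else {
      starts <- c(starts, os); ends <- c(ends, oe); nms <- c(nms, cur_nm)
      os <- s[i]; oe <- e[i]
      cur_nm <- if (keep_name) df$name[i] else NA_character_
    }
  }
  starts <- c(starts, os); ends <- c(ends, oe); nms <- c(nms, cur_nm)
  out <- data.frame(seqname = df$seqname[1], start = starts, end = ends,
                    stringsAsFactors = FALSE)
  if (keep_name) out$name <- nms
  out
}

#' Total width of a mask, optionally per sequence
#' @param mask a [region_mask()]
#' @param by_sequence return a named vector per sequence?
#' @export
mask_width <- function(mask, by_sequence = FALSE) {
  w <- mask$end - mask$start
  if (!by_sequence) return(sum(w))
  tapply(w, mask$seqname, sum)
}

#' Test 1-based positions for mask membership
#'
#' @param mask a [region_mask()]
#' @param seqname,pos vectors of sequence names and 1-based positions
#' @return logical vector, `TRUE` where `pos` falls inside the mask
#' @export
in_mask <- function(mask, seqname, pos) {
  if (nrow(mask) == 0) return(rep(FALSE, length(pos)))
  p0 <- pos - 1L  # to 0-based
  out <- logical(length(pos))
  for (sq in unique(seqname)) {
    rows <- mask$seqname == sq
    if (!any(rows)) next
    idx <- which(seqname == sq)
    for (i in which(rows)) {
      out[idx] <- out[idx] | (p0[idx] >= mask$start[i] & p0[idx] < mask$end[i])
    }
  }
  out
}

#' Complement of a mask within [0, length) on one sequence
#' @param mask a [region_mask()] restricted to `seqname`
#' @param seqname sequence name
#' @param length sequence length in bp
#' @export
mask_complement <- function(mask, seqname, length) {
  m <- mask[mask$seqname == seqname, , drop = FALSE]
  if (nrow(m) == 0)
    return(region_mask(seqname, 0L, as.integer(length)))
  if (any(m$end > length)) stop("mask extends beyond sequence length")
  bounds <- c(0L, as.vector(rbind(m$start, m$end)), as.integer(length))
  s <- bounds[seq(1, length(bounds), by = 2)]
  e <- bounds[seq(2, length(bounds), by = 2)]
  keep <- e > s
  if (!any(keep)) stop("mask covers the entire sequence; complement is empty")
  region_mask(rep(seqname, sum(keep)), s[keep], e[keep])
}

# widths of overlap between [bs,be) bins and mask intervals on one sequence
.overlap_widths <- function(bs, be, mstart, mend) {
  ov <- numeric(length(bs))
  for (i in seq_along(mstart)) {
    ov <- ov + pmax(0, pmin(be, mend[i]) - pmax(bs, mstart[i]))
  }
  pmin(ov, be - bs)  # merged masks never overlap, but guard anyway
}

#' Read a BED file as a region mask
#'
#' Tolerates LF/CRLF line endings, `#`-prefixed headers and `track` lines.
#' Column 4 (name), when present, is kept.
#' @param path BED file path
#' @export
read_bed_mask <- function(path) {
  ln <- .read_clean_lines(path)
  ln <- ln[!grepl("^(#|track|browser)", ln) & nzchar(ln)]
  if (length(ln) == 0) return(region_mask())
  parts <- strsplit(ln, "\t")
  nf <- lengths(parts)
  if (any(nf < 3)) stop("malformed BED row at line ", which(nf < 3)[1])
  sq <- vapply(parts, `[[`, "", 1)
  st <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2)))
  en <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3)))
  if (anyNA(st) || anyNA(en))
    stop("non-numeric BED coordinates at line ", which(is.na(st) | is.na(en))[1])
  nm <- if (all(nf >= 4)) vapply(parts, `[[`, "", 4) else NULL
  region_mask(sq, st, en, name = nm)
}

#' Write a region mask as BED
#' @param mask a [region_mask()]
#' @param path output path
#' @export
write_bed_mask <- function(mask, path) {
  cols <- c("seqname", "start", "end")
  if ("name" %in% names(mask)) cols <- c(cols, "name")
  utils::write.table(mask[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# shared line reader: strips CRLF
.read_clean_lines <- function(path) {
  ln <- readLines(path, warn = FALSE)
  sub("\r$", "", ln)
}
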