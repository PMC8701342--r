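#' Minimal VCF 4.2 output for simulated call sets
#'
#' One single-sample VCF per strain (the shape produced by per-sample
#' calling upstream). Zygosity maps to GT: hom -> `1/1`, het -> `0/1`;
#' multiple alt alleles at one site are written as one multi-allelic row.
#'
#' @param calls data frame (`sample`, `seqname`, `pos`, `ref`, `alt`,
#'   `zygosity`)
#' @param dir output directory; files are named `<sample>.vcf`
#' @return invisible character vector of file paths
#' @export
write_vcf <- function(calls, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (s in unique(calls$sample)) {
    sub <- calls[calls$sample == s, , drop = FALSE]
    sub <- sub[order(sub$seqname, sub$pos), , drop = FALSE]
    key <- paste(sub$seqname, sub$pos, sub$ref)
    rows <- vapply(unique(key), function(k) {
      g <- sub[key == k, , drop = FALSE]
      alts <- g$alt
      gt <- if (nrow(g) == 1) {
        if (g$zygosity[1] == "hom") "1/1" else "0/1"
      } else "1/2"  # two het alts at one site
      paste(g$seqname[1], g$pos[1], ".", g$ref[1],
            paste(alts, collapse = ","), ".", "PASS", ".", "GT", gt,
            sep = "\t")
    }, "")
    path <- file.path(dir, paste0(s, ".vcf"))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", s, sep = "\t"),
                 rows), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# left-align-free parsimony trim: drop shared suffix, then shared prefix
.trim_allele <- function(pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read small-variant calls from a VCF
#'
#' Accepts VCF 4.x with a GT FORMAT field; one or several sample columns.
#' Multi-allelic sites are decomposed into one record per sample-allele,
#' and indel keys are parsimony-trimmed so the same event keys identically
#' across samples. Genotypes containing two identical non-reference alleles
#' (`1/1`, `1|1`, haploid `1`) are `hom`; any mixed genotype is `het`.
#' Records without GT are skipped with a warning.
#'
#' @param path VCF file
#' @return data frame of variant records (`sample`, `seqname`, `pos`,
#'   `ref`, `alt`, `zygosity`)
#' @export
read_calls <- function(path) {
  ln <- .read_clean_lines(path)
  hdr <- grep("^#CHROM\t", ln)
  if (length(hdr) != 1) stop("no #CHROM header line in ", path)
  cols <- strsplit(ln[hdr], "\t")[[1]]
  if (length(cols) < 10) stop("VCF has no sample columns")
  samples <- cols[10:length(cols)]
  body <- ln[-seq_len(hdr)]
  body <- body[nzchar(body) & !grepl("^#", body)]
  out <- list()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    if (length(f) < 10) stop("malformed VCF row at line ", hdr + i)
    fmt <- strsplit(f[9], ":")[[1]]
    gti <- match("GT", fmt)
    if (is.na(gti)) {
      warning("record without GT at line ", hdr + i, "; skipped")
      next
    }
    alts <- strsplit(f[5], ",")[[1]]
    pos <- as.integer(f[2]); ref <- f[4]
    for (sj in seq_along(samples)) {
      gt <- strsplit(strsplit(f[9 + sj], ":")[[1]][gti], "[/|]")[[1]]
      gt <- gt[gt != "."]
      if (length(gt) == 0) next
      gt <- as.integer(gt)
      for (a in unique(gt[gt > 0])) {
        zyg <- if (length(gt) > 1 && all(gt == a)) "hom" else
          if (length(gt) == 1) "hom" else "het"
        tr <- .trim_allele(pos, ref, alts[a])
        out[[length(out) + 1]] <- data.frame(
          sample = samples[sj], seqname = f[1], pos = tr$pos,
          ref = tr$ref, alt = tr$alt, zygosity = zyg,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), seqname = character(),
                      pos = integer(), ref = character(), alt = character(),
                      zygosity = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate variant calls across samples into a recurrence report
#'
#' Counts carrier samples per variant key (`seqname:pos:ref>alt`) and
#' attaches flags: `shared_region_het_artifact` for heterozygous calls
#' inside the plasmid/genome shared mask (haploid strains should not emit
#' het calls; inside shared homology they are mapping artifacts),
#' `introduced_allele` for keys matching the engineered-substitution
#' table, `backbone_region` for keys inside an optional backbone
#' annotation mask. Aggregation is independent of sample order.
#'
#' @param calls variant records (one data frame with a `sample` column, or
#'   a list of per-sample frames which are row-bound)
#' @param shared_mask [region_mask()] of plasmid/genome shared sequence
#' @param introduced optional data frame (`seqname`, `pos`, `ref`, `alt`)
#'   of engineered alleles
#' @param backbone_mask optional [region_mask()] of plasmid backbone
#'   annotation (origins, polylinker)
#' @return `recurrence_report` data frame: key columns, `count`,
#'   `carriers` (comma-separated), flag columns
#' @export
aggregate_calls <- function(calls, shared_mask = region_mask(),
                            introduced = NULL, backbone_mask = NULL) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- do.call(rbind, calls)
  if (anyDuplicated(unique(calls[c("sample", "seqname", "pos", "ref", "alt")])) > 0)
    stop("duplicate sample-variant records")
  if (nrow(calls) == 0) {
    rep <- data.frame(seqname = character(), pos = integer(), ref = character(),
                      alt = character(), count = integer(), carriers = character(),
                      shared_region_het_artifact = logical(),
                      introduced_allele = logical(), backbone_region = logical(),
                      stringsAsFactors = FALSE)
    class(rep) <- c("recurrence_report", "data.frame")
    return(rep)
  }
  key <- paste(calls$seqname, calls$pos, calls$ref, calls$alt, sep = "\r")
  ord <- order(key, calls$sample)
  calls <- calls[ord, , drop = FALSE]; key <- key[ord]
  grp <- split(seq_len(nrow(calls)), key)
  rows <- lapply(grp, function(ix) {
    g <- calls[ix, , drop = FALSE]
    data.frame(seqname = g$seqname[1], pos = g$pos[1], ref = g$ref[1],
               alt = g$alt[1], count = length(unique(g$sample)),
               carriers = paste(sort(unique(g$sample)), collapse = ","),
               any_het = any(g$zygosity == "het"),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, c(rows, make.row.names = FALSE))
  rep <- rep[order(rep$seqname, rep$pos, rep$ref, rep$alt), , drop = FALSE]
  rep$shared_region_het_artifact <-
    rep$any_het & in_mask(shared_mask, rep$seqname, rep$pos)
  rep$introduced_allele <- FALSE
  if (!is.null(introduced) && nrow(introduced) > 0) {
    k <- paste(rep$seqname, rep$pos, rep$ref, rep$alt)
    ki <- paste(introduced$seqname, introduced$pos, introduced$ref, introduced$alt)
    rep$introduced_allele <- k %in% ki
  }
  rep$backbone_region <- if (!is.null(backbone_mask))
    in_mask(backbone_mask, rep$seqname, rep$pos) else FALSE
  rep$any_het <- NULL
  rownames(rep) <- NULL
  class(rep) <- c("recurrence_report", "data.frame")
  rep
}

#' Recurrent variants from a recurrence report
#'
#' A variant is recurrent when seen in at least `min_count` samples
#' (default 3 — i.e., "more than two"). Flagged keys (artifacts,
#' introduced alleles, backbone annotation) are excluded unless
#' `include_flagged`.
#'
#' @param report a [aggregate_calls()] result
#' @param min_count minimum carrier count (>= 1)
#' @param include_flagged keep flagged keys?
#' @return data frame of recurrent keys (subset of the report rows)
#' @export
recurrent <- function(report, min_count = 3L, include_flagged = FALSE) {
  stopifnot(min_count >= 1)
  keep <- report$count >= min_count
  if (!include_flagged) {
    flagged <- report$shared_region_het_artifact | report$introduced_allele |
      report$backbone_region
    keep <- keep & !flagged
  }
  out <- report[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a recurrence report as TSV
#' @param report a [aggregate_calls()] result
#' @param path output path
#' @export
write_recurrence_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
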