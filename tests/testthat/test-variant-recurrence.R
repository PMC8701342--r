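make_vcf <- function(rows, sample = "s1") {
  write_tmp(c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", sample, sep = "\t"),
              rows), ".vcf")
}

test_that("VCF records parse, decompose and key consistently", {
  v <- make_vcf(c("chrI\t100\t.\tA\tT\t.\tPASS\t.\tGT\t1/1",
                  "chrII\t55\t.\tG\tA,C\t.\tPASS\t.\tGT\t1/2",
                  "chrIII\t7\t.\tC\tG\t.\tPASS\t.\tGT\t0/1",
                  "chrIV\t9\t.\tT\tA\t.\tPASS\t.\tGT\t1"))
  r <- read_calls(v)
  expect_equal(nrow(r), 5)  # multi-allelic row decomposed into two keys
  expect_equal(r$zygosity[r$seqname == "chrI"], "hom")
  expect_equal(sort(r$alt[r$seqname == "chrII"]), c("A", "C"))
  expect_equal(unique(r$zygosity[r$seqname == "chrII"]), "het")
  expect_equal(r$zygosity[r$seqname == "chrIII"], "het")  # het in a haploid
  expect_equal(r$zygosity[r$seqname == "chrIV"], "hom")   # haploid call
})

test_that("records without GT are skipped with a warning", {
  v <- make_vcf(c("chrI\t100\t.\tA\tT\t.\tPASS\t.\tDP\t12",
                  "chrI\t200\t.\tG\tC\t.\tPASS\t.\tGT\t1/1"))
  expect_warning(r <- read_calls(v), "without GT")
  expect_equal(nrow(r), 1)
})

test_that("indel keys are parsimony-trimmed for cross-sample identity", {
  # GATK-style padded deletion and an equivalent over-padded representation
  a <- read_calls(make_vcf("chrI\t100\t.\tATG\tA\t.\tPASS\t.\tGT\t1/1"))
  b <- read_calls(make_vcf("chrI\t99\t.\tCATGG\tCAG\t.\tPASS\t.\tGT\t1/1"))
  expect_equal(a[, c("seqname", "pos", "ref", "alt")],
               b[, c("seqname", "pos", "ref", "alt")])
})

test_that("write_vcf / read_calls round-trip simulated call sets", {
  mask <- region_mask("chrA", 1000L, 3000L)
  sv <- simulate_variant_calls(6, mask, artifact_rate = 0.8, unique_rate = 2,
                               n_artifact_sites = 2, layout = tiny_layout(),
                               seed = 21)
  dir <- file.path(tempdir(), "vcfs")
  paths <- write_vcf(sv$calls, dir)
  back <- do.call(rbind, lapply(list.files(dir, full.names = TRUE), read_calls))
  ord <- function(d) {
    d <- d[order(d$sample, d$seqname, d$pos, d$alt), ]
    rownames(d) <- NULL
    d
  }
  expect_equal(ord(back), ord(sv$calls))
})

test_that("aggregation counts carriers and attaches flags", {
  mask <- region_mask("plas", 100L, 500L)
  samples <- sprintf("S%02d", 1:10)
  art <- data.frame(sample = samples, seqname = "plas", pos = 200L,
                    ref = "A", alt = "G", zygosity = "het",
                    stringsAsFactors = FALSE)
  intro <- data.frame(sample = samples[1:8], seqname = "chrA", pos = 700L,
                      ref = "C", alt = "T", zygosity = "hom",
                      stringsAsFactors = FALSE)
  priv <- data.frame(sample = "S01", seqname = "chrB", pos = 42L,
                     ref = "G", alt = "A", zygosity = "hom",
                     stringsAsFactors = FALSE)
  rep <- aggregate_calls(rbind(art, intro, priv), shared_mask = mask,
                         introduced = data.frame(seqname = "chrA", pos = 700L,
                                                 ref = "C", alt = "T"))
  a_row <- rep[rep$pos == 200L, ]
  expect_equal(a_row$count, 10)
  expect_true(a_row$shared_region_het_artifact)
  i_row <- rep[rep$pos == 700L, ]
  expect_equal(i_row$count, 8)
  expect_true(i_row$introduced_allele)
  expect_false(i_row$shared_region_het_artifact)
  p_row <- rep[rep$pos == 42L, ]
  expect_equal(p_row$count, 1)
  expect_equal(p_row$carriers, "S01")
  # conservation: carrier counts sum to total records
  expect_equal(sum(rep$count), nrow(rbind(art, intro, priv)))
})

test_that("aggregation is independent of sample processing order", {
  mask <- region_mask("chrA", 1000L, 3000L)
  sv <- simulate_variant_calls(8, mask, artifact_rate = 0.7, unique_rate = 3,
                               n_artifact_sites = 2, layout = tiny_layout(),
                               seed = 33)
  fwd <- aggregate_calls(sv$calls, mask)
  shuf <- sv$calls[rev(seq_len(nrow(sv$calls))), ]
  expect_equal(as.data.frame(aggregate_calls(shuf, mask)), as.data.frame(fwd))
})

test_that("recurrent filter applies count threshold and flag exclusion", {
  rep <- aggregate_calls(data.frame(
    sample = c(sprintf("S%d", 1:5), sprintf("S%d", 1:3), "S1", "S2"),
    seqname = c(rep("plas", 5), rep("chrA", 3), "chrB", "chrB"),
    pos = c(rep(10L, 5), rep(20L, 3), 30L, 30L),
    ref = "A", alt = "T",
    zygosity = c(rep("het", 5), rep("hom", 5)),
    stringsAsFactors = FALSE), shared_mask = region_mask("plas", 0L, 100L))
  # counts: plas:10 = 5 (flagged), chrA:20 = 3 (clean), chrB:30 = 2 (clean)
  r <- recurrent(rep)
  expect_equal(r$seqname, "chrA")
  r2 <- recurrent(rep, include_flagged = TRUE)
  expect_equal(sort(r2$seqname), c("chrA", "plas"))
  expect_equal(nrow(recurrent(rep, min_count = 6, include_flagged = TRUE)), 0)
  # empty report -> empty result
  empty <- aggregate_calls(data.frame(sample = character(),
                                      seqname = character(), pos = integer(),
                                      ref = character(), alt = character(),
                                      zygosity = character()))
  expect_equal(nrow(recurrent(empty)), 0)
})

test_that("simulated screen recovers exactly the planted recurrent artifacts", {
  mask <- region_mask("plas", 1500L, 6000L)
  lay <- genome_layout(data.frame(name = c("chrA", "plas"),
                                  length = c(200000L, 8500L)))
  sv <- simulate_variant_calls(20, mask, artifact_rate = 0.9, unique_rate = 2,
                               n_artifact_sites = 3, layout = lay, seed = 77)
  rep <- aggregate_calls(sv$calls, mask)
  # unflagged recurrent set must be empty (artifacts all flagged, privates unique)
  expect_equal(nrow(recurrent(rep)), 0)
  # flagged recurrent keys are exactly the planted artifact sites with count > 2
  rec_all <- recurrent(rep, include_flagged = TRUE)
  truth_keys <- with(sv$truth$artifacts, paste(seqname, pos, ref, alt))
  expect_setequal(paste(rec_all$seqname, rec_all$pos, rec_all$ref, rec_all$alt),
                  truth_keys)
})
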