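test_that("deterministic mode reproduces expectations exactly", {
  lay <- tiny_layout()
  det <- noise_model(mean_depth = 30, deterministic = TRUE)
  sim <- simulate_depth(lay, event_set(), det, bin_size = 1000L)
  expect_true(all(sim$track$depth == 30))
  expect_equal(genome_mean_depth(sim$track), 30)

  ev <- event_set(disomies = "chrB",
                  segments = data.frame(seqname = "chrA", start = 20000L,
                                        end = 40000L, factor = 2))
  sim2 <- simulate_depth(lay, ev, det, bin_size = 1000L)
  tb <- sim2$track
  expect_true(all(tb$depth[tb$seqname == "chrB"] == 60))
  inseg <- tb$seqname == "chrA" & tb$start >= 20000 & tb$end <= 40000
  expect_true(all(tb$depth[inseg] == 60))
  expect_true(all(tb$depth[tb$seqname == "chrA" & !inseg] == 30))
  # overlapping disomy + segment multiply
  ev3 <- event_set(disomies = "chrA",
                   segments = data.frame(seqname = "chrA", start = 0L,
                                         end = 10000L, factor = 2))
  tb3 <- simulate_depth(lay, ev3, det, bin_size = 1000L)$track
  expect_true(all(tb3$depth[tb3$seqname == "chrA" & tb3$end <= 10000] == 120))
})

test_that("binned depth matches negative-binomial moments", {
  # one 10-Mb sequence -> 10,000 bins; oracle: mean mu, var mu + mu^2/size
  lay <- genome_layout(data.frame(name = "chr1", length = 1e7))
  sim <- simulate_depth(lay, event_set(), noise_model(30, 10, seed = 11))
  d <- sim$track$depth
  expect_length(d, 10000)
  expect_lt(abs(mean(d) - 30) / 30, 0.01)
  v_expect <- 30 + 30^2 / 10
  expect_lt(abs(var(d) - v_expect) / v_expect, 0.15)
})

test_that("identical seeds reproduce identical output", {
  lay <- tiny_layout()
  ev <- event_set(disomies = "chrB")
  a <- simulate_depth(lay, ev, noise_model(30, 10, seed = 5))
  b <- simulate_depth(lay, ev, noise_model(30, 10, seed = 5))
  expect_identical(a, b)
  spec <- tiny_plasmid()
  pa <- simulate_plasmid_depth(spec, 3, 30, noise_model(seed = 6))
  pb <- simulate_plasmid_depth(spec, 3, 30, noise_model(seed = 6))
  expect_identical(pa, pb)
  qa <- simulate_qpcr_plate(c(s1 = 2, s2 = 4), seed = 7)
  qb <- simulate_qpcr_plate(c(s1 = 2, s2 = 4), seed = 7)
  expect_identical(qa, qb)
})

test_that("plasmid depth follows the additive shared-sequence model", {
  spec <- tiny_plasmid()
  det <- noise_model(deterministic = TRUE)
  shared <- in_mask(spec$shared, rep("plas", 1000), 1:1000)

  t0 <- simulate_plasmid_depth(spec, 0, 40, det)
  expect_true(all(t0$depth[!shared] == 0))
  expect_true(all(t0$depth[shared] == 40))

  t1 <- simulate_plasmid_depth(spec, 1, 40, det)
  expect_true(all(t1$depth[!shared] == 40))
  expect_true(all(t1$depth[shared] == 80))

  t75 <- simulate_plasmid_depth(spec, 7.5, 40, det)
  expect_true(all(t75$depth[!shared] == 300))  # 40 x 7.5

  expect_error(simulate_plasmid_depth(spec, -1, 40, det), "non-negative")
})

test_that("truth record round-trips through JSON", {
  lay <- tiny_layout()
  ev <- event_set(plasmid_cn = 5.5, disomies = "chrB",
                  segments = data.frame(seqname = "chrA", start = 10000L,
                                        end = 30000L, factor = 2))
  sim <- simulate_depth(lay, ev, noise_model(30, 10, seed = 3))
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$plasmid_cn, 5.5)
  expect_equal(back$disomies, "chrB")
  expect_equal(as.data.frame(back$segments), sim$truth$segments)
})

test_that("simulated variant calls honor their construction rules", {
  mask <- region_mask(rep("chrA", 2), c(1000L, 5000L), c(2000L, 6000L))
  # nothing planted -> empty
  sv0 <- simulate_variant_calls(5, mask, artifact_rate = 0, unique_rate = 0,
                                n_artifact_sites = 0,
                                layout = tiny_layout(), seed = 1)
  expect_equal(nrow(sv0$calls), 0)
  # artifacts are het and inside the mask; private calls hom and outside
  sv <- simulate_variant_calls(12, mask, artifact_rate = 0.9, unique_rate = 2,
                               n_artifact_sites = 3,
                               layout = tiny_layout(), seed = 2)
  art <- sv$calls[sv$calls$zygosity == "het", ]
  expect_true(all(in_mask(mask, art$seqname, art$pos)))
  priv <- sv$calls[sv$calls$zygosity == "hom", ]
  expect_false(any(in_mask(mask, priv$seqname, priv$pos)))
  # introduced allele appears exactly in designated samples
  intro <- data.frame(seqname = "chrB", pos = 1234L, ref = "G", alt = "T",
                      samples = "S01,S02,S03,S04,S05",
                      stringsAsFactors = FALSE)
  svi <- simulate_variant_calls(10, mask, artifact_rate = 0, unique_rate = 0,
                                introduced = intro, n_artifact_sites = 0,
                                layout = tiny_layout(), seed = 3)
  expect_equal(sort(unique(svi$calls$sample)), sprintf("S%02d", 1:5))
  expect_true(all(svi$calls$pos == 1234L))
  # empty mask with artifacts requested is an error
  expect_error(simulate_variant_calls(5, region_mask(), artifact_rate = 0.5),
               "non-empty shared mask")
})

test_that("simulated qPCR plates encode quantities in Ct space", {
  p1 <- simulate_qpcr_plate(c(a = 1), ct_noise_sd = 0, seed = 1)$plate
  expect_equal(p1$ct[p1$role == "target"], rep(20, 3))
  expect_equal(p1$ct[p1$role == "reference"], rep(20, 3))
  p8 <- simulate_qpcr_plate(c(a = 8), ct_noise_sd = 0, seed = 1)$plate
  dct <- mean(p8$ct[p8$role == "target"]) - mean(p8$ct[p8$role == "reference"])
  expect_equal(dct, -3)  # log2(8)
  expect_error(simulate_qpcr_plate(c(a = 0)), "positive")
})

test_that("config-driven simulation writes the full artifact set", {
  cfg <- write_tmp(c("seed: 4", "mean_depth: 30", "plasmid_cn: 3",
                     "disomies: chrII",
                     "segments: chrIV:600000-700000x2"))
  out <- file.path(tempdir(), "simcfg")
  res <- simulate_from_config(cfg, out)
  expect_true(all(file.exists(file.path(out, c("genome.bedgraph",
                                               "plasmid.depth.tsv",
                                               "shared.bed", "truth.json")))))
  tr <- read_truth(file.path(out, "truth.json"))
  expect_equal(tr$plasmid_cn, 3)
  expect_equal(tr$disomies, "chrII")
  expect_equal(as.integer(tr$segments$start), 600000L)
})
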