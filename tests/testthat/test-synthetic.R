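test_that("random transcripts are seed-deterministic with the right composition", {
  t1 <- random_transcript(500, 0.5, seed = 99)
  t2 <- random_transcript(500, 0.5, seed = 99)
  expect_identical(t1$seq, t2$seq)
  expect_false(identical(t1$seq, random_transcript(500, 0.5, seed = 100)$seq))

  # observed GC within 3 binomial standard errors of the target
  big <- random_transcript(10000, 0.5, seed = 7)
  gc <- sum(strsplit(big$seq, "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 10000))
  skewed <- random_transcript(10000, 0.7, seed = 7)
  gc <- sum(strsplit(skewed$seq, "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gc - 0.7), 3 * sqrt(0.21 / 10000))

  expect_error(random_transcript(500, 1.0), "gc_fraction")
  expect_error(random_transcript(20, 0.5), ">= 50")
})

test_that("planted sites carry analytic ratios verified by the duplex scorer", {
  set.seed(61)
  for (i in 1:15) {
    m <- random_rna(22)
    tx <- random_transcript(800, 0.5, seed = 200 + i)
    nw <- sample(0:3, 1)
    res <- plant_site(tx, m, start = 300, n_wobbles = nw, seed = i,
                      mirna_id = "m")
    d <- duplex_energy(m, substr(res$tx$seq, 300, 321))
    expect_equal(res$truth$expected_ratio, d$ratio, tolerance = 1e-9)
    if (nw == 0) expect_identical(d$ratio, 100)
    # scanning finds the site at its truth start
    hits <- scan_sites("m", m, res$tx, threshold = res$truth$expected_ratio - 1e-6)
    expect_true(300 %in% hits$start)
  }
  # the worked single-wobble example: one G.C pair becomes G.U
  m <- "AUGC"
  tx <- random_transcript(100, 0.5, seed = 3)
  res <- plant_site(tx, m, start = 50, n_wobbles = 1, seed = 5)
  expect_true(res$truth$expected_ratio %in%
                (100 * (21.24 - c(4.25, 2.13)) / 21.24))
  # overlapping a planted feature is refused
  expect_error(plant_site(res$tx, m, start = 52), "placement error")
})

test_that("tandem planting writes consistent periodic runs or refuses", {
  tx <- random_transcript(600, 0.5, seed = 71)
  m <- strrep("UG", 9)  # reverse complement CACACA..., period 2
  res <- plant_tandem_sites(tx, m, start = 100, n = 14, spacing = 2,
                            mirna_id = "m4")
  expect_identical(nrow(res$truth), 14L)
  s <- scan_sites("m4", m, res$tx, threshold = 100)
  expect_identical(s$start, as.integer(seq(100, by = 2, length.out = 14)))
  cl <- cluster_sites(s)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_sites, 14L)
  expect_identical(unique(cl$spacings[[1]]), 2L)
  expect_identical(cl$span, 18L + 2L * 13L)  # 44 nt

  # spacing beyond the miRNA length gives disjoint singletons
  tx2 <- random_transcript(600, 0.5, seed = 73)
  res2 <- plant_tandem_sites(tx2, m, start = 100, n = 3, spacing = 25,
                             mirna_id = "m4")
  s2 <- scan_sites("m4", m, res2$tx, threshold = 100)
  expect_identical(nrow(cluster_sites(s2)), 3L)

  # non-periodic miRNA at overlapping spacing is a placement error
  expect_error(plant_tandem_sites(tx2, "AUGCAUGCAUGCAUGCAUGC", start = 300,
                                  n = 2, spacing = 1),
               "placement error")
})

test_that("planted GCC clusters are detected with their class and peptide", {
  tx <- random_transcript(2000, 0.5, seed = 79)
  # 5'UTR run of 6 units
  res <- plant_gcc_cluster(tx, 6, region = "5UTR", seed = 81)
  b <- res$truth$start
  run <- find_gcc_run(substr(res$tx$seq, 1, res$tx$utr5_end))
  expect_identical(run$start, b)  # leftmost maximal 5'UTR run is ours
  expect_identical(run$run_length, 18L)
  expect_identical(run$length_class, "18")
  expect_identical(res$truth$expected_class, "18")

  # CDS run, frame offset 2 encodes polyR
  res2 <- plant_gcc_cluster(res$tx, 7, region = "CDS", frame_offset = 2,
                            seed = 83)
  cds_start <- res2$tx$utr5_end + 1L
  expect_identical((res2$truth$start - cds_start) %% 3L, 2L)
  expect_identical(res2$truth$expected_peptide, "RRRRRRR")
  run2 <- find_gcc_run(substr(res2$tx$seq, cds_start, res2$tx$cds_end))
  expect_identical(run2$run_length, 21L)
  expect_identical(
    translate_repeat(run2, (cds_start + run2$start - 1L - cds_start) %% 3L),
    "RRRRRRR")

  # 9 units classify as 27plus
  res3 <- plant_gcc_cluster(res2$tx, 9, region = "CDS", frame_offset = 0,
                            seed = 85)
  expect_identical(res3$truth$expected_class, "27plus")

  # region too short is a placement error
  tiny <- random_transcript(200, 0.5, seed = 87, utr5_frac = 0.05)
  expect_error(plant_gcc_cluster(tiny, 16, region = "5UTR"),
               "placement error")
})

test_that("generated studies are reproducible and fully recoverable", {
  g1 <- generate_study(demo_config(42), out_dir = tempfile("study"))
  g2 <- generate_study(demo_config(42), out_dir = tempfile("study"))
  for (k in names(g1$paths))
    expect_identical(readLines(g1$paths[[k]]), readLines(g2$paths[[k]]))
  expect_false(identical(
    readLines(g1$paths[["transcripts"]]),
    readLines(generate_study(demo_config(43),
                             out_dir = tempfile("study"))$paths[["transcripts"]])))

  # the file triple is self-consistent
  txs <- read_transcripts(g1$paths[["transcripts"]], g1$paths[["annotation"]])
  expect_identical(length(txs), 20L)
  mir <- read_mirnas(g1$paths[["mirnas"]])
  expect_identical(nrow(mir), 5L)

  # every planted site is recovered at its start with its analytic ratio
  sites <- scan_all(mir, txs, threshold = 90)
  tr <- g1$truth[g1$truth$feature == "site", ]
  for (i in seq_len(nrow(tr))) {
    hit <- sites[sites$transcript_id == tr$transcript_id[i] &
                   sites$mirna_id == tr$mirna_id[i] &
                   sites$start == tr$start[i], ]
    expect_identical(nrow(hit), 1L)
    expect_equal(hit$ratio, tr$expected_ratio[i], tolerance = 1e-6)
    expect_identical(hit$region, tr$expected_region[i])
  }

  # empty configuration still yields valid, empty outputs
  g0 <- generate_study(simulation_config(seed = 1, n_transcripts = 0),
                       out_dir = tempfile("study"))
  expect_identical(nrow(g0$truth), 0L)
  expect_true(all(file.exists(g0$paths)))
})

test_that("pure background yields essentially no high-complementarity sites", {
  # false-positive control: random 20-mers against 50% GC background
  hits <- 0L
  windows <- 0L
  for (seed in 1:2) {
    m <- random_rna(20, seed = seed)
    for (j in 1:25) {
      tx <- random_transcript(2019, 0.5, seed = 1000 * seed + j,
                              id = paste0("bg", j))
      windows <- windows + tx$length - 20L + 1L
      hits <- hits + nrow(scan_sites("m", m, tx, threshold = 90))
    }
  }
  expect_gte(windows, 1e5)
  expect_lte(hits / (windows / 1e5), 1)  # at most 1 site per 1e5 windows
})
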