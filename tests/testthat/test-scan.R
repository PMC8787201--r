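test_that("scanning recovers a planted exact site with its window energetics", {
  tx <- transcript("t1", "AAAAGCAUAAAA")
  s <- scan_sites("m", "AUGC", tx, threshold = 90)
  expect_identical(nrow(s), 1L)
  expect_identical(s$start, 5L)
  expect_equal(s$dG, -21.24)
  expect_identical(s$ratio, 100)

  # one wobble drops the site below a 100% threshold but not below 85%
  tx2 <- transcript("t1", "AAAAGCGUAAAA")
  expect_identical(nrow(scan_sites("m", "AUGC", tx2, threshold = 100)), 0L)
  s2 <- scan_sites("m", "AUGC", tx2, threshold = 85)
  expect_identical(s2$start, 5L)
  expect_equal(s2$ratio, 100 * 19.11 / 21.24, tolerance = 1e-9)

  # with a vanishing threshold every bonded window is reported
  s3 <- scan_sites("m", "AUGC", tx, threshold = 1e-4)
  all9 <- oracle_scan("AUGC", tx$seq, 1e-4)
  expect_identical(s3$start, as.integer(all9$start))

  # miRNA longer than transcript: empty result with a warning, not an error
  expect_warning(s4 <- scan_sites("m", strrep("A", 50), tx), "longer")
  expect_identical(nrow(s4), 0L)

  expect_error(scan_sites("m", "AUGC", tx, threshold = 101), "threshold")
})

test_that("scan output equals the brute-force window oracle on random inputs", {
  set.seed(29)
  for (i in 1:40) {
    lm <- sample(18:24, 1)
    lt <- sample(c(50:300, 1800:2000), 1)
    m <- random_rna(lm)
    tx <- transcript(paste0("t", i), random_rna(lt))
    thr <- sample(c(30, 50, 70), 1)  # low thresholds so matches exist
    got <- scan_sites("m", m, tx, threshold = thr)
    want <- oracle_scan(m, tx$seq, thr)
    expect_identical(got$start, as.integer(want$start))
    expect_equal(got$dG, want$dG)
    expect_equal(got$ratio, want$ratio, tolerance = 1e-12)
  }
})

test_that("site starts shift by exactly d when the transcript is 5'-extended", {
  set.seed(31)
  m <- random_rna(20)
  body <- paste0(random_rna(200), rna_revcomp(m), random_rna(150))
  for (d in c(1L, 7L, 24L)) {
    s0 <- scan_sites("m", m, transcript("a", body), threshold = 50)
    s1 <- scan_sites("m", m, transcript("a", paste0(random_rna(d), body)),
                     threshold = 50)
    # windows fully inside the original body shift by exactly d; windows
    # touching the new prefix are new and excluded from the comparison
    expect_identical(s1$start[s1$start > d], s0$start + d)
  }
})

test_that("N-containing windows bond nothing and N-heavy windows are skipped", {
  m <- "AUGC"
  # a single N in the window scores 0 for that position
  tx <- transcript("t", "AAGCANAAAAAA")
  s <- scan_sites("m", m, tx, threshold = 1e-4)
  expect_true(all(s$ratio <= 100))
  # >10% N: a 4-mer window with one N is 25% N, so skipped entirely
  expect_false(any(vapply(s$start, function(p)
    grepl("N", substr(tx$seq, p, p + 3)), TRUE)))
})

test_that("scan_all concatenates deterministically whatever the input order", {
  set.seed(37)
  m1 <- random_rna(20); m2 <- random_rna(20)
  t1 <- paste0(random_rna(100), rna_revcomp(m1), random_rna(50),
               rna_revcomp(m2), random_rna(30))
  t2 <- paste0(random_rna(60), rna_revcomp(m2), random_rna(80),
               rna_revcomp(m1), random_rna(40))
  mirnas <- data.frame(id = c("mA", "mB"), seq = c(m1, m2))
  txs <- list(transcript("tx1", t1), transcript("tx2", t2))
  s <- scan_all(mirnas, txs, threshold = 100)
  expect_identical(nrow(s), 4L)  # one planted site per miRNA per transcript
  s_perm <- scan_all(mirnas[2:1, ], rev(txs), threshold = 100)
  expect_identical(s, s_perm)
  # empty miRNA set gives an empty, well-formed table
  empty <- scan_all(mirnas[0, ], txs)
  expect_identical(nrow(empty), 0L)
  expect_identical(names(empty), names(s))
})

test_that("overlap resolution keeps the site with the greater binding energy", {
  mk <- function(mirna_id, start, dG, len = 20)
    data.frame(mirna_id = mirna_id, transcript_id = "t", gene = "g",
               start = start, length = len, end = start + len, dG = dG,
               dGm = -130, ratio = 100 * dG / -130, region = "CDS")
  # pairwise: stronger site survives
  s <- rbind(mk("a", 100, -110), mk("b", 110, -115))
  expect_identical(resolve_overlaps(s)$mirna_id, "b")
  # disjoint sites both retained
  s <- rbind(mk("a", 100, -110), mk("b", 200, -115))
  expect_identical(nrow(resolve_overlaps(s)), 2L)
  # same-miRNA tandem overlaps never removed
  s <- rbind(mk("a", 100, -110), mk("a", 102, -115))
  expect_identical(nrow(resolve_overlaps(s)), 2L)
  # transitive chain: only the strongest of three mutual overlaps remains
  s <- rbind(mk("a", 100, -110), mk("b", 105, -115), mk("c", 110, -120))
  expect_identical(resolve_overlaps(s)$mirna_id, "c")
  # chain where ends do not overlap each other: a(-110) ~ b(-120) ~ c(-112);
  # iterative removal drops a then c
  s <- rbind(mk("a", 100, -110), mk("b", 115, -120), mk("c", 130, -112))
  expect_identical(resolve_overlaps(s)$mirna_id, "b")
  # tie on |dG|: 5'-most start wins
  s <- rbind(mk("a", 100, -115), mk("b", 105, -115))
  expect_identical(resolve_overlaps(s)$mirna_id, "a")
  # equal start and |dG|: lexicographically smallest miRNA id wins
  s <- rbind(mk("b", 100, -115), mk("a", 100, -115))
  expect_identical(resolve_overlaps(s)$mirna_id, "a")
})

test_that("overlap resolution is idempotent, order-invariant and matches
           an exhaustive iterative-removal oracle", {
  oracle_resolve <- function(s) {
    repeat {
      drop <- NULL
      # find the weakest site in any cross-miRNA overlap, by exhaustive search
      cand <- which(vapply(seq_len(nrow(s)), function(i)
        any(s$start[i] < s$end & s$start < s$end[i] &
              s$mirna_id != s$mirna_id[i]), TRUE))
      if (!length(cand)) return(s)
      o <- cand[order(abs(s$dG[cand]), -s$start[cand], -xtfrm(s$mirna_id[cand]))]
      s <- s[-o[1], ]
    }
  }
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    s <- data.frame(mirna_id = sample(c("a", "b", "c"), n, replace = TRUE),
                    transcript_id = "t", gene = "g",
                    start = sample(1:60, n), length = 20L)
    s$end <- s$start + s$length
    s$dG <- -sample(100:130, n)
    s$dGm <- -135; s$ratio <- 100 * s$dG / -135; s$region <- "CDS"
    r1 <- resolve_overlaps(s)
    expect_identical(resolve_overlaps(r1), r1)                     # idempotent
    perm <- sample(nrow(s))
    r2 <- resolve_overlaps(s[perm, ])
    expect_identical(r2[order(r2$start, r2$mirna_id), ],
                     `rownames<-`(r1[order(r1$start, r1$mirna_id), ], NULL),
                     ignore_attr = TRUE)                           # order-free
    want <- oracle_resolve(s)
    expect_setequal(paste(r1$mirna_id, r1$start),
                    paste(want$mirna_id, want$start))              # oracle
  }
})
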