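mkHit <- function(q, s, pid, qc, ev, bs, ec = "1.1.1.1") {
  data.frame(qseqid = q, sseqid = s, pident = pid, length = 300L,
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 300L,
             sstart = 1L, send = 300L, evalue = ev, bitscore = bs,
             sec = ec, qcovs = qc, query_coverage = qc,
             stringsAsFactors = FALSE)
}

test_that("best-hit filter applies strict thresholds and the bitscore rule", {
  hits <- rbind(
    mkHit("q1", "s1", 40.0, 95, 1e-30, 200),   # identity at boundary -> out
    mkHit("q1", "s2", 41.0, 80.0, 1e-30, 210), # coverage at boundary -> out
    mkHit("q1", "s3", 41.0, 81.0, 1e-15, 220), # evalue at boundary -> out
    mkHit("q2", "s4", 70, 90, 1e-30, 198.0),
    mkHit("q2", "s5", 70, 90, 1e-30, 210.5))
  best <- filterBestHits(hits)
  expect_false("q1" %in% best$qseqid)
  expect_identical(best$sseqid[best$qseqid == "q2"], "s5")
  # bitscore tie -> lower evalue -> lexicographic subject id
  tie <- rbind(mkHit("q3", "sB", 70, 90, 1e-30, 300),
               mkHit("q3", "sA", 70, 90, 1e-30, 300),
               mkHit("q3", "sC", 70, 90, 1e-40, 300))
  expect_identical(filterBestHits(tie)$sseqid, "sC")
})

test_that("best-hit filter equals an exhaustive per-query scan oracle", {
  set.seed(41)
  hits <- do.call(rbind, lapply(1:50, function(i)
    mkHit(sprintf("q%d", sample(1:8, 1)), sprintf("s%02d", i),
          runif(1, 20, 99), runif(1, 50, 100), 10^-runif(1, 5, 40),
          round(runif(1, 100, 400), 1))))
  best <- filterBestHits(hits)
  for (q in unique(hits$qseqid)) {
    sub <- hits[hits$qseqid == q & hits$pident > 40 &
                  hits$query_coverage > 80 & hits$evalue < 1e-15, ]
    if (nrow(sub) == 0L) {
      expect_false(q %in% best$qseqid, info = q)
    } else {
      sub <- sub[order(-sub$bitscore, sub$evalue, sub$sseqid), ]
      expect_identical(best$sseqid[best$qseqid == q], sub$sseqid[1], info = q)
    }
  }
  # monotonicity: tightening any threshold never adds a query
  for (tweak in list(c(50, 80, 1e-15), c(40, 90, 1e-15), c(40, 80, 1e-20))) {
    tighter <- filterBestHits(hits, tweak[1], tweak[2], tweak[3])
    expect_true(all(tighter$qseqid %in% best$qseqid))
  }
})

test_that("enzyme DB indexes EC -> proteins -> genomes -> taxonomy", {
  best <- rbind(mkHit("p1", "r1", 70, 90, 1e-30, 300, "3.2.1.21"),
                mkHit("p2", "r1", 75, 92, 1e-35, 310, "3.2.1.21"),
                mkHit("p3", "r2", 60, 85, 1e-25, 250, "1.14.13.7"),
                mkHit("p9", "r3", 60, 85, 1e-25, 250, "2.4.1.17"))
  p2g <- data.frame(protein_id = c("p1", "p2", "p3"),
                    genome_id = c("G1", "G2", "G1"))
  tax <- data.frame(genome_id = c("G1", "G2"),
                    lineage = c("Bacteria; Bacillota; Lactobacillus",
                                "Bacteria; Bacteroidota; Bacteroides"))
  db <- buildEnzymeDB(best, p2g, tax)
  expect_identical(attr(db, "errors"), "p9")   # no genome mapping -> skipped
  hit <- lookupEC(db, "3.2.1.21")
  expect_setequal(hit$genome_id, c("G1", "G2"))
  expect_match(hit$lineage[hit$genome_id == "G2"], "Bacteroides")
  expect_identical(nrow(lookupEC(db, "6.1.1.1")), 0L)   # absent EC: empty
  # partial lookup by wildcard agrees with the prefix rule
  expect_identical(lookupEC(db, "1.14.-.-", allowPartial = TRUE)$protein_id, "p3")
  expect_identical(nrow(lookupEC(db, "1.14.-.-", allowPartial = FALSE)), 0L)
  expect_setequal(lookupEC(db, "3.-.-.-", allowPartial = TRUE)$protein_id,
                  c("p1", "p2"))
})

test_that("partial lookups over a randomized DB match a string-prefix oracle", {
  set.seed(42)
  ecs <- unique(sprintf("%d.%d.%d.%d", sample(1:6, 100, TRUE),
                        sample(1:14, 100, TRUE), sample(1:9, 100, TRUE),
                        sample(1:50, 100, TRUE)))
  best <- do.call(rbind, lapply(seq_along(ecs), function(i)
    mkHit(sprintf("p%03d", i), "r", 70, 90, 1e-30, 300, ecs[i])))
  p2g <- data.frame(protein_id = best$qseqid, genome_id = "G1")
  tax <- data.frame(genome_id = "G1", lineage = "Bacteria; x; y")
  db <- buildEnzymeDB(best, p2g, tax)
  queries <- c(sprintf("%d.-.-.-", 1:6),
               sprintf("%d.%d.-.-", sample(1:6, 10, TRUE), sample(1:14, 10, TRUE)),
               sample(ecs, 4))
  for (q in queries) {
    prefix <- paste0(sub("(\\.-)+$", "", q, perl = TRUE), ".")
    oracle <- best$qseqid[startsWith(paste0(ecs, "."), prefix)]
    expect_setequal(lookupEC(db, q, allowPartial = TRUE)$protein_id, oracle)
  }
})

test_that("identical inputs serialize to byte-identical databases", {
  b <- fixtureBundle("tiny", 7L)
  ew <- generateEnzymeWorld(b$sub, seed = 7L)
  db1 <- buildEnzymeDB(filterBestHits(ew$hits), ew$protein2genome, ew$taxonomy)
  db2 <- buildEnzymeDB(filterBestHits(ew$hits), ew$protein2genome, ew$taxonomy)
  d1 <- tempfile(); d2 <- tempfile()
  writeEnzymeDB(db1, d1); writeEnzymeDB(db2, d2)
  for (f in c("enzymes.tsv", "taxonomy.tsv", "ec_index.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})
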