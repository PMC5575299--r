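mkRecords <- function(smiles, ids, tags) {
  rec <- data.frame(id = ids, smiles = unname(canonicalSmiles(smiles)),
                    name = NA_character_, provenance = "parsed",
                    stringsAsFactors = FALSE)
  rec$ecTags <- tags
  rec
}

test_that("cofactor filter removes water and ATP under the packaged list", {
  cof <- defaultCofactors()
  expect_true(all(c("water", "atp", "nad_plus", "fad") %in% cof$name))
  rec <- mkRecords(
    c("O", "Nc1ncnc2c1ncn2C1OC(COP(=O)(O)OP(=O)(O)OP(=O)(O)O)C(O)C1O",
      "OC(=O)c1ccc(cc1)CN"),
    c("water", "atp", "drug"),
    list("1.1.1.1", "2.7.1.1", "1.1.1.2"))
  out <- filterCofactors(rec, cof$canonical_key)
  expect_identical(out$kept$id, "drug")
  expect_setequal(out$removed$id, c("water", "atp"))
  # empty list is a no-op; all-cofactor input warns
  expect_identical(filterCofactors(rec, character(0))$kept$id, rec$id)
  expect_warning(filterCofactors(rec[1:2, ], cof$canonical_key), "empty")
})

test_that("multi-class filter removes exactly the class-conflicted records", {
  rec <- mkRecords(
    c("OC(=O)c1ccc(cc1)CN", "OC(=O)c1ccc(cc1)CCl", "N#Cc1occ(c1)CN"),
    c("multi", "sameclass", "clean"),
    list(c("1.1.1.1", "2.4.1.17"), c("1.1.1.1", "1.14.13.2"), "3.2.1.21"))
  out <- filterMulticlass(rec)
  expect_identical(out$removed$id, "multi")
  expect_identical(out$conflicts$multi, c(1L, 2L))
  expect_setequal(out$kept$id, c("sameclass", "clean"))
  # brute-force check on a random 10-record mix with 3 planted conflicts
  set.seed(31)
  tags <- c(replicate(7, sprintf("%d.1.1.%d", sample(1:6, 1), sample(1:9, 2)),
                      simplify = FALSE),
            replicate(3, sprintf("%d.1.1.1", sample(1:6, 2)), simplify = FALSE))
  rec10 <- mkRecords(sprintf("OC(=O)c1ccc(cc1)%s",
                             c("C","CN","CF","CCl","CBr","CI","CP","CSC","CON","C=C")),
                     sprintf("r%02d", 1:10), tags)
  out10 <- filterMulticlass(rec10)
  oracle <- vapply(tags, function(t) length(unique(ecClass(t))) == 1L, logical(1))
  expect_identical(out10$kept$id, rec10$id[oracle])
})

test_that("redundancy removal matches an all-pairs greedy clustering oracle", {
  # 12 molecules in 4 duplicate groups (each: parent + 2 structural copies,
  # one written as the Open Babel canonical form, one as the raw composition)
  parents <- c("OC(=O)c1ccc(cc1)CCOC", "NS(=O)(=O)c1ncc(cc1)CSC",
               "N#Cc1scc(c1)CP", "OC(=O)C1CCC(CC1)CBr")
  smiles <- unlist(lapply(1:4, function(i)
    c(parents[i], as.character(canonicalSmiles(parents[i])), parents[i])))
  ids <- sprintf("g%d_%d", rep(1:4, each = 3), rep(0:2, 4))
  rec <- mkRecords(smiles, ids, as.list(rep("1.1.1.1", 12)))
  out <- removeRedundancy(rec, 0.95, "fp2like")
  expect_identical(out$representatives$id, sprintf("g%d_0", 1:4))
  expect_identical(out$clusterMap$representative,
                   rep(sprintf("g%d_0", 1:4), each = 3))
  # oracle: full pairwise Tanimoto matrix + leader clustering re-run by hand
  M <- fingerprintMatrix(stats::setNames(rec$smiles, rec$id), "fp2like")
  S <- M %*% t(M); pc <- rowSums(M)
  TC <- S / (outer(pc, pc, "+") - S)
  leaders <- character(0)
  for (id in rec$id)
    if (!any(TC[id, leaders] > 0.95)) leaders <- c(leaders, id)
  expect_identical(out$representatives$id, leaders)
  # no representative pair above threshold
  repTC <- TC[leaders, leaders]; diag(repTC) <- 0
  expect_lte(max(repTC), 0.95)
  # identical pair collapses to one; all-distinct input is untouched
  two <- mkRecords(c("CCO", "OCC"), c("a", "b"), as.list(rep("1.1.1.1", 2)))
  expect_identical(removeRedundancy(two)$representatives$id, "a")
  distinct <- rec[c(1, 4, 7, 10), ]
  expect_identical(removeRedundancy(distinct)$representatives$id, distinct$id)
})

test_that("substrate DB build recovers fixture ground truth and is idempotent", {
  b <- fixtureBundle("tiny", 7L)
  db <- b$db
  truth <- b$sub$truth
  expect_setequal(substrateRecords(db)$id, truth$survivorIds)
  # partition property: class index sizes sum to the record count
  expect_identical(sum(lengths(classIndex(db))), nrow(substrateRecords(db)))
  # every record's ground-truth class matches its index bucket
  for (cd in names(classIndex(db)))
    expect_true(all(truth$classOf[classIndex(db)[[cd]]] == as.integer(cd)))
  # idempotence: curating the curated set changes nothing
  rec <- substrateRecords(db)
  again <- suppressWarnings(buildSubstrateDB(
    data.frame(smiles = rec$smiles, id = rec$id,
               ec = vapply(rec$ecTags, paste, "", collapse = ";"))))
  expect_identical(substrateRecords(again)$id, rec$id)
  expect_identical(substrateRecords(again)$smiles, rec$smiles)
  # one-class input yields a single class index key
  one <- suppressWarnings(buildSubstrateDB(
    data.frame(smiles = c("OC(=O)c1ccc(cc1)CN", "OC(=O)c1ccc(cc1)CF"),
               id = c("a", "b"), ec = c("3.1.1.1", "3.2.1.2"))))
  expect_identical(names(classIndex(one)), "3")
  expect_identical(names(subclassIndex(one)), c("3.1", "3.2"))
})

test_that("substrate DB survives a plain-text directory round trip", {
  b <- fixtureBundle("tiny", 7L)
  dir <- tempfile()
  writeSubstrateDB(b$db, dir)
  back <- readSubstrateDB(dir)
  expect_identical(substrateRecords(back)$id, substrateRecords(b$db)$id)
  expect_identical(substrateRecords(back)$smiles, substrateRecords(b$db)$smiles)
  expect_identical(substrateRecords(back)$ecTags, substrateRecords(b$db)$ecTags)
  expect_identical(classIndex(back), classIndex(b$db))
})
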