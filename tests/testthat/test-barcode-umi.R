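test_that("whitelisted barcodes pass through unchanged", {
  wl <- barcodeWhitelist(c("AAAA", "CCCC", "GGGG"))
  expect_identical(correctBarcode("CCCC", qstr(rep(30, 4)), wl), "CCCC")
})

test_that("barcodes with no whitelist neighbour are rejected", {
  wl <- barcodeWhitelist(c("AAAA", "CCCC"))
  expect_identical(correctBarcode("AAGG", qstr(rep(30, 4)), wl),
                   NA_character_)
})

test_that("the two-candidate posterior matches the hand computation", {
  ## candidates AAAA (prior 900) and AAAT (prior 100), both at Hamming
  ## distance 1 from AAAG with the mismatch at the same Q20 base, so the
  ## likelihoods cancel: posteriors are 0.9 and 0.1 by direct
  ## normalization; 0.9 < 0.975 so no correction is made
  wl <- barcodeWhitelist(c("AAAA", "AAAT"),
                         priorCounts = c(AAAA = 899, AAAT = 99))
  expect_identical(correctBarcode("AAAG", qstr(rep(20, 4)), wl),
                   NA_character_)
  ## a lower threshold accepts the 0.9 candidate
  expect_identical(
    correctBarcode("AAAG", qstr(rep(20, 4)), wl,
                   correctionParams(posteriorThreshold = 0.9)),
    "AAAA")
})

test_that("a single candidate at distance 1 is always accepted", {
  wl <- barcodeWhitelist(c("AAAA", "CCCC"))
  expect_identical(correctBarcode("AAAT", qstr(rep(10, 4)), wl), "AAAA")
})

test_that("length mismatches are input errors", {
  wl <- barcodeWhitelist(c("AAAA", "CCCC"))
  expect_error(correctBarcode("AAAAA", qstr(rep(30, 5)), wl), "length")
})

test_that("correction never exceeds Hamming distance 1 and never touches
           whitelisted observations", {
  set.seed(21)
  wl <- barcodeWhitelist(unique(replicate(50, paste(
    sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = ""))))
  for (i in 1:200) {
    obs <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                 collapse = "")
    out <- correctBarcode(obs, qstr(rep(25, 6)), wl)
    if (obs %in% wl@sequences) {
      expect_identical(out, obs)
    } else if (!is.na(out)) {
      d <- sum(strsplit(out, "")[[1]] != strsplit(obs, "")[[1]])
      expect_identical(d, 1L)
    }
  }
})

test_that("UMI validation rejects homopolymers, low quality and N", {
  expect_false(validateUmi("AAAAAAAAAA", qstr(rep(30, 10))))
  expect_true(validateUmi("ACGTACGTAC", qstr(rep(30, 10))))
  ## the quality rule is strictly greater than 10
  expect_false(validateUmi("ACGTACGTAC", qstr(c(rep(30, 9), 10))))
  expect_true(validateUmi("ACGTACGTAC", qstr(c(rep(30, 9), 11))))
  expect_false(validateUmi("ACGTACGTNC", qstr(rep(30, 10))))
})

test_that("UMI collapse is directional toward strictly more reads", {
  expect_identical(collapseUmis(c(rep("AAAA", 5), "AAAT")),
                   rep("AAAA", 6))
  tie <- c(rep("AAAA", 3), rep("AAAT", 3))
  expect_identical(collapseUmis(tie), tie)
  expect_identical(collapseUmis("AAAA"), "AAAA")
  ## no chaining: corrections use pre-collapse counts in a single pass
  chain <- c(rep("AAAA", 5), rep("AAAT", 3), "AATT")
  out <- collapseUmis(chain)
  expect_identical(sort(unique(out)), c("AAAA", "AAAT"))
  expect_equal(sum(out == "AAAA"), 8)
})

test_that("duplicate marking keeps one record per (barcode, UMI, gene)", {
  rec <- makeRecords("AAAA", "ACGT", "G1")[rep(1, 10), ]
  out <- markDuplicates(rec)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$nDuplicates, 9L)

  rec2 <- makeRecords("AAAA", replicate(10, paste(
    sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = "")),
    gene = paste0("G", 1:10))
  out2 <- markDuplicates(rec2)
  expect_equal(nrow(out2$records), 10L)

  rec3 <- makeRecords(c(rep("AAAA", 4), rep("CCCC", 3), rep("GGGG", 3)),
                      umi = c(rep("ACGT", 4), rep("TGCA", 3),
                              rep("GGAA", 3)),
                      gene = "G1")
  out3 <- markDuplicates(rec3)
  expect_equal(nrow(out3$records), 3L)
  expect_equal(out3$nDuplicates, 7L)
})

test_that("empty input produces an empty matrix without errors", {
  wl <- barcodeWhitelist("AAAA")
  expect_warning(res <- countPipeline(makeRecords(character(0),
                                                  character(0),
                                                  character(0)), wl),
                 "no input records")
  expect_equal(dim(umiCounts(res$matrix)), c(0L, 0L))
})

test_that("zero-error simulation is recovered exactly, and reads failing the
           confident-mapping filter are excluded", {
  sim <- simulateReads(barnyardConfig(nCells = 25, seed = 5))
  res <- countPipeline(sim$records, sim$whitelist)
  expect_identical(geneIDs(res$matrix), geneIDs(sim$truth$matrix))
  expect_identical(barcodes(res$matrix), barcodes(sim$truth$matrix))
  expect_true(all(umiCounts(res$matrix) == umiCounts(sim$truth$matrix)))
  expect_equal(res$metrics$validBarcodeFraction, 1)
  expect_equal(res$metrics$validUmiFraction, 1)

  ## flip one molecule's reads to MAPQ 254: that molecule vanishes
  rec <- sim$records
  key <- paste(rec$barcode_seq, rec$umi_seq)
  victim <- key == key[1L]
  rec$mapq[victim] <- 254L
  res2 <- countPipeline(rec, sim$whitelist)
  expect_equal(sum(umiCounts(res2$matrix)),
               sum(umiCounts(res$matrix)) - 1)
})

test_that("the pipeline is idempotent and matrix totals equal distinct
           retained triples", {
  sim <- simulateReads(barnyardConfig(nCells = 20, seed = 9,
                                      errorRate = 0.005))
  res <- countPipeline(sim$records, sim$whitelist)
  ## brute-force set oracle on the retained molecules
  valid <- sim$records
  ok <- valid$mapq == 255L & !is.na(valid$gene_id)
  expect_equal(sum(umiCounts(res$matrix)), res$metrics$nMolecules)

  ## idempotence: molecules already corrected and deduplicated flow
  ## through unchanged
  sim0 <- simulateReads(barnyardConfig(nCells = 20, seed = 9))
  res0 <- countPipeline(sim0$records, sim0$whitelist)
  mol <- markDuplicates(sim0$records)$records
  res1 <- countPipeline(mol, sim0$whitelist)
  expect_true(all(umiCounts(res1$matrix) == umiCounts(res0$matrix)))
})
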