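test_that("hammingScan finds the best offset, leftmost on ties", {
  withr::with_seed(71, {
    bc <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    win <- paste0(pad(36), bc, pad(100))
  })
  hit <- hammingScan(win, bc)
  expect_equal(hit$position, 37L)
  expect_equal(hit$mismatches, 0L)

  win1 <- win
  substr(win1, 40, 40) <- if (substr(win1, 40, 40) == "A") "C" else "A"
  expect_equal(hammingScan(win1, bc)$mismatches, 1L)

  expect_true(is.na(hammingScan("ACGT", bc)$position))

  # perfect tie: identical barcode embedded twice -> leftmost offset wins
  win2 <- paste0(bc, "ACGT", bc)
  expect_equal(hammingScan(win2, bc)$position, 1L)
})

test_that("hammingScan equals the exhaustive oracle on random instances", {
  withr::with_seed(72, {
    for (i in 1:300) {
      L <- sample(16:200, 1)
      win <- paste(sample(c("A", "C", "G", "T", "N"), L, TRUE,
                          prob = c(.24, .24, .24, .24, .04)), collapse = "")
      bc <- paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")
      expect_identical(hammingScan(win, bc), oracleHamming(win, bc))
    }
  })
})

test_that("barcode assignment applies length, mismatch and tie rules", {
  wl <- simulateWhitelist(3, seed = 73)
  body <- function(n) {
    withr::with_seed(n, paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                              collapse = ""))
  }
  read <- paste0(substr(body(1), 1, 10), wl[1], substr(body(2), 1, 280))
  a <- assignBarcode(read, wl)
  expect_equal(a$status, "assigned")
  expect_equal(a$barcode, wl[1])
  expect_equal(a$orientation, "forward")
  expect_equal(a$position, 11L)
  expect_equal(a$mismatches, 0L)

  # reverse-complemented barcode near the 3' end is found too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(wl[2])))
  read_rc <- paste0(substr(body(3), 1, 280), rc, substr(body(4), 1, 10))
  a_rc <- assignBarcode(read_rc, wl)
  expect_equal(a_rc$status, "assigned")
  expect_equal(a_rc$barcode, wl[2])
  expect_equal(a_rc$orientation, "reverse_complement")

  # 'longer than 250 nt' is strict
  expect_equal(assignBarcode(substr(body(5), 1, 240), wl)$status, "too_short")
  expect_equal(assignBarcode(substr(body(5), 1, 250), wl)$status, "too_short")

  # two substitutions exceed '<2 mismatches'
  read2 <- read
  p <- 11L
  for (off in c(0L, 5L)) {
    ch <- substr(read2, p + off, p + off)
    substr(read2, p + off, p + off) <- if (ch == "A") "C" else "A"
  }
  expect_equal(assignBarcode(read2, wl)$status, "unassigned")

  # two whitelist barcodes at the same best distance -> ambiguous
  # (G padding keeps both barcodes and their reverse complements away
  # from spurious matches)
  bc1 <- strrep("A", 16); bc2 <- paste0(strrep("A", 14), "CC")
  mid <- paste0(strrep("A", 15), "C")  # distance 1 to both
  read3 <- paste0(strrep("G", 20), mid, strrep("G", 260))
  expect_equal(assignBarcode(read3, c(bc1, bc2))$status, "ambiguous")

  expect_error(assignBarcode(read, character(0)), "empty whitelist")
  expect_error(assignBarcode(read, "ACGT"), "16 nt")
})

test_that("read classification distinguishes fusion, canonical and conflicts", {
  mk <- fusionMarkers()
  fus <- paste0(mk$tcf7[["e4"]], substr(mk$spi1[["e3"]], 1, 40))
  fus_read <- paste0(strrep("T", 30), paste(mk$tcf7[1:4], collapse = ""),
                     paste(mk$spi1, collapse = ""), strrep("G", 30))
  can_read <- paste0(strrep("T", 30), paste(mk$tcf7, collapse = ""),
                     strrep("G", 30))
  expect_equal(classifyRead(fus_read, mk)$class, "fusion")
  expect_equal(classifyRead(can_read, mk)$class, "canonical")
  expect_equal(classifyRead(strrep("ACGT", 100), mk)$class, "other")

  conflict <- paste0(fus_read, mk$tcf7[["e7"]])
  res <- classifyRead(conflict, mk)
  expect_equal(res$class, "other")
  expect_true(res$conflict)

  expect_error(classifyRead(fus_read, mk[c("tcf7_e4", "junction")]),
               "missing marker")
})

test_that("classification agrees with truth at 0.5% substitution error", {
  wl <- simulateWhitelist(8, seed = 75)
  sim <- simulateLongReads(wl, reads_per_cell = 125, fusion_fraction = 0.3,
                           sub_error_rate = 0.005, seed = 76)
  mk <- fusionMarkers()
  got <- vapply(sim$reads$sequence, function(s) classifyRead(s, mk)$class,
                character(1), USE.NAMES = FALSE)
  expect_gte(mean(got == sim$truth$class), 0.99)
})

test_that("demux conserves reads and recovers error-free truth exactly", {
  wl <- simulateWhitelist(4, seed = 77)
  sim <- simulateLongReads(wl, reads_per_cell = 12, fusion_fraction = 0.5,
                           sub_error_rate = 0, seed = 78)
  # add reads that must fall through: too short, and foreign barcode
  extra <- data.frame(
    read_id = c("short", "foreign"),
    sequence = c(strrep("ACGT", 40),
                 simulateLongReads(simulateWhitelist(1, seed = 79),
                                   reads_per_cell = 1, sub_error_rate = 0,
                                   seed = 80)$reads$sequence),
    quality = NA_character_)
  reads <- rbind(sim$reads, extra)

  out_dir <- withr::local_tempdir()
  res <- demuxRun(reads, wl, fusionMarkers(), out_dir = out_dir)

  expect_equal(sum(res$counts), nrow(reads))  # conservation
  expect_equal(unname(res$counts["too_short"]), 1L)
  expect_equal(unname(res$counts["unassigned"]), 1L)

  asg <- res$assignments[seq_len(nrow(sim$reads)), ]
  expect_identical(asg$barcode, sim$truth$barcode)
  expect_identical(asg$read_class, sim$truth$class)
  expect_equal(res$summary$n_assigned, rep(12L, 4))

  # per-cell FASTQ files hold exactly the assigned reads
  cell1 <- readFastq(file.path(out_dir, paste0(wl[1], ".fastq")))
  expect_setequal(cell1$read_id, sim$truth$read_id[sim$truth$barcode == wl[1]])
  expect_true(file.exists(file.path(out_dir, "demux_report.json")))

  # whitelist restricted to one cell: other cells' reads go unassigned
  res1 <- demuxRun(sim$reads, wl[1], fusionMarkers())
  expect_equal(unname(res1$counts["assigned"]), 12L)
  expect_equal(unname(res1$counts["unassigned"]), nrow(sim$reads) - 12L)
})

test_that("per-cell fusion proportions track the simulated fraction", {
  wl <- simulateWhitelist(8, seed = 81)
  sim <- simulateLongReads(wl, reads_per_cell = 50, fusion_fraction = 0.3,
                           sub_error_rate = 0.005, seed = 82)
  res <- demuxRun(sim$reads, wl, fusionMarkers())
  frac <- res$summary$n_fusion / res$summary$n_assigned
  se <- sqrt(0.3 * 0.7 / 50)
  expect_true(all(abs(frac - 0.3) <= 3 * se))
})
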