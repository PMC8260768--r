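test_that("generators are pure functions of their seed", {
  expect_identical(simulatePairedVariants(20, 20, seed = 5),
                   simulatePairedVariants(20, 20, seed = 5))
  wl <- simulateWhitelist(4, seed = 2)
  expect_identical(wl, simulateWhitelist(4, seed = 2))
  expect_identical(simulateLongReads(wl, reads_per_cell = 5, seed = 3),
                   simulateLongReads(wl, reads_per_cell = 5, seed = 3))
  expect_identical(simulateExpression(n_genes = 100, n_signature_up = 5,
                                      n_signature_down = 5, seed = 4),
                   simulateExpression(n_genes = 100, n_signature_up = 5,
                                      n_signature_down = 5, seed = 4))
  expect_identical(simulateLimitingDilution(1e-4, seed = 6),
                   simulateLimitingDilution(1e-4, seed = 6))
})

test_that("paired-variant simulation matches its binomial moments", {
  # germline-only: both samples hover around VAF 0.5
  g <- simulatePairedVariants(0, 50, depth = 100, seed = 7)
  expect_true(all(abs(g$variants$vaf_tumor - g$variants$vaf_remission) < 0.3))
  expect_equal(mean(g$variants$vaf_tumor), 0.5, tolerance = 0.05)

  # somatic at fixed VAF 0.25: mean tumor VAF within 3 SE of 0.25
  s <- simulatePairedVariants(200, 0, depth = 100,
                              tumor_vaf_range = 0.25, seed = 8)
  se <- sqrt(0.25 * 0.75 / 100) / sqrt(200)
  expect_lt(abs(mean(s$variants$vaf_tumor) - 0.25), 3 * se)
  expect_true(all(s$variants$remission_alt == 0))

  expect_error(simulatePairedVariants(0, 0, seed = 1), "no records")
  expect_error(simulatePairedVariants(1, 1, depth = 0, seed = 1), "depth")
})

test_that("long-read simulation embeds recoverable barcodes", {
  wl <- simulateWhitelist(8, seed = 21)
  expect_error(simulateLongReads(c("ACGT"), seed = 1), "16 nt")

  # error-free reads demultiplex with zero mismatches
  sim0 <- simulateLongReads(wl, n_cells = 4, reads_per_cell = 5,
                            sub_error_rate = 0, seed = 22)
  asg <- lapply(sim0$reads$sequence, assignBarcode, whitelist = wl)
  expect_true(all(vapply(asg, `[[`, character(1), "status") == "assigned"))
  expect_true(all(vapply(asg, `[[`, integer(1), "mismatches") == 0L))

  # fusion_fraction 1 labels everything fusion; reads all exceed 250 nt
  sim1 <- simulateLongReads(wl, n_cells = 2, reads_per_cell = 5,
                            fusion_fraction = 1, seed = 23)
  expect_true(all(sim1$truth$class == "fusion"))
  expect_true(all(nchar(sim1$reads$sequence) > 250))

  # at 0.5% substitutions, Binomial(16, .005) puts >= 99% of reads at
  # <= 1 barcode error, so nearly all assign
  simE <- simulateLongReads(wl, n_cells = 8, reads_per_cell = 50,
                            sub_error_rate = 0.005, seed = 24)
  st <- vapply(simE$reads$sequence, function(s) assignBarcode(s, wl)$status,
               character(1))
  expect_gte(mean(st == "assigned"), 0.99)
})

test_that("expression simulation plants a recoverable signature", {
  expect_error(simulateExpression(n_groupA = 1, seed = 1), "at least 2")
  expect_error(simulateExpression(n_genes = 10, n_signature_up = 20,
                                  n_signature_down = 0, seed = 1), "universe")

  # null effect: the DE stand-in finds (almost) nothing
  null <- simulateExpression(n_genes = 500, n_signature_up = 20,
                             n_signature_down = 20, log2_effect = 0, seed = 31)
  de0 <- differentialExpression(null$counts,
                                names(null$groups)[null$groups == "A"],
                                names(null$groups)[null$groups == "B"])
  sig0 <- deriveSignature(de0)
  expect_lte(length(sig0$up) + length(sig0$down), 0.05 * 500)

  # default effect: planted genes recovered with high power
  sim <- simulateExpression(n_genes = 500, n_signature_up = 20,
                            n_signature_down = 20, seed = 32)
  de <- differentialExpression(sim$counts,
                               names(sim$groups)[sim$groups == "A"],
                               names(sim$groups)[sim$groups == "B"])
  hits <- de$gene[de$adjusted_p < 0.05]
  planted <- sim$truth$gene[sim$truth$planted != "none"]
  expect_gte(length(intersect(hits, planted)) / length(planted), 0.9)
})

test_that("limiting-dilution simulation follows the single-hit response curve", {
  # dose*f >> 1 everywhere: every animal responds
  hot <- simulateLimitingDilution(0.5, doses = c(100, 1000), seed = 41)
  expect_true(all(hot$responding == hot$tested))

  # at the published lowest dose and f = 1/1243, P(respond) ~ 0.80
  p_expect <- 1 - exp(-2000 / 1243)
  reps <- vapply(1:200, function(i) {
    simulateLimitingDilution(1 / 1243, seed = 100 + i)$responding[4] / 5
  }, numeric(1))
  se <- sqrt(p_expect * (1 - p_expect) / (200 * 5))
  expect_lt(abs(mean(reps) - p_expect), 3 * se)

  expect_error(simulateLimitingDilution(0, seed = 1), "f_true")
})
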