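test_that("TPM normalization matches the closed form and sums to 1e6", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  tpm <- tpmNormalize(m, c(g1 = 1000, g2 = 2000))
  expect_equal(tpm["g1", 1], 2e6 / 3)
  expect_equal(tpm["g2", 1], 1e6 / 3)

  single <- matrix(7, 1, 2, dimnames = list("g", c("a", "b")))
  expect_true(all(tpmNormalize(single, c(g = 500)) == 1e6))

  withr::with_seed(91, {
    big <- matrix(rpois(200, 20), 40, 5,
                  dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
    lens <- setNames(sample(200:3000, 40), rownames(big))
  })
  expect_equal(unname(colSums(tpmNormalize(big, lens))), rep(1e6, 5))

  big[, 3] <- 0
  expect_warning(tpm0 <- tpmNormalize(big, lens), "all-zero")
  expect_true(all(tpm0[, 3] == 0))
  expect_error(tpmNormalize(big, lens[-1]), "missing")
})

test_that("cell QC drops cells by strict threshold comparisons", {
  n_genes <- 460
  genes <- c("MT-1", "RPL1", sprintf("g%03d", seq_len(n_genes - 2)))
  mk_cell <- function(mito, ribo, n_expr) {
    x <- numeric(n_genes)
    x[2 + seq_len(n_expr - 2)] <- 2
    bulk <- sum(x)
    # choose mito/ribo counts to hit the requested fractions exactly
    tot <- bulk / (1 - mito - ribo)
    c(tot * mito, tot * ribo, x[-(1:2)])
  }
  counts <- cbind(
    at_mito_bound = mk_cell(0.10, 0.05, 402),   # mito exactly 0.1 -> kept
    over_mito = mk_cell(0.11, 0.05, 402),       # dropped
    at_ribo_bound = mk_cell(0.05, 0.60, 402),   # ribo exactly 0.6 -> kept
    over_ribo = mk_cell(0.05, 0.61, 402),       # dropped
    few_genes = mk_cell(0.05, 0.05, 199),       # 199 genes -> dropped
    at_gene_bound = mk_cell(0.05, 0.05, 200),   # exactly 200 -> kept
    clean = mk_cell(0.01, 0.10, 402))
  rownames(counts) <- genes
  res <- qcFilterCells(counts, "MT-1", "RPL1")
  expect_setequal(res$kept, c("at_mito_bound", "at_ribo_bound",
                              "at_gene_bound", "clean"))
  expect_equal(res$qc$mito_fraction[1], 0.10)
  expect_error(qcFilterCells(counts[, 0], "MT-1", "RPL1"), "empty")
})

test_that("DE stand-in handles degenerate genes and is calibrated", {
  m <- matrix(c(5, 5, 5, 5, 1, 9, 2, 8), 2, 4, byrow = TRUE,
              dimnames = list(c("flat", "var"), paste0("s", 1:4)))
  de <- differentialExpression(m, c("s1", "s2"), c("s3", "s4"))
  # identical values in all samples after CPM can differ; use a truly
  # constant matrix row on equal library sizes instead
  m2 <- matrix(c(3, 3, 3, 3, 7, 7, 7, 7), 2, 4, byrow = TRUE,
               dimnames = list(c("a", "b"), paste0("s", 1:4)))
  de2 <- differentialExpression(m2, c("s1", "s2"), c("s3", "s4"))
  expect_equal(de2$log2_fold_change, c(0, 0))
  expect_equal(de2$p_value, c(1, 1))

  expect_error(differentialExpression(m, "s1", c("s3", "s4")), "at least 2")
  expect_true(all(de$adjusted_p >= de$p_value))
})

test_that("signature derivation applies strict fold-change boundaries", {
  de <- data.frame(gene = c("up", "edge", "down", "ns"),
                   log2_fold_change = c(2.5, 1.0, -2.5, 3),
                   p_value = c(1e-4, 1e-4, 1e-4, 0.5),
                   adjusted_p = c(1e-3, 1e-3, 1e-3, 0.8))
  sig <- deriveSignature(de)
  expect_identical(sig$up, "up")          # FC exactly 2 excluded
  expect_identical(sig$down, "down")
  empty <- deriveSignature(de[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("bulk scoring matches the pinned hand computation", {
  m <- matrix(c(1, 3), 1, 2, dimnames = list("g1", c("p1", "p2")))
  sc <- scoreSignatureBulk(m, "g1")
  # z across samples with sample SD: (-1/sqrt(2), +1/sqrt(2)); the means
  # then already have SD 1, so rescaling is the identity here
  expect_equal(sc$score, c(-1, 1) / sqrt(2))
  expect_equal(mean(sc$score), 0)
  expect_equal(sd(sc$score), 1)
})

test_that("bulk scoring drops degenerate genes and is affine-invariant", {
  withr::with_seed(92, {
    m <- matrix(rnorm(50 * 6, 10), 50, 6,
                dimnames = list(paste0("g", 1:50), paste0("p", 1:6)))
  })
  sig <- paste0("g", 1:10)
  m["g1", ] <- 5  # constant
  expect_warning(sc <- scoreSignatureBulk(m, sig), "constant")
  # an absent gene and the constant gene each raise their own warning
  expect_warning(expect_warning(scoreSignatureBulk(m, c(sig, "nope")),
                                "absent"), "constant")
  expect_error(scoreSignatureBulk(m, "absent_gene"), "no signature gene")

  # per-gene affine transforms (positive scale) leave scores unchanged
  m2 <- m
  withr::with_seed(93, {
    for (g in sig[-1]) m2[g, ] <- m2[g, ] * runif(1, 0.5, 3) + rnorm(1, 0, 4)
  })
  expect_equal(suppressWarnings(scoreSignatureBulk(m2, sig))$score,
               sc$score)
})

test_that("bulk scores separate a planted two-group signature", {
  sim <- simulateExpression(n_genes = 400, n_signature_up = 20,
                            n_signature_down = 20, seed = 94)
  tpm <- tpmNormalize(sim$counts, sim$lengths)
  up <- sim$truth$gene[sim$truth$planted == "up"]
  sc <- scoreSignatureBulk(tpm, up)
  expect_gt(mean(sc$score[sim$groups == "A"]),
            mean(sc$score[sim$groups == "B"]))
})

test_that("per-cell module scores are seeded, null-centred and separating", {
  withr::with_seed(95, {
    counts <- matrix(rpois(600 * 40, 5), 600, 40,
                     dimnames = list(sprintf("g%03d", 1:600),
                                     sprintf("c%02d", 1:40)))
    # cells 1-20 overexpress the planted module
    planted <- sprintf("g%03d", 1:15)
    counts[planted, 1:20] <- counts[planted, 1:20] + 20
  })
  l <- logNormalizeCells(counts)

  s1 <- scoreSignatureCells(l, planted, seed = 7)
  s2 <- scoreSignatureCells(l, planted, seed = 7)
  expect_identical(s1, s2)  # deterministic under seed
  expect_gt(mean(s1$score[1:20]), mean(s1$score[21:40]) + 1)

  # a random gene set scores near zero before rescaling
  withr::with_seed(96, rand <- sample(rownames(counts), 15))
  s0 <- scoreSignatureCells(l, rand, seed = 8)
  expect_lt(abs(mean(s0$raw_score)), 0.1)
  expect_error(scoreSignatureCells(l[1:10, ], planted, seed = 1), "n_bins")
})

test_that("ranking statistic is -sign(log2FC) * log10(padj)", {
  de <- data.frame(gene = c("a", "b", "c"),
                   log2_fold_change = c(1.2, -0.8, 0),
                   p_value = c(0.001, 0.001, 0.5),
                   adjusted_p = c(0.01, 0.01, 0.6))
  rk <- rankGenes(de)
  expect_equal(rk$score[rk$gene == "a"], 2)
  expect_equal(rk$score[rk$gene == "b"], -2)
  expect_equal(rk$score[rk$gene == "c"], 0)
  expect_false(is.unsorted(rev(rk$score)))
  expect_warning(rankGenes(data.frame(gene = "z", log2_fold_change = 1,
                                      adjusted_p = 0)), "clipped")
})

test_that("anchor-gene correlation finds exact and null relationships", {
  withr::with_seed(97, {
    m <- matrix(rnorm(80 * 500), 80, 500,
                dimnames = list(sprintf("g%02d", 1:80), NULL))
  })
  m["g02", ] <- m["g01", ]            # duplicate of the anchor
  m["g03", ] <- -m["g01", ] + 5       # anti-correlated
  m["g04", ] <- 1                     # constant -> excluded
  res <- correlateWithGene(m, "g01", k = 5)
  expect_equal(unname(res$correlations["g02"]), 1)
  expect_equal(unname(res$correlations["g03"]), -1)
  expect_false("g01" %in% res$top)
  expect_false("g04" %in% names(res$correlations))
  expect_equal(res$top[1], "g02")
  expect_equal(res$bottom[1], "g03")
  # independent genes: null r has SD ~ 1/sqrt(n-1) ~ 0.045 at n = 500,
  # so even the max over ~76 genes stays well below 0.2
  others <- setdiff(names(res$correlations), c("g02", "g03"))
  expect_lt(mean(abs(res$correlations[others])), 0.1)
  expect_lt(max(abs(res$correlations[others])), 0.2)
  expect_error(correlateWithGene(m, "g04"), "constant")
})
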