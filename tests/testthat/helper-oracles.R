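# Independent brute-force oracles used to pin expected values.

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, using log-binomial coefficients (not dhyper).
oracleFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[xs == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exhaustive per-offset Hamming comparison on split characters.
oracleHamming <- function(window, barcode) {
  wc <- strsplit(window, "", fixed = TRUE)[[1L]]
  bc <- strsplit(barcode, "", fixed = TRUE)[[1L]]
  noff <- length(wc) - length(bc) + 1L
  if (noff < 1L) return(list(position = NA_integer_, mismatches = NA_integer_))
  best_p <- NA_integer_; best_m <- Inf
  for (o in seq_len(noff)) {
    m <- sum(wc[o:(o + length(bc) - 1L)] != bc)
    if (m < best_m) { best_m <- m; best_p <- o }
  }
  list(position = best_p, mismatches = as.integer(best_m))
}

# Step-by-step running-sum enrichment score (explicit loop). Extremum by
# absolute value; exact +x/-x ties resolve to the earlier position (1e-9
# relative tolerance), the convention the package pins.
oracleES <- function(scores, gene_set, weight = 1) {
  genes <- names(scores)
  hit <- genes %in% gene_set
  k <- sum(hit); N <- length(scores)
  denom <- sum(abs(scores[hit])^weight)
  running <- numeric(N); acc <- 0
  for (i in seq_len(N)) {
    acc <- acc + if (hit[i]) {
      if (denom > 0) abs(scores[i])^weight / denom else 1 / k
    } else -1 / (N - k)
    running[i] <- acc
  }
  m <- max(abs(running))
  running[which(abs(running) >= m * (1 - 1e-9))[1L]]
}

# Reference Benjamini-Hochberg step-up, written out longhand.
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- running_min
  }
  adj
}

# Shared synthetic gene models mirroring the fusion's exon anatomy:
# 7 exons for the 5' partner, 5 for the 3' partner, 100 nt apart.
toyTcf7 <- function() {
  GeneModel("TCF7", "+", seq(1, 601, 100), seq(40, 640, 100), 384,
            data.frame(domain = c("CTNNB1", "HMG"),
                       start = c(1L, 200L), end = c(55L, 290L)))
}

toySpi1 <- function() {
  GeneModel("SPI1", "+", seq(1, 401, 100), seq(40, 440, 100), 271,
            data.frame(domain = c("PEST", "ETS"),
                       start = c(118L, 171L), end = c(160L, 254L)))
}
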