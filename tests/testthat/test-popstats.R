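# independent brute-force oracle: mean pairwise differences between
# haplotype columns, site by site
pairwise_pi_oracle <- function(hap) {
  nh <- ncol(hap)
  tot <- 0
  for (i in seq_len(nh - 1)) for (j in (i + 1):nh)
    tot <- tot + sum(hap[, i] != hap[, j])
  tot / choose(nh, 2)
}

test_that("windowed pi matches direct arithmetic", {
  # monomorphic window
  hap <- matrix(0L, 5, 4)
  st <- st_from_hap(hap, pos = c(10, 20, 30, 40, 50) * 10L, L = 1000)
  pw <- pi_windows(st, win = 1000, step = 1000)
  expect_equal(pw$value, 0)
  # one site, n = 4 haplotypes, j = 2, window 1,000 bp
  hap <- matrix(c(1L, 1L, 0L, 0L), 1, 4)
  st <- st_from_hap(hap, pos = 500L, L = 1000)
  pw <- pi_windows(st, win = 1000, step = 1000)
  expect_equal(pw$value, (2 * 2 * 2 / 12) / 1000)
  expect_equal(pw$value, 6.67e-4, tolerance = 1e-3)
})

test_that("pi equals the pairwise-difference oracle on random fixtures", {
  set.seed(9)
  for (rep in 1:3) {
    hap <- matrix(rbinom(40 * 8, 1, 0.3), 40, 8)
    st <- st_from_hap(hap, pos = sort(sample.int(4000, 40)), L = 4000)
    pw <- pi_windows(st, win = 4000, step = 4000)
    expect_equal(pw$value * 4000, pairwise_pi_oracle(hap), tolerance = 1e-12)
  }
})

test_that("admixture elevates diversity above both sources", {
  truth <- small_truth(seed = 31, F = 0.25, n_sites = 2000, n_adm = 12,
                       n_ref = 16, m = c(0.5, 0.5))
  pi_adm <- mean(pi_windows(truth$target, win = 1e6, step = 1e6)$value)
  pi_a <- mean(pi_windows(truth$panels$haps[[1]], win = 1e6,
                          step = 1e6)$value)
  pi_b <- mean(pi_windows(truth$panels$haps[[2]], win = 1e6,
                          step = 1e6)$value)
  expect_gt(pi_adm, pi_a)
  expect_gt(pi_adm, pi_b)
})

# spreadsheet-style Tajima's D oracle written independently of the package
tajima_oracle <- function(hap) {
  n <- ncol(hap)
  S <- sum(apply(hap, 1, function(r) length(unique(r)) > 1))
  pihat <- pairwise_pi_oracle(hap)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

test_that("Tajima's D matches the brute-force oracle to 1e-10", {
  set.seed(12)
  hap <- matrix(rbinom(50 * 10, 1, 0.25), 50, 10)
  stopifnot(sum(apply(hap, 1, function(r) length(unique(r)) > 1)) >= 5)
  st <- st_from_hap(hap, pos = sort(sample.int(2000, 50)), L = 2000)
  td <- tajimas_d(st, win = 2000, step = 2000)
  expect_equal(td$value, tajima_oracle(hap), tolerance = 1e-10)
})

test_that("Tajima's D is NaN without segregating sites and errors at n < 4", {
  hap <- matrix(0L, 10, 4)
  st <- st_from_hap(hap, L = 2000)
  td <- tajimas_d(st, win = 2000, step = 2000)
  expect_true(is.nan(td$value[1]))
  expect_true(td$flagged[1])
  hap2 <- matrix(rbinom(10 * 2, 1, 0.5), 10, 2)
  expect_error(tajimas_d(st_from_hap(hap2)), ">= 4 haplotypes")
})

test_that("a neutral frequency spectrum gives mean D near zero", {
  # sites with derived counts ~ 1/j (the standard neutral spectrum),
  # randomly assigned across haplotypes: E[pi_hat] = S/a1, so E[D] = 0
  set.seed(33)
  n <- 20; S <- 4000
  j <- sample(1:(n - 1), S, replace = TRUE, prob = 1 / (1:(n - 1)))
  hap <- t(vapply(j, function(k) sample(c(rep(1L, k), rep(0L, n - k))),
                  integer(n)))
  st <- st_from_hap(hap, pos = sort(sample.int(8e6, S)), L = 8e6)
  td <- tajimas_d(st, win = 40000, step = 40000)
  expect_lt(abs(mean(td$value, na.rm = TRUE)), 0.3)
})

test_that("diversity log-ratio has its closed forms and guards", {
  grid <- data.frame(chrom = "chr1", start = c(0, 1000),
                     end = c(1000, 2000))
  a <- data.frame(grid, n_sites = 5, value = c(2e-3, 1e-3), flagged = FALSE)
  b <- data.frame(grid, n_sites = 5, value = c(2e-3, 0), flagged = FALSE)
  r <- theta_pi_ratio(a, b)
  expect_equal(r$value[1], 0)
  expect_true(is.nan(r$value[2]))
  a2 <- data.frame(grid, n_sites = 5, value = c(2e-3, 2e-3),
                   flagged = FALSE)
  b2 <- data.frame(grid, n_sites = 5, value = c(1e-3, 1e-3),
                   flagged = FALSE)
  expect_equal(theta_pi_ratio(a2, b2)$value, rep(log(2), 2))
  bad <- b2; bad$start <- bad$start + 1
  expect_error(theta_pi_ratio(a2, bad), "grids")
})

# independent per-site Weir-Cockerham oracle (textbook transcription,
# scalar loops, no shared code with the package implementation)
wc_oracle_site <- function(gA, gB) {
  n1 <- sum(!is.na(gA)); n2 <- sum(!is.na(gB)); r <- 2
  p1 <- sum(gA, na.rm = TRUE) / (2 * n1); p2 <- sum(gB, na.rm = TRUE) / (2 * n2)
  h1 <- mean(gA == 1, na.rm = TRUE); h2 <- mean(gB == 1, na.rm = TRUE)
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = h1 * n1 / (r * nbar) + h2 * n2 / (r * nbar)) *
    c(1, 1, 1) -> v
  v["c"] <- hbar / 2
  v
}

test_that("window FST equals the per-site oracle aggregation to 1e-10", {
  set.seed(14)
  gA <- matrix(rbinom(60 * 6, 2, 0.3), 60, 6)
  gB <- matrix(rbinom(60 * 6, 2, 0.6), 60, 6)
  st <- site_table(rep("chr1", 60), sort(sample.int(5000, 60)),
                   rep("A", 60), rep("G", 60), cbind(gA, gB),
                   samples = c(paste0("a", 1:6), paste0("b", 1:6)),
                   contig_len = c(chr1 = 5000))
  fst <- wc_fst_windows(st, paste0("a", 1:6), paste0("b", 1:6),
                        win = 5000, step = 5000)
  ora <- t(vapply(seq_len(60), function(i)
    wc_oracle_site(gA[i, ], gB[i, ]), c(a = 0, b = 0, c = 0)))
  mono <- vapply(seq_len(60), function(i) {
    p1 <- mean(gA[i, ]) / 2; p2 <- mean(gB[i, ]) / 2
    (p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)
  }, TRUE)
  expect_equal(fst$value,
               sum(ora[!mono, "a"]) / sum(ora[!mono, ]),
               tolerance = 1e-10)
})

test_that("FST hits its boundary cases", {
  # fixed difference -> 1
  gA <- matrix(2L, 10, 5); gB <- matrix(0L, 10, 5)
  st <- site_table(rep("chr1", 10), seq_len(10) * 10L, rep("A", 10),
                   rep("G", 10), cbind(gA, gB),
                   samples = c(paste0("a", 1:5), paste0("b", 1:5)),
                   contig_len = c(chr1 = 200))
  fst <- wc_fst_windows(st, paste0("a", 1:5), paste0("b", 1:5),
                        win = 200, step = 200)
  expect_equal(fst$value, 1)
  # identical allele counts -> near zero
  set.seed(15)
  g <- matrix(rbinom(500 * 8, 2, 0.4), 500, 8)
  st2 <- site_table(rep("chr1", 500), seq_len(500) * 10L, rep("A", 500),
                    rep("G", 500), cbind(g, g),
                    samples = c(paste0("a", 1:8), paste0("b", 1:8)),
                    contig_len = c(chr1 = 5001))
  fst2 <- wc_fst_windows(st2, paste0("a", 1:8), paste0("b", 1:8),
                         win = 5001, step = 5001)
  expect_lte(fst2$value, 0.01)   # slightly negative by construction
  expect_gt(fst2$value, -0.1)
  # independent samples from one frequency vector: noise around zero
  p <- runif(500, 0.2, 0.8)
  ga <- matrix(rbinom(500 * 8, 2, p), 500, 8)
  gb <- matrix(rbinom(500 * 8, 2, p), 500, 8)
  st3 <- site_table(rep("chr1", 500), seq_len(500) * 10L, rep("A", 500),
                    rep("G", 500), cbind(ga, gb),
                    samples = c(paste0("a", 1:8), paste0("b", 1:8)),
                    contig_len = c(chr1 = 5001))
  fst3 <- wc_fst_windows(st3, paste0("a", 1:8), paste0("b", 1:8),
                         win = 5001, step = 5001)
  expect_lt(abs(fst3$value), 0.02)
  expect_error(wc_fst_windows(st2, character(0), paste0("b", 1:8)),
               "empty population")
})

test_that("pi and FST are invariant to sample order and allele relabel", {
  truth <- small_truth(seed = 35, n_sites = 500, n_adm = 8, n_ref = 10)
  st <- truth$target
  pw1 <- pi_windows(st, win = 1e6, step = 1e6)
  pw2 <- pi_windows(st, samples = rev(st$samples), win = 1e6, step = 1e6)
  expect_equal(pw1$value, pw2$value)
  # ref/alt flip: dosage g -> 2 - g
  flip <- st
  flip$gt <- 2L - st$gt
  flip$hap <- 1L - st$hap
  pw3 <- pi_windows(flip, win = 1e6, step = 1e6)
  expect_equal(pw1$value, pw3$value)
  pa <- st$samples[1:4]; pb <- st$samples[5:8]
  f1 <- wc_fst_windows(st, pa, pb, win = 1e6, step = 1e6)
  f2 <- wc_fst_windows(flip, rev(pa), rev(pb), win = 1e6, step = 1e6)
  expect_equal(f1$value, f2$value)
})

test_that("KING-robust kinship recovers canonical relationships", {
  set.seed(16)
  p <- runif(3000, 0.1, 0.9)
  geno <- function() rbinom(3000, 1, p) + rbinom(3000, 1, p)
  g1 <- geno(); g2 <- geno()
  # parent-offspring: child inherits one allele from the parent
  par_h <- rbinom(3000, 1, p)
  child <- par_h + rbinom(3000, 1, p)
  parent <- par_h + rbinom(3000, 1, p)
  g <- cbind(dup1 = g1, dup2 = g1, unrel = g2, parent = parent,
             child = child)
  st <- site_table(rep("chr1", 3000), seq_len(3000) * 10L,
                   rep("A", 3000), rep("G", 3000), g,
                   contig_len = c(chr1 = 30001))
  kin <- king_kinship(st)
  phi <- function(a, b) kin$phi[kin$id1 == a & kin$id2 == b]
  expect_equal(phi("dup1", "dup2"), 0.5, tolerance = 0.02)
  expect_equal(kin$degree[kin$id1 == "dup1" & kin$id2 == "dup2"],
               "duplicate")
  expect_equal(phi("parent", "child"), 0.25, tolerance = 0.03)
  expect_equal(phi("dup1", "unrel"), 0, tolerance = 0.02)
  expect_false(kin$flag_related[kin$id1 == "dup1" & kin$id2 == "unrel"])
  expect_true(kin$flag_related[kin$id1 == "parent" & kin$id2 == "child"])
})
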