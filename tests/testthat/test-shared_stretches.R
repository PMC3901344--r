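test_that("longest_shared_stretch handles the elementary cases", {
  s <- random_seq(60)
  hit <- longest_shared_stretch(s, s)
  expect_equal(hit$length, 60)
  expect_equal(hit$pos_a, 0)
  expect_equal(hit$pos_b, 0)
  none <- longest_shared_stretch(strrep("A", 50), strrep("C", 50))
  expect_equal(none$length, 0)
  expect_error(longest_shared_stretch("", "ACGT"), "empty")
})

test_that("longest_shared_stretch equals the brute-force oracle on random
          pairs, with and without plants", {
  set.seed(61)
  for (i in 1:60) {
    na <- sample(20:200, 1)
    nb <- sample(20:200, 1)
    a <- random_seq(na)
    b <- random_seq(nb)
    if (i %% 3 == 0) {  # plant a shared window
      w <- sample(8:18, 1)
      pa <- sample(na - w + 1, 1)
      pb <- sample(nb - w + 1, 1)
      substr(b, pb, pb + w - 1) <- substr(a, pa, pa + w - 1)
    }
    expect_equal(longest_shared_stretch(a, b)$length, oracle_lcs(a, b))
  }
})

test_that("shared-stretch length is symmetric and the reported positions
          index an identical window", {
  set.seed(62)
  for (i in 1:20) {
    a <- random_seq(120)
    b <- random_seq(150)
    ha <- longest_shared_stretch(a, b)
    hb <- longest_shared_stretch(b, a)
    expect_equal(ha$length, hb$length)
    if (ha$length > 0) {
      expect_identical(substr(a, ha$pos_a + 1, ha$pos_a + ha$length),
                       substr(b, ha$pos_b + 1, ha$pos_b + ha$length))
    }
  }
})

test_that("reverse-complement search and masked secondary stretches work", {
  set.seed(63)
  a <- random_seq(100)
  b <- random_seq(100)
  w <- substr(a, 21, 50)
  substr(b, 41, 70) <- rc(w)
  fwd <- longest_shared_stretch(a, b)
  both <- longest_shared_stretch(a, b, search_revcomp = TRUE)
  expect_gte(both$length, 30)
  expect_equal(both$strand_b, "-")
  expect_lt(fwd$length, 30)
  # secondary stretch via masking
  a2 <- random_seq(200)
  b2 <- random_seq(200)
  substr(b2, 11, 40) <- substr(a2, 51, 80)    # 30-bp primary
  substr(b2, 101, 115) <- substr(a2, 141, 155)  # 15-bp secondary
  hit <- longest_shared_stretch(a2, b2, mask_primary = TRUE)
  expect_equal(hit$length, 30)
  expect_gte(hit$secondary$length, 15)
  expect_lt(hit$secondary$length, 30)
})

test_that("the Monte-Carlo null is deterministic, honours composition
          limits and grows with sequence length", {
  n1 <- null_longest_stretch(80, 80, reps = 300, seed = 5)
  n2 <- null_longest_stretch(80, 80, reps = 300, seed = 5)
  expect_identical(n1$distribution, n2$distribution)
  expect_error(null_longest_stretch(80, 80,
                                    base_composition = c(A = 1, C = 0,
                                                         G = 0, T = 0)),
               "degenerate")
  expect_error(null_longest_stretch(80, 80, reps = 50), "at least 100")
  # mean is non-decreasing in lenA over a doubling ladder
  means <- vapply(c(50, 100, 200, 400), function(n)
    null_longest_stretch(n, 100, reps = 1000, seed = 7)$mean, 0)
  expect_true(all(diff(means) >= 0))
})

test_that("scanning a genome with one planted stretch flags that pair at
          the top fold, with a calibrated chance-flag rate", {
  sim <- generate_genome(simulation_config(seed = 71))
  pl <- plant_shared_stretch(sim, "trnL1", "trnL2", 28, seed = 72)
  rep_df <- scan_gene_pairs(pl, reps = 120, seed = 73)
  expect_equal(nrow(rep_df), choose(37, 2))
  top <- rep_df[1, ]
  expect_setequal(c(top$gene_a, top$gene_b), c("trnL1", "trnL2"))
  expect_true(top$flagged)
  expect_gte(top$observed_len, 28)
  expect_gte(top$fold, 2)
  # chance flags stay within the q95 calibration (5% + binomial slack)
  others <- rep_df[-1, ]
  expect_lte(mean(others$flagged), 0.05 + 3 * sqrt(0.05 * 0.95 /
                                                     nrow(others)))
})
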