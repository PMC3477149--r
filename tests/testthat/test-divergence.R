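test_that("per-codon synonymous site counts match hand enumeration", {
  expect_equal(syn_sites_of_codon("TGG"), 0)          # Trp
  expect_equal(syn_sites_of_codon("CTC"), 1)          # 4-fold third position
  expect_equal(syn_sites_of_codon("TTT"), 1 / 3)      # Phe
  expect_error(syn_sites_of_codon("TAA"), "stop")
  expect_error(syn_sites_of_codon("ATN"), "A/C/G/T")
})

test_that("site counts equal the enumeration oracle for all sense codons", {
  sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  for (cod in sense) {
    expect_equal(syn_sites_of_codon(cod), oracle_syn_sites(cod),
                 tolerance = 1e-12, label = cod)
  }
})

test_that("pairwise synonymous divergence matches worked examples", {
  d0 <- pairwise_syn("ATGGCT", "ATGGCT")
  expect_equal(d0$Sd, 0)
  expect_equal(d0$pS, 0)
  expect_equal(d0$KS, 0)

  d1 <- pairwise_syn("CTTCGT", "CTCCGC")
  expect_equal(d1$S, 2)
  expect_equal(d1$Sd, 2)
  expect_equal(d1$pS, 1)
  expect_true(is.na(d1$KS))

  d2 <- pairwise_syn("AAAAAA", "AAGAAA")
  expect_equal(d2$S, 2 / 3)
  expect_equal(d2$Sd, 1)
  expect_equal(d2$pS, 1.5)
  expect_true(is.na(d2$KS))

  expect_error(pairwise_syn("---", "---"), "no complete codon")
})

test_that("pairwise divergence equals the pathway-enumeration oracle on
           random small alignments with gaps, N and stops", {
  set.seed(101)
  for (rep in 1:150) {
    n <- sample(1:5, 1)
    s1 <- random_cds(n)
    s2 <- mutate_cds(s1, p_sub = runif(1, 0.05, 0.6),
                     p_gap_codon = 0.1, p_n_codon = 0.1)
    got <- tryCatch(pairwise_syn(s1, s2), error = function(e) NULL)
    want <- oracle_pairwise_syn(s1, s2)
    if (is.null(got)) {
      expect_true(want$n_codons == 0 || want$S == 0)
    } else {
      expect_equal(got$S, want$S, tolerance = 1e-12)
      expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
      expect_equal(got$pS, want$pS, tolerance = 1e-12)
      expect_equal(got$n_codons, want$n_codons)
    }
  }
})

test_that("pairwise divergence is exactly symmetric", {
  set.seed(7)
  for (rep in 1:25) {
    s1 <- random_cds(8)
    s2 <- mutate_cds(s1, p_sub = 0.4, p_gap_codon = 0.05)
    a <- pairwise_syn(s1, s2)
    b <- pairwise_syn(s2, s1)
    expect_identical(a$S, b$S)
    expect_identical(a$Sd, b$Sd)
    expect_identical(a$pS, b$pS)
  }
})

test_that("Jukes-Cantor correction is monotone, dominates p, saturates", {
  expect_equal(jc_correct(0), 0)
  p <- seq(0.01, 0.74, by = 0.01)
  k <- jc_correct(p)
  expect_true(all(diff(k) > 0))
  expect_true(all(k > p))
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.9)))
  expect_error(jc_correct(-0.1), ">= 0")
})

test_that("Z comparison matches direct arithmetic", {
  z0 <- z_compare(0.5, 0.1, 0.5, 0.1)
  expect_equal(z0$Z, 0)
  expect_equal(z0$p_value, 1)

  z1 <- z_compare(0.70, 0.024, 0.41, 0.018)
  expect_equal(round(z1$Z, 2), 9.67)
  expect_lt(z1$p_value, 0.001)

  z2 <- z_compare(0.70, 0.024, 0.40, 0.018)
  expect_equal(signif(z2$Z, 3), 10.0)
  expect_error(z_compare(1, 0, 2, 0), "zero")
})

test_that("window profile counts differences with pairwise gap deletion", {
  s <- paste0(rep("A", 2000), collapse = "")
  wp <- window_profile(s, s, window_size = 500)
  expect_equal(nrow(wp), 4L)
  expect_true(all(wp$p == 0))
  expect_true(all(wp$reliable))

  # all of window 2 differs, everything else identical
  v1 <- rep("A", 1500); v2 <- v1; v2[501:1000] <- "G"
  wp2 <- window_profile(paste0(v1, collapse = ""), paste0(v2, collapse = ""))
  expect_equal(wp2$p, c(0, 1, 0))

  # gap columns are excluded from both numerator and denominator
  v3 <- v1; v3[1:400] <- "-"
  wp3 <- window_profile(paste0(v3, collapse = ""), paste0(v2, collapse = ""))
  expect_equal(wp3$n_sites[1], 100L)
  expect_false(wp3$reliable[1])

  # trailing partial window retained but flagged unreliable
  s4 <- paste0(rep("A", 1200), collapse = "")
  wp4 <- window_profile(s4, s4)
  expect_equal(nrow(wp4), 3L)
  expect_equal(wp4$end[3], 1200L)
  expect_false(wp4$reliable[3])
  expect_error(window_profile("AC", "AC", window_size = 0), "positive")
})

test_that("window means track regional divergence within binomial error", {
  set.seed(23)
  n <- 4000
  p_true <- c(rep(0.6, 2000), rep(0.3, 2000))
  v1 <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  v2 <- v1
  flip <- runif(n) < p_true
  v2[flip] <- vapply(v1[flip], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  wp <- window_profile(paste0(v1, collapse = ""), paste0(v2, collapse = ""))
  for (i in seq_len(nrow(wp))) {
    p0 <- p_true[wp$start[i] + 1]
    expect_lt(abs(wp$p[i] - p0), 3 * sqrt(p0 * (1 - p0) / wp$n_sites[i]))
  }
})

test_that("multi-copy averaging equals the mean over all X-by-Y pairs", {
  set.seed(31)
  base <- random_cds(30)
  seqs <- c(X1 = base,
            X2 = mutate_cds(base, 0.05),
            Y1 = mutate_cds(base, 0.3),
            Y2 = mutate_cds(base, 0.3))
  aln <- codon_alignment(seqs, mode = "codon")
  avg <- mean_syn_divergence(aln, c("X1", "X2"), c("Y1", "Y2"))
  singles <- c(pairwise_syn(seqs["X1"], seqs["Y1"])$pS,
               pairwise_syn(seqs["X1"], seqs["Y2"])$pS,
               pairwise_syn(seqs["X2"], seqs["Y1"])$pS,
               pairwise_syn(seqs["X2"], seqs["Y2"])$pS)
  expect_equal(avg$pS, mean(singles), tolerance = 1e-12)
  expect_length(attr(avg, "pairs"), 4L)
})

test_that("estimated pS converges to the Jukes-Cantor expectation on
           4-fold-degenerate simulated data", {
  cfg <- sim_config(n_codons = 10000, T_arrest = 1.8e8, T_split = 1.5e8,
                    m_f = 2e-9, alpha = 2, seed = 42)
  sim <- simulate_gametologs(cfg)
  s <- aln_seqs(sim$aln)
  dv <- pairwise_syn(s[["EutX"]], s[["EutY"]])
  expect_equal(dv$S, 10000)  # scaffold: exactly one synonymous site per codon
  p_exp <- sim$truth$expected_p$EX_EY
  expect_lt(abs(dv$pS - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
})
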