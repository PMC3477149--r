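test_that("runs test reproduces exact enumeration probabilities", {
  r1 <- runs_test(strsplit("AAAABBBB", "")[[1]])
  expect_equal(r1$runs_observed, 2L)
  expect_equal(r1$p_one_tailed, 2 / 70)
  expect_equal(r1$method, "exact")

  r2 <- runs_test(strsplit("ABABABAB", "")[[1]])
  expect_equal(r2$runs_observed, 8L)
  expect_equal(r2$p_one_tailed, 1)

  r3 <- runs_test(strsplit("AABB", "")[[1]])
  expect_equal(r3$p_one_tailed, 1 / 3)

  expect_error(runs_test(rep("A", 5)), "2 classes")
})

test_that("exact runs p equals brute-force enumeration up to n = 12", {
  set.seed(19)
  cases <- list(strsplit("AAAABBBB", "")[[1]],
                strsplit("AAABBBAB", "")[[1]],
                strsplit("ABBBBA", "")[[1]],
                strsplit("AABBBBBBBBAA", "")[[1]])
  for (rep in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    cases[[length(cases) + 1]] <- sample(c(rep("A", n1), rep("B", n2)))
  }
  for (lab in cases) {
    expect_equal(runs_test(lab)$p_one_tailed, oracle_runs_p(lab),
                 tolerance = 1e-12, label = paste(lab, collapse = ""))
  }
})

test_that("normal approximation tracks the exact tail at n1 = n2 = 10", {
  # exact at n = 20 (the implementation boundary) vs the continuity-
  # corrected normal tail, checked over the plausible clustering range
  n1 <- 10; n2 <- 10; n <- 20
  mu <- 1 + 2 * n1 * n2 / n
  sig <- sqrt(2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1)))
  seq_with_runs <- function(r) {
    # alternate A/B blocks: na A-blocks and nb B-blocks, first blocks of
    # size 1 and the remainder loaded into the last block of each class
    na <- ceiling(r / 2); nb <- r - na
    a_sizes <- c(rep(1, na - 1), n1 - (na - 1))
    b_sizes <- if (nb > 0) c(rep(1, nb - 1), n2 - (nb - 1)) else integer(0)
    x <- character(0)
    for (i in seq_len(na)) {
      x <- c(x, rep("A", a_sizes[i]),
             if (i <= nb) rep("B", b_sizes[i]) else NULL)
    }
    x
  }
  for (r_obs in 4:16) {
    x <- seq_with_runs(r_obs)
    r <- runs_test(x)
    expect_equal(r$runs_observed, r_obs)
    p_norm <- pnorm((r$runs_observed - mu + 0.5) / sig)
    expect_lt(abs(r$p_one_tailed - p_norm), 0.02)
  }
})

test_that("runs-test type-I error is near nominal under random shuffling", {
  set.seed(1234)
  labels <- c(rep("A", 50), rep("B", 50))
  rej <- mean(replicate(1000, {
    runs_test(sample(labels))$p_one_tailed <= 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("fragment test handles degenerate and deterministic cases", {
  aln0 <- codon_alignment(c(a = "ATGATG", b = "ATGATG", c = "ATGATG"),
                          mode = "codon")
  f0 <- fragment_permutation_test(aln0, n_perm = 50, seed = 1)
  expect_equal(f0$p_global, 1)
  expect_equal(f0$n_polymorphic, 0L)
  expect_equal(nrow(f0$fragments), 0L)

  set.seed(40)
  base <- random_cds(60)
  aln <- codon_alignment(c(a = base,
                           b = mutate_cds(base, 0.3),
                           c = mutate_cds(base, 0.3)),
                         mode = "codon")
  fa <- fragment_permutation_test(aln, n_perm = 300, seed = 5)
  fb <- fragment_permutation_test(aln, n_perm = 300, seed = 5)
  expect_identical(fa, fb)
  expect_true(all(fa$fragments$cond_end <= fa$n_polymorphic))
  expect_error(fragment_permutation_test(aln, n_perm = 10),
               "seed")
})

test_that("a shared tract between two otherwise diverged sequences is
           detected by the fragment test", {
  # three sequences, pairwise diverged; b and c made identical over a long
  # contiguous tract (a conversion signature)
  set.seed(61)
  base <- random_cds(120)
  a <- mutate_cds(base, 0.35)
  b <- mutate_cds(base, 0.35)
  cc <- mutate_cds(base, 0.35)
  tract <- 101:260  # columns
  bv <- strsplit(b, "")[[1]]; cv <- strsplit(cc, "")[[1]]
  cv[tract] <- bv[tract]
  aln <- codon_alignment(c(a = a, b = b, c = paste0(cv, collapse = "")),
                         mode = "codon")
  f <- fragment_permutation_test(aln, n_perm = 500, seed = 77)
  expect_lte(f$p_global, 0.01)
  best <- f$fragments[which.max(f$fragments$score), ]
  expect_setequal(c(best$id1, best$id2), c("b", "c"))
  expect_true(best$aln_start >= 90 && best$aln_end <= 270)
})

test_that("fragment-test p-values are super-uniform under the null", {
  set.seed(88)
  rej <- mean(replicate(120, {
    base <- random_cds(50)
    aln <- codon_alignment(c(a = mutate_cds(base, 0.3),
                             b = mutate_cds(base, 0.3),
                             c = mutate_cds(base, 0.3)),
                           mode = "codon")
    fragment_permutation_test(aln, n_perm = 99,
                              seed = sample.int(1e6, 1))$p_global <= 0.05
  }))
  expect_lte(rej, 0.12)  # 120 replicates; tighter bound in the large run
})

test_that("low-divergence regions are delineated by the pooled Z test", {
  mk_profile <- function(p_vec, n_sites = 500) {
    n_diff <- round(p_vec * n_sites)
    out <- data.frame(start = seq(0, by = 500, length.out = length(p_vec)),
                      end = seq(500, by = 500, length.out = length(p_vec)),
                      n_sites = n_sites, n_diff = n_diff,
                      p = n_diff / n_sites, reliable = TRUE)
    attr(out, "window_size") <- 500L
    class(out) <- c("window_profile", "data.frame")
    out
  }
  flat <- mk_profile(rep(0.5, 12))
  expect_equal(nrow(detect_low_divergence(flat)), 0L)

  prof <- mk_profile(c(rep(0.6, 16), rep(0.3, 4)))
  reg <- detect_low_divergence(prof)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 16 * 500)
  expect_equal(reg$end, 20 * 500)
  expect_equal(reg$n_windows, 4L)
  expect_lt(reg$p_value, 0.001)

  # a single dipped window is ignored at min_windows = 2
  single <- mk_profile(c(rep(0.6, 10), 0.25, rep(0.6, 9)))
  expect_equal(nrow(detect_low_divergence(single, min_windows = 2)), 0L)

  few <- mk_profile(rep(0.5, 3))
  expect_error(detect_low_divergence(few), "4 reliable")
})

test_that("regions export as 0-based half-open BED", {
  reg <- data.frame(start = 8000L, end = 10000L, n_windows = 4L,
                    p_inside = 0.3, p_outside = 0.6, Z = 12.1,
                    p_value = 1e-30)
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, f)
  lines <- readLines(f)
  expect_match(lines[1], "^alignment\t8000\t10000\tlow_divergence_1")
})
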