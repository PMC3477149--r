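# Ectopic gene-conversion evidence: spatial clustering of informative sites
# (two-sample runs test), a permutation global fragment test, and
# delineation of significantly low-divergence window regions.

# Exact distribution of the number of runs in a random arrangement of n1
# and n2 labels: number of arrangements with exactly r runs, divided by
# choose(n1 + n2, n1). Closed-form combinatorial identity; equals full
# enumeration of all arrangements.
runs_exact_cdf <- function(r_obs, n1, n2) {
  count_r <- function(r) {
    if (r %% 2L == 0L) {
      k <- r %/% 2L
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1)
    } else {
      k <- (r - 1L) %/% 2L
      choose(n1 - 1, k - 1) * choose(n2 - 1, k) +
        choose(n1 - 1, k) * choose(n2 - 1, k - 1)
    }
  }
  sum(vapply(2:r_obs, count_r, numeric(1L))) / choose(n1 + n2, n1)
}

#' Two-sample runs test for clustering
#'
#' Tests whether an ordered two-class label sequence (here: topology classes
#' of informative sites, in alignment order) has fewer runs than expected
#' under random interleaving — the one-tailed clustering alternative. Gene
#' conversion in a tract produces a block of one class and hence few runs.
#' The p-value is exact (full distribution of the run count) when
#' `n1 + n2 <= 20`, otherwise a normal approximation with continuity
#' correction is used.
#'
#' @param labels Vector over exactly two distinct values, in positional
#'   order.
#' @return A `runs_test` list: `n1`, `n2`, `runs_observed`, `p_one_tailed`,
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' runs_test(strsplit("AAAABBBB", "")[[1]])  # p = 2/70
#' @export
runs_test <- function(labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) {
    stop("labels must contain exactly 2 classes (got ", length(lev), ")",
         call. = FALSE)
  }
  n1 <- sum(labels == lev[1L]); n2 <- sum(labels == lev[2L])
  r <- 1L + sum(labels[-1L] != labels[-length(labels)])
  n <- n1 + n2
  if (n <= 20L) {
    p <- runs_exact_cdf(r, n1, n2)
    method <- "exact"
  } else {
    mu <- 1 + 2 * n1 * n2 / n
    sig2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    p <- stats::pnorm((r - mu + 0.5) / sqrt(sig2))
    method <- "normal"
  }
  structure(list(n1 = n1, n2 = n2, runs_observed = r,
                 p_one_tailed = min(max(p, 0), 1), method = method),
            class = "runs_test")
}

#' @export
print.runs_test <- function(x, ...) {
  cat(sprintf("runs test: n1 = %d, n2 = %d, runs = %d, one-tailed p = %.4g (%s)\n",
              x$n1, x$n2, x$runs_observed, x$p_one_tailed, x$method))
  invisible(x)
}

#' Permutation global fragment test for gene conversion
#'
#' A global inner-fragment test in the spirit of Sawyer's statistic: the
#' alignment is condensed to its polymorphic columns; for every sequence
#' pair the score is the length (in polymorphic sites) of the longest run of
#' consecutive condensed columns at which the pair is identical; the global
#' statistic is the maximum score over pairs. Significance comes from
#' permuting the condensed column order (`n_perm` permutations), which
#' destroys spatial clustering while preserving per-column configurations;
#' taking the maximum over pairs inside each permutation controls for
#' multiplicity. The p-value uses the add-one estimator
#' `(1 + #{perm >= obs}) / (1 + n_perm)`, so it is never zero. Only
#' mismatch-free fragments are scored; mismatch-penalised and outer
#' fragments are not implemented.
#'
#' @param aln A `codon_alignment` with at least 3 sequences.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed (required).
#' @return A `fragment_test` list: `observed` (max score), `p_global`,
#'   `fragments` (data.frame per pair: ids, score, condensed and alignment
#'   coordinates of the best fragment), `n_polymorphic`, `n_perm`, `seed`.
#'   With no polymorphic columns, `p_global = 1` and no fragments.
#' @export
fragment_permutation_test <- function(aln, n_perm = 10000L, seed) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  mat <- aln$mat
  if (nrow(mat) < 3L) stop("fragment test needs >= 3 sequences", call. = FALSE)
  good <- apply(mat, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  poly <- good & apply(mat, 2L, function(col) length(unique(col)) > 1L)
  cols <- which(poly)
  empty <- structure(list(observed = 0L, p_global = 1,
                          fragments = data.frame(), n_polymorphic = 0L,
                          n_perm = n_perm, seed = seed),
                     class = "fragment_test")
  if (length(cols) == 0L) return(empty)
  cmat <- mat[, cols, drop = FALSE]
  ids <- rownames(cmat)
  n <- nrow(cmat)
  pair_idx <- utils::combn(n, 2L)
  longest_run <- function(eq) {
    if (!any(eq)) return(c(len = 0L, start = 0L, end = 0L))
    r <- rle(eq)
    runs <- which(r$values)
    lens <- r$lengths[runs]
    k <- runs[which.max(lens)]
    start <- if (k == 1L) 1L else sum(r$lengths[1:(k - 1L)]) + 1L
    c(len = max(lens), start = start, end = start + max(lens) - 1L)
  }
  eq_list <- lapply(seq_len(ncol(pair_idx)), function(k) {
    cmat[pair_idx[1L, k], ] == cmat[pair_idx[2L, k], ]
  })
  obs <- t(vapply(eq_list, longest_run, c(len = 0L, start = 0L, end = 0L)))
  observed <- max(obs[, "len"])
  perm_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ord <- sample.int(length(cols))
      max(vapply(eq_list, function(eq) longest_run(eq[ord])[["len"]],
                 integer(1L)))
    }, integer(1L))
  })
  p <- (1 + sum(perm_max >= observed)) / (1 + n_perm)
  frags <- data.frame(
    id1 = ids[pair_idx[1L, ]], id2 = ids[pair_idx[2L, ]],
    score = obs[, "len"],
    cond_start = obs[, "start"], cond_end = obs[, "end"],
    aln_start = ifelse(obs[, "len"] > 0L, cols[obs[, "start"]] - 1L, NA),
    aln_end = ifelse(obs[, "len"] > 0L, cols[obs[, "end"]] - 1L, NA),
    stringsAsFactors = FALSE)
  structure(list(observed = observed, p_global = p, fragments = frags,
                 n_polymorphic = length(cols), n_perm = n_perm, seed = seed),
            class = "fragment_test")
}

#' @export
print.fragment_test <- function(x, ...) {
  cat(sprintf(
    "fragment permutation test: %d polymorphic columns, max fragment = %d sites, global p = %.4g (%d permutations)\n",
    x$n_polymorphic, x$observed, x$p_global, x$n_perm))
  invisible(x)
}

#' Delineate significantly low-divergence regions
#'
#' Scans a [window_profile()] for maximal runs of at least `min_windows`
#' consecutive reliable windows whose per-window divergence lies below the
#' pooled divergence of all reliable windows, and keeps a run when the
#' pooled two-proportion Z test of inside vs outside sites rejects at
#' `p_threshold` (one-tailed, reduction direction). Such regions are the
#' window-profile signature of an ectopic conversion tract.
#'
#' @param profile A `window_profile`.
#' @param min_windows Minimum run length in windows (default 2; singleton
#'   dips are ignored as artifacts).
#' @param p_threshold Significance threshold for the pooled Z test
#'   (default 0.001).
#' @return data.frame of regions: `start`, `end` (alignment bp, 0-based
#'   half-open), `n_windows`, `p_inside`, `p_outside`, `Z`, `p_value`.
#'   Empty when nothing is significant.
#' @export
detect_low_divergence <- function(profile, min_windows = 2L,
                                  p_threshold = 0.001) {
  stopifnot(inherits(profile, "window_profile"))
  rel <- profile[profile$reliable & !is.na(profile$p), , drop = FALSE]
  if (nrow(rel) < 4L) {
    stop("need at least 4 reliable windows", call. = FALSE)
  }
  pooled <- sum(rel$n_diff) / sum(rel$n_sites)
  below <- rel$p < pooled
  runs <- rle(below)
  out <- list()
  pos <- 1L
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    if (runs$values[k] && len >= min_windows) {
      idx <- pos:(pos + len - 1L)
      din <- sum(rel$n_diff[idx]); nin <- sum(rel$n_sites[idx])
      dout <- sum(rel$n_diff[-idx]); nout <- sum(rel$n_sites[-idx])
      if (nin > 0L && nout > 0L) {
        p_in <- din / nin; p_out <- dout / nout
        p_pool <- (din + dout) / (nin + nout)
        se <- sqrt(p_pool * (1 - p_pool) * (1 / nin + 1 / nout))
        Z <- if (se > 0) (p_out - p_in) / se else 0
        pval <- stats::pnorm(-Z)  # one-tailed: inside lower than outside
        if (Z > 0 && pval < p_threshold) {
          out[[length(out) + 1L]] <- data.frame(
            start = rel$start[idx[1L]], end = rel$end[idx[len]],
            n_windows = len, p_inside = p_in, p_outside = p_out,
            Z = Z, p_value = pval)
        }
      }
    }
    pos <- pos + len
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      n_windows = integer(), p_inside = numeric(),
                      p_outside = numeric(), Z = numeric(),
                      p_value = numeric()))
  }
  do.call(rbind, out)
}

#' Write low-divergence regions as BED
#'
#' Regions are emitted against the alignment coordinate system, 0-based
#' half-open as BED requires.
#'
#' @param regions data.frame from [detect_low_divergence()].
#' @param path Output path.
#' @param name Feature name prefix (default `"low_divergence"`).
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, name = "low_divergence") {
  lines <- if (nrow(regions)) {
    sprintf("alignment\t%d\t%d\t%s_%d\t%g", regions$start, regions$end,
            name, seq_len(nrow(regions)), regions$Z)
  } else character()
  writeLines(lines, path)
  invisible(path)
}
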