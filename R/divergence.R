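# Synonymous divergence between gametologs: unweighted Nei-Gojobori site and
# difference counting with Jukes-Cantor multiple-hit correction.

# Standard genetic code, codon order: position 1 slowest, bases T,C,A,G.
.gc_bases <- c("T", "C", "A", "G")
.gc_aa <- strsplit(paste0(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
  "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1L]]
.gc_codons <- as.vector(t(outer(
  as.vector(t(outer(.gc_bases, .gc_bases, paste0))), .gc_bases, paste0)))

#' Standard genetic code
#'
#' Named character vector mapping the 64 codons (T-containing, upper case)
#' to one-letter amino acids, with `"*"` for stops.
#' @format Named character vector of length 64.
#' @export
GENETIC_CODE_STD <- stats::setNames(.gc_aa, .gc_codons)

.codon_cache <- new.env(parent = emptyenv())

is_stop_codon <- function(codon) !is.na(GENETIC_CODE_STD[codon]) &
  GENETIC_CODE_STD[codon] == "*"

#' Synonymous site count of a codon
#'
#' Unweighted Nei-Gojobori count: for each of the three positions, the
#' fraction of single-nucleotide changes that preserve the amino acid, with
#' changes creating a stop codon excluded from the denominator. The three
#' fractions are summed, so a 4-fold degenerate third position contributes 1
#' full synonymous site.
#'
#' @param codon A 3-mer over A/C/G/T encoding a sense codon.
#' @return Synonymous site count in `[0, 3]`.
#' @examples
#' syn_sites_of_codon("TGG")  # Trp: 0
#' syn_sites_of_codon("CTC")  # Leu: 1 (4-fold third position)
#' syn_sites_of_codon("TTT")  # Phe: 1/3
#' @export
syn_sites_of_codon <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("codon must be a 3-mer over A/C/G/T: ", codon, call. = FALSE)
  }
  aa <- GENETIC_CODE_STD[[codon]]
  if (aa == "*") stop("stop codon has no synonymous sites: ", codon,
                      call. = FALSE)
  s <- 0
  cv <- strsplit(codon, "")[[1L]]
  for (pos in 1:3) {
    syn <- 0L; denom <- 0L
    for (b in setdiff(.gc_bases, cv[pos])) {
      mut <- cv; mut[pos] <- b
      maa <- GENETIC_CODE_STD[[paste0(mut, collapse = "")]]
      if (maa == "*") next
      denom <- denom + 1L
      if (maa == aa) syn <- syn + 1L
    }
    if (denom > 0L) s <- s + syn / denom
  }
  s
}

# Average number of synonymous differences between two sense codons over all
# minimal substitution pathways that avoid stop-codon intermediates
# (equal pathway weights). NA if every pathway is blocked by a stop.
syn_diffs_between_codons <- function(c1, c2) {
  if (c1 == c2) return(0)
  v1 <- strsplit(c1, "")[[1L]]; v2 <- strsplit(c2, "")[[1L]]
  diff_pos <- which(v1 != v2)
  pm <- permn_matrix(length(diff_pos))
  tot <- 0; nvalid <- 0L
  for (r in seq_len(nrow(pm))) {
    ord <- diff_pos[pm[r, ]]
    cur <- v1; syn <- 0; ok <- TRUE
    for (pos in ord) {
      prev_aa <- GENETIC_CODE_STD[[paste0(cur, collapse = "")]]
      cur[pos] <- v2[pos]
      nxt_aa <- GENETIC_CODE_STD[[paste0(cur, collapse = "")]]
      if (nxt_aa == "*") { ok <- FALSE; break }  # endpoints are sense codons
      if (nxt_aa == prev_aa) syn <- syn + 1
    }
    if (ok) { tot <- tot + syn; nvalid <- nvalid + 1L }
  }
  if (nvalid == 0L) return(NA_real_)
  tot / nvalid
}

# All permutations of 1..n as rows (n <= 3 needed here).
permn_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permn_matrix(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Lazily built lookup tables over the 61 sense codons:
#   $sites  named numeric vector, NG synonymous sites per codon
#   $sd     61x61 matrix of pathway-averaged synonymous differences
codon_tables <- function() {
  if (!is.null(.codon_cache$tables)) return(.codon_cache$tables)
  sense <- .gc_codons[GENETIC_CODE_STD != "*"]
  sites <- vapply(sense, syn_sites_of_codon, numeric(1L))
  n <- length(sense)
  sd <- matrix(NA_real_, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) for (j in i:n) {
    v <- syn_diffs_between_codons(sense[i], sense[j])
    sd[i, j] <- v; sd[j, i] <- v
  }
  .codon_cache$tables <- list(sense = sense, sites = sites, sd = sd)
  .codon_cache$tables
}

#' Jukes-Cantor correction of a difference proportion
#'
#' `K = -(3/4) * log(1 - (4/3) * p)`, the one-parameter multiple-hit
#' correction. Saturated inputs (`p >= 0.75`) have no finite image and
#' return `NA` (batch semantics: reported as undefined, not an error).
#'
#' @param p Proportion of differences per site, `0 <= p`.
#' @return Corrected distance; `NA_real_` where `p >= 0.75`.
#' @examples
#' jc_correct(0.40)  # 0.57 to 2 decimals
#' @export
jc_correct <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("p must be >= 0", call. = FALSE)
  out <- ifelse(p < 0.75, -0.75 * log(1 - (4 / 3) * p), NA_real_)
  out
}

#' Pairwise synonymous divergence (unweighted Nei-Gojobori)
#'
#' Counts synonymous sites and synonymous differences between two aligned
#' in-frame coding sequences. Codon columns containing a gap or N in either
#' sequence, or a stop codon in either sequence, are excluded pairwise.
#' Synonymous differences are averaged with equal weight over all minimal
#' substitution pathways that avoid stop-codon intermediates. `S` is the
#' mean of the two sequences' summed site counts; `pS = Sd / S`; `KS` is
#' the Jukes-Cantor image of `pS` when `pS < 0.75`.
#'
#' Standard errors: `se_pS = sqrt(pS (1 - pS) / S)` (binomial over
#' synonymous sites; `NA` when `pS > 1`) and the delta-method
#' `se_KS = se_pS / (1 - 4 pS / 3)`.
#'
#' @param seq1,seq2 Equal-length in-frame coding sequences (strings over
#'   A/C/G/T/N/-).
#' @return A `syn_divergence` list: `n_codons` (complete codon pairs
#'   compared), `S`, `Sd`, `pS`, `KS`, `se_pS`, `se_KS`, `n_excluded`
#'   (gap/N/stop/blocked-pathway codon columns dropped).
#' @export
pairwise_syn <- function(seq1, seq2) {
  seq1 <- normalize_seq(seq1); seq2 <- normalize_seq(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned (equal length)",
                                       call. = FALSE)
  if (nchar(seq1) %% 3L != 0L) stop("sequence length must be a multiple of 3",
                                    call. = FALSE)
  tb <- codon_tables()
  starts <- seq(1L, nchar(seq1), by = 3L)
  c1 <- substring(seq1, starts, starts + 2L)
  c2 <- substring(seq2, starts, starts + 2L)
  ok <- c1 %in% tb$sense & c2 %in% tb$sense
  n_total <- length(starts)
  c1 <- c1[ok]; c2 <- c2[ok]
  sd_vals <- tb$sd[cbind(c1, c2)]
  blocked <- is.na(sd_vals)
  c1 <- c1[!blocked]; c2 <- c2[!blocked]; sd_vals <- sd_vals[!blocked]
  n_codons <- length(c1)
  if (n_codons == 0L) stop("no complete codon pairs to compare", call. = FALSE)
  S <- (sum(tb$sites[c1]) + sum(tb$sites[c2])) / 2
  if (S <= 0) stop("zero synonymous sites: divergence undefined", call. = FALSE)
  Sd <- sum(sd_vals)
  pS <- Sd / S
  KS <- if (pS < 0.75) jc_correct(pS) else NA_real_
  se_pS <- if (pS <= 1) sqrt(pS * (1 - pS) / S) else NA_real_
  se_KS <- if (!is.na(KS) && !is.na(se_pS)) se_pS / (1 - 4 * pS / 3) else NA_real_
  structure(list(n_codons = n_codons, S = S, Sd = Sd, pS = pS, KS = KS,
                 se_pS = se_pS, se_KS = se_KS,
                 n_excluded = n_total - n_codons),
            class = "syn_divergence")
}

#' @export
print.syn_divergence <- function(x, ...) {
  cat(sprintf(
    "syn_divergence: %d codons, S = %.2f, Sd = %.2f\n  pS = %.4f (se %.4f), KS = %s\n",
    x$n_codons, x$S, x$Sd, x$pS, x$se_pS,
    if (is.na(x$KS)) "undefined (saturated)"
    else sprintf("%.4f (se %.4f)", x$KS, x$se_KS)))
  invisible(x)
}

#' Average divergence over all X-copy by Y-copy pairs
#'
#' Genes with multiple X or Y copies are summarised by the arithmetic mean of
#' the pairwise `pS` (and of `KS`) over all X-by-Y pairs, with standard
#' errors averaged the same way.
#'
#' @param aln A codon-mode `codon_alignment`.
#' @param x_ids,y_ids Record ids of the X and Y copies.
#' @return A `syn_divergence` with the averaged `pS`/`KS` and a `pairs`
#'   attribute holding the per-pair results.
#' @export
mean_syn_divergence <- function(aln, x_ids, y_ids) {
  seqs <- aln_seqs(aln)
  miss <- setdiff(c(x_ids, y_ids), names(seqs))
  if (length(miss)) stop("taxa not found: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  pairs <- list()
  for (x in x_ids) for (y in y_ids) {
    pairs[[paste(x, y, sep = "|")]] <- pairwise_syn(seqs[[x]], seqs[[y]])
  }
  agg <- function(f) mean(vapply(pairs, function(p) p[[f]], numeric(1L)))
  out <- structure(list(
    n_codons = round(agg("n_codons")), S = agg("S"), Sd = agg("Sd"),
    pS = agg("pS"), KS = agg("KS"), se_pS = agg("se_pS"),
    se_KS = agg("se_KS"), n_excluded = round(agg("n_excluded"))),
    class = "syn_divergence")
  attr(out, "pairs") <- pairs
  out
}

#' Two-sample Z comparison of divergence estimates
#'
#' `Z = |d1 - d2| / sqrt(se1^2 + se2^2)` with a two-tailed standard-normal
#' p-value; used to compare divergences between lineages or gene regions.
#'
#' @param d1,d2 Divergence estimates.
#' @param se1,se2 Their standard errors (not both zero).
#' @return List with `Z` and `p_value`.
#' @export
z_compare <- function(d1, se1, d2, se2) {
  if (se1 < 0 || se2 < 0) stop("standard errors must be >= 0", call. = FALSE)
  if (se1 == 0 && se2 == 0) stop("both standard errors are zero", call. = FALSE)
  Z <- abs(d1 - d2) / sqrt(se1^2 + se2^2)
  list(Z = Z, p_value = 2 * stats::pnorm(-Z))
}

#' Sliding-window nucleotide divergence
#'
#' Non-overlapping windows along an aligned genomic sequence pair; per
#' window, the proportion of differing sites among sites where both
#' sequences have an unambiguous base (gap/N columns pairwise-deleted).
#' Windows with fewer than `window_size / 2` compared sites, and any trailing
#' partial window, are flagged unreliable.
#'
#' @param seq1,seq2 Equal-length aligned sequences (strings), or a 2-row
#'   genomic `codon_alignment` may be split with [aln_seqs()].
#' @param window_size Window width in alignment columns (default 500).
#' @return A `window_profile` data.frame: `start`, `end` (0-based half-open
#'   alignment columns), `n_sites`, `n_diff`, `p`, `reliable`.
#' @export
window_profile <- function(seq1, seq2, window_size = 500L) {
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1L) {
    stop("window_size must be a positive integer", call. = FALSE)
  }
  seq1 <- normalize_seq(seq1); seq2 <- normalize_seq(seq2)
  if (nchar(seq1) != nchar(seq2)) stop("sequences must be aligned (equal length)",
                                       call. = FALSE)
  v1 <- strsplit(seq1, "")[[1L]]; v2 <- strsplit(seq2, "")[[1L]]
  L <- length(v1)
  comp <- v1 %in% c("A", "C", "G", "T") & v2 %in% c("A", "C", "G", "T")
  diffs <- comp & v1 != v2
  starts <- seq(0L, L - 1L, by = window_size)
  ends <- pmin(starts + window_size, L)
  n_sites <- vapply(seq_along(starts),
                    function(i) sum(comp[(starts[i] + 1L):ends[i]]), integer(1L))
  n_diff <- vapply(seq_along(starts),
                   function(i) sum(diffs[(starts[i] + 1L):ends[i]]), integer(1L))
  p <- ifelse(n_sites > 0L, n_diff / n_sites, NA_real_)
  reliable <- n_sites >= window_size / 2 & (ends - starts) == window_size
  out <- data.frame(start = starts, end = ends, n_sites = n_sites,
                    n_diff = n_diff, p = p, reliable = reliable)
  attr(out, "window_size") <- window_size
  class(out) <- c("window_profile", "data.frame")
  out
}
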