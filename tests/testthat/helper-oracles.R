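# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.
#
# - The synonymous-site/difference oracle enumerates every mutant and every
#   substitution pathway literally, using seqinr's genetic code for
#   translation (an independent code source).
# - The runs-test oracle enumerates all C(n1+n2, n1) label arrangements.

oracle_translate <- function(codon_chars) {
  seqinr::translate(codon_chars, numcode = 1)
}

oracle_syn_sites <- function(codon) {
  cv <- strsplit(codon, "")[[1]]
  aa <- oracle_translate(cv)
  total <- 0
  for (pos in 1:3) {
    muts <- setdiff(c("A", "C", "G", "T"), cv[pos])
    aas <- sapply(muts, function(b) {
      m <- cv; m[pos] <- b; oracle_translate(m)
    })
    non_stop <- aas[aas != "*"]
    if (length(non_stop) > 0) total <- total + mean(non_stop == aa)
  }
  total
}

# Average synonymous differences between two sense codons over all minimal
# pathways avoiding stop intermediates; NA if all pathways blocked.
oracle_syn_diffs <- function(c1, c2) {
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  dpos <- which(v1 != v2)
  if (length(dpos) == 0) return(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  syn_counts <- c()
  for (ord in perms(dpos)) {
    cur <- v1; syn <- 0; blocked <- FALSE
    for (pos in ord) {
      before <- oracle_translate(cur)
      cur[pos] <- v2[pos]
      after <- oracle_translate(cur)
      if (after == "*") { blocked <- TRUE; break }
      if (after == before) syn <- syn + 1
    }
    if (!blocked) syn_counts <- c(syn_counts, syn)
  }
  if (length(syn_counts) == 0) NA_real_ else mean(syn_counts)
}

# Full pairwise oracle over aligned coding strings (gap/N/stop codons
# excluded pairwise, like the implementation contract states).
oracle_pairwise_syn <- function(seq1, seq2) {
  st <- seq(1, nchar(seq1), by = 3)
  c1 <- substring(toupper(seq1), st, st + 2)
  c2 <- substring(toupper(seq2), st, st + 2)
  S <- 0; Sd <- 0; n <- 0
  for (k in seq_along(c1)) {
    if (grepl("[^ACGT]", c1[k]) || grepl("[^ACGT]", c2[k])) next
    if (oracle_translate(strsplit(c1[k], "")[[1]]) == "*" ||
        oracle_translate(strsplit(c2[k], "")[[1]]) == "*") next
    d <- oracle_syn_diffs(c1[k], c2[k])
    if (is.na(d)) next
    S <- S + (oracle_syn_sites(c1[k]) + oracle_syn_sites(c2[k])) / 2
    Sd <- Sd + d
    n <- n + 1
  }
  list(S = S, Sd = Sd, pS = if (S > 0) Sd / S else NA_real_, n_codons = n)
}

# Exact one-tailed clustering p by literal enumeration of all arrangements.
oracle_runs_p <- function(labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  n <- length(labels); n1 <- sum(labels == lev[1])
  count_runs <- function(x) 1 + sum(x[-1] != x[-length(x)])
  r_obs <- count_runs(labels)
  placements <- utils::combn(n, n1)
  rs <- apply(placements, 2, function(idx) {
    x <- rep("b", n); x[idx] <- "a"; count_runs(x)
  })
  mean(rs <= r_obs)
}

# Random sense-codon coding string of n codons (no stops).
random_cds <- function(n_codons) {
  sense <- names(gametolog::GENETIC_CODE_STD)[gametolog::GENETIC_CODE_STD != "*"]
  paste0(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Mutate a coding string: per-position substitutions with prob p_sub, and
# optionally overwrite whole codons with gaps or N.
mutate_cds <- function(seq, p_sub = 0.3, p_gap_codon = 0, p_n_codon = 0) {
  v <- strsplit(seq, "")[[1]]
  hit <- runif(length(v)) < p_sub
  v[hit] <- sapply(v[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1))
  n_cod <- length(v) / 3
  for (k in seq_len(n_cod)) {
    u <- runif(1)
    if (u < p_gap_codon) v[(3 * k - 2):(3 * k)] <- "-"
    else if (u < p_gap_codon + p_n_codon) v[(3 * k - 2):(3 * k)] <- "N"
  }
  paste0(v, collapse = "")
}

# Small deterministic codon alignment for I/O and pipeline tests.
toy_alignment <- function() {
  codon_alignment(
    c(EutX = "ATGGCTACTTGTCCTGGA",
      EutY = "ATGGCAACATGTCCAGGA",
      MarX = "ATGGCTACCTGTCCTGGT",
      MarY = "ATGGCGACATGCCCAGGA"),
    tags = list(
      EutX = taxon_tag("Eut", "X", "eutherian"),
      EutY = taxon_tag("Eut", "Y", "eutherian"),
      MarX = taxon_tag("Mar", "X", "marsupial"),
      MarY = taxon_tag("Mar", "Y", "marsupial")),
    mode = "codon")
}
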