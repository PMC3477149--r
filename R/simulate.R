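# Forward simulator of gametolog evolution: a proto-sex-chromosome pair
# stops recombining at T_arrest, the X and Y copies then evolve under
# sex-biased rates, speciation at T_split creates eutherian and marsupial
# lineages, and optional ectopic conversion events overwrite tracts of the
# recipient with the donor copy. Emits alignments plus a ground-truth
# ledger so every analysis stage is testable without external data.

#' Simulation configuration
#'
#' Times are years before present; rates are per site per year. Branch
#' rates follow the male-biased model: X lineages evolve at
#' `(2/3 + alpha/3) m_f`, Y lineages at `alpha m_f`, and pre-arrest /
#' autosomal / outgroup branches at `(1 + alpha)/2 m_f`.
#'
#' @param n_codons Number of codons (codon mode) or `n_sites` free sites
#'   (nucleotide mode) per sequence.
#' @param mode `"codon"`: a 4-fold-degenerate scaffold in which codon
#'   positions 1-2 are frozen and every third-position change is synonymous,
#'   so the Nei-Gojobori `S` equals `n_codons` exactly. `"nucleotide"`:
#'   free sites under plain JC69, for window/conversion analyses.
#' @param n_sites Sequence length in nucleotide mode (defaults to
#'   `3 * n_codons`).
#' @param T_arrest X/Y recombination arrest time (start of gametolog
#'   divergence).
#' @param T_split Eutherian-marsupial speciation time (`<= T_arrest`).
#' @param T_outgroup Outgroup (monotreme-like) split time (`>= T_arrest`).
#' @param m_f Female germ-line mutation rate per site per year.
#' @param alpha Male/female mutation-rate ratio.
#' @param conversion_events List of events, each a list with `clade`
#'   (`"eutherian"` or `"marsupial"`), `direction` (`"Y->X"` or `"X->Y"`),
#'   `region` = `c(start, end)` (0-based half-open, codon units in codon
#'   mode, site units otherwise), `t_event` years before present
#'   (`< T_split`).
#' @param include_outgroup Add an autosomal-rate outgroup sequence.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_codons = 1000L,
                       mode = c("codon", "nucleotide"),
                       n_sites = NULL,
                       T_arrest = 2.0e8, T_split = 1.7e8,
                       T_outgroup = 2.24e8,
                       m_f = 2e-9, alpha = 2,
                       conversion_events = list(),
                       include_outgroup = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  n_codons <- as.integer(n_codons)
  if (mode == "nucleotide" && is.null(n_sites)) n_sites <- 3L * n_codons
  n_units <- if (mode == "codon") n_codons else as.integer(n_sites)
  if (is.na(n_units) || n_units < 1L) stop("sequence length must be >= 1",
                                           call. = FALSE)
  if (!(T_arrest >= T_split && T_split > 0)) {
    stop("need T_arrest >= T_split > 0", call. = FALSE)
  }
  if (T_outgroup < T_arrest) stop("outgroup must split before arrest (T_outgroup >= T_arrest)",
                                  call. = FALSE)
  if (m_f < 0 || alpha <= 0) stop("need m_f >= 0 and alpha > 0", call. = FALSE)
  for (ev in conversion_events) {
    if (!all(c("clade", "direction", "region", "t_event") %in% names(ev))) {
      stop("conversion event needs clade, direction, region, t_event",
           call. = FALSE)
    }
    if (!ev$clade %in% c("eutherian", "marsupial")) {
      stop("event clade must be eutherian or marsupial", call. = FALSE)
    }
    if (!ev$direction %in% c("Y->X", "X->Y")) {
      stop("event direction must be 'Y->X' or 'X->Y'", call. = FALSE)
    }
    r <- ev$region
    if (length(r) != 2L || r[1L] < 0 || r[1L] >= r[2L] || r[2L] > n_units) {
      stop("event region out of bounds", call. = FALSE)
    }
    if (!(ev$t_event >= 0 && ev$t_event < T_split)) {
      stop("need T_split > t_event >= 0 for every event", call. = FALSE)
    }
  }
  structure(list(n_codons = n_codons, mode = mode, n_units = n_units,
                 T_arrest = T_arrest, T_split = T_split,
                 T_outgroup = T_outgroup, m_f = m_f, alpha = alpha,
                 conversion_events = conversion_events,
                 include_outgroup = isTRUE(include_outgroup),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# JC69 segment evolution on an integer base vector (values 0..3).
# Realized substitution events are Poisson(d * L); the end state of a site
# hit k times is resampled from the exact k-step JC chain:
# P(same) = 1/4 + (3/4)(-1/3)^k. Returns list(seq, n_events).
evolve_jc <- function(seq_int, d) {
  L <- length(seq_int)
  n <- stats::rpois(1L, d * L)
  if (n > 0L) {
    hits <- tabulate(sample.int(L, n, replace = TRUE), nbins = L)
    hit_sites <- which(hits > 0L)
    k <- hits[hit_sites]
    p_same <- 1 / 4 + (3 / 4) * (-1 / 3)^k
    change <- stats::runif(length(hit_sites)) >= p_same
    ch <- hit_sites[change]
    if (length(ch)) {
      seq_int[ch] <- (seq_int[ch] +
                        sample.int(3L, length(ch), replace = TRUE)) %% 4L
    }
  }
  list(seq = seq_int, n_events = n)
}

#' Simulate a gametolog alignment with ground truth
#'
#' Evolves a root sequence down the gametolog tree: outgroup splits at
#' `T_outgroup`, recombination arrest duplicates the proto-gene into X and
#' Y copies at `T_arrest`, speciation at `T_split` yields the four
#' gametolog lineages EX, EY, MX, MY, and conversion events replace the
#' recipient's tract with the donor copy at `t_event`. Substitutions are
#' Poisson under JC69; in codon mode only third positions mutate, so every
#' change is synonymous by construction. Branches are evolved in a fixed
#' documented order (outgroup, XY stem, X stem, Y stem, then eutherian
#' X/Y and marsupial X/Y with event breakpoints), so identical seeds give
#' identical alignments.
#'
#' @param cfg A [sim_config()].
#' @return List with `aln` (a `codon_alignment` with taxa `EutX`, `EutY`,
#'   `MarX`, `MarY` and optionally `Out`) and `truth` (a `sim_truth` list:
#'   per-branch realized substitution counts, branch rates, converted-region
#'   coordinates in alignment columns, and expected pairwise divergences
#'   overall and per converted region).
#' @export
simulate_gametologs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  r_X <- (2 / 3 + cfg$alpha / 3) * cfg$m_f
  r_Y <- cfg$alpha * cfg$m_f
  r_A <- (1 + cfg$alpha) / 2 * cfg$m_f
  n <- cfg$n_units
  bases <- c("A", "C", "G", "T")
  events_of <- function(clade) {
    evs <- Filter(function(e) e$clade == clade, cfg$conversion_events)
    evs[order(-vapply(evs, function(e) e$t_event, numeric(1L)))]
  }
  res <- with_seed(cfg$seed, {
    counts <- list()
    root <- sample.int(4L, n, replace = TRUE) - 1L
    prefixes <- if (cfg$mode == "codon") {
      # 4-fold families whose codons carry exactly 1 synonymous site
      # (Leu CTN and Arg CGN are excluded: synonymous first-position
      # changes there would make S exceed n_codons)
      fams <- c("GT", "TC", "CC", "AC", "GC", "GG")
      sample(fams, n, replace = TRUE)
    } else NULL
    out_seq <- NULL
    if (cfg$include_outgroup) {
      e <- evolve_jc(root, r_A * cfg$T_outgroup)
      out_seq <- e$seq; counts$outgroup <- e$n_events
    }
    e <- evolve_jc(root, r_A * (cfg$T_outgroup - cfg$T_arrest))
    xy_anc <- e$seq; counts$xy_stem <- e$n_events
    e <- evolve_jc(xy_anc, r_X * (cfg$T_arrest - cfg$T_split))
    x_anc <- e$seq; counts$x_stem <- e$n_events
    e <- evolve_jc(xy_anc, r_Y * (cfg$T_arrest - cfg$T_split))
    y_anc <- e$seq; counts$y_stem <- e$n_events
    tips <- list()
    for (clade in c("eutherian", "marsupial")) {
      x <- x_anc; y <- y_anc
      t_now <- cfg$T_split
      key <- if (clade == "eutherian") "Eut" else "Mar"
      counts[[paste0(key, "X")]] <- 0L
      counts[[paste0(key, "Y")]] <- 0L
      for (ev in c(events_of(clade), list(NULL))) {
        t_next <- if (is.null(ev)) 0 else ev$t_event
        ex <- evolve_jc(x, r_X * (t_now - t_next))
        ey <- evolve_jc(y, r_Y * (t_now - t_next))
        x <- ex$seq; y <- ey$seq
        counts[[paste0(key, "X")]] <- counts[[paste0(key, "X")]] + ex$n_events
        counts[[paste0(key, "Y")]] <- counts[[paste0(key, "Y")]] + ey$n_events
        if (!is.null(ev)) {
          idx <- (ev$region[1L] + 1L):ev$region[2L]
          if (ev$direction == "Y->X") x[idx] <- y[idx] else y[idx] <- x[idx]
        }
        t_now <- t_next
      }
      tips[[paste0(key, "X")]] <- x
      tips[[paste0(key, "Y")]] <- y
    }
    list(counts = counts, tips = tips, out_seq = out_seq,
         prefixes = prefixes)
  })
  to_string <- function(third) {
    if (cfg$mode == "codon") {
      paste0(paste0(res$prefixes, bases[third + 1L]), collapse = "")
    } else paste0(bases[third + 1L], collapse = "")
  }
  seqs <- vapply(res$tips, to_string, character(1L))
  tags <- list(
    EutX = taxon_tag("Eut", "X", "eutherian"),
    EutY = taxon_tag("Eut", "Y", "eutherian"),
    MarX = taxon_tag("Mar", "X", "marsupial"),
    MarY = taxon_tag("Mar", "Y", "marsupial"))
  if (cfg$include_outgroup) {
    seqs <- c(seqs, Out = to_string(res$out_seq))
    tags$Out <- taxon_tag("Out", "autosome", "outgroup")
  }
  aln <- codon_alignment(seqs, tags = tags,
                         mode = if (cfg$mode == "codon") "codon" else "genomic")
  unit <- if (cfg$mode == "codon") 3L else 1L
  # third positions within a codon: region [a,b) in units -> columns
  conv_regions <- lapply(cfg$conversion_events, function(ev) {
    list(clade = ev$clade, direction = ev$direction,
         region_units = ev$region,
         aln_start = ev$region[1L] * unit, aln_end = ev$region[2L] * unit,
         t_event = ev$t_event,
         expected_d_xy = (r_X + r_Y) * ev$t_event)
  })
  jc_p <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  truth <- structure(list(
    rates = list(m_X = r_X, m_Y = r_Y, m_A = r_A, m_f = cfg$m_f,
                 alpha = cfg$alpha),
    branch_events = res$counts,
    converted_regions = conv_regions,
    expected_d = list(
      EX_EY = (r_X + r_Y) * cfg$T_arrest,
      EX_MX = 2 * r_X * cfg$T_split,
      EY_MY = 2 * r_Y * cfg$T_split),
    expected_p = list(
      EX_EY = jc_p((r_X + r_Y) * cfg$T_arrest),
      EX_MX = jc_p(2 * r_X * cfg$T_split),
      EY_MY = jc_p(2 * r_Y * cfg$T_split)),
    config = cfg), class = "sim_truth")
  list(aln = aln, truth = truth)
}

#' Write a simulated fixture to disk
#'
#' Emits the file set every pipeline stage can consume: an aligned FASTA,
#' the sidecar taxon TSV, and the ground-truth ledger as JSON. Output is
#' byte-identical for identical inputs.
#'
#' @param aln A `codon_alignment` from [simulate_gametologs()].
#' @param truth The matching `sim_truth`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(aln, truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta <- file.path(dir, "alignment.fasta")
  tsv <- file.path(dir, "taxa.tsv")
  json <- file.path(dir, "truth.json")
  write_alignment(aln, fasta)
  utils::write.table(aln$taxa, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tr <- truth
  tr$config <- unclass(tr$config)
  jsonlite::write_json(unclass(tr), json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(fasta = fasta, taxa = tsv, truth = json))
}
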