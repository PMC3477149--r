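# End-to-end per-gene analysis: divergence table -> NJ + bootstrap tree ->
# informative-site partition -> conversion tests -> window regions ->
# optional dating. Each stage error is re-thrown with the stage name
# attached so failures in composite runs are attributable.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full per-gene gametolog analysis
#'
#' Composes the package's operations over one gene's alignments and emits a
#' structured report. All thresholds carry the conventional defaults
#' (500-bp windows, 1000 bootstrap replicates, 10,000 permutations,
#' region significance P < 0.001, alpha = 2) and are overridable through
#' `config`.
#'
#' @param config A list with components:
#'   \describe{
#'     \item{gene}{Gene name for the report.}
#'     \item{alignment}{Codon `codon_alignment`, or FASTA path.}
#'     \item{tags}{Optional taxon-map TSV path or named `taxon_tag` list
#'       (used when `alignment` is a path).}
#'     \item{pairs}{Optional list of X/Y pair specs, each
#'       `list(label =, x_ids =, y_ids =)`; defaults to one pair per
#'       species code having both X- and Y-tagged rows.}
#'     \item{roles}{Optional named ids `c(EX=, EY=, MX=, MY=)` for the
#'       quartet informative-site partition and runs test.}
#'     \item{outgroup}{Optional outgroup id for clade queries.}
#'     \item{regions}{Optional named character vector of 1-based inclusive
#'       region strings (e.g. `c(a = "1-1000")`); each gets a sub-report.}
#'     \item{genomic}{Optional `list(alignment = <genomic codon_alignment
#'       or FASTA path>, pair = c(id1, id2))` for window analysis.}
#'     \item{dating}{Optional `list(KS =, m_A_lo =, m_A_hi =, alpha = 2,
#'       rounding = "full-precision")`.}
#'     \item{seed}{Seed for bootstrap/permutations (default 1).}
#'     \item{bootstrap_reps, n_perm, window_size, min_windows,
#'       region_p_threshold}{Analysis knobs with the defaults above.}
#'     \item{out_dir}{Optional directory; when given, TSV/newick/BED/JSON
#'       outputs are written there.}
#'   }
#' @return A `gene_report` list: `divergence` (per-pair table),
#'   `tree` (bootstrapped `phylo`), `monophyly` (X and Y cluster queries if
#'   an outgroup is given), `sites` (informative-site partition),
#'   `runs` (runs test on A-vs-B site classes), `fragment`
#'   (permutation fragment test), `windows` + `regions` (genomic profile),
#'   `region_reports` (per-region divergence sub-tables), `dating`, `log`.
#' @export
run_gene <- function(config) {
  cfg <- config
  if (is.null(cfg$gene)) cfg$gene <- "gene"
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  reps <- if (is.null(cfg$bootstrap_reps)) 1000L else cfg$bootstrap_reps
  n_perm <- if (is.null(cfg$n_perm)) 10000L else cfg$n_perm
  wsize <- if (is.null(cfg$window_size)) 500L else cfg$window_size
  minw <- if (is.null(cfg$min_windows)) 2L else cfg$min_windows
  pthr <- if (is.null(cfg$region_p_threshold)) 0.001 else cfg$region_p_threshold
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  aln <- stage("alignment_io", {
    if (inherits(cfg$alignment, "codon_alignment")) cfg$alignment
    else {
      tags <- cfg$tags
      if (is.character(tags)) tags <- read_taxon_map(tags)
      read_alignment(cfg$alignment, mode = "codon", tags = tags)
    }
  })

  pairs <- cfg$pairs
  if (is.null(pairs)) {
    pairs <- list()
    for (sp in unique(aln$taxa$species_code)) {
      xs <- aln$taxa$id[aln$taxa$species_code == sp & aln$taxa$chromosome == "X"]
      ys <- aln$taxa$id[aln$taxa$species_code == sp & aln$taxa$chromosome == "Y"]
      if (length(xs) && length(ys)) {
        pairs[[length(pairs) + 1L]] <- list(label = sp, x_ids = xs, y_ids = ys)
      }
    }
  }

  div_table <- stage("divergence", {
    rows <- lapply(pairs, function(p) {
      d <- mean_syn_divergence(aln, p$x_ids, p$y_ids)
      if (d$n_excluded > 0L) {
        note("divergence %s: %d codon columns excluded (gap/N/stop)",
             p$label, d$n_excluded)
      }
      data.frame(pair = p$label, n_codons = d$n_codons, S = d$S, Sd = d$Sd,
                 pS = d$pS, se_pS = d$se_pS, KS = d$KS, se_KS = d$se_KS)
    })
    do.call(rbind, rows)
  })

  tree <- stage("phylogeny", {
    tr <- bootstrap_nj(aln, reps = reps, seed = seed)
    nc <- attr(tr, "n_clamped")
    if (!is.null(nc) && nc > 0L) note("phylogeny: %d branch clamps", nc)
    tr
  })

  monophyly <- NULL
  if (!is.null(cfg$outgroup)) {
    monophyly <- stage("phylogeny", {
      xs <- setdiff(aln$taxa$id[aln$taxa$chromosome == "X"], cfg$outgroup)
      ys <- setdiff(aln$taxa$id[aln$taxa$chromosome == "Y"], cfg$outgroup)
      list(X_cluster = if (length(xs) > 1L)
        is_monophyletic(tree, xs, cfg$outgroup) else NA,
        Y_cluster = if (length(ys) > 1L)
          is_monophyletic(tree, ys, cfg$outgroup) else NA)
    })
  }

  sites <- runs <- NULL
  if (!is.null(cfg$roles)) {
    sites <- stage("sites", {
      ids <- cfg$roles[c("EX", "EY", "MX", "MY")]
      classify_informative_sites(
        second_position_sites(aln, unlist(ids)))
    })
    runs <- stage("conversion", {
      cls <- sites$classes
      keep <- cls %in% c("A", "B")  # topology C sites uninformative here
      if (sum(keep) >= 2L && length(unique(cls[keep])) == 2L) {
        runs_test(cls[keep])
      } else {
        note("runs test skipped: need both A and B site classes")
        NULL
      }
    })
  }

  fragment <- stage("conversion", {
    fragment_permutation_test(aln, n_perm = n_perm, seed = seed)
  })

  windows <- regions <- NULL
  if (!is.null(cfg$genomic)) {
    windows <- stage("windows", {
      g <- cfg$genomic
      galn <- if (inherits(g$alignment, "codon_alignment")) g$alignment
      else read_alignment(g$alignment, mode = "genomic")
      s <- aln_seqs(galn, g$pair)
      window_profile(s[[1L]], s[[2L]], window_size = wsize)
    })
    regions <- stage("conversion", {
      if (sum(windows$reliable) >= 4L) {
        detect_low_divergence(windows, min_windows = minw,
                              p_threshold = pthr)
      } else {
        note("region detection skipped: fewer than 4 reliable windows")
        NULL
      }
    })
  }

  region_reports <- NULL
  if (!is.null(cfg$regions)) {
    region_reports <- stage("divergence", {
      out <- list()
      for (lab in names(cfg$regions)) {
        reg <- parse_region(cfg$regions[[lab]], label = lab)
        sub <- slice_region(aln, reg)
        rows <- lapply(pairs, function(p) {
          d <- tryCatch(mean_syn_divergence(sub, p$x_ids, p$y_ids),
                        error = function(e) NULL)
          if (is.null(d)) return(NULL)
          data.frame(pair = p$label, region = lab, pS = d$pS,
                     se_pS = d$se_pS, KS = d$KS, se_KS = d$se_KS)
        })
        out[[lab]] <- do.call(rbind, rows)
      }
      do.call(rbind, out)
    })
  }

  dating <- NULL
  if (!is.null(cfg$dating)) {
    dating <- stage("dating", {
      dc <- cfg$dating
      model <- build_rate_model(
        dc$m_A_lo, if (is.null(dc$m_A_hi)) dc$m_A_lo else dc$m_A_hi,
        alpha = if (is.null(dc$alpha)) 2 else dc$alpha,
        rounding = if (is.null(dc$rounding)) "full-precision" else dc$rounding)
      date_divergence(dc$KS, model)
    })
  }

  report <- structure(list(
    gene = cfg$gene, divergence = div_table, tree = tree,
    monophyly = monophyly, sites = sites, runs = runs, fragment = fragment,
    windows = windows, regions = regions, region_reports = region_reports,
    dating = dating, seed = seed, log = log), class = "gene_report")

  if (!is.null(cfg$out_dir)) write_gene_report(report, cfg$out_dir)
  report
}

#' Write a gene report's artifacts
#'
#' Emits the divergence table (TSV), tree (newick with percent supports),
#' window profile (TSV), low-divergence regions (BED), a JSON summary of
#' the tests, and the run log.
#'
#' @param report A `gene_report` from [run_gene()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_gene_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$divergence, "divergence.tsv")
  ape::write.tree(report$tree, file.path(dir, "tree.nwk"))
  if (!is.null(report$windows)) w(report$windows, "windows.tsv")
  if (!is.null(report$regions)) {
    w(report$regions, "regions.tsv")
    write_regions_bed(report$regions, file.path(dir, "regions.bed"))
  }
  if (!is.null(report$region_reports)) w(report$region_reports, "region_divergence.tsv")
  summ <- list(
    gene = report$gene, seed = report$seed,
    monophyly = report$monophyly,
    sites = if (!is.null(report$sites))
      report$sites[c("nA", "nB", "nC", "n_informative", "n_skipped")],
    runs = if (!is.null(report$runs)) unclass(report$runs),
    fragment_p = report$fragment$p_global,
    dating = if (!is.null(report$dating))
      report$dating[c("KS", "T_lo", "T_hi")])
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf("gene report: %s\n", x$gene))
  print(x$divergence)
  if (!is.null(x$monophyly)) {
    cat(sprintf("  X cluster monophyletic: %s; Y cluster: %s\n",
                x$monophyly$X_cluster, x$monophyly$Y_cluster))
  }
  if (!is.null(x$sites)) {
    cat(sprintf("  informative sites: A = %d, B = %d, C = %d\n",
                x$sites$nA, x$sites$nB, x$sites$nC))
  }
  if (!is.null(x$runs)) print(x$runs)
  if (!is.null(x$fragment)) print(x$fragment)
  if (!is.null(x$regions) && nrow(x$regions)) {
    cat(sprintf("  low-divergence regions: %d\n", nrow(x$regions)))
  }
  if (!is.null(x$dating)) print(x$dating)
  invisible(x)
}
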