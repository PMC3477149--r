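# Neighbor-joining on synonymous distances, codon bootstrap, and quartet
# informative-site classification. Tree containers are ape "phylo" objects.

#' Pairwise synonymous-distance matrix
#'
#' All-pairs uncorrected synonymous divergence (`pS`) for a codon alignment;
#' the substrate for [nj_tree()]. Pairs whose divergence is undefined (no
#' complete codons or zero synonymous sites) are `NA`.
#'
#' @param aln A codon-mode `codon_alignment`.
#' @param ids Optional subset/order of record ids (default all).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
ps_dist_matrix <- function(aln, ids = NULL) {
  seqs <- aln_seqs(aln, ids)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- tryCatch(pairwise_syn(seqs[[i]], seqs[[j]])$pS,
                  error = function(e) NA_real_)
    d[i, j] <- v; d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (ties in the
#' Q criterion are resolved toward the lexicographically smallest cluster
#' index pair) and negative-branch handling: a negative branch length is
#' clamped to zero and the deficit transferred to its sibling branch, so
#' path lengths through the joined node are preserved. On an additive
#' matrix the generating tree's topology and branch lengths are recovered
#' exactly. The result is unrooted.
#'
#' @param d Symmetric distance matrix with dimnames (e.g. from
#'   [ps_dist_matrix()]); at least 3 taxa, no `NA` entries.
#' @return An ape `phylo` tree; attribute `n_clamped` counts clamping
#'   events.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || is.null(rownames(d))) {
    stop("d must be a matrix with taxon dimnames", call. = FALSE)
  }
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(is.na(d))) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined (saturated/degenerate) distances for pairs: ",
         paste(paste(rownames(d)[bad[, 1L]], colnames(d)[bad[, 2L]],
                     sep = "-"), collapse = ", "), call. = FALSE)
  }
  labels <- rownames(d)
  # cluster i is represented by a growing newick fragment
  frag <- labels
  D <- d
  n_clamped <- 0L
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3L) {
    m <- nrow(D)
    R <- rowSums(D)
    best <- NULL; bestq <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      q <- (m - 2) * D[i, j] - R[i] - R[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0; n_clamped <- n_clamped + 1L }
    if (bj < 0) { bi <- bi + bj; bj <- 0; n_clamped <- n_clamped + 1L }
    if (bi < 0) bi <- 0
    newfrag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":",
                      fmt(bj), ")")
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  # final trifurcation: three-point formulas
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  for (nm in c("b1", "b2", "b3")) {
    if (get(nm) < 0) { assign(nm, 0); n_clamped <- n_clamped + 1L }
  }
  nwk <- paste0("(", frag[1L], ":", fmt(b1), ",", frag[2L], ":", fmt(b2),
                ",", frag[3L], ":", fmt(b3), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "n_clamped") <- n_clamped
  tr
}

#' Neighbor-joining tree with codon bootstrap
#'
#' Builds the NJ tree on the full alignment's `pS` matrix, then resamples
#' codon columns with replacement (the resampling unit is the codon, so
#' synonymous-site structure is preserved), rebuilds the tree per replicate
#' and reports, for each internal branch, the percentage of replicates
#' containing the same bipartition. Replicates in which any pairwise `pS`
#' is undefined are redrawn, up to `10 * reps` draws in total.
#'
#' @param aln A codon-mode `codon_alignment`.
#' @param reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; supports are reproducible given the seed.
#' @param ids Optional subset/order of record ids.
#' @return An ape `phylo`; `node.label` carries integer percent supports
#'   (empty at the basal trifurcation), and attribute `boot_trees` the
#'   replicate trees as a `multiPhylo`.
#' @export
bootstrap_nj <- function(aln, reps = 1000L, seed, ids = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$mode != "codon") stop("codon bootstrap needs a codon-mode alignment",
                                call. = FALSE)
  if (missing(seed)) stop("seed is required for reproducible supports",
                          call. = FALSE)
  seqs <- aln_seqs(aln, ids)
  main <- nj_tree(ps_dist_matrix(aln, ids))
  n_codons <- aln_length(aln) %/% 3L
  sub_aln <- function(cols) {
    # cols: codon indices; rebuild sequences from resampled codons
    keep <- as.vector(rbind(3L * cols - 2L, 3L * cols - 1L, 3L * cols))
    mat <- aln$mat[names(seqs), keep, drop = FALSE]
    s <- apply(mat, 1L, paste0, collapse = "")
    names(s) <- names(seqs)
    s
  }
  boot <- with_seed(seed, {
    out <- vector("list", reps)
    draws <- 0L
    for (r in seq_len(reps)) {
      repeat {
        if (draws >= 10L * reps) {
          stop("bootstrap redraw cap exceeded: too many saturated replicates",
               call. = FALSE)
        }
        draws <- draws + 1L
        cols <- sample.int(n_codons, n_codons, replace = TRUE)
        s <- sub_aln(cols)
        dm <- matrix(0, length(s), length(s),
                     dimnames = list(names(s), names(s)))
        bad <- FALSE
        for (i in seq_len(length(s) - 1L)) {
          for (j in (i + 1L):length(s)) {
            v <- tryCatch(pairwise_syn(s[[i]], s[[j]])$pS,
                          error = function(e) NA_real_)
            if (is.na(v)) { bad <- TRUE; break }
            dm[i, j] <- v; dm[j, i] <- v
          }
          if (bad) break
        }
        if (!bad) break
      }
      out[[r]] <- nj_tree(dm)
    }
    out
  })
  class(boot) <- "multiPhylo"
  counts <- ape::prop.clades(main, boot, rooted = FALSE)
  counts[is.na(counts)] <- reps  # trivial bipartition at the basal node
  main$node.label <- as.character(round(100 * counts / reps))
  attr(main, "boot_trees") <- boot
  main
}

#' Clade (monophyly) query against an outgroup-rooted tree
#'
#' Roots the tree on the designated outgroup and asks whether the given taxa
#' form a clade. Trees are built unrooted, so every clade statement is
#' relative to the chosen outgroup (platypus or chicken in typical gametolog
#' work).
#'
#' @param tree An ape `phylo`.
#' @param taxa Character vector of tip labels to test.
#' @param outgroup Tip label to root on.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, taxa, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup not in tree: ", outgroup, call. = FALSE)
  }
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss)) stop("taxa not in tree: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (length(taxa) <= 1L || setequal(taxa, tree$tip.label)) return(TRUE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, taxa)
}

#' Classify quartet informative sites by supported topology
#'
#' For second-position sites of a eutherian-X / eutherian-Y / marsupial-X /
#' marsupial-Y quartet, a site is phylogenetically informative when exactly
#' two states each occur exactly twice. It then supports one of three
#' quartet topologies by which roles share a state:
#' A = (\[EX, MX\], \[EY, MY\]) — X/Y differentiation before the
#' eutherian-marsupial split; B = (\[EX, EY\], \[MX, MY\]) — differentiation
#' after the split (or lineage-specific gene conversion); C =
#' (\[EX, MY\], \[MX, EY\]) — incompatible with both, attainable by chance.
#'
#' @param sites data.frame from [second_position_sites()] with the four
#'   residue columns in role order EX, EY, MX, MY.
#' @return List: counts `nA`, `nB`, `nC`, `n_informative`, `n_skipped`, and
#'   0-based alignment `positions` per class.
#' @export
classify_informative_sites <- function(sites) {
  need <- c("column", "b1", "b2", "b3", "b4")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cls <- character(nrow(sites))
  for (k in seq_len(nrow(sites))) {
    b <- c(sites$b1[k], sites$b2[k], sites$b3[k], sites$b4[k])
    tab <- table(b)
    if (length(tab) == 2L && all(tab == 2L)) {
      cls[k] <- if (b[1L] == b[3L] && b[2L] == b[4L]) "A"
      else if (b[1L] == b[2L] && b[3L] == b[4L]) "B"
      else "C"
    } else cls[k] <- "skip"
  }
  list(nA = sum(cls == "A"), nB = sum(cls == "B"), nC = sum(cls == "C"),
       n_informative = sum(cls != "skip"), n_skipped = sum(cls == "skip"),
       positions = list(A = sites$column[cls == "A"],
                        B = sites$column[cls == "B"],
                        C = sites$column[cls == "C"]),
       classes = cls)
}

#' Ratio of two terminal branch lengths
#'
#' Used to compare how far two tips have diverged from their respective
#' attachment nodes, e.g. to flag a gametolog whose terminal branch is
#' anomalously short (a gene-conversion signature).
#'
#' @param tree An ape `phylo` with branch lengths.
#' @param taxon1,taxon2 Tip labels; the ratio is `taxon1 / taxon2`.
#' @return Numeric ratio.
#' @export
terminal_branch_ratio <- function(tree, taxon1, taxon2) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  tip_len <- function(lbl) {
    k <- match(lbl, tree$tip.label)
    if (is.na(k)) stop("taxon not in tree: ", lbl, call. = FALSE)
    tree$edge.length[tree$edge[, 2L] == k]
  }
  denom <- tip_len(taxon2)
  if (denom == 0) stop("zero-length denominator branch", call. = FALSE)
  tip_len(taxon1) / denom
}
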