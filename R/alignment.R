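#' Taxon tag
#'
#' A small record attaching a species code, chromosome of origin and clade to
#' one alignment row. Chromosome and clade come from fixed vocabularies so
#' downstream role assignment (eutherian X, marsupial Y, ...) is unambiguous.
#'
#' @param species_code Non-empty short species code (e.g. `"Hosa"`, `"Modo"`).
#' @param chromosome One of `"X"`, `"Y"`, `"autosome"`, `"unknown"`.
#' @param clade One of `"eutherian"`, `"marsupial"`, `"monotreme"`,
#'   `"outgroup"`.
#' @return A `taxon_tag` object (named list).
#' @export
taxon_tag <- function(species_code, chromosome = "unknown", clade = "outgroup") {
  if (!is.character(species_code) || length(species_code) != 1L ||
      is.na(species_code) || !nzchar(species_code)) {
    stop("species_code must be a non-empty string", call. = FALSE)
  }
  chromosome <- match.arg(chromosome, c("X", "Y", "autosome", "unknown"))
  clade <- match.arg(clade, c("eutherian", "marsupial", "monotreme", "outgroup"))
  structure(list(species_code = species_code, chromosome = chromosome,
                 clade = clade), class = "taxon_tag")
}

# Normalise raw sequence strings: upper-case, IUPAC ambiguity codes other
# than N collapse to N. Anything outside {A,C,G,T,N,-} afterwards is an error.
normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("RYSWKMBDHVU", "NNNNNNNNNNT", x)
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    stop("alignment contains characters outside A/C/G/T/N/- and IUPAC codes",
         call. = FALSE)
  }
  x
}

#' Construct a codon or genomic alignment
#'
#' The core container consumed by every divergence, tree and conversion
#' operation: an equal-length set of aligned nucleotide sequences with a
#' taxon tag per row. In `"codon"` mode the alignment must be in frame
#' (length divisible by 3, frame starting at column 1).
#'
#' @param seqs Named character vector of aligned sequences (names are record
#'   ids), or a character matrix with one row per taxon.
#' @param tags Optional named list of [taxon_tag()] objects keyed by record
#'   id; records without a tag get `chromosome = "unknown"`,
#'   `clade = "outgroup"`.
#' @param mode `"codon"` or `"genomic"`.
#' @return A `codon_alignment`: list with `mat` (character matrix, one row
#'   per taxon, rownames = ids), `taxa` (data.frame of id/species_code/
#'   chromosome/clade) and `mode`.
#' @export
codon_alignment <- function(seqs, tags = NULL, mode = c("codon", "genomic")) {
  mode <- match.arg(mode)
  if (is.matrix(seqs)) {
    seqs <- apply(seqs, 1L, paste0, collapse = "")
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named by record id", call. = FALSE)
  }
  if (length(seqs) < 2L) {
    stop("an alignment needs at least 2 records", call. = FALSE)
  }
  seqs <- normalize_seq(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("aligned records have unequal lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  if (mode == "codon" && lens[1L] %% 3L != 0L) {
    stop("codon-mode alignment length ", lens[1L],
         " is not divisible by 3 (frame error)", call. = FALSE)
  }
  mat <- t(vapply(strsplit(seqs, "", fixed = TRUE), identity,
                  character(lens[1L])))
  rownames(mat) <- names(seqs)
  ids <- names(seqs)
  tag_of <- function(id) {
    tg <- if (!is.null(tags)) tags[[id]] else NULL
    if (is.null(tg)) taxon_tag(id, "unknown", "outgroup") else tg
  }
  taxa <- do.call(rbind, lapply(ids, function(id) {
    tg <- tag_of(id)
    data.frame(id = id, species_code = tg$species_code,
               chromosome = tg$chromosome, clade = tg$clade,
               stringsAsFactors = FALSE)
  }))
  structure(list(mat = mat, taxa = taxa, mode = mode),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa x %d columns (%s mode)\n",
              nrow(x$mat), ncol(x$mat), x$mode))
  cat(" taxa:", paste(x$taxa$id, collapse = ", "), "\n")
  invisible(x)
}

#' Number of alignment columns
#' @param aln A `codon_alignment`.
#' @return Integer column count.
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' Sequences of an alignment as strings
#' @param aln A `codon_alignment`.
#' @param ids Optional record ids to extract (default all, in order).
#' @return Named character vector.
#' @export
aln_seqs <- function(aln, ids = NULL) {
  mat <- aln$mat
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(mat))
    if (length(miss)) {
      stop("taxa not found in alignment: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    mat <- mat[ids, , drop = FALSE]
  }
  out <- apply(mat, 1L, paste0, collapse = "")
  names(out) <- rownames(mat)
  out
}

#' Read an aligned FASTA file
#'
#' Reads a multi-record aligned FASTA and validates it as a
#' [codon_alignment()]. Taxon tags come from a sidecar map (see
#' [read_taxon_map()]); untagged records default to
#' `chromosome = "unknown"`, `clade = "outgroup"`.
#'
#' @param path FASTA file path.
#' @param mode `"codon"` (in-frame coding) or `"genomic"`.
#' @param tags Optional named list of [taxon_tag()] keyed by FASTA record id
#'   (first whitespace-delimited token of the header).
#' @return A `codon_alignment`.
#' @export
read_alignment <- function(path, mode = c("codon", "genomic"), tags = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) < 2L) stop("an alignment needs at least 2 records", call. = FALSE)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    paste0(gsub("\\s", "", lines[(hdr[i] + 1L):ends[i]]), collapse = "")
  }, character(1L))
  names(seqs) <- ids
  codon_alignment(seqs, tags = tags, mode = mode)
}

#' Write an alignment as FASTA
#'
#' Round-trips with [read_alignment()]: sequence content and record order are
#' preserved byte-for-byte for A/C/G/T/N/- content.
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @param width Line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  seqs <- aln_seqs(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a taxon tag map from TSV
#'
#' Sidecar table with columns `id`, `species_code`, `chromosome`, `clade`
#' mapping FASTA record ids to [taxon_tag()]s. A sidecar file is used rather
#' than parsing record names because label conventions vary between sources.
#'
#' @param path TSV file with a header row.
#' @return Named list of `taxon_tag`, keyed by record id.
#' @export
read_taxon_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species_code", "chromosome", "clade")
  if (!all(need %in% names(df))) {
    stop("taxon map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tags <- lapply(seq_len(nrow(df)), function(i) {
    taxon_tag(df$species_code[i], df$chromosome[i], df$clade[i])
  })
  names(tags) <- df$id
  tags
}

#' Alignment region
#'
#' Internal coordinates are 0-based half-open `[start, end)`. User-facing
#' strings use the field's 1-based inclusive convention; see
#' [parse_region()].
#'
#' @param start 0-based inclusive start column.
#' @param end Exclusive end column.
#' @param label Free-text label (e.g. `"a"`, `"b"`).
#' @return A `region` object.
#' @export
region <- function(start, end, label = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("region requires 0 <= start < end", call. = FALSE)
  }
  structure(list(start = start, end = end, label = label), class = "region")
}

#' Parse a 1-based inclusive region string
#'
#' Converts the conventional `"1-1000"` style (1-based, both ends included)
#' into the internal 0-based half-open [region()].
#'
#' @param x String like `"1-1000"` (en dashes also accepted).
#' @param label Optional label.
#' @return A `region`; `"1-1000"` becomes `region(0, 1000)`.
#' @export
parse_region <- function(x, label = "") {
  x <- gsub("–|—", "-", x)
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", x))[[1L]]
  if (length(m) != 3L) stop("cannot parse region string: ", x, call. = FALSE)
  a <- as.integer(m[2L]); b <- as.integer(m[3L])
  if (a < 1L || b < a) stop("region string must satisfy 1 <= start <= end",
                            call. = FALSE)
  region(a - 1L, b, label = label)
}

#' Extract a sub-alignment
#'
#' Slices the alignment columns `[start, end)` of `reg`. In codon mode the
#' region boundaries must fall on codon boundaries so the frame is preserved.
#'
#' @param aln A `codon_alignment`.
#' @param reg A [region()].
#' @return A `codon_alignment` over the selected columns, same mode and taxa.
#' @export
slice_region <- function(aln, reg) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(reg, "region"))
  L <- aln_length(aln)
  if (reg$end > L) {
    stop(sprintf("region [%d,%d) out of bounds for alignment of %d columns",
                 reg$start, reg$end, L), call. = FALSE)
  }
  if (aln$mode == "codon" && (reg$start %% 3L != 0L || reg$end %% 3L != 0L)) {
    stop("codon-mode region boundaries must be multiples of 3", call. = FALSE)
  }
  out <- aln
  out$mat <- aln$mat[, (reg$start + 1L):reg$end, drop = FALSE]
  out
}

#' Second-codon-position sites for a taxon quartet
#'
#' For a 4-taxon selection, returns the residues at the second position of
#' every codon. Second positions are the slowest-evolving codon positions, so
#' they are used for informative-site counting where saturation would
#' otherwise scramble the signal. Codons where any selected taxon has a gap
#' or N at the second position are dropped.
#'
#' @param aln A codon-mode `codon_alignment`.
#' @param ids Character vector of exactly 4 record ids, in role order
#'   (conventionally EX, EY, MX, MY).
#' @return data.frame with `column` (0-based alignment column of the second
#'   position) and `b1`..`b4` (the four residues, in `ids` order).
#' @export
second_position_sites <- function(aln, ids) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$mode != "codon") stop("second positions need a codon-mode alignment",
                                call. = FALSE)
  if (length(ids) != 4L) stop("exactly 4 taxa required", call. = FALSE)
  miss <- setdiff(ids, rownames(aln$mat))
  if (length(miss)) {
    stop("taxa not found in alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  L <- aln_length(aln)
  cols <- seq(2L, L, by = 3L)                  # 1-based second positions
  sub <- aln$mat[ids, cols, drop = FALSE]
  ok <- colSums(sub == "-" | sub == "N") == 0L
  data.frame(column = cols[ok] - 1L,
             b1 = sub[1L, ok], b2 = sub[2L, ok],
             b3 = sub[3L, ok], b4 = sub[4L, ok],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' All-column sites for a taxon quartet
#'
#' Like [second_position_sites()] but over every alignment column, for
#' genomic (non-coding or unconstrained) alignments where any column can
#' carry quartet signal. Columns with a gap or N in any selected taxon are
#' dropped.
#'
#' @param aln A `codon_alignment` (either mode).
#' @param ids Exactly 4 record ids in role order (EX, EY, MX, MY).
#' @return data.frame with `column` (0-based) and `b1`..`b4`.
#' @export
quartet_sites <- function(aln, ids) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(ids) != 4L) stop("exactly 4 taxa required", call. = FALSE)
  miss <- setdiff(ids, rownames(aln$mat))
  if (length(miss)) {
    stop("taxa not found in alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sub <- aln$mat[ids, , drop = FALSE]
  ok <- colSums(sub == "-" | sub == "N") == 0L
  cols <- which(ok)
  data.frame(column = cols - 1L,
             b1 = sub[1L, cols], b2 = sub[2L, cols],
             b3 = sub[3L, cols], b4 = sub[4L, cols],
             stringsAsFactors = FALSE, row.names = NULL)
}
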