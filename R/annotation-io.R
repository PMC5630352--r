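# Annotation and peak I/O. Internal coordinates are 0-based half-open
# everywhere (the BED convention); GTF is converted on read.

MARKS <- c("H3K4me3", "H3K27me3")

validate_intervals <- function(chrom, start, end, where = "interval") {
  if (any(!nzchar(chrom))) stopf("%s: empty chromosome name", where)
  if (any(start < 0)) stopf("%s: negative start", where)
  if (any(end <= start)) stopf("%s: end <= start", where)
  invisible(TRUE)
}

new_peak_set <- function(chrom, start, end, mark, condition, score = NA_real_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   mark = as.character(mark),
                   condition = as.character(condition),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a BED file of peak calls
#'
#' Parses a 3- to 6-column tab-separated BED file into a peak table tagged
#' with a histone mark and a condition label. Coordinates are kept in the
#' native BED convention (0-based half-open) and input order is preserved.
#' Malformed lines (fewer than 3 fields, non-integer coordinates, or
#' `end <= start`) abort the read with the offending line numbers.
#'
#' @param path path to a BED file.
#' @param mark histone mark label, one of `"H3K4me3"` or `"H3K27me3"`.
#' @param condition condition label (free string, e.g. `"vector"`).
#' @param chrom_style chromosome-name normalization passed to
#'   [normalize_chroms()].
#' @return a `peak_set` data.frame with columns `chrom`, `start`, `end`,
#'   `mark`, `condition`, `score` (column 5 when present, else `NA`).
#' @export
read_bed <- function(path, mark, condition, chrom_style = "asis") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  mark <- match.arg(mark, MARKS)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(new_peak_set(character(), integer(), integer(),
                        character(), character(), numeric()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- idx[nf < 3L]
  if (length(bad))
    stopf("BED parse error in %s: fewer than 3 fields on line(s) %s",
          path, paste(bad, collapse = ", "))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- idx[is.na(start) | is.na(end)]
  if (length(bad))
    stopf("BED parse error in %s: non-integer coordinate on line(s) %s",
          path, paste(bad, collapse = ", "))
  bad <- idx[end <= start]
  if (length(bad))
    stopf("BED parse error in %s: end <= start on line(s) %s",
          path, paste(bad, collapse = ", "))
  score <- rep(NA_real_, length(idx))
  has5 <- nf >= 5L
  if (any(has5))
    score[has5] <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  new_peak_set(normalize_chroms(chrom, chrom_style), start, end,
               mark, condition, score)
}

#' Write intervals as 3-column BED
#'
#' @param x a data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), e.g. a `peak_set` or a promoter table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  dat <- data.frame(x$chrom, as.integer(x$start), as.integer(x$end))
  utils::write.table(dat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

new_gene_annotation <- function(gene_id, symbol, chrom, start, end, strand,
                                tss) {
  df <- data.frame(gene_id = as.character(gene_id),
                   symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   strand = as.character(strand),
                   tss = as.integer(tss),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_annotation", "data.frame")
  df
}

# TSS on the 0-based half-open body: + strand -> start; - strand -> end - 1.
tss_from_body <- function(start, end, strand) {
  ifelse(strand == "+", start, end - 1L)
}

#' Read a gene annotation from GTF or BED
#'
#' GTF records (1-based closed) are converted to the internal 0-based
#' half-open convention; `gene`-typed records are used when present,
#' otherwise the first record per `gene_id` defines the gene body. BED input
#' must be 6-column (name and strand required). One record is kept per
#' `gene_id` (first occurrence wins); duplicates trigger a warning. Genes
#' without a strand are rejected because the TSS is undefined.
#'
#' @param path path to the annotation file.
#' @param format `"auto"` (by extension), `"gtf"`, or `"bed"`.
#' @param chrom_style chromosome-name normalization passed to
#'   [normalize_chroms()].
#' @param multi_tss `"first"` (default: one canonical TSS per gene, first
#'   record wins, duplicates warned about) or `"any"` (keep every record;
#'   downstream mark calls treat a gene as marked when *any* of its TSS
#'   windows carries the mark).
#' @return a `gene_annotation` data.frame with columns `gene_id`, `symbol`,
#'   `chrom`, `start`, `end`, `strand`, `tss` (all coordinates 0-based
#'   half-open; `tss` is a 0-based position).
#' @export
read_gene_annotation <- function(path, format = c("auto", "gtf", "bed"),
                                 chrom_style = "asis",
                                 multi_tss = c("first", "any")) {
  format <- match.arg(format)
  multi_tss <- match.arg(multi_tss)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff2?)$", path, ignore.case = TRUE)) "gtf"
              else "bed"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    if (!is.null(md$type) && any(md$type == "gene")) {
      gr <- gr[md$type == "gene"]
      md <- S4Vectors::mcols(gr)
    }
    gene_id <- as.character(md$gene_id)
    if (is.null(md$gene_id) || anyNA(gene_id) || any(!nzchar(gene_id)))
      stopf("GTF record without a gene_id attribute in %s", path)
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*"))
      stopf("GTF record without strand in %s (TSS undefined)", path)
    symbol <- if (!is.null(md$gene_name)) as.character(md$gene_name)
              else gene_id
    # GTF is 1-based closed: [s, e] -> [s-1, e) half-open.
    start <- BiocGenerics::start(gr) - 1L
    end <- BiocGenerics::end(gr)
    chrom <- as.character(GenomicRanges::seqnames(gr))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 6L))
      stopf("BED gene annotation in %s needs 6 columns (name and strand)",
            path)
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.integer(vapply(fields, `[[`, "", 2L))
    end <- as.integer(vapply(fields, `[[`, "", 3L))
    gene_id <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
    if (any(!strand %in% c("+", "-")))
      stopf("gene without strand in %s (TSS undefined)", path)
    symbol <- gene_id
  }
  dup <- if (multi_tss == "any") rep(FALSE, length(gene_id))
         else duplicated(gene_id)
  if (any(dup)) {
    warnf("%d duplicate gene_id record(s) dropped (first occurrence wins): %s",
          sum(dup), paste(unique(gene_id[dup]), collapse = ", "))
    keep <- !dup
    chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]
    gene_id <- gene_id[keep]; strand <- strand[keep]; symbol <- symbol[keep]
  }
  validate_intervals(chrom, start, end, "gene annotation")
  new_gene_annotation(gene_id, symbol, normalize_chroms(chrom, chrom_style),
                      start, end, strand, tss_from_body(start, end, strand))
}

#' Write a gene annotation as GTF
#'
#' Emits one 1-based closed `gene` record per gene, round-tripping the
#' internal 0-based half-open representation.
#'
#' @param genes a `gene_annotation` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gtf <- function(genes, path) {
  attrs <- sprintf('gene_id "%s"; gene_name "%s";', genes$gene_id,
                   genes$symbol)
  dat <- data.frame(genes$chrom, "bivalency", "gene",
                    as.integer(genes$start) + 1L, as.integer(genes$end),
                    ".", genes$strand, ".", attrs)
  utils::write.table(dat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware promoter windows around the TSS
#'
#' Builds, for each gene, the promoter interval extending `upstream` bp
#' against the direction of transcription and `downstream` bp with it.
#' On the plus strand the window is `[tss - upstream, tss + downstream)`;
#' on the minus strand it is `[tss - downstream + 1, tss + upstream + 1)`,
#' which mirrors the plus-strand window about the TSS base. Starts are
#' clamped at 0.
#'
#' @param genes a `gene_annotation` data.frame (or any data.frame with
#'   `gene_id`, `chrom`, `strand`, `tss`).
#' @param upstream,downstream non-negative window extents in bp;
#'   `upstream + downstream` must be positive. Default 2000/2000 (a
#'   conventional bivalency-analysis promoter; configurable, not a constant).
#' @return a data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open windows).
#' @export
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 10000)
#' promoter_window(g, 2000, 2000)  # [8000, 12000)
promoter_window <- function(genes, upstream = 2000, downstream = 2000) {
  assert_scalar_number(upstream, "upstream")
  assert_scalar_number(downstream, "downstream")
  if (upstream < 0 || downstream < 0 || upstream + downstream <= 0)
    stopf("upstream/downstream must be >= 0 with a positive total width")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  start <- pmax(start, 0)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = as.integer(start), end = as.integer(end),
             strand = genes$strand, stringsAsFactors = FALSE)
}
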