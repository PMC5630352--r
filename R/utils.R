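# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  invisible(x)
}

#' Normalize chromosome names
#'
#' Chromosome comparison is literal by default; this helper adds or strips a
#' "chr" prefix so that peak and annotation dialects can be reconciled.
#'
#' @param chrom character vector of chromosome names.
#' @param style one of `"asis"` (default, no change), `"strip"` (remove a
#'   leading "chr"), `"add"` (ensure a leading "chr").
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_chroms(c("chr1", "2"), style = "add")
normalize_chroms <- function(chrom, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  switch(style,
    asis  = chrom,
    strip = sub("^chr", "", chrom),
    add   = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

# Write a data.frame as a TSV with stable formatting.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE),
                stringsAsFactors = FALSE)
}
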