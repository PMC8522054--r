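# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_twohit <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_twohit(sprintf("'%s' must be a single number in [%s, %s]",
                        name, format(lower), format(upper)))
  invisible(x)
}

# 0-based half-open interval overlap width
overlap_width <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

# reciprocal overlap = min(overlap/lenA, overlap/lenB); symmetric by
# construction
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- overlap_width(s1, e1, s2, e2)
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR q-values as used throughout the pipeline.  Thin validated
#' wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\]; `NA`s are propagated.
#' @return numeric vector of q-values, monotone in `p` and capped at 1.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop_twohit("p-values must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_twohit("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# deterministic sub-seed derivation: keeps every stage's RNG use independent
# of the others while remaining reproducible from one user seed.  Result is
# kept well below .Machine$integer.max.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147480000)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "", ...)
}

# matrix writer/reader: first column gene_id (or feature id), remaining
# columns sample.replicate
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
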