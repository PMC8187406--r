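#' @keywords internal
"_PACKAGE"

# Shared internal helpers: TSV IO with fixed conventions (tab separated,
# header row, no quoting) and small assertion utilities.

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

# Read a numeric matrix stored as TSV with an id column first.
read_matrix_tsv <- function(path, id_col = 1L) {
  df <- read_tsv(path)
  ids <- as.character(df[[id_col]])
  m <- as.matrix(df[, -id_col, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  write_tsv(df, path)
}

# One gene id per line, no header.
read_gene_set <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Trim whitespace and strip a trailing ".<digits>" version suffix so ids
# from different source dialects compare equal.
normalize_gene_id <- function(x) {
  sub("\\.[0-9]+$", "", trimws(as.character(x)))
}
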