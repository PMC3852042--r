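`%||%` <- function(x, y) if (is.null(x)) y else x

utils::globalVariables(c("score", "proportion", "term_id", "significant"))

read_tsv_strict <- function(path, required = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0L)
      stop(sprintf("file '%s' lacks required column(s): %s",
                   path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
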