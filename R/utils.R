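#' @keywords internal
"_PACKAGE"

# shared small helpers -------------------------------------------------------

geometric_mean <- function(x) exp(mean(log(x)))

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

#' Write a result table as TSV
#'
#' All pipeline outputs are written in a single dialect: UTF-8, tab-separated,
#' header row, no quoting, missing numeric values encoded as ".".
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  out <- x
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.numeric(col)) {
      col <- as.character(col)
      col[is.na(col)] <- "."
      out[[j]] <- col
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path file path.
#' @param numeric_cols character vector of columns to coerce back to numeric
#'   ("." becomes `NA`). Columns not listed are kept as character.
#' @return data.frame.
#' @export
read_table <- function(path, numeric_cols = NULL) {
  stop_if(!file.exists(path), "file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character",
                         na.strings = NULL, fileEncoding = "UTF-8")
  for (nm in intersect(numeric_cols, names(x))) {
    v <- x[[nm]]
    v[v == "."] <- NA
    x[[nm]] <- as.numeric(v)
  }
  x
}
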