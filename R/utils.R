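#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; frequency percentages are reported
#' with conventional half-up rounding (30.35 -> 30.4).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(30.35, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# collapse internal whitespace and trim
squish <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable zero-padded id maker: prefix + width-padded integer
make_ids <- function(prefix, n, width = max(4L, nchar(n))) {
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}

# deterministic concatenation of data.frame rows from a list
rbind_all <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

# write a data.frame as plain CSV with stable quoting (byte-stable output)
write_csv_stable <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8",
            eol = "\n")
  invisible(path)
}

msg <- function(...) message(sprintf(...))
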