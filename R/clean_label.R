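#' Default measurement-unit lexicon
#'
#' UCUM-flavoured unit strings recognized when stripping a trailing
#' parenthesized or bracketed unit from an item label. Extensible: pass your
#' own character vector (or a CSV with a `unit` column via [read_unit_lexicon()])
#' to [clean_label()].
#'
#' @return character vector of unit strings.
#' @export
default_unit_lexicon <- function() {
  path <- system.file("extdata", "unit_lexicon.csv", package = "cdeinventory")
  read_unit_lexicon(path)
}

#' Read a unit lexicon CSV
#'
#' @param path CSV file with a `unit` column.
#' @return character vector of unit strings.
#' @export
read_unit_lexicon <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"unit" %in% names(df)) stop("unit lexicon must have a 'unit' column")
  unique(df$unit)
}

#' Clean a raw item label
#'
#' Removes markup tags (including any style attributes inside them), decodes
#' the common HTML entities, strips leading/trailing CRF decoration
#' (required-field asterisks, trailing colons), peels a trailing parenthesized
#' or bracketed measurement unit into `removed_units` when it matches the unit
#' lexicon, and collapses whitespace. Letter case is preserved: case-folding
#' happens inside matching, not here.
#'
#' @param raw character vector of raw labels.
#' @param unit_lexicon character vector of unit strings (default the shipped
#'   lexicon).
#' @return data.frame with columns `raw`, `text`, `removed_units`,
#'   `removal_log` (comma-joined rule ids) and `empty_after_clean`.
#' @examples
#' clean_label("<b>Heart Rate</b> (bpm)")$text  # "Heart Rate"
#' @export
clean_label <- function(raw, unit_lexicon = default_unit_lexicon()) {
  if (any(is.na(raw))) stop("raw labels must be non-null")
  raw <- as.character(raw)
  x <- raw
  log <- vector("list", length(x))
  add_rule <- function(idx, rule) {
    for (i in which(idx)) log[[i]] <<- c(log[[i]], rule)
    log
  }

  has_tag <- grepl("<[^>]+>", x)
  x <- gsub("<[^>]+>", " ", x)
  log <- add_rule(has_tag, "strip_markup")

  has_ent <- grepl("&(nbsp|amp|lt|gt|#\\d+);", x)
  x <- gsub("&nbsp;", " ", x, fixed = TRUE)
  x <- gsub("&amp;", "&", x, fixed = TRUE)
  x <- gsub("&lt;", "<", x, fixed = TRUE)
  x <- gsub("&gt;", ">", x, fixed = TRUE)
  x <- gsub("&#\\d+;", " ", x)
  log <- add_rule(has_ent, "decode_entities")

  x <- squish(x)

  # trailing (unit) or [unit], matched case-insensitively against the lexicon
  removed_units <- rep(NA_character_, length(x))
  m <- regmatches(x, regexec("[\\(\\[]\\s*([^\\)\\]]*?)\\s*[\\)\\]]\\s*$", x,
                             perl = TRUE))
  cand <- vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_,
                 character(1))
  lex_cf <- tolower(unit_lexicon)
  is_unit <- !is.na(cand) & tolower(cand) %in% lex_cf
  if (any(is_unit)) {
    removed_units[is_unit] <- cand[is_unit]
    x[is_unit] <- sub("[\\(\\[]\\s*[^\\)\\]]*?\\s*[\\)\\]]\\s*$", "",
                      x[is_unit], perl = TRUE)
    log <- add_rule(is_unit, "strip_unit")
  }

  deco <- grepl("^\\*+|[:*]+$", x)
  x <- sub("^\\*+\\s*", "", x)
  x <- sub("\\s*[:*]+$", "", x)
  log <- add_rule(deco, "strip_decoration")

  x <- squish(x)
  empty <- !nzchar(x)
  log <- add_rule(empty, "empty_after_clean")

  data.frame(
    raw = raw,
    text = x,
    removed_units = removed_units,
    removal_log = vapply(log, function(r) paste(r, collapse = ","), character(1)),
    empty_after_clean = empty,
    stringsAsFactors = FALSE
  )
}
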