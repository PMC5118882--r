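#' Read a column-mapping dialect
#'
#' A dialect maps the columns of a tabular CRF export onto the trial-master
#' model. YAML with a `columns` block (`trial_id`, `form_id`, `form_name`,
#' `label` mandatory; `item_id`, `cdisc_variable_name`, `data_type`, `units`,
#' `repeating` optional) plus optional `sep` (default `","`) and `encoding`
#' (default `"UTF-8"`).
#'
#' @param path YAML dialect file.
#' @return a named list describing the dialect.
#' @export
read_dialect <- function(path) {
  d <- yaml::read_yaml(path)
  validate_dialect(d)
}

validate_dialect <- function(d) {
  if (is.null(d$columns)) stop("dialect config lacks a 'columns' block")
  mandatory <- c("trial_id", "form_id", "form_name", "label")
  miss <- setdiff(mandatory, names(d$columns))
  if (length(miss) > 0)
    stop("dialect config missing mandatory column mapping(s): ",
         paste(miss, collapse = ", "))
  d$sep <- d$sep %||% ","
  d$encoding <- d$encoding %||% "UTF-8"
  d
}

#' Parse a tabular CRF export
#'
#' Reads a delimited CRF export through a column-mapping dialect into the
#' same model as [parse_odm()]. Rows whose label is empty are dropped and
#' counted; a mapped column absent from the file is a fatal configuration
#' error; duplicate (form, item) pairs abort with the colliding keys listed.
#'
#' @param path delimited text file.
#' @param dialect dialect list (from [read_dialect()]) or path to a YAML
#'   dialect file.
#' @return a `study_fragment` (see [parse_odm()]).
#' @export
parse_table <- function(path, dialect) {
  if (is.character(dialect)) dialect <- read_dialect(dialect)
  dialect <- validate_dialect(dialect)
  cols <- dialect$columns
  df <- read.csv(path, sep = dialect$sep, stringsAsFactors = FALSE,
                 fileEncoding = dialect$encoding, check.names = FALSE)
  mapped <- unlist(cols, use.names = FALSE)
  absent <- setdiff(mapped, names(df))
  if (length(absent) > 0)
    stop("mapped column(s) not found in '", path, "': ",
         paste(absent, collapse = ", "))

  get <- function(key, default = NA_character_) {
    if (!is.null(cols[[key]])) as.character(df[[cols[[key]]]])
    else rep(default, nrow(df))
  }
  lab <- squish(get("label", ""))
  keep <- nzchar(lab) & !is.na(lab)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    msg("parse_table: dropped %d row(s) with empty labels from '%s'",
        n_drop, basename(path))

  trial_id <- get("trial_id")[keep]
  form_id <- get("form_id")[keep]
  form_name <- get("form_name")[keep]
  item_id <- if (!is.null(cols$item_id)) get("item_id")[keep]
             else paste0(form_id, ".IT", stats::ave(seq_along(form_id), form_id,
                                                    FUN = seq_along))
  dup <- duplicated(paste(form_id, item_id, sep = "\r"))
  if (any(dup)) {
    coll <- unique(paste0("(", form_id[dup], ", ", item_id[dup], ")"))
    stop("duplicate (form_id, item_id) in '", path, "': ",
         paste(coll, collapse = ", "))
  }

  rep_col <- if (!is.null(cols$repeating)) {
    tolower(get("repeating"))[keep] %in% c("true", "yes", "1")
  } else rep(FALSE, sum(keep))

  fk <- !duplicated(form_id)
  forms <- data.frame(form_id = form_id[fk], trial_id = trial_id[fk],
                      form_name = form_name[fk], repeating = rep_col[fk],
                      stringsAsFactors = FALSE)
  items <- data.frame(
    item_id = item_id, form_id = form_id, trial_id = trial_id,
    raw_label = lab[keep],
    cdisc_variable_name = na_if_empty(get("cdisc_variable_name")[keep]),
    data_type = normalize_data_type(get("data_type")[keep]),
    units = na_if_empty(get("units")[keep]),
    stringsAsFactors = FALSE)
  new_fragment(list(forms), list(items), source = path, format = "table",
               n_dropped = n_drop)
}

na_if_empty <- function(x) {
  x[is.na(x) | !nzchar(x)] <- NA_character_
  x
}

normalize_data_type <- function(x) {
  allowed <- c("text", "integer", "float", "date", "datetime", "boolean",
               "codelist")
  x <- tolower(x)
  x[is.na(x) | !x %in% allowed] <- "text"
  x
}
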