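#' Disease areas recognized in trial metadata
#'
#' @return character vector of the seven disease-area labels.
#' @export
disease_areas <- function() {
  c("cardiovascular", "diabetes", "infectious", "neuroscience",
    "oncology", "psychiatric", "respiratory")
}

#' Read a trial-metadata table
#'
#' CSV with columns `trial_id`, `disease_area`, `planned_enrollment`,
#' `n_sites`. Trials lacking a planned enrollment are rejected outright:
#' enrollment is the ranking weight downstream and cannot be defaulted.
#'
#' @param path CSV file path.
#' @return data.frame of trial metadata.
#' @export
read_trial_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_trial_meta(df)
}

validate_trial_meta <- function(df) {
  need <- c("trial_id", "disease_area", "planned_enrollment", "n_sites")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trial metadata missing column(s): ", paste(miss, collapse = ", "))
  df$trial_id <- as.character(df$trial_id)
  if (anyDuplicated(df$trial_id))
    stop("duplicate trial_id in trial metadata: ",
         paste(unique(df$trial_id[duplicated(df$trial_id)]), collapse = ", "))
  bad_area <- !df$disease_area %in% disease_areas()
  if (any(bad_area))
    stop("unknown disease_area: ",
         paste(unique(df$disease_area[bad_area]), collapse = ", "),
         " (allowed: ", paste(disease_areas(), collapse = ", "), ")")
  pe <- suppressWarnings(as.integer(df$planned_enrollment))
  if (any(is.na(pe) | pe < 1))
    stop("trial(s) with missing or non-positive planned_enrollment rejected: ",
         paste(df$trial_id[is.na(pe) | pe < 1], collapse = ", "))
  df$planned_enrollment <- pe
  df$n_sites <- as.integer(df$n_sites)
  if (any(is.na(df$n_sites) | df$n_sites < 1))
    stop("n_sites must be a positive integer")
  df[order(df$trial_id), , drop = FALSE]
}

#' Assemble a study set (trial master model)
#'
#' Combines trial metadata with one or more ingestion fragments (from
#' [parse_odm()] or [parse_table()]) into a single validated trial-master
#' model holding all forms and items of the corpus.
#'
#' @param trials trial-metadata data.frame (see [read_trial_meta()]).
#' @param ... fragments returned by [parse_odm()] / [parse_table()].
#' @return an object of class `study_set` with components `trials`, `forms`,
#'   `items` and `provenance`.
#' @export
study_set <- function(trials, ...) {
  trials <- validate_trial_meta(trials)
  frags <- list(...)
  if (length(frags) == 1 && is.list(frags[[1]]) &&
      !inherits(frags[[1]], "study_fragment")) {
    frags <- frags[[1]]
  }
  for (f in frags) {
    if (!inherits(f, "study_fragment"))
      stop("all fragments must come from parse_odm() or parse_table()")
  }
  forms <- rbind_all(lapply(frags, `[[`, "forms"))
  items <- rbind_all(lapply(frags, `[[`, "items"))
  prov <- rbind_all(lapply(frags, `[[`, "provenance"))
  if (is.null(forms)) {
    forms <- empty_forms()
    items <- empty_items()
  }
  ss <- structure(
    list(trials = trials, forms = forms, items = items,
         provenance = prov %||% data.frame()),
    class = "study_set"
  )
  validate_study_set(ss)
}

empty_forms <- function() {
  data.frame(form_id = character(0), trial_id = character(0),
             form_name = character(0), repeating = logical(0),
             stringsAsFactors = FALSE)
}

empty_items <- function() {
  data.frame(item_id = character(0), form_id = character(0),
             trial_id = character(0), raw_label = character(0),
             cdisc_variable_name = character(0), data_type = character(0),
             units = character(0), stringsAsFactors = FALSE)
}

validate_study_set <- function(ss) {
  stopifnot(inherits(ss, "study_set"))
  forms <- ss$forms
  items <- ss$items
  unresolved <- setdiff(unique(forms$trial_id), ss$trials$trial_id)
  if (length(unresolved) > 0)
    stop("forms reference unknown trial(s): ", paste(unresolved, collapse = ", "))
  if (anyDuplicated(forms[, c("trial_id", "form_id")]))
    stop("duplicate form_id within a trial")
  orphan <- setdiff(unique(items$form_id), forms$form_id)
  if (length(orphan) > 0)
    stop("items reference unknown form(s): ", paste(orphan, collapse = ", "))
  if (nrow(items) > 0 && anyDuplicated(items[, c("form_id", "item_id")]))
    stop("duplicate item_id within a form")
  if (nrow(items) > 0 && any(is.na(items$raw_label)))
    stop("items with null raw_label")
  ss
}

#' @export
print.study_set <- function(x, ...) {
  cat(sprintf("study_set: %d trials, %d forms, %d items\n",
              nrow(x$trials), nrow(x$forms), nrow(x$items)))
  invisible(x)
}

#' Subset a study set to selected trials
#'
#' @param ss a `study_set`.
#' @param trial_ids character vector of trial ids to keep.
#' @return a `study_set` restricted to those trials.
#' @export
subset_trials <- function(ss, trial_ids) {
  stopifnot(inherits(ss, "study_set"))
  unknown <- setdiff(trial_ids, ss$trials$trial_id)
  if (length(unknown) > 0)
    stop("unknown trial id(s): ", paste(unknown, collapse = ", "))
  out <- ss
  out$trials <- ss$trials[ss$trials$trial_id %in% trial_ids, , drop = FALSE]
  out$forms <- ss$forms[ss$forms$trial_id %in% trial_ids, , drop = FALSE]
  out$items <- ss$items[ss$items$trial_id %in% trial_ids, , drop = FALSE]
  out
}

#' Tabulate a corpus by disease area
#'
#' Counts trials and forms per disease area, appending a `Sum` row whose
#' entries equal the column sums (count conservation).
#'
#' @param ss a `study_set`.
#' @return data.frame with columns `disease_area`, `n_trials`, `n_forms`.
#' @export
tabulate_corpus <- function(ss) {
  stopifnot(inherits(ss, "study_set"))
  areas <- disease_areas()
  present <- areas[areas %in% ss$trials$disease_area]
  rows <- lapply(present, function(a) {
    tid <- ss$trials$trial_id[ss$trials$disease_area == a]
    data.frame(disease_area = a,
               n_trials = length(tid),
               n_forms = sum(ss$forms$trial_id %in% tid),
               stringsAsFactors = FALSE)
  })
  tab <- rbind_all(rows)
  if (is.null(tab)) {
    tab <- data.frame(disease_area = character(0), n_trials = integer(0),
                      n_forms = integer(0), stringsAsFactors = FALSE)
  }
  sum_row <- data.frame(disease_area = "Sum",
                        n_trials = sum(tab$n_trials),
                        n_forms = sum(tab$n_forms),
                        stringsAsFactors = FALSE)
  rbind(tab, sum_row, make.row.names = FALSE)
}

#' Write a provenance manifest
#'
#' @param ss a `study_set`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(ss, path) {
  stopifnot(inherits(ss, "study_set"))
  manifest <- list(
    n_trials = nrow(ss$trials),
    n_forms = nrow(ss$forms),
    n_items = nrow(ss$items),
    sources = ss$provenance
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
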