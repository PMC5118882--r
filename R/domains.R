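#' Default form-domain dictionary
#'
#' The fourteen topic domains commonly used to classify CRF forms, with their
#' SDTM two-letter codes where one exists (Disease Characteristics carries the
#' custom code ZC; Surgery has none) and keyword rules used as a surrogate for
#' expert allocation. Dictionary order is the rule-precedence order.
#'
#' @return data.frame with columns `domain_key`, `sdtm_code`, `display_name`,
#'   `custom`, `keywords` (semicolon-separated, case-insensitive substrings).
#' @export
default_domain_dictionary <- function() {
  path <- system.file("extdata", "domain_dictionary.csv",
                      package = "cdeinventory")
  read_domain_dictionary(path)
}

#' Read a form-domain dictionary CSV
#'
#' @param path CSV with the columns of [default_domain_dictionary()].
#' @return validated dictionary data.frame.
#' @export
read_domain_dictionary <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("domain_key", "sdtm_code", "display_name", "keywords")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0)
    stop("domain dictionary missing column(s): ", paste(miss, collapse = ", "))
  if (!"custom" %in% names(d)) d$custom <- FALSE
  d$sdtm_code <- na_if_empty(d$sdtm_code)
  if (anyDuplicated(d$domain_key))
    stop("duplicate domain_key in dictionary")
  bad <- !is.na(d$sdtm_code) & !grepl("^[A-Z]{2}$", d$sdtm_code)
  if (any(bad))
    stop("sdtm_code must be two uppercase letters: ",
         paste(d$sdtm_code[bad], collapse = ", "))
  d
}

#' Assign topic domains to forms
#'
#' Per form: an override row wins; otherwise the first dictionary entry (in
#' dictionary order) with a keyword contained case-insensitively in the
#' cleaned form name; otherwise `unassigned`. Conflicting overrides for one
#' form are a fatal error. Deterministic for fixed inputs.
#'
#' @param ss a `study_set`.
#' @param dictionary a domain dictionary (default the shipped one).
#' @param overrides optional data.frame or CSV path with columns `form_id`,
#'   `domain_key`.
#' @return data.frame `form_id`, `trial_id`, `domain_key`, `method`
#'   (`override`, `keyword` or `unassigned`).
#' @export
assign_domains <- function(ss, dictionary = default_domain_dictionary(),
                           overrides = NULL) {
  stopifnot(inherits(ss, "study_set"), nrow(dictionary) > 0)
  if (is.character(overrides)) overrides <- read.csv(overrides,
                                                     stringsAsFactors = FALSE)
  forms <- ss$forms
  res <- data.frame(form_id = forms$form_id, trial_id = forms$trial_id,
                    domain_key = "unassigned", method = "unassigned",
                    stringsAsFactors = FALSE)
  kw <- lapply(strsplit(dictionary$keywords, ";", fixed = TRUE),
               function(k) tolower(trimws(k)))
  name_cf <- tolower(squish(forms$form_name))
  for (d in seq_len(nrow(dictionary))) {
    open <- res$method == "unassigned"
    if (!any(open)) break
    hit <- open & Reduce(`|`, lapply(kw[[d]], function(k)
      grepl(k, name_cf, fixed = TRUE)), rep(FALSE, nrow(forms)))
    res$domain_key[hit] <- dictionary$domain_key[d]
    res$method[hit] <- "keyword"
  }
  if (!is.null(overrides) && nrow(overrides) > 0) {
    stopifnot(all(c("form_id", "domain_key") %in% names(overrides)))
    conf <- tapply(overrides$domain_key, overrides$form_id,
                   function(x) length(unique(x)))
    if (any(conf > 1))
      stop("conflicting domain overrides for form(s): ",
           paste(names(conf)[conf > 1], collapse = ", "))
    unknown_f <- setdiff(overrides$form_id, forms$form_id)
    if (length(unknown_f) > 0)
      stop("domain overrides reference unknown form(s): ",
           paste(unknown_f, collapse = ", "))
    unknown_d <- setdiff(overrides$domain_key, dictionary$domain_key)
    if (length(unknown_d) > 0)
      stop("domain overrides reference unknown domain(s): ",
           paste(unknown_d, collapse = ", "))
    ix <- match(overrides$form_id, res$form_id)
    res$domain_key[ix] <- overrides$domain_key
    res$method[ix] <- "override"
  }
  res
}

#' Rank form domains by frequency of occurrence
#'
#' One row per assigned domain (plus `unassigned` when present): the number
#' of distinct trials containing at least one form of the domain, the number
#' of forms, and the number of unique elements (clusters) occurring on those
#' forms when a clustering is supplied. Sorted by `n_trials` then `n_forms`
#' descending, ties broken by `domain_key`.
#'
#' @param assignments output of [assign_domains()].
#' @param ss the `study_set`.
#' @param clusters optional `element_clusters` for unique-element counts.
#' @param dictionary dictionary used for display names / SDTM codes.
#' @return data.frame `domain_key`, `sdtm_code`, `display_name`, `n_trials`,
#'   `n_forms`, `n_unique_elements`.
#' @export
domain_table <- function(assignments, ss, clusters = NULL,
                         dictionary = default_domain_dictionary()) {
  stopifnot(inherits(ss, "study_set"))
  doms <- sort(unique(assignments$domain_key))
  rows <- lapply(doms, function(d) {
    sel <- assignments$domain_key == d
    fids <- assignments$form_id[sel]
    n_el <- NA_integer_
    if (!is.null(clusters)) {
      n_el <- length(unique(
        clusters$members$cluster_id[clusters$members$form_id %in% fids]))
    }
    data.frame(domain_key = d,
               sdtm_code = dictionary$sdtm_code[match(d, dictionary$domain_key)],
               display_name = if (d %in% dictionary$domain_key)
                 dictionary$display_name[match(d, dictionary$domain_key)]
               else d,
               n_trials = length(unique(assignments$trial_id[sel])),
               n_forms = length(fids),
               n_unique_elements = n_el,
               stringsAsFactors = FALSE)
  })
  out <- rbind_all(rows)
  out[order(-out$n_trials, -out$n_forms, out$domain_key, method = "radix"), ,
      drop = FALSE]
}
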