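#' Drop singleton form domains
#'
#' Removes domains whose forms appear no more than once across the whole
#' corpus (`n_forms <= 1`); removals are logged. This is the filter applied
#' before element ranking so that one-off special-purpose forms do not seed
#' inventory entries.
#'
#' @param dt a domain table from [domain_table()].
#' @return the filtered domain table.
#' @export
filter_domains <- function(dt) {
  drop <- dt$n_forms <= 1
  if (any(drop))
    msg("filter_domains: removed singleton domain(s): %s",
        paste(dt$domain_key[drop], collapse = ", "))
  dt[!drop, , drop = FALSE]
}

#' Rank elements by enrollment-weighted frequency
#'
#' For every (element, domain) pair the weighted score is the sum of the
#' planned enrollments of the distinct trials in which the element occurs on
#' a form of that domain (`weight = "per_trial"`, the default); with
#' `weight = "per_form"` every form occurrence contributes its trial's
#' enrollment. Elements spanning several domains are kept once per domain
#' with per-domain scores. Rows are sorted by weighted score, then number of
#' trials, then canonical label, and ranked densely 1..N.
#'
#' @param clusters an `element_clusters` object.
#' @param assignments form-domain assignments from [assign_domains()].
#' @param trials trial-metadata data.frame.
#' @param domains optional character vector of domain keys to keep (e.g. the
#'   `domain_key` column of a [filter_domains()] result); default all.
#' @param weight weighting rule, `"per_trial"` or `"per_form"`.
#' @return data.frame `cde_id`, `canonical_label`, `domain_key`, `category`,
#'   `cdisc_variable_name`, `n_trials`, `n_form_occurrences`,
#'   `weighted_score`, `rank`.
#' @export
rank_elements <- function(clusters, assignments, trials, domains = NULL,
                          weight = c("per_trial", "per_form")) {
  stopifnot(inherits(clusters, "element_clusters"))
  weight <- match.arg(weight)
  trials <- validate_trial_meta(trials)
  mem <- clusters$members
  mem$domain_key <- assignments$domain_key[match(mem$form_id,
                                                 assignments$form_id)]
  if (any(is.na(mem$domain_key)))
    stop("members reference forms without a domain assignment")
  if (!is.null(domains)) mem <- mem[mem$domain_key %in% domains, , drop = FALSE]
  if (nrow(mem) == 0) return(empty_inventory())

  enr <- setNames(trials$planned_enrollment, trials$trial_id)
  key <- paste(mem$cluster_id, mem$domain_key, sep = "\r")
  multi <- tapply(mem$domain_key, mem$cluster_id,
                  function(x) length(unique(x)))
  if (any(multi > 1))
    msg("rank_elements: %d element(s) span multiple domains; kept once per domain",
        sum(multi > 1))
  rows <- lapply(split(seq_len(nrow(mem)), key), function(ix) {
    tid <- unique(mem$trial_id[ix])
    score <- if (weight == "per_trial") sum(enr[tid]) else {
      distinct_forms <- !duplicated(mem$form_id[ix])
      sum(enr[mem$trial_id[ix][distinct_forms]])
    }
    data.frame(cluster_id = mem$cluster_id[ix[1]],
               domain_key = mem$domain_key[ix[1]],
               n_trials = length(tid),
               n_form_occurrences = length(unique(mem$form_id[ix])),
               weighted_score = as.numeric(score),
               stringsAsFactors = FALSE)
  })
  inv <- rbind_all(rows)
  cl <- clusters$clusters
  inv$canonical_label <- cl$canonical_label[match(inv$cluster_id,
                                                  cl$cluster_id)]
  inv$category <- cl$category[match(inv$cluster_id, cl$cluster_id)]
  inv$cdisc_variable_name <- cl$cdisc_variable_name[match(inv$cluster_id,
                                                          cl$cluster_id)]
  inv <- inv[order(-inv$weighted_score, -inv$n_trials,
                   tolower(inv$canonical_label), inv$canonical_label,
                   inv$domain_key, method = "radix"), , drop = FALSE]
  inv$rank <- seq_len(nrow(inv))
  inv$cde_id <- paste(inv$cluster_id, inv$domain_key, sep = ".")
  rownames(inv) <- NULL
  inv[, c("cde_id", "cluster_id", "canonical_label", "domain_key", "category",
          "cdisc_variable_name", "n_trials", "n_form_occurrences",
          "weighted_score", "rank")]
}

empty_inventory <- function() {
  data.frame(cde_id = character(0), cluster_id = character(0),
             canonical_label = character(0), domain_key = character(0),
             category = character(0), cdisc_variable_name = character(0),
             n_trials = integer(0), n_form_occurrences = integer(0),
             weighted_score = numeric(0), rank = integer(0),
             stringsAsFactors = FALSE)
}

#' Attach semantic codes to an inventory
#'
#' Joins a static code-mapping table (UMLS CUI / SNOMED CT) onto inventory
#' rows by `cde_id` or case-folded canonical label. Codes are validated
#' syntactically (`C` + 7 digits; SNOMED all digits); an invalid code aborts
#' naming the offending row. Unmapped elements are flagged `uncoded`.
#'
#' @param inventory output of [rank_elements()].
#' @param code_map data.frame or CSV path with columns `key`, `umls_cui`,
#'   `snomed_code` (either code may be empty).
#' @return the inventory with `umls_cui`, `snomed_code`, `uncoded` columns.
#' @export
annotate <- function(inventory, code_map) {
  if (is.character(code_map)) code_map <- read.csv(code_map,
                                                   stringsAsFactors = FALSE)
  inventory$umls_cui <- NA_character_
  inventory$snomed_code <- NA_character_
  if (!is.null(code_map) && nrow(code_map) > 0) {
    stopifnot("key" %in% names(code_map))
    code_map$umls_cui <- na_if_empty(as.character(code_map$umls_cui %||%
                                                    NA_character_))
    code_map$snomed_code <- na_if_empty(as.character(code_map$snomed_code %||%
                                                       NA_character_))
    bad_cui <- !is.na(code_map$umls_cui) &
      !grepl("^C\\d{7}$", code_map$umls_cui)
    if (any(bad_cui))
      stop("invalid UMLS CUI in code map row(s) ",
           paste(which(bad_cui), collapse = ", "), ": ",
           paste(code_map$umls_cui[bad_cui], collapse = ", "))
    bad_sn <- !is.na(code_map$snomed_code) &
      !grepl("^\\d+$", code_map$snomed_code)
    if (any(bad_sn))
      stop("invalid SNOMED code in code map row(s) ",
           paste(which(bad_sn), collapse = ", "), ": ",
           paste(code_map$snomed_code[bad_sn], collapse = ", "))
    ix <- match(inventory$cde_id, code_map$key)
    fallback <- match(tolower(inventory$canonical_label),
                      tolower(code_map$key))
    ix[is.na(ix)] <- fallback[is.na(ix)]
    hit <- !is.na(ix)
    inventory$umls_cui[hit] <- code_map$umls_cui[ix[hit]]
    inventory$snomed_code[hit] <- code_map$snomed_code[ix[hit]]
  }
  inventory$uncoded <- is.na(inventory$umls_cui) & is.na(inventory$snomed_code)
  if (any(inventory$uncoded))
    msg("annotate: %d element(s) uncoded", sum(inventory$uncoded))
  inventory
}

#' Compare an inventory with a prior element list
#'
#' An element counts as already present in the prior inventory when the UMLS
#' CUIs of both sides are equal, or — when either side lacks a CUI — the
#' case-folded canonical labels are equal. The partition is exhaustive:
#' `n_identical + n_new` equals the current inventory size.
#'
#' @param current inventory data.frame (ideally [annotate()]d).
#' @param prior data.frame or CSV path with columns `label` and optionally
#'   `umls_cui`.
#' @return list `n_identical`, `n_new`, `identical_ids`, `new_ids`.
#' @export
compare_inventories <- function(current, prior) {
  if (is.character(prior)) prior <- read.csv(prior, stringsAsFactors = FALSE)
  stopifnot("label" %in% names(prior))
  if (!"umls_cui" %in% names(prior))
    prior$umls_cui <- rep(NA_character_, nrow(prior))
  prior$umls_cui <- na_if_empty(as.character(prior$umls_cui))
  pk <- ifelse(is.na(prior$umls_cui), paste0("L:", tolower(prior$label)),
               paste0("C:", prior$umls_cui))
  if (anyDuplicated(pk))
    stop("duplicate keys in prior inventory: ",
         paste(unique(pk[duplicated(pk)]), collapse = ", "))
  cur_cui <- if ("umls_cui" %in% names(current)) current$umls_cui
             else rep(NA_character_, nrow(current))
  cui_match <- !is.na(cur_cui) & cur_cui %in% prior$umls_cui
  # label matching applies when either side lacks a CUI
  lab_prior <- tolower(prior$label)
  lab_match <- tolower(current$canonical_label) %in% lab_prior &
    (is.na(cur_cui) |
       is.na(prior$umls_cui[match(tolower(current$canonical_label), lab_prior)]))
  identical <- cui_match | lab_match
  list(n_identical = sum(identical),
       n_new = sum(!identical),
       identical_ids = current$cde_id[identical],
       new_ids = current$cde_id[!identical])
}

#' Write an inventory CSV
#'
#' @param inventory inventory data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_inventory_csv <- function(inventory, path) {
  write_csv_stable(inventory, path)
}
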