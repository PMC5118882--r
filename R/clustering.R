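#' Similarity configuration for label matching
#'
#' Controls the fuzzy-matching rule used by [is_match()] and
#' [cluster_labels()]. Two cleaned labels are fuzzy-matched when their
#' Jaro-Winkler similarity reaches `jw_threshold` AND their Levenshtein
#' distance is at most `min(lev_max, floor(lev_len_ratio * max(nchar)))`,
#' optionally also requiring identical Metaphone codes. The configuration is
#' attached to every clustering result so each run logs its parameters.
#'
#' @param jw_threshold minimum Jaro-Winkler similarity in \[0, 1\].
#' @param lev_max maximum Levenshtein distance (edit operations).
#' @param lev_len_ratio length-relative cap on the Levenshtein distance,
#'   in (0, 1\].
#' @param require_phonetic_agreement require equal Metaphone codes for a
#'   fuzzy match.
#' @param winkler_prefix_weight Jaro-Winkler prefix weight, at most 0.25.
#' @param max_cluster_frac fraction of all items beyond which a single
#'   cluster triggers a threshold-review warning.
#' @param scope `"corpus"` to match across the whole corpus (default) or
#'   `"domain"` to match only within form domains.
#' @return an object of class `similarity_config`.
#' @export
similarity_config <- function(jw_threshold = 0.90, lev_max = 3L,
                              lev_len_ratio = 0.25,
                              require_phonetic_agreement = FALSE,
                              winkler_prefix_weight = 0.1,
                              max_cluster_frac = 0.25,
                              scope = c("corpus", "domain")) {
  stopifnot(jw_threshold >= 0, jw_threshold <= 1,
            lev_max >= 0,
            lev_len_ratio > 0, lev_len_ratio <= 1,
            is.logical(require_phonetic_agreement),
            winkler_prefix_weight >= 0, winkler_prefix_weight <= 0.25,
            max_cluster_frac > 0, max_cluster_frac <= 1)
  structure(list(jw_threshold = jw_threshold, lev_max = as.integer(lev_max),
                 lev_len_ratio = lev_len_ratio,
                 require_phonetic_agreement = require_phonetic_agreement,
                 winkler_prefix_weight = winkler_prefix_weight,
                 max_cluster_frac = max_cluster_frac,
                 scope = match.arg(scope)),
            class = "similarity_config")
}

#' Decide whether two cleaned labels denote the same element
#'
#' Decision order: equal non-missing CDISC variable names match outright
#' (reason `"cdisc"`); unequal non-missing variable names veto any match;
#' case-folded equal texts match (reason `"exact"`); otherwise the fuzzy rule
#' of [similarity_config()] applies (reason `"fuzzy"`).
#'
#' @param a,b cleaned label texts (single strings).
#' @param va,vb optional CDISC variable names (`NA` when absent).
#' @param cfg a [similarity_config()].
#' @return list with elements `match` (logical) and `reason`
#'   (`"cdisc"`, `"exact"`, `"fuzzy"` or `"none"`).
#' @export
is_match <- function(a, b, va = NA_character_, vb = NA_character_,
                     cfg = similarity_config()) {
  va_ok <- !is.na(va) && nzchar(va)
  vb_ok <- !is.na(vb) && nzchar(vb)
  if (va_ok && vb_ok) {
    if (toupper(va) == toupper(vb))
      return(list(match = TRUE, reason = "cdisc"))
    return(list(match = FALSE, reason = "none"))  # hard-key veto
  }
  ca <- tolower(a); cb <- tolower(b)
  if (ca == cb) return(list(match = TRUE, reason = "exact"))
  if (fuzzy_pair(ca, cb, cfg))
    return(list(match = TRUE, reason = "fuzzy"))
  list(match = FALSE, reason = "none")
}

# vectorized fuzzy rule on case-folded texts: b may be a vector
fuzzy_pair <- function(a, b, cfg) {
  ok <- jaro_winkler(a, b, cfg$winkler_prefix_weight) >= cfg$jw_threshold
  if (any(ok)) {
    cap <- pmin(cfg$lev_max,
                floor(cfg$lev_len_ratio * pmax(nchar(a), nchar(b[ok]))))
    ok[ok] <- levenshtein(a, b[ok]) <= cap
  }
  if (cfg$require_phonetic_agreement && any(ok)) {
    ok[ok] <- metaphone(a) == metaphone(b[ok])
  }
  ok
}

# union-find with component-level CDISC-name compatibility
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Cluster item labels into canonical elements
#'
#' Single-linkage agglomeration over [is_match()] decisions. Items are
#' cleaned, sorted into a canonical order (case-folded text, trial, form,
#' item) so the result is independent of input order, deduplicated into
#' label nodes, and merged in three passes: exact case-folded equality,
#' shared CDISC variable names (a cross-block pass), and fuzzy matching
#' within blocks keyed by the first character of the Metaphone code. Two
#' components carrying distinct non-missing variable names are never merged.
#' The canonical label is the modal variant's cleaned text, ties broken by
#' shortest then lexicographically smallest.
#'
#' @param items data.frame with columns `item_id`, `form_id`, `trial_id`,
#'   `raw_label` and optionally `cdisc_variable_name`.
#' @param cfg a [similarity_config()].
#' @param unit_lexicon unit strings passed to [clean_label()].
#' @return an object of class `element_clusters`: list with `clusters`
#'   (cluster_id, canonical_label, cdisc_variable_name, category, locked,
#'   n_items), `members` (one row per clustered item), `excluded`
#'   (items empty after cleaning) and `config`.
#' @export
cluster_labels <- function(items, cfg = similarity_config(),
                           unit_lexicon = default_unit_lexicon()) {
  stopifnot(is.data.frame(items),
            all(c("item_id", "form_id", "trial_id", "raw_label") %in%
                  names(items)))
  if (!"cdisc_variable_name" %in% names(items))
    items$cdisc_variable_name <- NA_character_
  if (nrow(items) == 0) return(empty_clusters(cfg))

  cl <- clean_label(items$raw_label, unit_lexicon)
  items$clean_text <- cl$text
  items$removed_units <- cl$removed_units
  excluded <- items[cl$empty_after_clean, , drop = FALSE]
  if (nrow(excluded) > 0)
    msg("cluster_labels: excluded %d item(s) empty after cleaning",
        nrow(excluded))
  items <- items[!cl$empty_after_clean, , drop = FALSE]
  if (nrow(items) == 0) return(empty_clusters(cfg, excluded))

  items$cf_text <- tolower(items$clean_text)
  items$var_key <- toupper(na_if_empty(items$cdisc_variable_name))
  ord <- order(items$cf_text, items$trial_id, items$form_id, items$item_id,
               method = "radix")
  items <- items[ord, , drop = FALSE]

  # label nodes: unique (case-folded text, variable-name key)
  node_key <- paste(items$cf_text, ifelse(is.na(items$var_key), "", items$var_key),
                    sep = "\r")
  first <- !duplicated(node_key)
  nodes <- data.frame(cf_text = items$cf_text[first],
                      var_key = items$var_key[first],
                      stringsAsFactors = FALSE)
  node_of_item <- match(node_key, node_key[first])
  n <- nrow(nodes)
  nodes$mp <- metaphone(nodes$cf_text)

  parent <- seq_len(n)
  comp_var <- nodes$var_key  # representative non-missing variable name
  try_union <- function(i, j, check_var = TRUE) {
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri == rj) return(invisible())
    vi <- comp_var[ri]; vj <- comp_var[rj]
    if (check_var && !is.na(vi) && !is.na(vj) && vi != vj) return(invisible())
    lo <- min(ri, rj); hi <- max(ri, rj)
    parent[hi] <<- lo
    comp_var[lo] <<- if (!is.na(vi)) vi else vj
    invisible()
  }

  # pass 1: exact case-folded text equality (variable names permitting)
  by_text <- split(seq_len(n), nodes$cf_text)
  for (idx in by_text) {
    if (length(idx) > 1)
      for (k in idx[-1]) try_union(idx[1], k)
  }
  # pass 2: shared CDISC variable names are hard keys across blocks
  has_var <- which(!is.na(nodes$var_key))
  by_var <- split(has_var, nodes$var_key[has_var])
  for (idx in by_var) {
    if (length(idx) > 1)
      for (k in idx[-1]) try_union(idx[1], k, check_var = FALSE)
  }
  # pass 3: fuzzy matching within metaphone-initial blocks
  block <- substr(nodes$mp, 1, 1)
  block[!nzchar(block)] <- "_"
  for (idx in split(seq_len(n), block)) {
    m <- length(idx)
    if (m < 2) next
    # unique texts within the block to avoid rescoring equal strings
    txt <- nodes$cf_text[idx]
    for (i in seq_len(m - 1)) {
      rest <- idx[(i + 1):m]
      hit <- fuzzy_pair(txt[i], txt[(i + 1):m], cfg)
      for (j in rest[hit]) try_union(idx[i], j)
    }
  }

  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  items$node_root <- roots[node_of_item]

  # canonical label per cluster: modal cleaned text over items,
  # ties -> shortest, then lexicographically smallest
  clusters_l <- lapply(split(seq_len(nrow(items)), items$node_root), function(ix) {
    tx <- items$clean_text[ix]
    tab <- table(tx)
    best <- names(tab)[tab == max(tab)]
    best <- best[order(nchar(best), best)][1]
    vk <- unique(items$var_key[ix])
    vk <- vk[!is.na(vk)]
    data.frame(canonical_label = best,
               cdisc_variable_name = if (length(vk) == 1) vk else NA_character_,
               n_items = length(ix), root = items$node_root[ix[1]],
               stringsAsFactors = FALSE)
  })
  clusters <- rbind_all(clusters_l)
  clusters <- clusters[order(tolower(clusters$canonical_label),
                             clusters$canonical_label, method = "radix"), ,
                       drop = FALSE]
  clusters$cluster_id <- make_ids("CL", nrow(clusters))
  clusters$category <- "clinical"
  clusters$locked <- FALSE

  items$cluster_id <- clusters$cluster_id[match(items$node_root, clusters$root)]
  canon_cf <- tolower(clusters$canonical_label)[match(items$cluster_id,
                                                      clusters$cluster_id)]
  canon_var <- clusters$cdisc_variable_name[match(items$cluster_id,
                                                  clusters$cluster_id)]
  items$reason <- ifelse(items$cf_text == canon_cf, "exact",
                         ifelse(!is.na(items$var_key) & !is.na(canon_var) &
                                  items$var_key == canon_var, "cdisc", "fuzzy"))

  if (nrow(items) >= 50 &&
      max(clusters$n_items) > cfg$max_cluster_frac * nrow(items) &&
      nrow(clusters) > 1)
    warning("one cluster absorbed ",
            round(100 * max(clusters$n_items) / nrow(items)),
            "% of all items; review similarity thresholds")

  members <- items[, c("cluster_id", "item_id", "form_id", "trial_id",
                       "raw_label", "clean_text", "removed_units", "reason")]
  structure(
    list(clusters = clusters[, c("cluster_id", "canonical_label",
                                 "cdisc_variable_name", "category",
                                 "locked", "n_items")],
         members = members, excluded = excluded, removed = empty_members(),
         config = cfg),
    class = "element_clusters"
  )
}

empty_members <- function() {
  data.frame(cluster_id = character(0), item_id = character(0),
             form_id = character(0), trial_id = character(0),
             raw_label = character(0), clean_text = character(0),
             removed_units = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

empty_clusters <- function(cfg, excluded = NULL) {
  structure(
    list(clusters = data.frame(cluster_id = character(0),
                               canonical_label = character(0),
                               cdisc_variable_name = character(0),
                               category = character(0), locked = logical(0),
                               n_items = integer(0), stringsAsFactors = FALSE),
         members = empty_members(),
         excluded = excluded %||% empty_items(), removed = empty_members(),
         config = cfg),
    class = "element_clusters"
  )
}

#' @export
print.element_clusters <- function(x, ...) {
  cat(sprintf("element_clusters: %d clusters over %d items (%d excluded, %d removed)\n",
              nrow(x$clusters), nrow(x$members), nrow(x$excluded),
              nrow(x$removed)))
  invisible(x)
}

#' Apply an expert override table to clusters
#'
#' Overrides stand in for the expert review that validates automated label
#' normalization. Rows are applied in file order; every touched cluster is
#' marked `locked`. Supported actions (columns `action`, `cluster`, `variant`,
#' `value`):
#' \describe{
#'   \item{merge}{absorb cluster `value` into cluster `cluster`}
#'   \item{split}{move members of `cluster` whose raw label equals `variant`
#'     into a new cluster named `value` (default: the variant's cleaned text)}
#'   \item{rename}{set the canonical label of `cluster` to `value`}
#'   \item{remove}{drop `cluster`; its members are logged under `removed`}
#'   \item{recategorize}{set `cluster`'s category to `value`
#'     (`clinical` or `administrative`)}
#' }
#' Clusters may be referenced by `cluster_id` or canonical label.
#'
#' @param ec an `element_clusters` object.
#' @param overrides data.frame or CSV path with the columns above.
#' @return the modified `element_clusters`.
#' @export
apply_overrides <- function(ec, overrides) {
  stopifnot(inherits(ec, "element_clusters"))
  if (is.character(overrides)) overrides <- read.csv(overrides,
                                                     stringsAsFactors = FALSE)
  if (is.null(overrides) || nrow(overrides) == 0) return(ec)
  for (col in c("variant", "value"))
    if (!col %in% names(overrides)) overrides[[col]] <- NA_character_
  stopifnot(all(c("action", "cluster") %in% names(overrides)))

  resolve <- function(ref) {
    hit <- which(ec$clusters$cluster_id == ref)
    if (length(hit) == 0)
      hit <- which(tolower(ec$clusters$canonical_label) == tolower(ref))
    hit
  }
  unresolved <- character(0)
  for (r in seq_len(nrow(overrides))) {
    act <- overrides$action[r]
    ref <- as.character(overrides$cluster[r])
    val <- as.character(overrides$value[r])
    hit <- resolve(ref)
    if (length(hit) != 1) {
      unresolved <- c(unresolved, sprintf("row %d: cluster '%s'", r, ref))
      next
    }
    cid <- ec$clusters$cluster_id[hit]
    if (act == "rename") {
      ec$clusters$canonical_label[hit] <- val
      ec$clusters$locked[hit] <- TRUE
    } else if (act == "recategorize") {
      if (!val %in% c("clinical", "administrative"))
        stop("recategorize value must be 'clinical' or 'administrative' (row ",
             r, ")")
      ec$clusters$category[hit] <- val
      ec$clusters$locked[hit] <- TRUE
    } else if (act == "remove") {
      gone <- ec$members$cluster_id == cid
      rem <- ec$members[gone, , drop = FALSE]
      rem$reason <- paste0("removed:row", r)
      ec$removed <- rbind(ec$removed, rem, make.row.names = FALSE)
      ec$members <- ec$members[!gone, , drop = FALSE]
      ec$clusters <- ec$clusters[-hit, , drop = FALSE]
      msg("apply_overrides: removed cluster %s ('%s'), %d member(s)",
          cid, ref, nrow(rem))
    } else if (act == "merge") {
      hit2 <- resolve(val)
      if (length(hit2) != 1) {
        unresolved <- c(unresolved, sprintf("row %d: cluster '%s'", r, val))
        next
      }
      cid2 <- ec$clusters$cluster_id[hit2]
      if (cid2 == cid) next
      ec$members$cluster_id[ec$members$cluster_id == cid2] <- cid
      ec$clusters$n_items[hit] <- ec$clusters$n_items[hit] +
        ec$clusters$n_items[hit2]
      ec$clusters$locked[hit] <- TRUE
      ec$clusters <- ec$clusters[-hit2, , drop = FALSE]
    } else if (act == "split") {
      variant <- as.character(overrides$variant[r])
      sel <- ec$members$cluster_id == cid & ec$members$raw_label == variant
      if (!any(sel)) {
        unresolved <- c(unresolved,
                        sprintf("row %d: variant '%s' not in cluster '%s'",
                                r, variant, ref))
        next
      }
      new_id <- next_cluster_id(ec$clusters$cluster_id)
      new_label <- if (!is.na(val) && nzchar(val)) val
                   else ec$members$clean_text[sel][1]
      ec$clusters <- rbind(
        ec$clusters,
        data.frame(cluster_id = new_id, canonical_label = new_label,
                   cdisc_variable_name = NA_character_,
                   category = ec$clusters$category[hit], locked = TRUE,
                   n_items = sum(sel), stringsAsFactors = FALSE),
        make.row.names = FALSE)
      ec$clusters$n_items[hit] <- ec$clusters$n_items[hit] - sum(sel)
      ec$clusters$locked[hit] <- TRUE
      ec$members$cluster_id[sel] <- new_id
    } else {
      stop("unknown override action '", act, "' (row ", r, ")")
    }
  }
  if (length(unresolved) > 0)
    stop("override rows reference unknown clusters/variants:\n  ",
         paste(unresolved, collapse = "\n  "))
  ec
}

next_cluster_id <- function(existing) {
  k <- suppressWarnings(max(as.integer(sub("^CL", "", existing)), 0L,
                            na.rm = TRUE))
  sprintf("CL%0*d", max(4L, nchar(k + 1L)), k + 1L)
}

#' Pairwise precision, recall and F1 of a clustering against ground truth
#'
#' Pairs of items placed in the same predicted cluster are compared with
#' pairs sharing a true element. Computed from the contingency table, so it
#' scales to large corpora.
#'
#' @param predicted,truth vectors of cluster / element labels, aligned by item.
#' @return list with `precision`, `recall` and `f1`.
#' @export
pairwise_cluster_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  choose2 <- function(x) sum(x * (x - 1) / 2)
  tab <- table(predicted, truth)
  tp <- choose2(as.vector(tab))
  pred_pairs <- choose2(as.vector(table(predicted)))
  true_pairs <- choose2(as.vector(table(truth)))
  precision <- if (pred_pairs == 0) 1 else tp / pred_pairs
  recall <- if (true_pairs == 0) 1 else tp / true_pairs
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Write cluster output as CSV
#'
#' One row per member: `cluster_id`, `canonical_label`, `variant`,
#' `trial_id`, `form_id`, `reason`.
#'
#' @param ec an `element_clusters` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_clusters_csv <- function(ec, path) {
  stopifnot(inherits(ec, "element_clusters"))
  out <- ec$members
  out$canonical_label <- ec$clusters$canonical_label[
    match(out$cluster_id, ec$clusters$cluster_id)]
  out <- out[, c("cluster_id", "canonical_label", "raw_label", "trial_id",
                 "form_id", "reason")]
  names(out)[3] <- "variant"
  write_csv_stable(out, path)
}
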