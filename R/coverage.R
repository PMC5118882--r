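#' Frequency of documentation
#'
#' Percent of patients for whom an element was documented in the reference
#' year: `100 * n_values / n_patients`, rounded half-up to one decimal.
#' Values above 100 are legitimate (several values per patient).
#'
#' @param n_values number of entered values in the reference year.
#' @param n_patients total patients in the reference year (>= 1).
#' @return numeric vector of percentages with one decimal.
#' @examples
#' compute_frequency(9574, 31493)  # 30.4
#' @export
compute_frequency <- function(n_values, n_patients) {
  if (any(is.na(n_values) | n_values < 0))
    stop("n_values must be non-negative")
  if (any(is.na(n_patients) | n_patients < 1))
    stop("undefined frequency: n_patients must be >= 1")
  round_half_up(100 * n_values / n_patients, 1)
}

#' Read per-site EHR export tables
#'
#' Each file carries columns `site_id`, `element_key`, `n_values`,
#' `n_patients`, `availability` (`available` / `not_available` / `unknown`),
#' `year`.
#'
#' @param paths character vector of CSV paths.
#' @return one combined data.frame.
#' @export
read_site_exports <- function(paths) {
  need <- c("site_id", "element_key", "n_values", "n_patients",
            "availability", "year")
  dfs <- lapply(paths, function(p) {
    df <- read.csv(p, stringsAsFactors = FALSE)
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop("site export '", p, "' missing column(s): ",
           paste(miss, collapse = ", "))
    df[, need]
  })
  rbind_all(dfs)
}

#' Classify export rows into coverage cells
#'
#' A row with usable counts becomes a `frequency` cell; otherwise the
#' availability flag is passed through (`available` / `not_available`);
#' `unknown` availability without counts degrades to `not_available` with a
#' warning. Rows violating the export invariant (`not_available` yet
#' `n_values > 0`) are rejected and logged.
#'
#' @param exports data.frame of export rows (see [read_site_exports()]).
#' @return data.frame `site_id`, `element_key`, `status`, `frequency_pct`,
#'   with rejected rows in attribute `"rejected"`.
#' @export
classify_cells <- function(exports) {
  ex <- exports
  ex$n_values <- suppressWarnings(as.numeric(ex$n_values))
  ex$n_patients <- suppressWarnings(as.numeric(ex$n_patients))
  bad <- !is.na(ex$availability) & ex$availability == "not_available" &
    !is.na(ex$n_values) & ex$n_values > 0
  if (any(bad)) {
    msg("classify_cells: rejected %d row(s) flagged not_available with values",
        sum(bad))
  }
  rejected <- ex[bad, , drop = FALSE]
  ex <- ex[!bad, , drop = FALSE]

  has_counts <- !is.na(ex$n_values) & !is.na(ex$n_patients) & ex$n_patients >= 1
  status <- character(nrow(ex))
  freq <- rep(NA_real_, nrow(ex))
  status[has_counts] <- "frequency"
  if (any(has_counts))
    freq[has_counts] <- compute_frequency(ex$n_values[has_counts],
                                          ex$n_patients[has_counts])
  flag <- ex$availability
  no_counts <- !has_counts
  status[no_counts & flag == "available"] <- "available"
  status[no_counts & flag == "not_available"] <- "not_available"
  unk <- no_counts & (is.na(flag) | flag == "unknown")
  if (any(unk)) {
    warning(sum(unk), " export row(s) with unknown availability degraded to",
            " not_available")
    status[unk] <- "not_available"
  }
  out <- data.frame(site_id = as.character(ex$site_id),
                    element_key = as.character(ex$element_key),
                    status = status, frequency_pct = freq,
                    stringsAsFactors = FALSE)
  attr(out, "rejected") <- rejected
  out
}

#' Build the coverage heat-map matrix
#'
#' Matches coverage cells to inventory elements (by `cde_id`, then semantic
#' code, then case-folded canonical label; keys matching several elements are
#' rejected with a warning), completes the grid — any (element, site) pair a
#' site did not report defaults to `not_available` — and orders rows by the
#' number of sites where the element is present, then by mean frequency, then
#' by label. Duplicate (site, element) cells are a fatal error.
#'
#' @param cells classified cells from [classify_cells()].
#' @param inventory inventory data.frame (with codes if [annotate()]d).
#' @param sites optional fixed site set; default the sites present in `cells`.
#' @return object of class `coverage_heatmap`: list with `matrix` (character,
#'   `"30.4"` / `"A"` / `"N/A"`), `frequency` (numeric matrix, NA where no
#'   frequency), `cells` (completed long form) and `ordering_rule`.
#' @export
build_heatmap <- function(cells, inventory, sites = NULL) {
  stopifnot(nrow(inventory) > 0)
  sites <- sort(unique(as.character(sites %||% cells$site_id)))

  # resolve element keys against the inventory
  key_ix <- resolve_element_keys(cells$element_key, inventory)
  amb <- is.na(key_ix$ix) & key_ix$ambiguous
  if (any(amb)) {
    warning("rejected ", sum(amb), " cell(s) with ambiguous element key(s): ",
            paste(unique(cells$element_key[amb]), collapse = ", "))
  }
  unk <- is.na(key_ix$ix) & !key_ix$ambiguous
  if (any(unk))
    msg("build_heatmap: %d cell(s) reference elements outside the inventory",
        sum(unk))
  cells <- cells[!is.na(key_ix$ix), , drop = FALSE]
  cells$cde_id <- inventory$cde_id[key_ix$ix[!is.na(key_ix$ix)]]

  dup <- duplicated(paste(cells$site_id, cells$cde_id, sep = "\r"))
  if (any(dup))
    stop("duplicate (site, element) cells: ",
         paste(unique(paste0("(", cells$site_id[dup], ", ", cells$cde_id[dup],
                             ")")), collapse = ", "))

  # complete grid
  grid <- expand.grid(cde_id = inventory$cde_id, site_id = sites,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ix <- match(paste(grid$site_id, grid$cde_id, sep = "\r"),
              paste(cells$site_id, cells$cde_id, sep = "\r"))
  grid$status <- ifelse(is.na(ix), "not_available", cells$status[ix])
  grid$frequency_pct <- ifelse(is.na(ix), NA_real_, cells$frequency_pct[ix])

  # row ordering
  lab <- inventory$canonical_label[match(grid$cde_id, inventory$cde_id)]
  present <- tapply(grid$status != "not_available", grid$cde_id, sum)
  meanfreq <- tapply(grid$frequency_pct, grid$cde_id,
                     function(x) if (all(is.na(x))) -Inf else mean(x, na.rm = TRUE))
  labs <- tapply(lab, grid$cde_id, `[`, 1)
  ids <- names(present)
  row_order <- ids[order(-present, -meanfreq, tolower(labs), labs,
                         method = "radix")]

  fmt <- ifelse(grid$status == "frequency", sprintf("%.1f", grid$frequency_pct),
                ifelse(grid$status == "available", "A", "N/A"))
  m <- matrix(NA_character_, nrow = length(row_order), ncol = length(sites),
              dimnames = list(row_order, sites))
  fm <- matrix(NA_real_, nrow = length(row_order), ncol = length(sites),
               dimnames = list(row_order, sites))
  m[cbind(match(grid$cde_id, row_order), match(grid$site_id, sites))] <- fmt
  fsel <- grid$status == "frequency"
  fm[cbind(match(grid$cde_id[fsel], row_order),
           match(grid$site_id[fsel], sites))] <- grid$frequency_pct[fsel]
  rownames(m) <- rownames(fm) <-
    inventory$canonical_label[match(row_order, inventory$cde_id)]

  structure(
    list(matrix = m, frequency = fm, cells = grid, row_ids = row_order,
         ordering_rule = "n_sites_present desc, mean frequency desc, label asc"),
    class = "coverage_heatmap")
}

resolve_element_keys <- function(keys, inventory) {
  keys <- as.character(keys)
  n_match <- integer(length(keys))
  ix <- rep(NA_integer_, length(keys))
  lookup <- function(vec, key_vec) {
    vapply(key_vec, function(k) {
      hits <- which(!is.na(vec) & vec == k)
      if (length(hits) == 0) NA_integer_
      else if (length(hits) == 1) as.integer(hits)
      else -1L  # ambiguous
    }, integer(1), USE.NAMES = FALSE)
  }
  by_id <- lookup(inventory$cde_id, keys)
  by_cui <- if ("umls_cui" %in% names(inventory))
    lookup(inventory$umls_cui, keys) else rep(NA_integer_, length(keys))
  by_sn <- if ("snomed_code" %in% names(inventory))
    lookup(as.character(inventory$snomed_code), keys)
  else rep(NA_integer_, length(keys))
  by_lab <- lookup(tolower(inventory$canonical_label), tolower(keys))
  pick <- by_id
  pick[is.na(pick)] <- by_cui[is.na(pick)]
  pick[is.na(pick)] <- by_sn[is.na(pick)]
  pick[is.na(pick)] <- by_lab[is.na(pick)]
  ambiguous <- !is.na(pick) & pick == -1L
  pick[ambiguous] <- NA_integer_
  list(ix = pick, ambiguous = ambiguous)
}

#' @export
print.coverage_heatmap <- function(x, ...) {
  cat(sprintf("coverage_heatmap: %d elements x %d sites\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Write a heat-map matrix as CSV
#'
#' Cells are `"30.4"` (frequency percent), `"A"` (available) or `"N/A"`.
#'
#' @param hm a `coverage_heatmap`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_heatmap_csv <- function(hm, path) {
  stopifnot(inherits(hm, "coverage_heatmap"))
  df <- data.frame(element = rownames(hm$matrix), hm$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_csv_stable(df, path)
}

#' Render a coverage heat map
#'
#' Draws the frequency matrix with pheatmap when available; availability-only
#' cells are blank. Intended for quick visual inspection, not the canonical
#' output (which is the CSV matrix).
#'
#' @param hm a `coverage_heatmap`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
render_heatmap <- function(hm, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("render_heatmap requires the 'pheatmap' package")
  fm <- hm$frequency
  fm[is.na(fm)] <- 0
  p <- pheatmap::pheatmap(fm, cluster_rows = FALSE, cluster_cols = FALSE, ...)
  invisible(p)
}
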