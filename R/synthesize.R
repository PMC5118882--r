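#' Label-noise model for the synthetic corpus
#'
#' Parameterizes the perturbations applied to vocabulary labels when CRF items
#' are generated: sporadic case changes, markup wrapping, unit suffixes and
#' typos — exactly the variation label normalization exists to undo. Draw
#' order is fixed (typo, unit suffix, markup, case) so results are stable for
#' a given seed.
#'
#' @param p_case_change probability of re-casing the label.
#' @param p_html_wrap probability of wrapping the label in markup.
#' @param p_unit_suffix probability of appending the element's unit.
#' @param p_typo probability of injecting a typo (labels of 8+ characters
#'   only; the first four characters are left intact, mirroring the
#'   empirical tendency of misspellings to spare word onsets).
#' @param typo_edits integer range of edit operations per injected typo.
#' @param p_cdisc_name_present probability that an item carries its CDISC
#'   variable name.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(p_case_change = 0.15, p_html_wrap = 0.10,
                        p_unit_suffix = 0.15, p_typo = 0.05,
                        typo_edits = c(1L, 1L),
                        p_cdisc_name_present = 0.4) {
  p <- c(p_case_change, p_html_wrap, p_unit_suffix, p_typo,
         p_cdisc_name_present)
  stopifnot(all(p >= 0 & p <= 1), all(typo_edits >= 1),
            length(typo_edits) == 2, typo_edits[1] <= typo_edits[2])
  structure(list(p_case_change = p_case_change, p_html_wrap = p_html_wrap,
                 p_unit_suffix = p_unit_suffix, p_typo = p_typo,
                 typo_edits = as.integer(typo_edits),
                 p_cdisc_name_present = p_cdisc_name_present),
            class = "noise_model")
}

#' Synthetic-corpus generator configuration
#'
#' Defaults emulate the shape of a 23-trial multi-company CRF corpus: trials
#' per disease area (3, 3, 2, 1, 3, 1, 10), per-area form totals
#' (158, 172, 60, 64, 192, 69, 371 — 1086 forms in all), 22–164 forms per
#' trial, four-digit planned enrollments, and a serious-adverse-event item
#' block on adverse-event forms.
#'
#' @param n_trials_per_area named integer vector over [disease_areas()].
#' @param forms_per_area named integer vector of per-area form totals, or
#'   `NULL` to draw per-trial form counts uniformly from `forms_per_trial`.
#' @param forms_per_trial inclusive bounds on forms per trial.
#' @param elements_per_form inclusive bounds on items per form.
#' @param enrollment_range inclusive bounds on planned enrollment.
#' @param n_sites_range inclusive bounds on participating sites per trial.
#' @param noise a [noise_model()].
#' @param seed integer RNG seed, recorded in the output manifest.
#' @param sae_block include the SAE item set on adverse-event forms.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(
    n_trials_per_area = c(cardiovascular = 3L, diabetes = 3L, infectious = 2L,
                          neuroscience = 1L, oncology = 3L, psychiatric = 1L,
                          respiratory = 10L),
    forms_per_area = c(cardiovascular = 158L, diabetes = 172L,
                       infectious = 60L, neuroscience = 64L, oncology = 192L,
                       psychiatric = 69L, respiratory = 371L),
    forms_per_trial = c(22L, 164L),
    elements_per_form = c(8L, 18L),
    enrollment_range = c(1000L, 9999L),
    n_sites_range = c(20L, 300L),
    noise = noise_model(),
    seed = 1L,
    sae_block = TRUE) {
  stopifnot(all(names(n_trials_per_area) %in% disease_areas()),
            all(n_trials_per_area >= 0),
            forms_per_trial[1] >= 1, forms_per_trial[1] < forms_per_trial[2],
            elements_per_form[1] >= 1,
            elements_per_form[1] < elements_per_form[2],
            enrollment_range[1] >= 1, enrollment_range[1] < enrollment_range[2],
            inherits(noise, "noise_model"))
  if (!is.null(forms_per_area)) {
    stopifnot(identical(sort(names(forms_per_area)),
                        sort(names(n_trials_per_area))))
    lo <- n_trials_per_area * forms_per_trial[1]
    hi <- n_trials_per_area * forms_per_trial[2]
    fa <- forms_per_area[names(n_trials_per_area)]
    if (any(fa < lo | fa > hi))
      stop("forms_per_area incompatible with forms_per_trial bounds for: ",
           paste(names(fa)[fa < lo | fa > hi], collapse = ", "))
  }
  structure(list(n_trials_per_area = n_trials_per_area,
                 forms_per_area = forms_per_area,
                 forms_per_trial = as.integer(forms_per_trial),
                 elements_per_form = as.integer(elements_per_form),
                 enrollment_range = as.integer(enrollment_range),
                 n_sites_range = as.integer(n_sites_range),
                 noise = noise, seed = as.integer(seed),
                 sae_block = isTRUE(sae_block)),
            class = "generator_config")
}

#' Element vocabulary backing the generator
#'
#' Around 300 synthetic-but-plausible element names across the fourteen form
#' domains plus a block of administrative elements reused on every form, with
#' CDISC-style variable names, units, data types and synthetic semantic codes.
#'
#' @return data.frame with columns `element_id`, `label`, `domain_key`,
#'   `category`, `sdtm_variable`, `unit`, `data_type`, `sae`, `umls_cui`,
#'   `snomed_code`.
#' @export
element_vocabulary <- function() {
  path <- system.file("extdata", "element_vocabulary_synthetic.csv",
                      package = "cdeinventory")
  v <- read.csv(path, stringsAsFactors = FALSE)
  v$sdtm_variable <- na_if_empty(v$sdtm_variable)
  v$unit <- na_if_empty(v$unit)
  v$umls_cui <- na_if_empty(v$umls_cui)
  v$snomed_code <- na_if_empty(as.character(v$snomed_code))
  v$sae <- as.logical(v$sae)
  v
}

#' Default semantic code map derived from the vocabulary
#'
#' @return data.frame `key`, `umls_cui`, `snomed_code` keyed by element label,
#'   usable with [annotate()].
#' @export
default_code_map <- function() {
  v <- element_vocabulary()
  data.frame(key = v$label, umls_cui = v$umls_cui,
             snomed_code = v$snomed_code, stringsAsFactors = FALSE)
}

#' Synthetic prior inventory
#'
#' A fixed subset of the vocabulary (demographics, vital signs and common
#' laboratory analytes) standing in for a previously published recruitment
#' inventory, used by [compare_inventories()].
#'
#' @return data.frame `label`, `umls_cui`.
#' @export
synthetic_prior_inventory <- function() {
  v <- element_vocabulary()
  sel <- v$domain_key %in% c("demographics", "vital_signs") |
    (v$domain_key == "laboratory" & seq_len(nrow(v)) %% 2 == 0) |
    v$category == "administrative"
  data.frame(label = v$label[sel], umls_cui = v$umls_cui[sel],
             stringsAsFactors = FALSE)
}

#' Perturb a label under a noise model
#'
#' Applies, in fixed draw order, an optional typo (edit operations after the
#' fourth character of labels with at least eight), a unit suffix, markup
#' wrapping and a case change. The typo's true edit distance is recomputed
#' with [levenshtein()] and recorded.
#'
#' @param label the clean vocabulary label.
#' @param noise a [noise_model()].
#' @param unit unit string appended when the unit-suffix perturbation fires
#'   (skipped when `NA`).
#' @return list `label` (perturbed), `rules` (character vector of applied
#'   perturbations), `typo_edit_distance` (0 when no typo).
#' @export
perturb_label <- function(label, noise, unit = NA_character_) {
  stopifnot(nzchar(label))
  out <- label
  rules <- character(0)
  typo_d <- 0L

  if (stats::runif(1) < noise$p_typo && nchar(out) >= 8) {
    n_edits <- sample(seq(noise$typo_edits[1], noise$typo_edits[2]), 1)
    mutated <- out
    for (k in seq_len(n_edits)) {
      pos <- sample(5:nchar(mutated), 1)
      op <- sample(c("sub", "del", "ins"), 1)
      letters_pool <- letters[letters != tolower(substr(mutated, pos, pos))]
      mutated <- switch(op,
        sub = paste0(substr(mutated, 1, pos - 1), sample(letters_pool, 1),
                     substr(mutated, pos + 1, nchar(mutated))),
        del = paste0(substr(mutated, 1, pos - 1),
                     substr(mutated, pos + 1, nchar(mutated))),
        ins = paste0(substr(mutated, 1, pos), sample(letters, 1),
                     substr(mutated, pos + 1, nchar(mutated))))
    }
    typo_d <- as.integer(levenshtein(out, mutated))
    if (typo_d > 0) {
      out <- mutated
      rules <- c(rules, "typo")
    }
  }
  if (stats::runif(1) < noise$p_unit_suffix && !is.na(unit)) {
    brack <- sample(c("()", "[]"), 1)
    out <- if (brack == "()") paste0(out, " (", unit, ")")
           else paste0(out, " [", unit, "]")
    rules <- c(rules, "unit_suffix")
  }
  if (stats::runif(1) < noise$p_html_wrap) {
    wrap <- sample(c("b", "i", "span style='font-weight:bold'"), 1)
    tag <- sub(" .*", "", wrap)
    out <- paste0("<", wrap, ">", out, "</", tag, ">")
    rules <- c(rules, "html_wrap")
  }
  if (stats::runif(1) < noise$p_case_change) {
    mode <- sample(c("upper", "lower"), 1)
    # case changes leave markup intact; only the wrapped text matters for
    # matching, but recasing the whole string is what messy exports do
    out <- if (mode == "upper") toupper(out) else tolower(out)
    rules <- c(rules, paste0("case_", mode))
  }
  list(label = out, rules = rules, typo_edit_distance = typo_d)
}

# deterministic partition of `total` into `k` parts within [lo, hi]
partition_forms <- function(total, k, lo, hi) {
  stopifnot(total >= k * lo, total <= k * hi)
  if (k == 1) return(total)
  base <- rep(total %/% k, k)
  rem <- total - sum(base)
  if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
  # random jitter within bounds, conserving the total
  for (step in seq_len(3 * k)) {
    ij <- sample(k, 2)
    delta <- sample(0:8, 1)
    if (base[ij[1]] + delta <= hi && base[ij[2]] - delta >= lo) {
      base[ij[1]] <- base[ij[1]] + delta
      base[ij[2]] <- base[ij[2]] - delta
    }
  }
  stopifnot(sum(base) == total, all(base >= lo), all(base <= hi))
  base
}

form_name_templates <- function() {
  list(
    medical_history = c("Medical History", "General Medical History",
                        "Medical History Review"),
    adverse_event = c("Adverse Events", "Adverse Event Log",
                      "Serious Adverse Event Report",
                      "Adverse Event Follow-up"),
    laboratory = c("Laboratory test results", "Coagulation Panel",
                   "Hematology Panel", "Clinical Chemistry Panel",
                   "Urinalysis Panel", "Central Laboratory Results"),
    disposition = c("Disposition", "End of Study Disposition",
                    "Study Completion and Disposition"),
    vital_signs = c("Vital Signs", "Vital Signs Assessment"),
    concomitant_medications = c("Concomitant Medications",
                                "Prior and Concomitant Medications"),
    questionnaire = c("Questionnaire", "Patient Reported Outcome",
                      "Quality of Life Questionnaire"),
    demographics = c("Demographics", "Demography"),
    ecg = c("ECG", "12-Lead ECG", "Electrocardiogram"),
    disease_characteristics = c("Disease Characteristics",
                                "Baseline Disease Characteristics"),
    substance_use = c("Substance Use", "Tobacco and Alcohol Use",
                      "Smoking and Substance Use"),
    surgery = c("Surgery", "Surgical History", "Surgery and Procedures"),
    physical_exam = c("Physical Examination", "Physical Exam"),
    tumor_response = c("Tumor Response", "Tumor Response Assessment")
  )
}

# domain mix: every trial carries the ubiquitous domains at least once;
# remaining forms are drawn by weight, with tumor response restricted to
# oncology trials
domain_weights <- function(area) {
  w <- c(medical_history = 10, adverse_event = 10, laboratory = 9,
         disposition = 8, vital_signs = 7, concomitant_medications = 6,
         questionnaire = 5, demographics = 3, ecg = 4,
         disease_characteristics = 3, substance_use = 3, surgery = 2,
         physical_exam = 1, tumor_response = 0)
  if (area == "oncology") w["tumor_response"] <- 2
  w
}

#' Generate a synthetic multi-trial study set with ground truth
#'
#' Builds trials, forms and noisy item labels from the shipped vocabulary
#' under a [generator_config()], optionally writing per-trial ODM 1.3 files,
#' a trial-metadata CSV and a ground-truth JSON. Fully deterministic for a
#' fixed seed; the seed and every label perturbation are recorded in the
#' manifest.
#'
#' @param cfg a [generator_config()].
#' @param dir optional output directory for ODM files, `trials.csv` and
#'   `ground_truth.json`.
#' @return list with `study_set`, `truth` (`partition`, `domains`,
#'   `occurrence`, `perturbations`) and `config`; when `dir` is given also
#'   `files`.
#' @export
generate_studyset <- function(cfg = generator_config(), dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  vocab <- element_vocabulary()
  admin <- vocab[vocab$domain_key == "any", , drop = FALSE]
  dom_vocab <- split(vocab[vocab$domain_key != "any", , drop = FALSE],
                     vocab$domain_key[vocab$domain_key != "any"])
  templates <- form_name_templates()

  max_needed <- cfg$elements_per_form[2]
  pool_sizes <- vapply(dom_vocab, nrow, integer(1)) + nrow(admin)
  if (any(pool_sizes < max_needed))
    stop("vocabulary smaller than requested unique elements per form for ",
         "domain(s): ",
         paste(names(pool_sizes)[pool_sizes < max_needed], collapse = ", "))

  areas <- names(cfg$n_trials_per_area)
  trials_l <- list()
  tix <- 0L
  for (a in areas) {
    for (k in seq_len(cfg$n_trials_per_area[[a]])) {
      tix <- tix + 1L
      trials_l[[tix]] <- data.frame(
        trial_id = sprintf("T%02d", tix), disease_area = a,
        planned_enrollment = sample(cfg$enrollment_range[1]:cfg$enrollment_range[2], 1),
        n_sites = sample(cfg$n_sites_range[1]:cfg$n_sites_range[2], 1),
        stringsAsFactors = FALSE)
    }
  }
  trials <- rbind_all(trials_l)

  # forms per trial honoring per-area totals when configured
  n_forms_per_trial <- integer(nrow(trials))
  for (a in areas) {
    sel <- which(trials$disease_area == a)
    if (length(sel) == 0) next
    n_forms_per_trial[sel] <- if (!is.null(cfg$forms_per_area)) {
      partition_forms(cfg$forms_per_area[[a]], length(sel),
                      cfg$forms_per_trial[1], cfg$forms_per_trial[2])
    } else {
      sample(cfg$forms_per_trial[1]:cfg$forms_per_trial[2], length(sel),
             replace = TRUE)
    }
  }

  ubiquitous <- c("medical_history", "adverse_event", "vital_signs",
                  "demographics", "concomitant_medications")
  forms_l <- list()
  items_l <- list()
  pert_l <- list()
  fix <- 0L
  iix <- 0L
  for (t in seq_len(nrow(trials))) {
    tid <- trials$trial_id[t]
    nf <- n_forms_per_trial[t]
    w <- domain_weights(trials$disease_area[t])
    doms <- c(ubiquitous,
              sample(names(w), nf - length(ubiquitous), replace = TRUE,
                     prob = w))
    for (d in doms) {
      fix <- fix + 1L
      fid <- sprintf("F%04d", fix)
      tmpl <- templates[[d]]
      nm <- sample(tmpl, 1)
      suffix <- sample(c("", "", "", " - Visit 1", " - Visit 2", " - Week 12",
                         " - Follow-up", " (Unscheduled)"), 1)
      repeating <- stats::runif(1) < 0.15
      forms_l[[fix]] <- data.frame(
        form_id = fid, trial_id = tid, form_name = paste0(nm, suffix),
        repeating = repeating, domain_key = d, stringsAsFactors = FALSE)

      n_items <- sample(cfg$elements_per_form[1]:cfg$elements_per_form[2], 1)
      pool <- dom_vocab[[d]]
      n_admin <- min(sample(2:3, 1), n_items - 1)
      if (cfg$sae_block && d == "adverse_event") {
        sae_pool <- pool[pool$sae, , drop = FALSE]
        base_pool <- pool[!pool$sae, , drop = FALSE]
        n_sae <- min(nrow(sae_pool), sample(3:6, 1))
        n_rest <- max(n_items - n_admin - n_sae, 1)
        chosen <- rbind(
          sae_pool[sample(nrow(sae_pool), n_sae), , drop = FALSE],
          base_pool[sample(nrow(base_pool), min(n_rest, nrow(base_pool))), ,
                    drop = FALSE])
      } else {
        chosen <- pool[sample(nrow(pool), min(n_items - n_admin, nrow(pool))), ,
                       drop = FALSE]
      }
      chosen <- rbind(chosen, admin[sample(nrow(admin), n_admin), , drop = FALSE])
      for (e in seq_len(nrow(chosen))) {
        iix <- iix + 1L
        el <- chosen[e, ]
        p <- perturb_label(el$label, cfg$noise, el$unit)
        with_var <- !is.na(el$sdtm_variable) &&
          stats::runif(1) < cfg$noise$p_cdisc_name_present
        item_id <- sprintf("IT%06d", iix)
        items_l[[iix]] <- data.frame(
          item_id = item_id, form_id = fid, trial_id = tid,
          raw_label = p$label,
          cdisc_variable_name = if (with_var) el$sdtm_variable
                                else NA_character_,
          data_type = el$data_type, units = NA_character_,
          element_id = el$element_id, stringsAsFactors = FALSE)
        if (length(p$rules) > 0) {
          pert_l[[length(pert_l) + 1L]] <- data.frame(
            item_id = item_id, element_id = el$element_id,
            rules = paste(p$rules, collapse = ","),
            typo_edit_distance = p$typo_edit_distance,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  forms <- rbind_all(forms_l)
  items <- rbind_all(items_l)

  truth <- list(
    partition = items[, c("item_id", "element_id")],
    domains = forms[, c("form_id", "domain_key")],
    occurrence = unique(items[, c("element_id", "trial_id")]),
    perturbations = rbind_all(pert_l) %||%
      data.frame(item_id = character(0), element_id = character(0),
                 rules = character(0), typo_edit_distance = integer(0)),
    seed = cfg$seed)

  frag <- new_fragment(list(forms[, c("form_id", "trial_id", "form_name",
                                      "repeating")]),
                       list(items[, c("item_id", "form_id", "trial_id",
                                      "raw_label", "cdisc_variable_name",
                                      "data_type", "units")]),
                       source = sprintf("generator(seed=%d)", cfg$seed),
                       format = "synthetic")
  ss <- study_set(trials, frag)

  out <- list(study_set = ss, truth = truth, config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (tid in trials$trial_id) {
      f <- file.path(dir, paste0("odm_", tid, ".xml"))
      write_odm(subset_trials(ss, tid), f)
      files <- c(files, f)
    }
    meta_path <- file.path(dir, "trials.csv")
    write_csv_stable(trials, meta_path)
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, gt_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    out$files <- list(odm = files, trials = meta_path, ground_truth = gt_path)
  }
  out
}

#' Generate per-site EHR export tables
#'
#' Emulates hospital data exports against an inventory: each site is either
#' frequency-capable (counts of entered values over a fixed patient
#' population) or availability-only (flags without counts, as for sites whose
#' access policies forbid patient-level queries). When `sae_block` is set,
#' SAE elements are forced sparse: more than half of the sites export no SAE
#' documentation at all. When the inventory contains "Bilirubin, total", the
#' first site reports the worked-example counts (9574 values / 31493
#' patients).
#'
#' @param inventory inventory data.frame (from [rank_elements()], ideally
#'   [annotate()]d).
#' @param n_sites number of sites (default 7).
#' @param seed RNG seed.
#' @param year reference year written to the export rows.
#' @param sae_block force-sparse SAE documentation.
#' @param dir optional directory to write one CSV per site.
#' @return list with `exports` (combined data.frame), `truth` (per-cell
#'   ground truth) and `sites` (site profile table).
#' @export
generate_exports <- function(inventory, n_sites = 7L, seed = 1L, year = 2013L,
                             sae_block = TRUE, dir = NULL) {
  stopifnot(nrow(inventory) > 0, n_sites >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  vocab <- element_vocabulary()
  sae_labels <- tolower(vocab$label[vocab$sae])
  is_sae <- tolower(inventory$canonical_label) %in% sae_labels

  mode <- rep("frequency", n_sites)
  if (n_sites >= 3) mode[(n_sites - 1):n_sites] <- "availability_only"
  sites <- data.frame(site_id = paste0("S", seq_len(n_sites)), mode = mode,
                      n_patients = sample(8000:60000, n_sites, replace = TRUE),
                      stringsAsFactors = FALSE)
  sites$n_patients[1] <- 31493L
  no_sae_sites <- if (sae_block && n_sites > 1)
    sites$site_id[seq_len(floor(n_sites / 2) + 1)] else character(0)

  p_avail <- function(domain, sae) {
    if (sae) return(0.25)
    switch(domain,
           demographics = 0.98, laboratory = 0.9, vital_signs = 0.85,
           adverse_event = 0.4, disposition = 0.5, 0.55)
  }
  rate_for <- function(domain) {
    base <- switch(domain,
                   demographics = stats::runif(1, 0.7, 1.0),
                   laboratory = stats::rlnorm(1, log(0.3), 0.8),
                   vital_signs = stats::runif(1, 0.3, 1.5),
                   stats::rbeta(1, 1.2, 4))
    min(base, 3)
  }

  rows_l <- list()
  truth_l <- list()
  for (s in seq_len(nrow(sites))) {
    sid <- sites$site_id[s]
    np <- sites$n_patients[s]
    uses_codes <- s <= 2 && "umls_cui" %in% names(inventory)
    for (e in seq_len(nrow(inventory))) {
      el <- inventory[e, ]
      sae <- is_sae[e]
      if (sae && sid %in% no_sae_sites) {
        avail <- FALSE
      } else {
        avail <- stats::runif(1) < p_avail(el$domain_key, sae)
      }
      key <- if (uses_codes && !is.na(el$umls_cui)) el$umls_cui
             else el$canonical_label
      if (!avail) {
        rows_l[[length(rows_l) + 1L]] <- data.frame(
          site_id = sid, element_key = key, n_values = NA_integer_,
          n_patients = NA_integer_, availability = "not_available",
          year = year, stringsAsFactors = FALSE)
        truth_l[[length(truth_l) + 1L]] <- data.frame(
          site_id = sid, cde_id = el$cde_id, n_values = NA_integer_,
          n_patients = NA_integer_, status = "not_available",
          stringsAsFactors = FALSE)
        next
      }
      if (sites$mode[s] == "availability_only" || stats::runif(1) < 0.1) {
        rows_l[[length(rows_l) + 1L]] <- data.frame(
          site_id = sid, element_key = key, n_values = NA_integer_,
          n_patients = NA_integer_, availability = "available",
          year = year, stringsAsFactors = FALSE)
        truth_l[[length(truth_l) + 1L]] <- data.frame(
          site_id = sid, cde_id = el$cde_id, n_values = NA_integer_,
          n_patients = NA_integer_, status = "available",
          stringsAsFactors = FALSE)
        next
      }
      nv <- as.integer(round(np * rate_for(el$domain_key)))
      if (s == 1 && tolower(el$canonical_label) == "bilirubin, total")
        nv <- 9574L
      rows_l[[length(rows_l) + 1L]] <- data.frame(
        site_id = sid, element_key = key, n_values = nv, n_patients = np,
        availability = "available", year = year, stringsAsFactors = FALSE)
      truth_l[[length(truth_l) + 1L]] <- data.frame(
        site_id = sid, cde_id = el$cde_id, n_values = nv, n_patients = np,
        status = "frequency", stringsAsFactors = FALSE)
    }
  }
  exports <- rbind_all(rows_l)
  truth <- rbind_all(truth_l)
  out <- list(exports = exports, truth = truth, sites = sites)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character(0)
    for (sid in sites$site_id) {
      p <- file.path(dir, paste0("export_", sid, ".csv"))
      write_csv_stable(exports[exports$site_id == sid, , drop = FALSE], p)
      paths <- c(paths, p)
    }
    out$files <- paths
  }
  out
}
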