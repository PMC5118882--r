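test_that("generation is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  g1 <- generate_studyset(small_gen_config(seed = 9), dir = d1)
  g2 <- generate_studyset(small_gen_config(seed = 9), dir = d2)
  for (f in basename(unlist(g1$files))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
  g3 <- generate_studyset(small_gen_config(seed = 10))
  expect_false(identical(g1$study_set$items$raw_label,
                         g3$study_set$items$raw_label))
})

test_that("zero noise means labels are verbatim and recovery is exact", {
  quiet <- noise_model(0, 0, 0, 0, c(1L, 1L), p_cdisc_name_present = 0)
  gen <- generate_studyset(small_gen_config(seed = 11, noise = quiet))
  vocab <- element_vocabulary()
  expect_true(all(gen$study_set$items$raw_label %in% vocab$label))
  ec <- cluster_labels(gen$study_set$items)
  ord <- order(gen$truth$partition$item_id)
  mem_ord <- order(ec$members$item_id)
  m <- pairwise_cluster_metrics(ec$members$cluster_id[mem_ord],
                                gen$truth$partition$element_id[ord])
  expect_identical(m$precision, 1)
  expect_identical(m$recall, 1)
  expect_identical(nrow(ec$clusters),
                   length(unique(gen$truth$partition$element_id)))
})

test_that("perturbations behave as configured and log true edit distances", {
  set.seed(23)
  p <- perturb_label("Weight", noise_model(0, 1, 0, 0), unit = "kg")
  expect_match(p$label, "^<.+>Weight</.+>$")
  expect_identical(p$rules, "html_wrap")

  set.seed(23)
  p2 <- perturb_label("Weight", noise_model(0, 0, 1, 0), unit = "kg")
  expect_true(p2$label %in% c("Weight (kg)", "Weight [kg]"))
  expect_identical(p2$rules, "unit_suffix")

  set.seed(23)
  p3 <- perturb_label("Body temperature", noise_model(0, 0, 0, 1))
  expect_identical(p3$typo_edit_distance,
                   as.integer(levenshtein("Body temperature", p3$label)))
  expect_identical(as.integer(adist("Body temperature", p3$label)),
                   p3$typo_edit_distance)  # DP oracle agrees
  expect_identical(p3$typo_edit_distance, 1L)

  # short labels are left alone by the typo channel
  set.seed(23)
  expect_identical(perturb_label("Age", noise_model(0, 0, 0, 1))$label, "Age")
})

test_that("recorded typo distances in a corpus match recomputation", {
  gen <- generate_studyset(small_gen_config(seed = 13))
  pert <- gen$truth$perturbations
  typos <- pert[grepl("typo", pert$rules) &
                  !grepl("case|html|unit", pert$rules), , drop = FALSE]
  if (nrow(typos) > 0) {
    vocab <- element_vocabulary()
    items <- gen$study_set$items
    orig <- vocab$label[match(typos$element_id, vocab$element_id)]
    raw <- items$raw_label[match(typos$item_id, items$item_id)]
    expect_identical(levenshtein(orig, raw), typos$typo_edit_distance)
  }
  expect_gt(nrow(pert), 0)
})

test_that("ground truth and emitted files are mutually consistent", {
  d <- withr::local_tempdir()
  gen <- generate_studyset(small_gen_config(seed = 15), dir = d)
  trials <- read_trial_meta(file.path(d, "trials.csv"))
  ss <- study_set(trials, lapply(gen$files$odm, parse_odm))
  # every generated item survives ingestion (count conservation)
  expect_identical(nrow(ss$items), nrow(gen$truth$partition))
  # brute-force occurrence recount equals the recorded ground truth
  items <- ss$items
  items$element_id <- gen$truth$partition$element_id[
    match(items$item_id, gen$truth$partition$item_id)]
  occ <- unique(items[, c("element_id", "trial_id")])
  occ <- occ[order(occ$element_id, occ$trial_id), ]
  tocc <- gen$truth$occurrence[order(gen$truth$occurrence$element_id,
                                     gen$truth$occurrence$trial_id), ]
  rownames(occ) <- rownames(tocc) <- NULL
  expect_identical(occ, tocc)
  # generated form domains carry the keyword their dictionary rule expects
  asg <- assign_domains(ss)
  truth_dom <- gen$truth$domains$domain_key[match(asg$form_id,
                                                  gen$truth$domains$form_id)]
  expect_identical(asg$domain_key, truth_dom)
})

test_that("a vocabulary too small for the requested form size is fatal", {
  cfg <- small_gen_config(seed = 1)
  cfg$elements_per_form <- c(30L, 60L)
  expect_error(generate_studyset(cfg), "vocabulary smaller")
})

test_that("site exports respect site modes and the worked-example fixture", {
  inv <- data.frame(
    cde_id = c("e1", "e2"), cluster_id = c("c1", "c2"),
    canonical_label = c("Bilirubin, total", "Heart rate"),
    domain_key = c("laboratory", "vital_signs"), stringsAsFactors = FALSE)
  exp <- generate_exports(inv, n_sites = 4, seed = 2)
  expect_identical(nrow(exp$exports), 8L)  # complete site x element rows
  avail_only <- exp$sites$site_id[exp$sites$mode == "availability_only"]
  ao_rows <- exp$exports[exp$exports$site_id %in% avail_only, ]
  expect_true(all(is.na(ao_rows$n_values)))
  bil <- exp$exports[exp$exports$site_id == "S1" &
                       exp$exports$element_key == "Bilirubin, total", ]
  if (nrow(bil) == 1 && !is.na(bil$n_values)) {
    expect_identical(bil$n_values, 9574L)
    expect_identical(bil$n_patients, 31493L)
    expect_identical(compute_frequency(bil$n_values, bil$n_patients), 30.4)
  }
  # determinism
  exp2 <- generate_exports(inv, n_sites = 4, seed = 2)
  expect_identical(exp$exports, exp2$exports)
})
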