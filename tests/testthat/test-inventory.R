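two_trial_fixture <- function(env = parent.frame()) {
  trials <- make_trials(c("T01", "T02"), areas = c("oncology", "diabetes"),
                        enroll = c(1000L, 2500L))
  items <- rbind(
    make_items(c("Heart Rate", "Weight"), trial_id = "T01", form_id = "F001"),
    make_items(c("heart rate", "Creatinine"), trial_id = "T02",
               form_id = "F002"))
  items$item_id <- sprintf("IT%03d", seq_len(nrow(items)))
  asg <- data.frame(form_id = c("F001", "F002"), trial_id = c("T01", "T02"),
                    domain_key = "vital_signs", method = "keyword",
                    stringsAsFactors = FALSE)
  list(trials = trials, items = items, asg = asg)
}

test_that("singleton form domains are dropped, others kept", {
  dt <- data.frame(domain_key = c("a", "b", "c"), n_trials = c(1L, 1L, 3L),
                   n_forms = c(1L, 2L, 0L), stringsAsFactors = FALSE)
  expect_message(kept <- filter_domains(dt), "singleton")
  # one form -> removed; two forms in one trial -> kept; zero forms -> removed
  expect_identical(kept$domain_key, "b")
  empty <- dt[0, ]
  expect_identical(nrow(filter_domains(empty)), 0L)
})

test_that("weighted score sums planned enrollment over distinct trials", {
  fx <- two_trial_fixture()
  ec <- cluster_labels(fx$items)
  inv <- rank_elements(ec, fx$asg, fx$trials)
  hr <- inv[inv$canonical_label == "Heart Rate", ]
  expect_identical(hr$weighted_score, 3500)      # 1000 + 2500
  expect_identical(hr$n_trials, 2L)
  expect_identical(hr$rank, 1L)
  # ranks are dense 1..N
  expect_identical(inv$rank, seq_len(nrow(inv)))
  # equal scores order by n_trials then label
  wt <- inv[inv$canonical_label %in% c("Creatinine", "Weight"), ]
  expect_identical(wt$canonical_label[order(wt$rank)],
                   c("Creatinine", "Weight"))
})

test_that("per-form weighting counts each form occurrence", {
  trials <- make_trials("T01", enroll = 1000L)
  items <- rbind(make_items("Heart Rate", form_id = "F001"),
                 make_items("Heart Rate", form_id = "F002"))
  items$item_id <- c("IT001", "IT002")
  asg <- data.frame(form_id = c("F001", "F002"), trial_id = "T01",
                    domain_key = "vital_signs", method = "keyword")
  ec <- cluster_labels(items)
  expect_identical(
    rank_elements(ec, asg, trials, weight = "per_trial")$weighted_score, 1000)
  expect_identical(
    rank_elements(ec, asg, trials, weight = "per_form")$weighted_score, 2000)
})

test_that("ranking matches the brute-force oracle and ignores input order", {
  gen <- generate_studyset(small_gen_config(seed = 31))
  ss <- gen$study_set
  asg <- assign_domains(ss)
  ec <- cluster_labels(ss$items)
  inv <- rank_elements(ec, asg, ss$trials)
  orc <- oracle_rank(ec, asg, ss$trials)
  cols <- c("cluster_id", "domain_key", "canonical_label", "n_trials",
            "n_form_occurrences", "weighted_score", "rank")
  expect_identical(inv[, cols], orc[, cols])

  for (k in 1:3) {
    perm <- ss$items[sample(nrow(ss$items)), , drop = FALSE]
    inv2 <- rank_elements(cluster_labels(perm), asg, ss$trials)
    expect_identical(inv2, inv)
  }
})

test_that("adding a trial containing an element never lowers its score", {
  fx <- two_trial_fixture()
  ec <- cluster_labels(fx$items)
  inv <- rank_elements(ec, fx$asg, fx$trials)
  # extend with a third trial containing Heart Rate
  trials3 <- rbind(fx$trials,
                   make_trials("T03", areas = "respiratory", enroll = 1200L))
  items3 <- rbind(fx$items, {
    x <- make_items("HEART RATE", trial_id = "T03", form_id = "F003")
    x$item_id <- "IT099"; x })
  asg3 <- rbind(fx$asg, data.frame(form_id = "F003", trial_id = "T03",
                                   domain_key = "vital_signs",
                                   method = "keyword"))
  inv3 <- rank_elements(cluster_labels(items3), asg3, trials3)
  for (lab in tolower(inv$canonical_label)) {
    expect_gte(inv3$weighted_score[tolower(inv3$canonical_label) == lab],
               inv$weighted_score[tolower(inv$canonical_label) == lab])
  }
})

test_that("inventory comparison partitions by CUI first, then label", {
  current <- data.frame(
    cde_id = c("e1", "e2", "e3"),
    canonical_label = c("Heart rate", "Creatinine", "Weird element"),
    umls_cui = c("C0018810", NA, NA), stringsAsFactors = FALSE)
  prior <- data.frame(label = c("Pulse frequency", "creatinine"),
                      umls_cui = c("C0018810", NA), stringsAsFactors = FALSE)
  cmp <- compare_inventories(current, prior)
  expect_identical(cmp$n_identical, 2L)   # CUI match despite label mismatch
  expect_identical(cmp$n_new, 1L)
  expect_identical(cmp$new_ids, "e3")
  expect_identical(cmp$n_identical + cmp$n_new, nrow(current))  # conservation

  all_new <- compare_inventories(current, data.frame(label = character(0)))
  expect_identical(all_new$n_new, 3L)

  expect_error(
    compare_inventories(current,
                        data.frame(label = c("x", "X"),
                                   umls_cui = c(NA, NA))),
    "duplicate keys")
})

test_that("annotation attaches validated codes and flags the unmapped", {
  inv <- data.frame(cde_id = c("e1", "e2"),
                    canonical_label = c("Heart Rate", "Mystery"),
                    stringsAsFactors = FALSE)
  map <- data.frame(key = "Heart Rate", umls_cui = "C0018810",
                    snomed_code = "364075005", stringsAsFactors = FALSE)
  expect_message(out <- annotate(inv, map), "1 element\\(s\\) uncoded")
  expect_identical(out$umls_cui, c("C0018810", NA))
  expect_identical(out$snomed_code, c("364075005", NA))
  expect_identical(out$uncoded, c(FALSE, TRUE))

  expect_message(all_uncoded <- annotate(inv, NULL), "2 element")
  expect_true(all(all_uncoded$uncoded))

  bad <- data.frame(key = "Heart Rate", umls_cui = "X123",
                    snomed_code = "364075005")
  expect_error(annotate(inv, bad), "invalid UMLS CUI")
  bad2 <- data.frame(key = "Heart Rate", umls_cui = "C0018810",
                     snomed_code = "36-40")
  expect_error(annotate(inv, bad2), "invalid SNOMED")
})
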