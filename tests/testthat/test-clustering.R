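test_that("is_match applies hard key > exact > fuzzy with hard-key veto", {
  cfg <- similarity_config()
  expect_identical(is_match("Heart Rate", "heart rate"),
                   list(match = TRUE, reason = "exact"))
  # equal CDISC names match even with different labels
  expect_identical(is_match("Pulse", "Heart Rate", "HR", "hr"),
                   list(match = TRUE, reason = "cdisc"))
  # unequal non-missing names veto regardless of text similarity
  expect_identical(is_match("Systolic BP", "Diastolic BP", "SYSBP", "DIABP"),
                   list(match = FALSE, reason = "none"))
  expect_false(is_match("Heart Rate", "Heart Rate", "HR", "PULSE")$match)
  # fuzzy: both metrics must pass
  expect_identical(is_match("Hemoglobin", "Haemoglobin"),
                   list(match = TRUE, reason = "fuzzy"))
  expect_equal(jaro_winkler("hemoglobin", "haemoglobin"), 0.9, tolerance = 0.1)
  expect_false(is_match("Weight", "Height")$match)
  # phonetic agreement can be demanded on top
  cfg_ph <- similarity_config(require_phonetic_agreement = TRUE)
  expect_true(is_match("Hemoglobin", "Haemoglobin", cfg = cfg_ph)$match)
})

test_that("variants of one label collapse into one cluster with modal canonical", {
  items <- make_items(c("Heart Rate", "heart rate",
                        "<b>Heart Rate</b> (bpm)"))
  ec <- cluster_labels(items)
  expect_identical(nrow(ec$clusters), 1L)
  expect_identical(ec$clusters$canonical_label, "Heart Rate")
  expect_identical(nrow(ec$members), 3L)
})

test_that("canonical election breaks ties by shortest then lexicographic", {
  # two variants each occurring once: tie on frequency
  items <- make_items(c("Hemoglobin", "Haemoglobin"))
  ec <- cluster_labels(items)
  expect_identical(ec$clusters$canonical_label, "Hemoglobin")
  items2 <- make_items(c("Body Mass", "Body Mess"))  # equal length, lex order
  ec2 <- cluster_labels(items2)
  expect_identical(ec2$clusters$canonical_label, "Body Mass")
})

test_that("clustering partitions the items and is permutation invariant", {
  set.seed(21)
  gen <- generate_studyset(small_gen_config(seed = 21))
  items <- gen$study_set$items
  ec <- cluster_labels(items)
  # partition: every non-excluded item in exactly one cluster
  expect_identical(nrow(ec$members) + nrow(ec$excluded), nrow(items))
  expect_identical(sort(ec$members$item_id), sort(items$item_id))
  expect_identical(sum(ec$clusters$n_items), nrow(ec$members))

  for (k in 1:3) {
    perm <- items[sample(nrow(items)), , drop = FALSE]
    ec2 <- cluster_labels(perm)
    expect_identical(ec2$clusters, ec$clusters)
    expect_identical(
      ec2$members[order(ec2$members$item_id), , drop = FALSE]$cluster_id,
      ec$members[order(ec$members$item_id), , drop = FALSE]$cluster_id)
  }
})

test_that("clusters never mix two distinct CDISC variable names", {
  items <- make_items(c("Blood Pressure", "Blood Pressure", "blood pressure"),
                      vars = c("SYSBP", "DIABP", NA))
  ec <- cluster_labels(items)
  for (cid in ec$clusters$cluster_id) {
    vars <- items$cdisc_variable_name[match(
      ec$members$item_id[ec$members$cluster_id == cid], items$item_id)]
    expect_lte(length(unique(vars[!is.na(vars)])), 1L)
  }
  expect_gte(nrow(ec$clusters), 2L)
})

test_that("items that clean to nothing are excluded and counted", {
  items <- make_items(c("Heart Rate", "<b></b>"))
  expect_message(ec <- cluster_labels(items), "excluded 1 item")
  expect_identical(nrow(ec$excluded), 1L)
  expect_identical(nrow(ec$members), 1L)
})

test_that("overrides rename, merge, split, remove and recategorize", {
  items <- make_items(c("Heart Rate", "heart rate", "Hemoglobin",
                        "Haemoglobin", "Creatinine"))
  ec <- cluster_labels(items)
  n_members <- nrow(ec$members)

  # empty override table is the identity
  expect_identical(apply_overrides(ec, NULL), ec)
  expect_identical(
    apply_overrides(ec, data.frame(action = character(0),
                                   cluster = character(0))), ec)

  ov <- data.frame(
    action = c("rename", "recategorize", "merge", "split"),
    cluster = c("Heart Rate", "Heart rate", "Hemoglobin", "Hemoglobin"),
    variant = c(NA, NA, NA, "Haemoglobin"),
    value = c("Heart rate", "clinical", "Creatinine", "Haemoglobin level"),
    stringsAsFactors = FALSE)
  ec2 <- apply_overrides(ec, ov)
  hr <- ec2$clusters[ec2$clusters$canonical_label == "Heart rate", ]
  expect_identical(nrow(hr), 1L)
  expect_true(hr$locked)
  # merge then split conserves every variant
  expect_identical(nrow(ec2$members), n_members)
  expect_identical(sum(ec2$clusters$n_items), n_members)
  expect_true("Haemoglobin level" %in% ec2$clusters$canonical_label)

  expect_message(
    ec3 <- apply_overrides(ec, data.frame(action = "remove",
                                          cluster = "Creatinine")),
    "removed cluster")
  expect_identical(nrow(ec3$members) + nrow(ec3$removed), n_members)

  expect_error(
    apply_overrides(ec, data.frame(action = "rename", cluster = "Nope",
                                   value = "x")),
    "unknown clusters")
})

test_that("pairwise cluster metrics are exact on hand-checked partitions", {
  pred <- c(1, 1, 2, 2, 3)
  truth <- c(1, 1, 1, 2, 2)
  # pred pairs: {12},{34}; truth pairs: {12},{13},{23},{45}; TP = {12}
  m <- pairwise_cluster_metrics(pred, truth)
  expect_equal(m$precision, 1 / 2)
  expect_equal(m$recall, 1 / 4)
  perfect <- pairwise_cluster_metrics(c("a", "a", "b"), c("x", "x", "y"))
  expect_equal(perfect$f1, 1)
})
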