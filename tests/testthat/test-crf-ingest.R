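test_that("a minimal ODM file ingests losslessly with label precedence", {
  f <- mini_odm(withr::local_tempfile(fileext = ".xml"))
  frag <- parse_odm(f)
  expect_s3_class(frag, "study_fragment")
  expect_identical(nrow(frag$forms), 1L)
  expect_identical(nrow(frag$items), 2L)
  # Question text preferred over item Name; Name is the fallback
  expect_identical(frag$items$raw_label, c("Heart Rate", "Weight item name"))
  expect_identical(frag$items$cdisc_variable_name, c("HR", NA))
  expect_identical(frag$forms$form_name, "Vital Signs")
})

test_that("ODM error handling: malformed XML, missing metadata, odd version", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<ODM><unclosed>", bad)
  expect_error(parse_odm(bad), "malformed XML")
  expect_error(parse_odm(bad), basename(dirname(bad)), fixed = FALSE)

  nometa <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?><ODM ODMVersion="1.3"><Other/></ODM>',
             nometa)
  expect_error(parse_odm(nometa), "no study metadata")

  oldver <- mini_odm(withr::local_tempfile(fileext = ".xml"),
                     odm_version = "1.2")
  expect_warning(frag <- parse_odm(oldver), "unknown ODM version")
  expect_identical(nrow(frag$items), 2L)  # best-effort parse still works
})

test_that("tabular ingestion maps columns, drops empty labels, flags errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study,form,formname,question,var",
               "T01,F001,Vitals,Heart Rate,HR",
               "T01,F001,Vitals,Weight,",
               "T01,F001,Vitals,,", # empty label -> dropped
               "T01,F001,Vitals,Height,HEIGHT"), csv)
  dialect <- list(columns = list(trial_id = "study", form_id = "form",
                                 form_name = "formname", label = "question",
                                 cdisc_variable_name = "var"))
  expect_message(frag <- parse_table(csv, dialect), "dropped 1 row")
  expect_identical(nrow(frag$items), 3L)
  expect_identical(frag$provenance$n_dropped_labels, 1L)
  expect_identical(frag$items$raw_label, c("Heart Rate", "Weight", "Height"))
  expect_identical(frag$items$cdisc_variable_name, c("HR", NA, "HEIGHT"))

  bad_dialect <- list(columns = list(trial_id = "study", form_id = "form",
                                     form_name = "formname", label = "nope"))
  expect_error(parse_table(csv, bad_dialect), "not found")
  expect_error(validate_dialect(list(columns = list(trial_id = "study"))),
               "mandatory")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study,form,formname,question,item",
               "T01,F001,Vitals,Heart Rate,I1",
               "T01,F001,Vitals,Weight,I1"), dup)
  expect_error(parse_table(dup, list(columns = list(
    trial_id = "study", form_id = "form", form_name = "formname",
    label = "question", item_id = "item"))), "duplicate \\(form_id, item_id\\)")
})

test_that("the same content ingests identically from ODM and CSV", {
  f <- mini_odm(withr::local_tempfile(fileext = ".xml"))
  odm_frag <- parse_odm(f)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial,form,fname,item,label,var",
               "T01,F001,Vital Signs,IT001,Heart Rate,HR",
               "T01,F001,Vital Signs,IT002,Weight item name,"), csv)
  tab_frag <- parse_table(csv, list(columns = list(
    trial_id = "trial", form_id = "form", form_name = "fname",
    item_id = "item", label = "label", cdisc_variable_name = "var")))
  cols <- c("item_id", "form_id", "trial_id", "raw_label",
            "cdisc_variable_name")
  expect_identical(odm_frag$items[, cols], tab_frag$items[, cols])
  expect_identical(odm_frag$forms[, c("form_id", "trial_id", "form_name")],
                   tab_frag$forms[, c("form_id", "trial_id", "form_name")])
})

test_that("writing a study set as ODM and re-ingesting round-trips", {
  gen <- generate_studyset(small_gen_config(seed = 3))
  ss <- gen$study_set
  f <- withr::local_tempfile(fileext = ".xml")
  write_odm(ss, f)
  frags <- parse_odm(f)
  ss2 <- study_set(ss$trials, frags)
  cols <- c("item_id", "form_id", "trial_id", "raw_label",
            "cdisc_variable_name", "data_type")
  expect_identical(ss2$items[, cols], ss$items[, cols])
  expect_identical(ss2$forms, ss$forms)
  # writing twice is byte-identical (no wall-clock in the output); the file
  # name is part of the header, so compare same-named files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_odm(ss, file.path(d1, "out.xml"))
  write_odm(ss, file.path(d2, "out.xml"))
  expect_identical(readLines(file.path(d1, "out.xml")),
                   readLines(file.path(d2, "out.xml")))
})

test_that("trial metadata validation rejects unusable rows", {
  expect_error(validate_trial_meta(make_trials("T01", areas = "dermatology")),
               "unknown disease_area")
  bad <- make_trials(c("T01", "T02"))
  bad$planned_enrollment[2] <- NA
  expect_error(validate_trial_meta(bad), "planned_enrollment")
  dup <- make_trials(c("T01", "T01"))
  expect_error(validate_trial_meta(dup), "duplicate trial_id")
})

test_that("tabulate_corpus conserves counts and appends an exact Sum row", {
  gen <- generate_studyset(small_gen_config(seed = 5))
  tab <- tabulate_corpus(gen$study_set)
  sum_row <- tab[tab$disease_area == "Sum", ]
  body <- tab[tab$disease_area != "Sum", ]
  expect_identical(sum_row$n_trials, sum(body$n_trials))
  expect_identical(sum_row$n_forms, sum(body$n_forms))
  expect_identical(sum_row$n_forms, nrow(gen$study_set$forms))

  # single trial, single form
  trials <- make_trials("T01", areas = "diabetes")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,f,fn,l", "T01,F1,Vitals,Heart Rate"), csv)
  frag <- parse_table(csv, list(columns = list(trial_id = "t", form_id = "f",
                                               form_name = "fn", label = "l")))
  tab1 <- tabulate_corpus(study_set(trials, frag))
  expect_identical(tab1$n_trials, c(1L, 1L))
  expect_identical(tab1$n_forms, c(1L, 1L))
  expect_identical(tab1$disease_area, c("diabetes", "Sum"))
})

test_that("study set validation enforces referential integrity", {
  trials <- make_trials("T01")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,f,fn,l", "T99,F1,Vitals,Heart Rate"), csv)
  frag <- parse_table(csv, list(columns = list(trial_id = "t", form_id = "f",
                                               form_name = "fn", label = "l")))
  expect_error(study_set(trials, frag), "unknown trial")
})
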