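# Independent reference implementations used only as test oracles.
# Deliberately naive and written from the published definitions, sharing no
# code with the package.

# --- Jaro and Jaro-Winkler, straight from the definition ---
oracle_jaro <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  if (la == 0 && lb == 0) return(1)
  if (la == 0 || lb == 0) return(0)
  win <- max(floor(max(la, lb) / 2) - 1, 0)
  am <- logical(la); bm <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1, i - win); hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!bm[j] && av[i] == bv[j]) { am[i] <- bm[j] <- TRUE; break }
    }
  }
  m <- sum(am)
  if (m == 0) return(0)
  t <- sum(av[am] != bv[bm]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

oracle_jaro_winkler <- function(a, b, p = 0.1) {
  j <- oracle_jaro(a, b)
  l <- 0
  for (i in seq_len(max(min(nchar(a), nchar(b), 4), 0))) {
    if (substr(a, i, i) == substr(b, i, i)) l <- l + 1 else break
  }
  j + l * p * (1 - j)
}

# --- original Metaphone, an independent transcription of the rule table ---
oracle_metaphone <- function(s) {
  w <- toupper(gsub("[^A-Za-z]", "", s))
  if (!nzchar(w)) return("")
  if (grepl("^(AE|GN|KN|PN|WR)", w)) w <- substring(w, 2)
  else if (grepl("^X", w)) w <- sub("^X", "S", w)
  else if (grepl("^WH", w)) w <- sub("^WH", "W", w)
  n <- nchar(w)
  if (n == 0) return("")
  at <- function(i) if (i >= 1 && i <= n) substr(w, i, i) else ""
  vow <- function(ch) ch %in% c("A", "E", "I", "O", "U")
  res <- ""
  i <- 1
  while (i <= n) {
    c0 <- at(i)
    if (c0 == at(i - 1) && c0 != "C") { i <- i + 1; next }
    nx <- at(i + 1); nx2 <- at(i + 2); pv <- at(i - 1)
    adv <- 1
    add <- ""
    if (vow(c0)) { if (i == 1) add <- c0 }
    else if (c0 == "B") { if (!(i == n && pv == "M")) add <- "B" }
    else if (c0 == "C") {
      if (pv == "S" && nx %in% c("I", "E", "Y")) add <- ""
      else if (nx == "I" && nx2 == "A") add <- "X"
      else if (nx == "H") { add <- if (pv == "S") "K" else "X"; adv <- 2 }
      else if (nx %in% c("I", "E", "Y")) add <- "S"
      else add <- "K"
    } else if (c0 == "D") {
      if (nx == "G" && nx2 %in% c("E", "Y", "I")) { add <- "J"; adv <- 2 }
      else add <- "T"
    } else if (c0 == "G") {
      if (nx == "H") {
        if (vow(at(i + 2))) add <- "K"
        adv <- 2
      } else if (nx == "N") {
        gn_end <- (i + 1 == n)
        gned <- (nx2 == "E" && at(i + 3) == "D" && i + 3 == n)
        if (!gn_end && !gned) add <- "K"
      } else if (nx %in% c("I", "E", "Y")) add <- "J"
      else add <- "K"
    } else if (c0 == "H") {
      if (!(vow(pv) && !vow(nx))) add <- "H"
    } else if (c0 == "K") {
      if (pv != "C") add <- "K"
    } else if (c0 == "P") {
      if (nx == "H") { add <- "F"; adv <- 2 } else add <- "P"
    } else if (c0 == "Q") add <- "K"
    else if (c0 == "S") {
      if (nx == "H") { add <- "X"; adv <- 2 }
      else if (nx == "I" && nx2 %in% c("O", "A")) add <- "X"
      else add <- "S"
    } else if (c0 == "T") {
      if (nx == "I" && nx2 %in% c("O", "A")) add <- "X"
      else if (nx == "H") { add <- "0"; adv <- 2 }
      else if (nx == "C" && nx2 == "H") add <- ""
      else add <- "T"
    } else if (c0 == "V") add <- "F"
    else if (c0 == "W") { if (vow(nx)) add <- "W" }
    else if (c0 == "X") add <- "KS"
    else if (c0 == "Y") { if (vow(nx)) add <- "Y" }
    else if (c0 == "Z") add <- "S"
    else add <- c0  # F J L M N R
    res <- paste0(res, add)
    i <- i + adv
  }
  res
}

# --- random-string generators (fixed alphabet, caller sets the seed) ---
rand_strings <- function(n, max_len = 12, alphabet = letters) {
  vapply(seq_len(n), function(i) {
    len <- sample(0:max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# mutate a string by k random single-character edits
mutate_string <- function(s, k = 1) {
  for (j in seq_len(k)) {
    if (nchar(s) == 0) { s <- paste(sample(letters, 1), collapse = ""); next }
    pos <- sample(nchar(s), 1)
    op <- sample(c("sub", "del", "ins"), 1)
    s <- switch(op,
      sub = paste0(substr(s, 1, pos - 1), sample(letters, 1),
                   substr(s, pos + 1, nchar(s))),
      del = paste0(substr(s, 1, pos - 1), substr(s, pos + 1, nchar(s))),
      ins = paste0(substr(s, 1, pos), sample(letters, 1),
                   substr(s, pos + 1, nchar(s))))
  }
  s
}

# --- brute-force re-derivation of the enrollment-weighted ranking, written
# independently of rank_elements(): plain loops over an occurrence table ---
oracle_rank <- function(ec, asg, trials) {
  mem <- ec$members
  mem$domain <- asg$domain_key[match(mem$form_id, asg$form_id)]
  mem$label <- ec$clusters$canonical_label[match(mem$cluster_id,
                                                 ec$clusters$cluster_id)]
  keys <- unique(mem[, c("cluster_id", "domain", "label")])
  out <- NULL
  for (r in seq_len(nrow(keys))) {
    sel <- mem$cluster_id == keys$cluster_id[r] & mem$domain == keys$domain[r]
    tids <- unique(mem$trial_id[sel])
    score <- 0
    for (t in tids)
      score <- score + trials$planned_enrollment[trials$trial_id == t]
    out <- rbind(out, data.frame(
      cluster_id = keys$cluster_id[r], domain_key = keys$domain[r],
      canonical_label = keys$label[r], n_trials = length(tids),
      n_form_occurrences = length(unique(mem$form_id[sel])),
      weighted_score = as.numeric(score), stringsAsFactors = FALSE))
  }
  out <- out[order(-out$weighted_score, -out$n_trials,
                   tolower(out$canonical_label), out$canonical_label,
                   out$domain_key), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# --- tiny corpus builders ---
make_items <- function(labels, trial_id = "T01", form_id = "F001",
                       vars = NA_character_) {
  data.frame(item_id = sprintf("IT%03d", seq_along(labels)),
             form_id = form_id, trial_id = trial_id, raw_label = labels,
             cdisc_variable_name = rep_len(vars, length(labels)),
             stringsAsFactors = FALSE)
}

make_trials <- function(ids, areas = "oncology", enroll = 1000L,
                        n_sites = 10L) {
  data.frame(trial_id = ids, disease_area = rep_len(areas, length(ids)),
             planned_enrollment = rep_len(enroll, length(ids)),
             n_sites = rep_len(n_sites, length(ids)),
             stringsAsFactors = FALSE)
}

# small generator configuration for quick synthetic corpora
small_gen_config <- function(seed = 1L, noise = noise_model()) {
  generator_config(
    n_trials_per_area = c(oncology = 2L, diabetes = 2L, respiratory = 1L),
    forms_per_area = NULL,
    forms_per_trial = c(6L, 10L),
    elements_per_form = c(5L, 9L),
    noise = noise,
    seed = seed)
}

# minimal hand-written ODM document
mini_odm <- function(path, odm_version = "1.3") {
  xml <- sprintf('<?xml version="1.0" encoding="UTF-8"?>
<ODM xmlns="http://www.cdisc.org/ns/odm/v1.3" FileOID="mini" FileType="Snapshot" ODMVersion="%s" CreationDateTime="2016-01-01T00:00:00">
  <Study OID="T01">
    <GlobalVariables><StudyName>T01</StudyName><StudyDescription/><ProtocolName>T01</ProtocolName></GlobalVariables>
    <MetaDataVersion OID="MDV.1" Name="metadata">
      <FormDef OID="F001" Name="Vital Signs" Repeating="No">
        <ItemGroupRef ItemGroupOID="IG.F001" Mandatory="Yes"/>
      </FormDef>
      <ItemGroupDef OID="IG.F001" Name="Vital Signs" Repeating="No">
        <ItemRef ItemOID="IT001" OrderNumber="1" Mandatory="No"/>
        <ItemRef ItemOID="IT002" OrderNumber="2" Mandatory="No"/>
      </ItemGroupDef>
      <ItemDef OID="IT001" Name="HR_ITEM" DataType="float" SDSVarName="HR">
        <Question><TranslatedText xml:lang="en">Heart Rate</TranslatedText></Question>
      </ItemDef>
      <ItemDef OID="IT002" Name="Weight item name" DataType="float"/>
    </MetaDataVersion>
  </Study>
</ODM>', odm_version)
  writeLines(xml, path)
  path
}
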