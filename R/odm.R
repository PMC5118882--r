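ODM_NS <- "http://www.cdisc.org/ns/odm/v1.3"

#' Parse CDISC ODM 1.3 study metadata
#'
#' Reads the metadata section of an ODM file (FormDef / ItemGroupDef /
#' ItemDef) into an ingestion fragment. Item labels are taken from the item's
#' `Question/TranslatedText` in the preferred language, falling back to any
#' question text and finally to the item `Name`. `SDSVarName` attributes
#' populate the CDISC variable name. Clinical (subject) data sections are
#' ignored: this is a metadata reader.
#'
#' @param path ODM XML file.
#' @param lang preferred `xml:lang` for question text (default `"en"`).
#' @return a `study_fragment` with `forms`, `items` and `provenance`
#'   data.frames, suitable for [study_set()].
#' @export
parse_odm <- function(path, lang = "en") {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed XML in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (xml2::xml_name(doc) != "ODM")
    stop("'", path, "' is not an ODM document (root <",
         xml2::xml_name(doc), ">)")
  ver <- xml2::xml_attr(doc, "ODMVersion")
  if (!is.na(ver) && ver != "1.3")
    warning("'", path, "': unknown ODM version '", ver,
            "', attempting best-effort parse")
  xml2::xml_ns_strip(doc)

  studies <- xml2::xml_find_all(doc, "./Study")
  if (length(studies) == 0)
    stop("'", path, "': no study metadata (missing <Study>)")

  forms_l <- list()
  items_l <- list()
  dropped <- 0L
  for (study in studies) {
    trial_id <- xml2::xml_attr(study, "OID")
    mdv <- xml2::xml_find_first(study, "./MetaDataVersion")
    if (inherits(mdv, "xml_missing"))
      stop("'", path, "': no study metadata (missing <MetaDataVersion> in study '",
           trial_id, "')")

    # index ItemGroupDefs and ItemDefs by OID
    igds <- xml2::xml_find_all(mdv, "./ItemGroupDef")
    igd_by_oid <- setNames(as.list(igds), xml2::xml_attr(igds, "OID"))
    itds <- xml2::xml_find_all(mdv, "./ItemDef")
    itd_by_oid <- setNames(as.list(itds), xml2::xml_attr(itds, "OID"))

    for (fd in xml2::xml_find_all(mdv, "./FormDef")) {
      form_id <- xml2::xml_attr(fd, "OID")
      form_name <- xml2::xml_attr(fd, "Name")
      repeating <- identical(xml2::xml_attr(fd, "Repeating"), "Yes")
      forms_l[[length(forms_l) + 1L]] <- data.frame(
        form_id = form_id, trial_id = trial_id, form_name = form_name,
        repeating = repeating, stringsAsFactors = FALSE)

      for (igr in xml2::xml_find_all(fd, "./ItemGroupRef")) {
        ig_oid <- xml2::xml_attr(igr, "ItemGroupOID")
        igd <- igd_by_oid[[ig_oid]]
        if (is.null(igd)) next
        for (ir in xml2::xml_find_all(igd, "./ItemRef")) {
          it_oid <- xml2::xml_attr(ir, "ItemOID")
          itd <- itd_by_oid[[it_oid]]
          if (is.null(itd)) next
          lab <- odm_item_label(itd, lang)
          if (!nzchar(lab)) { dropped <- dropped + 1L; next }
          items_l[[length(items_l) + 1L]] <- data.frame(
            item_id = it_oid, form_id = form_id, trial_id = trial_id,
            raw_label = lab,
            cdisc_variable_name = xml2::xml_attr(itd, "SDSVarName"),
            data_type = odm_data_type(itd),
            units = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (dropped > 0)
    msg("parse_odm: dropped %d item(s) with empty labels from '%s'",
        dropped, basename(path))
  new_fragment(forms_l, items_l, source = path, format = "odm",
               n_dropped = dropped)
}

odm_item_label <- function(itd, lang) {
  tts <- xml2::xml_find_all(itd, "./Question/TranslatedText")
  if (length(tts) > 0) {
    langs <- xml2::xml_attr(tts, "lang")
    pick <- which(langs == lang)
    if (length(pick) == 0) pick <- 1L
    lab <- squish(xml2::xml_text(tts[[pick[1]]]))
    if (nzchar(lab)) return(lab)
  }
  q <- xml2::xml_find_first(itd, "./Question")
  if (!inherits(q, "xml_missing")) {
    lab <- squish(xml2::xml_text(q))
    if (nzchar(lab)) return(lab)
  }
  squish(xml2::xml_attr(itd, "Name", default = ""))
}

odm_data_type <- function(itd) {
  if (length(xml2::xml_find_all(itd, "./CodeListRef")) > 0) return("codelist")
  dt <- xml2::xml_attr(itd, "DataType", default = "text")
  map <- c(integer = "integer", float = "float", double = "float",
           date = "date", datetime = "datetime", boolean = "boolean",
           text = "text", string = "text")
  if (!is.na(dt) && dt %in% names(map)) unname(map[[dt]]) else "text"
}

new_fragment <- function(forms_l, items_l, source, format, n_dropped = 0L) {
  forms <- rbind_all(forms_l) %||% empty_forms()
  items <- rbind_all(items_l) %||% empty_items()
  structure(
    list(forms = forms, items = items,
         provenance = data.frame(source_file = source, format = format,
                                 n_forms = nrow(forms), n_items = nrow(items),
                                 n_dropped_labels = n_dropped,
                                 stringsAsFactors = FALSE)),
    class = "study_fragment"
  )
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a study set as canonical ODM 1.3 XML
#'
#' Emits one `<Study>` per trial with FormDef / ItemGroupDef / ItemDef
#' metadata. The creation timestamp is a fixed parameter (not the wall clock)
#' so that repeated exports of the same study set are byte-identical.
#' Re-ingesting the written file with [parse_odm()] reproduces the same forms
#' and items.
#'
#' @param ss a `study_set`.
#' @param path output file.
#' @param creation_datetime ISO timestamp recorded in the file header.
#' @param lang language tag written on question text.
#' @return the path, invisibly.
#' @export
write_odm <- function(ss, path, creation_datetime = "2016-01-01T00:00:00",
                      lang = "en") {
  stopifnot(inherits(ss, "study_set"))
  buf <- character(0)
  push <- function(...) buf[[length(buf) + 1L]] <<- sprintf(...)
  push('<?xml version="1.0" encoding="UTF-8"?>')
  push(paste0('<ODM xmlns="', ODM_NS, '" FileOID="%s" FileType="Snapshot"',
              ' ODMVersion="1.3" CreationDateTime="%s">'),
       xml_escape(basename(path)), creation_datetime)
  for (tid in ss$trials$trial_id) {
    dup <- ss$items$item_id[ss$items$trial_id == tid]
    if (anyDuplicated(dup))
      stop("write_odm requires item ids unique within trial '", tid, "'")
    push('  <Study OID="%s">', xml_escape(tid))
    push('    <GlobalVariables><StudyName>%s</StudyName><StudyDescription/><ProtocolName>%s</ProtocolName></GlobalVariables>',
         xml_escape(tid), xml_escape(tid))
    push('    <MetaDataVersion OID="MDV.1" Name="metadata">')
    forms <- ss$forms[ss$forms$trial_id == tid, , drop = FALSE]
    for (k in seq_len(nrow(forms))) {
      f <- forms[k, ]
      push('      <FormDef OID="%s" Name="%s" Repeating="%s">',
           xml_escape(f$form_id), xml_escape(f$form_name),
           if (isTRUE(f$repeating)) "Yes" else "No")
      push('        <ItemGroupRef ItemGroupOID="IG.%s" Mandatory="Yes"/>',
           xml_escape(f$form_id))
      push('      </FormDef>')
    }
    for (k in seq_len(nrow(forms))) {
      f <- forms[k, ]
      it <- ss$items[ss$items$form_id == f$form_id, , drop = FALSE]
      push('      <ItemGroupDef OID="IG.%s" Name="%s" Repeating="No">',
           xml_escape(f$form_id), xml_escape(f$form_name))
      for (j in seq_len(nrow(it))) {
        push('        <ItemRef ItemOID="%s" OrderNumber="%d" Mandatory="No"/>',
             xml_escape(it$item_id[j]), j)
      }
      push('      </ItemGroupDef>')
    }
    it <- ss$items[ss$items$trial_id == tid, , drop = FALSE]
    dt_map <- c(integer = "integer", float = "float", date = "date",
                datetime = "datetime", boolean = "boolean", text = "text",
                codelist = "text")
    for (j in seq_len(nrow(it))) {
      sds <- it$cdisc_variable_name[j]
      sds_attr <- if (!is.na(sds) && nzchar(sds))
        sprintf(' SDSVarName="%s"', xml_escape(sds)) else ""
      dt <- it$data_type[j]
      odt <- if (!is.na(dt) && dt %in% names(dt_map)) dt_map[[dt]] else "text"
      push('      <ItemDef OID="%s" Name="%s" DataType="%s"%s>',
           xml_escape(it$item_id[j]), xml_escape(it$item_id[j]), odt, sds_attr)
      push('        <Question><TranslatedText xml:lang="%s">%s</TranslatedText></Question>',
           lang, xml_escape(it$raw_label[j]))
      if (identical(dt, "codelist"))
        push('        <CodeListRef CodeListOID="CL.%s"/>', xml_escape(it$item_id[j]))
      push('      </ItemDef>')
    }
    # minimal codelists so CodeListRef targets resolve
    cl <- it$item_id[!is.na(it$data_type) & it$data_type == "codelist"]
    for (oid in cl) {
      push('      <CodeList OID="CL.%s" Name="CL.%s" DataType="text"><CodeListItem CodedValue="Y"><Decode><TranslatedText xml:lang="%s">Yes</TranslatedText></Decode></CodeListItem></CodeList>',
           xml_escape(oid), xml_escape(oid), lang)
    }
    push('    </MetaDataVersion>')
    push('  </Study>')
  }
  push('</ODM>')
  writeLines(buf, path, useBytes = TRUE)
  invisible(path)
}
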