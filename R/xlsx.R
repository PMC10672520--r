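# Minimal OOXML spreadsheet writer/reader (one workbook, one sheet per
# table, inline strings, full-precision numbers). Reading goes through
# utils::unzip (internal) + xml2.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

col_letter <- function(j) {
  out <- character(length(j))
  for (i in seq_along(j)) {
    n <- j[i]; s <- ""
    while (n > 0L) {
      s <- paste0(LETTERS[(n - 1L) %% 26L + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[i] <- s
  }
  out
}

sanitize_sheet_name <- function(x) {
  x <- gsub("[][*?/\\:]", "_", x)
  substr(x, 1L, 31L)
}

sheet_xml <- function(df) {
  df <- as.data.frame(df)
  nr <- nrow(df); nc <- ncol(df)
  cell <- function(ref, value) {
    if (is.character(value) || is.factor(value) || is.logical(value))
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
              ref, xml_escape(as.character(value)))
    else if (is.na(value))
      sprintf('<c r="%s"/>', ref)
    else
      sprintf('<c r="%s"><v>%.17g</v></c>', ref, as.numeric(value))
  }
  rows <- character(nr + 1L)
  letters_ <- col_letter(seq_len(nc))
  hdr <- vapply(seq_len(nc), function(j)
    cell(paste0(letters_[j], 1L), names(df)[j]), character(1))
  rows[1] <- sprintf('<row r="1">%s</row>', paste(hdr, collapse = ""))
  for (i in seq_len(nr)) {
    cells <- vapply(seq_len(nc), function(j)
      cell(paste0(letters_[j], i + 1L), df[[j]][i]), character(1))
    rows[i + 1L] <- sprintf('<row r="%d">%s</row>', i + 1L,
                            paste(cells, collapse = ""))
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""), "</sheetData></worksheet>")
}

# tables: named list of data frames -> xlsx file at path
xlsx_write <- function(tables, path) {
  stopifnot(length(tables) >= 1L, !is.null(names(tables)))
  nm <- sanitize_sheet_name(names(tables))
  ns <- length(tables)
  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf(
      '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
      seq_len(ns)), collapse = ""),
    "</Types>")
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>")
  wb <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships"><sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  xml_escape(nm), seq_len(ns), seq_len(ns)), collapse = ""),
    "</sheets></workbook>")
  wbrels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf(
      '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
      seq_len(ns), seq_len(ns)), collapse = ""),
    "</Relationships>")
  files <- c(
    list("[Content_Types].xml" = charToRaw(ct),
         "_rels/.rels" = charToRaw(rels),
         "xl/workbook.xml" = charToRaw(wb),
         "xl/_rels/workbook.xml.rels" = charToRaw(wbrels)),
    stats::setNames(
      lapply(tables, function(df) charToRaw(sheet_xml(df))),
      sprintf("xl/worksheets/sheet%d.xml", seq_len(ns))))
  zip_write(files, path)
}

#' Read one sheet of a spreadsheet report
#'
#' Reads a worksheet written by [write_report()] back into a data frame
#' (inline-string and shared-string cells as text, other cells numeric;
#' first row taken as header).
#'
#' @param path Path to the `.xlsx` file.
#' @param sheet Sheet name or 1-based index.
#' @return A data frame.
#' @export
read_xlsx_sheet <- function(path, sheet = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  tmp <- tempfile("xlsx_")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, exdir = tmp)
  ns_strip <- function(doc) { xml2::xml_ns_strip(doc); doc }
  wb <- ns_strip(xml2::read_xml(file.path(tmp, "xl", "workbook.xml")))
  sheets <- xml2::xml_find_all(wb, ".//sheet")
  nms <- xml2::xml_attr(sheets, "name")
  rids <- xml2::xml_attr(sheets, "id")
  idx <- if (is.character(sheet)) match(sheet, nms) else as.integer(sheet)
  if (is.na(idx) || idx < 1L || idx > length(nms))
    stop("no such sheet: ", sheet)
  rels <- ns_strip(xml2::read_xml(
    file.path(tmp, "xl", "_rels", "workbook.xml.rels")))
  rel <- xml2::xml_find_all(rels, ".//Relationship")
  target <- xml2::xml_attr(rel, "Target")[
    match(rids[idx], xml2::xml_attr(rel, "Id"))]
  shared <- character(0)
  ss_path <- file.path(tmp, "xl", "sharedStrings.xml")
  if (file.exists(ss_path))
    shared <- xml2::xml_text(
      xml2::xml_find_all(ns_strip(xml2::read_xml(ss_path)), ".//si"))
  sh <- ns_strip(xml2::read_xml(file.path(tmp, "xl", target)))
  rows <- xml2::xml_find_all(sh, ".//row")
  parse_row <- function(row) {
    cells <- xml2::xml_find_all(row, ".//c")
    refs <- xml2::xml_attr(cells, "r")
    cols <- vapply(refs, function(r) {
      letters_ <- gsub("[0-9]", "", r)
      sum((utf8ToInt(letters_) - 64L) * 26^(rev(seq_len(nchar(letters_))) - 1L))
    }, numeric(1))
    types <- xml2::xml_attr(cells, "t")
    vals <- vapply(seq_along(cells), function(k) {
      if (identical(types[k], "inlineStr"))
        xml2::xml_text(xml2::xml_find_first(cells[[k]], ".//t"))
      else if (identical(types[k], "s"))
        shared[as.integer(xml2::xml_text(
          xml2::xml_find_first(cells[[k]], ".//v"))) + 1L]
      else xml2::xml_text(xml2::xml_find_first(cells[[k]], ".//v"))
    }, character(1))
    list(cols = cols, vals = vals)
  }
  parsed <- lapply(rows, parse_row)
  if (length(parsed) == 0L) return(data.frame())
  ncol_ <- max(unlist(lapply(parsed, `[[`, "cols")))
  mat <- matrix(NA_character_, length(parsed), ncol_)
  for (i in seq_along(parsed))
    mat[i, parsed[[i]]$cols] <- parsed[[i]]$vals
  hdr <- mat[1, ]
  hdr[is.na(hdr)] <- sprintf("V%d", which(is.na(hdr)))
  body <- mat[-1, , drop = FALSE]
  out <- as.data.frame(body, stringsAsFactors = FALSE)
  names(out) <- hdr
  for (j in seq_along(out)) {
    suppressWarnings(num <- as.numeric(out[[j]]))
    if (!anyNA(num) || all(is.na(out[[j]]) == is.na(num)))
      out[[j]] <- num
  }
  out
}
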