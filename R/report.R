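html_escape <- function(x) {
  x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, digits = 4) {
  if (is.null(df) || nrow(df) == 0L)
    return("<p><em>none</em></p>")
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "g")
    else html_escape(v)
  }
  head <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(as.data.frame(lapply(df, fmt), check.names = FALSE,
                              stringsAsFactors = FALSE), 1L, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table>", head, paste(rows, collapse = ""), "</table>")
}

#' Generate the four-section HTML analysis report
#'
#' Assembles a single self-contained HTML document (inline CSS, no
#' scripts) with exactly four top-level sections:
#' 1. sample names and their class labels;
#' 2. the exemplars with their ranking statistics and network
#'    characteristics;
#' 3. the classification performance metrics (labelled cross-validation
#'    or hold-out);
#' 4. annotation info per exemplar.
#' Any missing bundle part renders as "not computed". The generation
#' timestamp sits alone on one line so that reports from identical
#' bundles differ in that line only.
#'
#' @param bundle list with (all optional) `samples` (data.frame
#'   `sample_id`, `type`), `result` (a [mapkl()] fit), `metrics` (a
#'   `"class_metrics"`), `annot` (an [annotate_probes()] table) and
#'   `netstats` (a [network_stats()] result).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
generate_report <- function(bundle, path) {
  stopifnot(is.list(bundle))
  nc <- "<p><em>not computed</em></p>"
  sec1 <- if (is.null(bundle$samples)) nc else html_table(bundle$samples)

  sec2 <- nc
  if (!is.null(bundle$result)) {
    fit <- bundle$result
    ex <- fit$exemplars
    if (length(ex) == 0L) {
      sec2 <- "<p><em>no exemplars selected</em></p>"
    } else {
      tab <- fit$ranked[match(ex, fit$ranked$probe),
                        c("probe", "t", "p_raw", "p_adj", "fc", "rank"),
                        drop = FALSE]
      if (!is.null(bundle$netstats)) {
        ns <- bundle$netstats$local
        tab <- cbind(tab, ns[match(ex, ns$gene),
                             c("wdegree", "closeness", "betweenness",
                               "transitivity"), drop = FALSE])
      }
      sec2 <- html_table(tab)
    }
  }

  sec3 <- nc
  if (!is.null(bundle$metrics)) {
    m <- bundle$metrics
    sec3 <- paste0(
      "<p>", if (isTRUE(m$holdout)) "Hold-out validation"
             else "Cross-validation (pooled out-of-fold predictions)",
      "</p>",
      html_table(data.frame(AUC = sprintf("%.2f", m$AUC),
                            MCC = sprintf("%.2f", m$MCC),
                            ACC = sprintf("%.1f", m$ACC),
                            TNR = sprintf("%.2f", m$TNR),
                            TPR = sprintf("%.2f", m$TPR))))
  }

  sec4 <- if (is.null(bundle$annot)) nc else html_table(bundle$annot)

  doc <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"/>",
    "<title>Gene exemplar analysis report</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em;} h2{border-bottom:1px solid #999;}",
    "table{border-collapse:collapse;} td,th{border:1px solid #ccc;padding:4px 8px;}",
    ".timestamp{color:#777;font-size:smaller;}",
    "</style></head><body>",
    "<h1>Gene exemplar analysis report</h1>",
    paste0("<p class=\"timestamp\">Generated: ",
           format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "</p>"),
    "<h2>1. Samples and class labels</h2>", sec1,
    "<h2>2. Exemplars: statistics and network characteristics</h2>", sec2,
    "<h2>3. Classification performance</h2>", sec3,
    "<h2>4. Annotation per exemplar</h2>", sec4,
    "</body></html>")
  tryCatch(writeLines(doc, path),
           error = function(e) stop("cannot write report to '", path,
                                    "': ", conditionMessage(e)))
  invisible(path)
}
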