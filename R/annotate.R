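#' Annotate probes against an offline annotation table
#'
#' Left-joins a probe list against a user-supplied annotation table
#' (typically extracted from a chip annotation database), preserving the
#' probe order. Probes absent from the table yield records with NA
#' fields; duplicated table rows for a probe are resolved first-wins with
#' a warning.
#'
#' @param probes character vector of probe ids.
#' @param table data.frame with columns `probe_id`, `symbol`,
#'   `entrez_id`, `ensembl_id`, `chromosome`.
#' @return data.frame with one row per queried probe, columns as in
#'   `table`.
#' @export
annotate_probes <- function(probes, table) {
  need <- c("probe_id", "symbol", "entrez_id", "ensembl_id", "chromosome")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(table$probe_id)) {
    warning("duplicate annotation rows; keeping the first per probe")
    table <- table[!duplicated(table$probe_id), , drop = FALSE]
  }
  out <- table[match(probes, table$probe_id), need, drop = FALSE]
  out$probe_id <- probes
  rownames(out) <- NULL
  out
}

#' Map annotated probes to pathways
#'
#' Records without an entrez id are dropped first; the remainder are
#' joined against an entrez-to-pathway mapping table. Alongside the
#' per-record hits, the de-duplicated set of matched pathways is
#' reported.
#'
#' @param records an [annotate_probes()] result (needs `entrez_id`).
#' @param pathway_table data.frame with columns `entrez_id`,
#'   `pathway_id`, `pathway_name`.
#' @return list with `hits` (data.frame `entrez_id`, `pathway_id`,
#'   `pathway_name`, one row per match) and `pathways` (distinct matched
#'   pathways).
#' @export
probes_to_pathways <- function(records, pathway_table) {
  if (!is.data.frame(records) || !"entrez_id" %in% names(records))
    stop("'records' needs an 'entrez_id' column")
  need <- c("entrez_id", "pathway_id", "pathway_name")
  if (!is.data.frame(pathway_table) || !all(need %in% names(pathway_table)))
    stop("pathway table needs columns: ", paste(need, collapse = ", "))
  entrez <- unique(records$entrez_id[!is.na(records$entrez_id)])
  hits <- pathway_table[pathway_table$entrez_id %in% entrez, need,
                        drop = FALSE]
  rownames(hits) <- NULL
  pathways <- unique(hits[, c("pathway_id", "pathway_name"), drop = FALSE])
  rownames(pathways) <- NULL
  list(hits = hits, pathways = pathways)
}
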