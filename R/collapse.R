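# Probe-to-symbol collapse and mouse-to-human symbol mapping. Mirrors the
# conventional GSEA "collapse" behaviour: one row per target symbol, keeping
# the probe with the largest across-sample mean; ties broken by the
# lexicographically smallest probe id so runs are platform-independent.

# shared collapse kernel: rows of `values` grouped by `target`, keep max-mean
.collapse_by_target <- function(values, target) {
  means <- rowMeans(values)
  ord <- order(target, -means, rownames(values), method = "radix")
  keep <- ord[!duplicated(target[ord])]
  out <- values[keep, , drop = FALSE]
  rownames(out) <- target[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Collapse a probe-level dataset to gene symbols
#'
#' For each target symbol the retained row is the probe whose across-sample
#' mean is largest (the conventional GSEA collapse default); ties are broken
#' by the lexicographically smallest probe id. Unmapped probes are dropped
#' and counted in a message.
#'
#' @param data an [expression_dataset] with probe-level feature ids.
#' @param map named character vector (probe id -> gene symbol), e.g. from
#'   [read_symbol_map].
#' @return an [expression_dataset] with one row per gene symbol.
#' @export
collapse_probes <- function(data, map) {
  stopifnot(inherits(data, "expr_dataset"))
  probes <- rownames(data$values)
  tgt <- map[probes]
  mapped <- !is.na(tgt) & tgt != ""
  if (!any(mapped))
    stop("no probe maps to a symbol; collapse would produce an empty dataset")
  n_drop <- sum(!mapped)
  if (n_drop > 0L)
    message(n_drop, " unmapped probe(s) dropped during collapse")
  out <- .collapse_by_target(data$values[mapped, , drop = FALSE],
                             unname(tgt[mapped]))
  expression_dataset(out, as.character(data$phenotype),
                     case = data$case, control = data$control,
                     scale_note = data$scale_note)
}

#' Map mouse gene symbols to human (HUGO) symbols
#'
#' With an explicit ortholog table, rows are renamed via the table and
#' unmapped rows dropped. Without a table, the fallback heuristic uppercases
#' the mouse symbols (most one-to-one mouse orthologs differ from their HUGO
#' symbol only in case). Many-to-one collisions are re-collapsed by the
#' max-mean rule of [collapse_probes].
#'
#' @param data an [expression_dataset] with mouse symbol feature ids.
#' @param ortholog optional named character vector (mouse symbol -> HUGO
#'   symbol). \code{NULL} selects the uppercase heuristic.
#' @return an [expression_dataset] keyed by human symbols (possibly with
#'   fewer rows). An empty result is returned with a warning; the downstream
#'   gene-set size filter handles it.
#' @export
map_mouse_to_human <- function(data, ortholog = NULL) {
  stopifnot(inherits(data, "expr_dataset"))
  sym <- rownames(data$values)
  if (is.null(ortholog)) {
    tgt <- toupper(sym)
    mapped <- rep(TRUE, length(sym))
  } else {
    tgt <- unname(ortholog[sym])
    mapped <- !is.na(tgt) & tgt != ""
    n_drop <- sum(!mapped)
    if (n_drop > 0L)
      message(n_drop, " symbol(s) without ortholog dropped")
  }
  if (!any(mapped)) {
    warning("no symbol mapped; returning empty dataset")
    empty <- data$values[0, , drop = FALSE]
    d <- data; d$values <- empty
    return(d)
  }
  out <- .collapse_by_target(data$values[mapped, , drop = FALSE], tgt[mapped])
  expression_dataset(out, as.character(data$phenotype),
                     case = data$case, control = data$control,
                     scale_note = data$scale_note)
}
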