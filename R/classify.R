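#' Three-state pathway regulation calls from a GSEA fit
#'
#' Each pathway of the reference collection receives exactly one state:
#' \code{up} if FDR q <= threshold and NES > 0, \code{down} if q <= threshold
#' and NES < 0, and \code{null} otherwise — covering non-significant
#' pathways (q > threshold), pathways excluded by the size filter
#' (too few or too many detectable genes) and untested pathways. A NES of
#' exactly 0 has no direction and is called \code{null}.
#'
#' @param fit a [gsea] fit over the same collection.
#' @param collection the reference [gene_sets] collection (defaults to the
#'   sets of the fit). Every pathway of the collection gets a state; a
#'   pathway present in the fit but absent from the collection is an error.
#' @param fdr_threshold significance threshold on the permutation FDR q
#'   (default 0.25).
#' @param id dataset identifier carried into downstream comparisons.
#' @return object of class \code{"pathway_profile"}: data.frame with columns
#'   \code{pathway}, \code{state} (factor up/down/null), \code{NES},
#'   \code{q}, plus attributes \code{id} and \code{fdr_threshold}.
#' @examples
#' sim <- simulate_dataset(simulation_design(n_genes = 400, n_sets = 5,
#'                                           set_size = 20, delta = 2, seed = 1))
#' fit <- gsea(sim$dataset, sim$sets, gsea_params(n_perm = 100, seed = 1))
#' table(pathway_states(fit)$state)
#' @export
pathway_states <- function(fit, collection = NULL, fdr_threshold = 0.25,
                           id = "dataset") {
  stopifnot(inherits(fit, "gsea"), fdr_threshold >= 0)
  tab <- fit$table
  coll_names <- if (is.null(collection)) tab$set else names(collection)
  if (!all(tab$set %in% coll_names))
    stop("pathway in results but absent from the collection: ",
         paste(setdiff(tab$set, coll_names), collapse = ", "))
  i <- match(coll_names, tab$set)
  nes <- tab$NES[i]; q <- tab$q_fdr[i]; status <- tab$status[i]
  state <- rep("null", length(coll_names))
  tested <- !is.na(status) & status == "tested"
  up <- tested & !is.na(q) & q <= fdr_threshold & nes > 0
  down <- tested & !is.na(q) & q <= fdr_threshold & nes < 0
  state[up] <- "up"; state[down] <- "down"
  out <- data.frame(pathway = coll_names,
                    state = factor(state, levels = c("up", "down", "null")),
                    NES = nes, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, id = id, fdr_threshold = fdr_threshold,
            class = c("pathway_profile", "data.frame"))
}

#' @export
print.pathway_profile <- function(x, ...) {
  counts <- table(x$state)
  cat(sprintf("Pathway profile '%s' (FDR <= %g): %d up, %d down, %d null of %d\n",
              attr(x, "id"), attr(x, "fdr_threshold"),
              counts[["up"]], counts[["down"]], counts[["null"]], nrow(x)))
  invisible(x)
}

# up/down pathway name sets, used throughout model comparison
.up_set <- function(profile) profile$pathway[profile$state == "up"]
.down_set <- function(profile) profile$pathway[profile$state == "down"]
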