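# End-to-end orchestration: per-dataset GSEA -> three-state profiles ->
# all-pairs concordance -> species-group statistics -> optional
# shared-pathway report for a configured subgroup, plus stable TSV/JSON
# exports of every stage.

# deterministic per-dataset seed substream derived from the global seed and
# the dataset id, so adding or reordering datasets does not perturb the
# others' results
.dataset_seed <- function(seed, id) {
  if (is.null(seed)) return(NULL)
  u <- utf8ToInt(id)
  as.integer((seed + 7919 * (sum(u * seq_along(u)) %% 100000L)) %% .Machine$integer.max)
}

#' Run the full concordance pipeline
#'
#' For each dataset: GSEA against the collection, then the three-state
#' pathway profile; then all-pairs predictive-value concordance with
#' species-group summaries, Kruskal-Wallis/Dunn group tests on the pairwise
#' mean predictive values, equality-of-proportions tests on the
#' significant-pair counts, and (optionally) the shared-regulation report
#' for a subgroup of datasets. Output table row order is canonicalized
#' (datasets sorted by id) so results do not depend on input order.
#'
#' @param datasets named list of [expression_dataset]s keyed by gene symbol
#'   (>= 2).
#' @param sets a [gene_sets] collection.
#' @param species optional per-dataset \code{"human"}/\code{"mouse"} labels
#'   (same order/names as \code{datasets}).
#' @param params a [gsea_params]; its \code{seed} is expanded into
#'   id-derived per-dataset substreams.
#' @param fdr_threshold three-state call threshold (default 0.25).
#' @param alpha pairwise chi-squared significance threshold (default 0.05).
#' @param subgroup optional character vector of dataset ids for the
#'   shared-regulation report.
#' @param out_dir optional directory; when given, [write_results] is called.
#' @return object of class \code{"pipeline_result"}: \code{fits},
#'   \code{profiles}, \code{concordance} ([compare_models] output),
#'   \code{group_test} (Kruskal-Wallis/Dunn on mean_pv, or NULL),
#'   \code{prop_tests} (pair-level and partner-level human-vs-mouse
#'   proportion tests, or NULL), \code{shared} (or NULL), \code{params},
#'   \code{fdr_threshold}, \code{alpha}.
#' @export
run_pipeline <- function(datasets, sets, species = NULL,
                         params = gsea_params(), fdr_threshold = 0.25,
                         alpha = 0.05, subgroup = NULL, out_dir = NULL) {
  stopifnot(length(datasets) >= 2L, !is.null(names(datasets)),
            inherits(sets, "gene_sets"))
  ids <- names(datasets)
  if (!is.null(species)) {
    stopifnot(length(species) == length(datasets))
    names(species) <- ids
  }
  ord <- order(ids)
  ids <- ids[ord]; datasets <- datasets[ord]
  if (!is.null(species)) species <- species[ids]
  fits <- vector("list", length(datasets)); names(fits) <- ids
  profiles <- vector("list", length(datasets)); names(profiles) <- ids
  for (i in seq_along(datasets)) {
    p_i <- params
    p_i$seed <- .dataset_seed(params$seed, ids[i])
    fits[[i]] <- tryCatch(
      gsea(datasets[[i]], sets, p_i),
      error = function(e) stop("GSEA failed for dataset '", ids[i], "': ",
                               conditionMessage(e)))
    profiles[[i]] <- pathway_states(fits[[i]], sets,
                                    fdr_threshold = fdr_threshold,
                                    id = ids[i])
  }
  conc <- compare_models(profiles, species = species, alpha = alpha)
  group_test <- NULL; prop_tests <- NULL
  if (!is.null(species) && length(unique(species)) == 2L) {
    pr <- conc$pairs
    ok_groups <- names(which(table(pr$group) >= 2L))
    if (length(ok_groups) >= 2L) {
      keep <- pr$group %in% ok_groups & !is.na(pr$mean_pv)
      group_test <- tryCatch(
        kruskal_wallis_dunn(pr$mean_pv[keep], pr$group[keep]),
        error = function(e) NULL)
    }
    hh <- pr[pr$group == "hh", ]; mm <- pr[pr$group == "mm", ]
    if (nrow(hh) > 0L && nrow(mm) > 0L) {
      pair_level <- proportions_test(sum(hh$significant), nrow(hh),
                                     sum(mm$significant), nrow(mm))
      n_sig <- conc$n_significant
      is_h <- species[names(n_sig)] == "human"
      # partner-level: significant partners per dataset, out of possible
      partner_level <- proportions_test(
        sum(n_sig[is_h]), sum(is_h) * (length(n_sig) - 1L),
        sum(n_sig[!is_h]), sum(!is_h) * (length(n_sig) - 1L))
      prop_tests <- list(pair_level = pair_level,
                         partner_level = partner_level)
    }
  }
  shared <- NULL
  if (!is.null(subgroup)) {
    missing_ids <- setdiff(subgroup, ids)
    if (length(missing_ids))
      stop("subgroup dataset(s) not in manifest: ",
           paste(missing_ids, collapse = ", "))
    shared <- shared_regulation(profiles[subgroup])
  }
  res <- structure(list(fits = fits, profiles = profiles,
                        concordance = conc, group_test = group_test,
                        prop_tests = prop_tests, shared = shared,
                        params = params, fdr_threshold = fdr_threshold,
                        alpha = alpha),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pathway-concordance pipeline result\n")
  print(x$concordance)
  if (!is.null(x$group_test))
    cat(sprintf("  species effect (Kruskal-Wallis on mean PV): p = %.4g\n",
                x$group_test$p))
  invisible(x)
}

#' Write all pipeline result tables
#'
#' Emits, with documented stable column order: one enrichment TSV per
#' dataset (\code{gsea_<id>.tsv}: set, size, ES, NES, p_nominal, q_fdr,
#' leading_edge, status), one profile TSV per dataset
#' (\code{profile_<id>.tsv}: pathway, state, NES, q), the pair table
#' \code{pairs.tsv}, the mean-PV and delta matrices, group summaries, the
#' shared-pathway report when present, and a machine-readable
#' \code{run_summary.json} with parameters and headline numbers. Reruns
#' with the same inputs and seed are byte-identical.
#'
#' @param result a \code{"pipeline_result"}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (id in names(result$fits)) {
    f <- file.path(out_dir, paste0("gsea_", id, ".tsv"))
    .write_tsv(result$fits[[id]]$table, f)
    files <- c(files, f)
    f <- file.path(out_dir, paste0("profile_", id, ".tsv"))
    .write_tsv(as.data.frame(result$profiles[[id]]), f)
    files <- c(files, f)
  }
  conc <- result$concordance
  f <- file.path(out_dir, "pairs.tsv")
  .write_tsv(conc$pairs, f); files <- c(files, f)
  for (nm in c("mean_pv_matrix", "delta_matrix")) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    m <- conc[[nm]]
    .write_tsv(data.frame(dataset = rownames(m), m, check.names = FALSE), f)
    files <- c(files, f)
  }
  if (!is.null(conc$groups)) {
    f <- file.path(out_dir, "group_summary.tsv")
    .write_tsv(conc$groups, f); files <- c(files, f)
  }
  if (!is.null(result$shared)) {
    f <- file.path(out_dir, "shared_pathways.tsv")
    .write_tsv(result$shared$shared, f); files <- c(files, f)
    f <- file.path(out_dir, "shared_nes_matrix.tsv")
    m <- result$shared$nes_matrix
    .write_tsv(data.frame(pathway = rownames(m), m, check.names = FALSE), f)
    files <- c(files, f)
  }
  summary_obj <- list(
    package = "pathconcord",
    version = as.character(utils::packageVersion("pathconcord")),
    params = result$params[c("n_perm", "weight", "min_size", "max_size",
                             "metric", "seed")],
    fdr_threshold = result$fdr_threshold, alpha = result$alpha,
    n_datasets = length(result$fits),
    n_pairs = nrow(conc$pairs),
    n_significant_pairs = sum(conc$pairs$significant),
    n_significant_per_dataset = as.list(conc$n_significant),
    groups = conc$groups,
    kruskal_wallis_p = if (is.null(result$group_test)) NULL
                       else result$group_test$p,
    prop_test_pair_p = if (is.null(result$prop_tests)) NULL
                       else result$prop_tests$pair_level$p)
  f <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary_obj, f, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
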