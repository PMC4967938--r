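# Pairwise pathway-concordance statistics: positive/negative predictive
# values, their chance expectation, change over chance in percentage points,
# the 3x3 contingency chi-squared test, plus shared-pathway and core-gene
# reports across a subgroup of datasets.

#' Predictive values between two pathway profiles
#'
#' Answers whether the pathway regulation of model 1 can be predicted by
#' model 2: \code{PPV = |Up1 n Up2| / |Up2|} and
#' \code{NPV = |Down1 n Down2| / |Down2|}. A zero denominator leaves the
#' corresponding value undefined (NA, excluded from averages); if both are
#' undefined \code{mean_pv} is NA and the pair is excluded from summaries.
#'
#' @param profile1 the [pathway_states] profile being predicted.
#' @param profile2 the predictor profile, over the identical collection.
#' @return list with \code{PPV}, \code{NPV}, \code{mean_pv} (mean of the
#'   defined values).
#' @examples
#' # Up1 = {P1,P2,P5}, Up2 = {P1,P2,P3,P4} gives PPV = 2/4
#' @export
predictive_values <- function(profile1, profile2) {
  .check_same_collection(profile1, profile2)
  up1 <- .up_set(profile1); up2 <- .up_set(profile2)
  dn1 <- .down_set(profile1); dn2 <- .down_set(profile2)
  ppv <- if (length(up2) == 0L) NA_real_
         else length(intersect(up1, up2)) / length(up2)
  npv <- if (length(dn2) == 0L) NA_real_
         else length(intersect(dn1, dn2)) / length(dn2)
  vals <- c(ppv, npv)
  mean_pv <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  list(PPV = ppv, NPV = npv, mean_pv = mean_pv)
}

.check_same_collection <- function(p1, p2) {
  if (!identical(sort(p1$pathway), sort(p2$pathway)))
    stop("profiles are not over the identical pathway collection")
}

#' Chance expectation of the predictive values
#'
#' If the regulation of the two models were independent, the predictive
#' value toward model 1 would equal model 1's base rate of calls: with 10%
#' of pathways upregulated in model 1, the expected PPV from any independent
#' model 2 is 10%.
#'
#' @param profile1 the profile being predicted.
#' @return list with \code{E_PPV}, \code{E_NPV} (fractions in [0, 1]).
#' @export
chance_expectation <- function(profile1) {
  n <- nrow(profile1)
  list(E_PPV = length(.up_set(profile1)) / n,
       E_NPV = length(.down_set(profile1)) / n)
}

#' Change of the predictive values over chance, in percentage points
#'
#' @param pv list with \code{PPV}, \code{NPV} from [predictive_values].
#' @param chance list with \code{E_PPV}, \code{E_NPV} from
#'   [chance_expectation].
#' @return mean of \code{(PPV - E_PPV)} and \code{(NPV - E_NPV)} over the
#'   defined sides, times 100 (percentage points).
#' @export
delta_over_chance <- function(pv, chance) {
  d <- c(pv$PPV - chance$E_PPV, pv$NPV - chance$E_NPV)
  if (all(is.na(d))) return(NA_real_)
  100 * mean(d, na.rm = TRUE)
}

#' 3x3 contingency table of two pathway profiles
#'
#' Rows are the model-1 state, columns the model-2 state, both over
#' \code{up}, \code{down}, \code{null}; counts cover all pathways of the
#' collection and sum to its size.
#'
#' @param profile1,profile2 [pathway_states] profiles over one collection.
#' @return 3x3 integer matrix.
#' @export
contingency_table <- function(profile1, profile2) {
  .check_same_collection(profile1, profile2)
  i <- match(profile1$pathway, profile2$pathway)
  tab <- table(model1 = profile1$state, model2 = profile2$state[i])
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(model1 = c("up", "down", "null"),
                              model2 = c("up", "down", "null")))
  m
}

#' Pearson chi-squared test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1) = 4 for
#' a full 3x3 table. Rows or columns with zero margin carry no information
#' and are dropped, with the degrees of freedom adjusted accordingly (a
#' message records the drop). If fewer than two rows or columns remain the
#' table is degenerate: the statistic is 0 and p = 1 is reported with a
#' warning.
#'
#' @param table numeric matrix of counts with positive total.
#' @return list with \code{stat}, \code{df}, \code{p}.
#' @examples
#' chi_squared_test(diag(c(10, 10, 10)))  # stat 60, df 4
#' @export
chi_squared_test <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0), sum(table) > 0)
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    message("dropping ", sum(rs == 0), " zero-margin row(s) and ",
            sum(cs == 0), " zero-margin column(s); df adjusted")
    table <- table[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(table); cs <- colSums(table)
  }
  if (nrow(table) < 2L || ncol(table) < 2L) {
    warning("degenerate contingency table; reporting p = 1")
    return(list(stat = 0, df = 0L, p = 1))
  }
  n <- sum(table)
  expected <- outer(rs, cs) / n
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Full concordance summary of one dataset pair
#'
#' Computes both prediction directions, the direction-averaged mean
#' predictive value and change over chance, and the (direction-symmetric)
#' 3x3 chi-squared test.
#'
#' @param profile1,profile2 [pathway_states] profiles over one collection.
#' @param alpha significance threshold on the chi-squared p (default 0.05,
#'   uncorrected).
#' @return list of class \code{"pair_comparison"}: ids, \code{PPV12},
#'   \code{NPV12}, \code{PPV21}, \code{NPV21} (\code{12} = model 1 predicted
#'   by model 2), direction-wise \code{mean_pv_12}/\code{mean_pv_21} and the
#'   direction-averaged \code{mean_pv} and \code{delta_points}, chance
#'   expectations, \code{table}, \code{chi2_stat}, \code{chi2_df},
#'   \code{chi2_p}, \code{significant}.
#' @export
compare_pair <- function(profile1, profile2, alpha = 0.05) {
  pv12 <- predictive_values(profile1, profile2)
  pv21 <- predictive_values(profile2, profile1)
  ch1 <- chance_expectation(profile1)
  ch2 <- chance_expectation(profile2)
  d12 <- delta_over_chance(pv12, ch1)
  d21 <- delta_over_chance(pv21, ch2)
  all4 <- c(pv12$PPV, pv12$NPV, pv21$PPV, pv21$NPV)
  mean_pv <- if (all(is.na(all4))) NA_real_ else mean(all4, na.rm = TRUE)
  delta <- if (all(is.na(c(d12, d21)))) NA_real_
           else mean(c(d12, d21), na.rm = TRUE)
  tab <- contingency_table(profile1, profile2)
  chi <- suppressMessages(chi_squared_test(tab))
  structure(list(
    id1 = attr(profile1, "id"), id2 = attr(profile2, "id"),
    PPV12 = pv12$PPV, NPV12 = pv12$NPV,
    PPV21 = pv21$PPV, NPV21 = pv21$NPV,
    mean_pv_12 = pv12$mean_pv, mean_pv_21 = pv21$mean_pv,
    mean_pv = mean_pv,
    E_PPV1 = ch1$E_PPV, E_NPV1 = ch1$E_NPV,
    E_PPV2 = ch2$E_PPV, E_NPV2 = ch2$E_NPV,
    delta_points = delta, table = tab,
    chi2_stat = chi$stat, chi2_df = chi$df, chi2_p = chi$p,
    significant = !is.na(chi$p) && chi$p <= alpha),
    class = "pair_comparison")
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf("Pair %s vs %s: mean PV %.2f, delta over chance %+.1f points, chi2 p = %.3g%s\n",
              x$id1, x$id2, x$mean_pv, x$delta_points, x$chi2_p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' All-pairs model concordance
#'
#' Runs [compare_pair] on every unordered pair of profiles and summarizes
#' by species group (human-human, mouse-mouse, human-mouse) when species
#' labels are given: group means of the pairwise mean predictive value and
#' of the change over chance, and the percentage of significant pairs per
#' group, plus per-dataset counts of significant partners.
#'
#' @param profiles named list of [pathway_states] profiles over one
#'   collection (names default to the profiles' \code{id} attributes).
#' @param species optional character vector (\code{"human"}/\code{"mouse"})
#'   per profile.
#' @param alpha pairwise significance threshold (default 0.05, uncorrected
#'   across pairs).
#' @return object of class \code{"model_concordance"}: \code{pairs}
#'   (data.frame, one row per unordered pair), \code{mean_pv_matrix} and
#'   \code{delta_matrix} (symmetric dataset-by-dataset), \code{n_significant}
#'   (per-dataset significant-partner counts), \code{groups} (per-group
#'   summary data.frame, when species given), \code{species}, \code{alpha}.
#' @examples
#' pair <- simulate_model_pair(simulation_design(n_genes = 400, n_sets = 6,
#'                                               set_size = 20, delta = 2,
#'                                               seed = 7), rho = 1)
#' fits <- lapply(pair[c("dataset_A", "dataset_B")], gsea, sets = pair$sets,
#'                params = gsea_params(n_perm = 100, seed = 3))
#' profs <- Map(pathway_states, fits, id = c("A", "B"))
#' compare_models(profs)
#' @export
compare_models <- function(profiles, species = NULL, alpha = 0.05) {
  stopifnot(length(profiles) >= 2L)
  ids <- names(profiles)
  if (is.null(ids))
    ids <- vapply(profiles, attr, "", "id")
  if (anyDuplicated(ids)) stop("duplicate dataset ids")
  names(profiles) <- ids
  if (!is.null(species)) {
    stopifnot(length(species) == length(profiles),
              all(species %in% c("human", "mouse")))
    names(species) <- ids
  }
  n <- length(profiles)
  pair_idx <- utils::combn(n, 2L)
  rows <- vector("list", ncol(pair_idx))
  m_pv <- m_delta <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(m_pv) <- 1; diag(m_delta) <- NA
  n_sig <- stats::setNames(integer(n), ids)
  for (k in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1L, k]; j <- pair_idx[2L, k]
    pc <- compare_pair(profiles[[i]], profiles[[j]], alpha = alpha)
    pc$id1 <- ids[i]; pc$id2 <- ids[j]
    grp <- if (is.null(species)) NA_character_ else
      paste(sort(substr(c(species[i], species[j]), 1L, 1L)), collapse = "")
    rows[[k]] <- data.frame(
      model1 = ids[i], model2 = ids[j], group = grp,
      PPV12 = pc$PPV12, NPV12 = pc$NPV12,
      PPV21 = pc$PPV21, NPV21 = pc$NPV21,
      mean_pv = pc$mean_pv,
      E_PPV1 = pc$E_PPV1, E_NPV1 = pc$E_NPV1,
      E_PPV2 = pc$E_PPV2, E_NPV2 = pc$E_NPV2,
      delta_points = pc$delta_points,
      chi2 = pc$chi2_stat, df = pc$chi2_df, p = pc$chi2_p,
      significant = pc$significant, stringsAsFactors = FALSE)
    m_pv[i, j] <- m_pv[j, i] <- pc$mean_pv
    m_delta[i, j] <- m_delta[j, i] <- pc$delta_points
    if (pc$significant) {
      n_sig[i] <- n_sig[i] + 1L; n_sig[j] <- n_sig[j] + 1L
    }
  }
  pairs <- do.call(rbind, rows)
  groups <- NULL
  if (!is.null(species)) {
    groups <- do.call(rbind, lapply(c("hh", "mm", "hm"), function(g) {
      sub <- pairs[pairs$group == g, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      data.frame(group = g, n_pairs = nrow(sub),
                 mean_pv = mean(sub$mean_pv, na.rm = TRUE),
                 mean_delta_points = mean(sub$delta_points, na.rm = TRUE),
                 pct_significant = 100 * mean(sub$significant),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(pairs = pairs, mean_pv_matrix = m_pv,
                 delta_matrix = m_delta, n_significant = n_sig,
                 groups = groups, species = species, alpha = alpha),
            class = "model_concordance")
}

#' @export
print.model_concordance <- function(x, ...) {
  cat(sprintf("Model concordance: %d datasets, %d pairs, %d significant (P <= %g)\n",
              nrow(x$mean_pv_matrix), nrow(x$pairs),
              sum(x$pairs$significant), x$alpha))
  if (!is.null(x$groups)) {
    cat("  group summaries (mean PV / delta points / % significant):\n")
    for (i in seq_len(nrow(x$groups)))
      cat(sprintf("    %s: %.2f / %+.1f / %.0f%%  (%d pairs)\n",
                  x$groups$group[i], x$groups$mean_pv[i],
                  x$groups$mean_delta_points[i],
                  x$groups$pct_significant[i], x$groups$n_pairs[i]))
  }
  invisible(x)
}

#' @describeIn compare_models the per-pair table.
#' @param object,x a \code{"model_concordance"} object.
#' @param ... unused.
#' @export
summary.model_concordance <- function(object, ...) object$pairs

#' @describeIn compare_models heatmap of the pairwise mean predictive values.
#' @export
plot.model_concordance <- function(x, ...) {
  m <- x$mean_pv_matrix
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  zlim = c(0, 1), main = "pairwise mean predictive value",
                  ...)
  graphics::axis(1, seq_len(n), colnames(m), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(n), rev(rownames(m)), las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Shared-regulation NES matrix for a subgroup of datasets
#'
#' Builds the pathways-by-datasets matrix of normalized enrichment scores,
#' masked (NA) wherever the pathway is not significantly regulated
#' (state \code{null}: q > threshold, or undetectable), and lists the
#' pathways significantly regulated in every subgroup member with a
#' consistent sign.
#'
#' @param profiles non-empty named list of [pathway_states] profiles over
#'   one collection.
#' @return list with \code{nes_matrix} (NES where significant, NA
#'   elsewhere) and \code{shared} (data.frame pathway/direction for
#'   pathways regulated in all datasets with one sign).
#' @export
shared_regulation <- function(profiles) {
  if (length(profiles) == 0L) stop("empty subgroup")
  ids <- names(profiles)
  if (is.null(ids)) ids <- vapply(profiles, attr, "", "id")
  ref <- profiles[[1L]]$pathway
  m <- matrix(NA_real_, length(ref), length(profiles),
              dimnames = list(ref, ids))
  state_m <- matrix(NA_character_, length(ref), length(profiles))
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    .check_same_collection(profiles[[1L]], p)
    i <- match(ref, p$pathway)
    sig <- p$state[i] != "null"
    m[sig, j] <- p$NES[i][sig]
    state_m[, j] <- as.character(p$state[i])
  }
  all_up <- apply(state_m == "up", 1L, all)
  all_down <- apply(state_m == "down", 1L, all)
  shared <- data.frame(
    pathway = c(ref[all_up], ref[all_down]),
    direction = rep(c("up", "down"), c(sum(all_up), sum(all_down))),
    stringsAsFactors = FALSE)
  shared <- shared[order(shared$pathway), , drop = FALSE]
  rownames(shared) <- NULL
  list(nes_matrix = m, shared = shared)
}

#' Consistently upregulated core genes of one pathway
#'
#' Among the datasets where the pathway is called \code{up}, tallies each
#' gene's leading-edge membership and returns genes appearing in at least
#' \code{k_min} of those leading edges — the recurrent drivers of the
#' shared enrichment.
#'
#' @param fits named list of [gsea] fits (one per dataset).
#' @param profiles matching named list of [pathway_states] profiles.
#' @param pathway pathway (gene-set) name.
#' @param k_min minimum number of leading edges a gene must appear in.
#' @return data.frame with columns \code{gene}, \code{n_leading_edges},
#'   sorted by tally (descending) then symbol; attribute
#'   \code{n_up_datasets} gives the number of up-called datasets tallied.
#' @export
consistent_core_genes <- function(fits, profiles, pathway, k_min) {
  stopifnot(length(fits) == length(profiles), k_min >= 1L)
  up_in <- vapply(profiles, function(p) {
    i <- match(pathway, p$pathway)
    !is.na(i) && p$state[i] == "up"
  }, TRUE)
  if (sum(up_in) < k_min)
    warning("pathway '", pathway, "' is up-called in only ", sum(up_in),
            " dataset(s); fewer than k_min = ", k_min)
  les <- lapply(fits[up_in], function(f) f$leading_edges[[pathway]])
  tally <- table(unlist(les, use.names = FALSE))
  keep <- tally >= k_min
  out <- data.frame(gene = names(tally)[keep],
                    n_leading_edges = as.integer(tally[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_leading_edges, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up_datasets") <- sum(up_in)
  out
}
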