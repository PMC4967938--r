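# Two-class GSEA built from first principles: signal-to-noise ranking,
# weighted Kolmogorov-Smirnov running-sum enrichment score, gene-set
# permutation null, NES, nominal p, permutation FDR q.
#
# The null model is GENE-SET permutation (random same-size gene sets drawn
# from the ranked universe), not phenotype permutation; the two give
# different nulls and this package implements only the former.

#' GSEA parameter bundle
#'
#' Defaults follow the standard weighted configuration: 1,000 gene-set
#' permutations, weight exponent 1 ("weighted" statistic), gene-set size
#' between 15 and 500, signal-to-noise ranking metric.
#'
#' @param n_perm number of gene-set permutations (>= 1).
#' @param weight weight exponent p applied to |score| in the running sum
#'   (0 = classic Kolmogorov-Smirnov, 1 = weighted).
#' @param min_size,max_size detectable-size bounds; sets outside are not
#'   tested.
#' @param seed integer seed for the permutation RNG, or NULL to use the
#'   current RNG state.
#' @return list of class \code{"gsea_params"}.
#' @export
gsea_params <- function(n_perm = 1000L, weight = 1, min_size = 15L,
                        max_size = 500L, seed = NULL) {
  stopifnot(n_perm >= 1L, weight >= 0,
            min_size >= 1L, min_size <= max_size)
  structure(list(n_perm = as.integer(n_perm), weight = weight,
                 min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 metric = "signal_to_noise", seed = seed),
            class = "gsea_params")
}

# run code under a temporary RNG state seeded with `seed` (NULL = no-op)
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Signal-to-noise ranking of a two-class dataset
#'
#' Per gene, \eqn{s = (\mu_{case} - \mu_{ctrl}) / (\sigma_{case} +
#' \sigma_{ctrl})} with sample (n-1) standard deviations, each standard
#' deviation floored at \eqn{\max(0.2 |\mu|, 0.2)} of its own class (the
#' conventional signal-to-noise variance adjustment, which also guarantees a
#' strictly positive denominator). Genes are sorted by descending score; ties
#' broken by ascending gene symbol so ranks are platform-independent.
#'
#' @param data an [expression_dataset] keyed by gene symbol.
#' @return object of class \code{"ranked_list"}: list with \code{gene}
#'   (character, descending-score order), \code{score} (numeric) and
#'   \code{N}.
#' @examples
#' m <- rbind(A = c(1, 2, 3, 3, 4, 5), B = c(5, 4, 3, 1, 2, 3))
#' colnames(m) <- paste0("S", 1:6)
#' ds <- expression_dataset(m, rep(c("ctrl", "dis"), each = 3), case = "dis")
#' signal_to_noise(ds)$score  # +1 for A, -1 for B
#' @export
signal_to_noise <- function(data) {
  stopifnot(inherits(data, "expr_dataset"))
  is_case <- data$phenotype == data$case
  if (sum(is_case) < 2L || sum(!is_case) < 2L)
    stop("signal-to-noise needs >= 2 samples per class")
  x_case <- data$values[, is_case, drop = FALSE]
  x_ctrl <- data$values[, !is_case, drop = FALSE]
  mu1 <- rowMeans(x_case); mu0 <- rowMeans(x_ctrl)
  sd1 <- apply(x_case, 1L, stats::sd)
  sd0 <- apply(x_ctrl, 1L, stats::sd)
  s1 <- pmax(sd1, 0.2 * abs(mu1), 0.2)
  s0 <- pmax(sd0, 0.2 * abs(mu0), 0.2)
  s <- (mu1 - mu0) / (s1 + s0)
  ord <- order(-s, rownames(data$values), method = "radix")
  structure(list(gene = rownames(data$values)[ord],
                 score = unname(s[ord]), N = length(s)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("Ranked list: %d genes, scores %.3f .. %.3f\n",
              x$N, x$score[1L], x$score[x$N]))
  invisible(x)
}

# Fast ES from sorted hit positions. The running sum is piecewise linear
# with vertices at hits, so its extremes occur just after a hit (maximum
# candidates) or just before one (minimum candidates). O(N_H) per call.
# absw = |score|^p at the hit positions (unnormalized); N = list length.
.es_stat <- function(hit_pos, absw, N) {
  h <- length(hit_pos)
  nr <- sum(absw)
  w <- if (nr > 0) absw / nr else rep(1 / h, h)  # all-zero scores: uniform
  miss_dec <- 1 / (N - h)
  W <- cumsum(w)
  drop_after <- (hit_pos - seq_len(h)) * miss_dec  # misses before each hit
  after <- W - drop_after
  before <- c(0, W[-h]) - drop_after
  pos <- max(after)
  neg <- min(before, 0)
  # tie in magnitude (within numerical noise): positive extreme kept
  if (pos >= -neg - 1e-12) pos else neg
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; positions holding set members ("hits") add
#' \eqn{|r_j|^p / N_R} (with \eqn{N_R = \sum_{hits} |r_j|^p}), the other
#' positions subtract \eqn{1/(N - N_H)}. ES is the extreme of the running
#' sum with largest absolute value, sign kept (a tie in magnitude keeps the
#' positive extreme). If every hit score is zero the hits are weighted
#' uniformly \eqn{1/N_H}. The leading edge contains the hit genes at or
#' before the extreme for ES > 0, at or after it for ES < 0.
#'
#' @param ranked a [ranked_list] (or list with \code{gene}, \code{score}).
#' @param members character vector of set member symbols; intersected with
#'   the list, must leave 1 <= N_H < N.
#' @param weight weight exponent p (default 1).
#' @return list with \code{ES}, \code{running} (length-N profile),
#'   \code{leading_edge} (gene symbols in rank order), \code{n_hits}.
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  hit <- ranked$gene %in% members
  n_h <- sum(hit)
  N <- ranked$N
  if (n_h == 0L) stop("no set member present in the ranked list")
  if (n_h >= N) stop("set covers the entire list; no misses to walk")
  absw <- abs(ranked$score)^weight
  nr <- sum(absw[hit])
  incr <- rep(-1 / (N - n_h), N)
  incr[hit] <- if (nr > 0) absw[hit] / nr else 1 / n_h
  running <- cumsum(incr)
  stopifnot(abs(running[N]) < 1e-9)  # proper subset: walk must end at 0
  i_max <- which.max(running); i_min <- which.min(running)
  # tie in magnitude (within numerical noise): positive extreme kept
  es <- if (running[i_max] >= -running[i_min] - 1e-12) running[i_max]
        else running[i_min]
  if (es > 0) {
    le <- ranked$gene[hit & seq_len(N) <= i_max]
  } else if (es < 0) {
    le <- ranked$gene[hit & seq_len(N) >= i_min]
  } else le <- character(0)
  list(ES = es, running = running, leading_edge = le, n_hits = n_h)
}

#' Gene-set permutation null for the enrichment score
#'
#' Draws \code{n_perm} random gene sets of size \code{n_h} uniformly without
#' replacement from the ranked universe and records each ES (weights are
#' renormalized per draw, as for a real set of that size).
#'
#' @param ranked a [ranked_list].
#' @param n_h set size to emulate.
#' @param params a [gsea_params] (uses \code{n_perm}, \code{weight},
#'   \code{seed}).
#' @return numeric vector of null ES values, all in [-1, 1].
#' @export
permutation_null <- function(ranked, n_h, params = gsea_params()) {
  stopifnot(n_h >= 1L, n_h < ranked$N)
  absw <- abs(ranked$score)^params$weight
  N <- ranked$N
  .with_seed(params$seed, {
    vapply(seq_len(params$n_perm), function(b) {
      pos <- sort.int(sample.int(N, n_h))
      .es_stat(pos, absw[pos], N)
    }, 0)
  })
}

#' Normalize an ES against its permutation null
#'
#' NES = ES divided by the mean |null ES| of the same sign as ES. The
#' nominal p-value is the fraction of same-signed null values at least as
#' extreme as ES, with the (k+1)/(n+1) guard so p is never zero. With no
#' same-signed null values the set is not normalizable and is flagged
#' \code{not_testable}.
#'
#' @param es observed enrichment score.
#' @param null numeric vector of null ES values from [permutation_null].
#' @return list with \code{NES}, \code{p_nominal}, \code{testable}.
#' @export
normalize_and_test <- function(es, null) {
  stopifnot(length(null) >= 1L)
  same <- if (es >= 0) null[null >= 0] else null[null < 0]
  if (es == 0) same <- null[null >= 0]
  n <- length(same)
  if (n == 0L || mean(abs(same)) == 0)
    return(list(NES = NA_real_, p_nominal = NA_real_, testable = FALSE))
  nes <- es / mean(abs(same))
  p <- (sum(abs(same) >= abs(es)) + 1) / (n + 1)
  list(NES = nes, p_nominal = p, testable = TRUE)
}

# Permutation FDR q: for a set with NES* > 0,
#   q = [fraction of pooled null NES >= NES*] / [fraction of observed NES >= NES*]
# mirrored with <= for NES* < 0; each direction uses only same-signed values
# in numerator and denominator; clipped to [0, 1]. The pooled null contains
# every permutation ES normalized by its own set's same-signed null mean.
.fdr_q <- function(obs_nes, null_nes_pool) {
  vapply(obs_nes, function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      null_dir <- null_nes_pool[null_nes_pool >= 0]
      obs_dir <- obs_nes[!is.na(obs_nes) & obs_nes >= 0]
      num <- if (length(null_dir)) mean(null_dir >= nes) else 0
      den <- mean(obs_dir >= nes)
    } else {
      null_dir <- null_nes_pool[null_nes_pool < 0]
      obs_dir <- obs_nes[!is.na(obs_nes) & obs_nes < 0]
      num <- if (length(null_dir)) mean(null_dir <= nes) else 0
      den <- mean(obs_dir <= nes)
    }
    min(1, num / den)  # den > 0: the set itself is counted
  }, 0)
}

#' Gene set enrichment analysis of a two-class dataset
#'
#' The full procedure: signal-to-noise ranking, per-set weighted running-sum
#' ES, gene-set permutation null, NES, nominal p and permutation FDR q.
#' Each set is first restricted to genes present in the data; sets with
#' fewer than \code{min_size} detectable genes get status \code{too_small},
#' more than \code{max_size} get \code{too_large}, and both are excluded
#' from testing and from the FDR pooling.
#'
#' @param data an [expression_dataset] keyed by gene symbol.
#' @param sets a [gene_sets] collection.
#' @param params a [gsea_params]. \code{seed} makes the run fully
#'   deterministic.
#' @return object of class \code{"gsea"}: list with \code{table} (one row
#'   per set, sorted by NES descending: set, size, ES, NES, p_nominal,
#'   q_fdr, leading_edge, status), \code{leading_edges} (named list of
#'   gene vectors), \code{ranked} (the [ranked_list]), \code{params}.
#' @examples
#' sim <- simulate_dataset(simulation_design(n_genes = 400, n_sets = 5,
#'                                           set_size = 20, delta = 2, seed = 1))
#' fit <- gsea(sim$dataset, sim$sets, gsea_params(n_perm = 100, seed = 1))
#' head(summary(fit))
#' @export
gsea <- function(data, sets, params = gsea_params()) {
  stopifnot(inherits(data, "expr_dataset"), inherits(sets, "gene_sets"))
  ranked <- signal_to_noise(data)
  nm <- names(sets)
  n_set <- length(sets)
  size <- integer(n_set); status <- character(n_set)
  es <- nes <- p_nom <- rep(NA_real_, n_set)
  led <- vector("list", n_set); names(led) <- nm
  null_nes_pool <- vector("list", n_set)
  absw <- abs(ranked$score)^params$weight
  gene_index <- stats::setNames(seq_len(ranked$N), ranked$gene)
  seeds <- if (is.null(params$seed)) rep(list(NULL), n_set)
           else as.list(params$seed + seq_len(n_set) - 1L)
  for (i in seq_len(n_set)) {
    present <- sets[[i]][sets[[i]] %in% ranked$gene]
    size[i] <- length(present)
    if (size[i] < params$min_size) { status[i] <- "too_small"; next }
    if (size[i] > params$max_size || size[i] >= ranked$N) {
      status[i] <- "too_large"; next
    }
    sc <- enrichment_score(ranked, present, params$weight)
    es[i] <- sc$ES
    p_i <- params; p_i$seed <- seeds[[i]]
    null_es <- permutation_null(ranked, size[i], p_i)
    nt <- normalize_and_test(es[i], null_es)
    if (!nt$testable) { status[i] <- "not_testable"; next }
    nes[i] <- nt$NES; p_nom[i] <- nt$p_nominal
    status[i] <- "tested"
    led[[i]] <- sc$leading_edge
    # normalize this set's null draws by their own same-signed null means
    mpos <- mean(null_es[null_es >= 0])
    mneg <- mean(abs(null_es[null_es < 0]))
    null_nes_pool[[i]] <- ifelse(null_es >= 0,
                                 null_es / mpos, null_es / mneg)
  }
  if (!any(status == "tested"))
    warning("no testable gene set (all filtered by size)")
  q <- rep(NA_real_, n_set)
  tested <- status == "tested"
  if (any(tested))
    q[tested] <- .fdr_q(nes[tested],
                        unlist(null_nes_pool[tested], use.names = FALSE))
  tab <- data.frame(
    set = nm, size = size, ES = es, NES = nes, p_nominal = p_nom,
    q_fdr = q,
    leading_edge = vapply(led, function(g)
      if (is.null(g)) "" else paste(g, collapse = ","), ""),
    status = status, stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(!tested, -ifelse(is.na(nes), -Inf, nes), nm)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  detectable <- lapply(seq_len(n_set), function(i)
    sets[[i]][sets[[i]] %in% ranked$gene])
  names(detectable) <- nm
  structure(list(table = tab, leading_edges = led, members = detectable,
                 ranked = ranked, params = params, n_genes = ranked$N),
            class = "gsea")
}

#' @export
print.gsea <- function(x, ...) {
  n_tested <- sum(x$table$status == "tested")
  cat(sprintf("GSEA fit: %d gene sets (%d tested), %d ranked genes, %d permutations\n",
              nrow(x$table), n_tested, x$n_genes, x$params$n_perm))
  sig <- x$table[x$table$status == "tested" & x$table$q_fdr <= 0.25, ]
  cat(sprintf("  sets at FDR <= 0.25: %d up, %d down\n",
              sum(sig$NES > 0), sum(sig$NES < 0)))
  invisible(x)
}

#' @describeIn gsea enrichment table (one row per set, NES descending).
#' @param object,x a \code{"gsea"} fit.
#' @param ... unused.
#' @export
summary.gsea <- function(object, ...) object$table

#' @describeIn gsea running-sum profile plot for one gene set.
#' @param set set name to plot (default: top NES).
#' @export
plot.gsea <- function(x, set = NULL, ...) {
  tab <- x$table[x$table$status == "tested", ]
  if (nrow(tab) == 0L) stop("no tested set to plot")
  if (is.null(set)) set <- tab$set[1L]
  i <- match(set, names(x$members))
  if (is.na(i)) stop("unknown set: ", set)
  sc <- enrichment_score(x$ranked, x$members[[set]], x$params$weight)
  plot(seq_len(x$ranked$N), sc$running, type = "l",
       xlab = "rank in ordered list", ylab = "running enrichment score",
       main = set, ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
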