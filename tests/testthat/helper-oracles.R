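# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately use naive element-by-element loops so they stay
# independent of the vectorized implementation paths they check.

# brute-force weighted running-sum walk over a ranked list
brute_running_sum <- function(scores, is_hit, p = 1) {
  N <- length(scores)
  n_h <- sum(is_hit)
  n_r <- sum(abs(scores[is_hit])^p)
  running <- numeric(N)
  acc <- 0
  for (j in seq_len(N)) {
    if (is_hit[j]) {
      acc <- acc + if (n_r > 0) abs(scores[j])^p / n_r else 1 / n_h
    } else {
      acc <- acc - 1 / (N - n_h)
    }
    running[j] <- acc
  }
  running
}

brute_es <- function(scores, is_hit, p = 1) {
  running <- brute_running_sum(scores, is_hit, p)
  hi <- max(running); lo <- min(running)
  # magnitude ties (within numerical noise) resolve to the positive extreme
  if (hi >= -lo - 1e-12) hi else lo
}

# textbook Pearson chi-squared, no corrections, no margin handling
brute_chi2 <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

# pathway profile built directly from a state vector
mk_profile <- function(states, id = "p", nes = NULL, q = NULL) {
  n <- length(states)
  structure(
    data.frame(pathway = sprintf("P%03d", seq_len(n)),
               state = factor(states, levels = c("up", "down", "null")),
               NES = if (is.null(nes)) NA_real_ else nes,
               q = if (is.null(q)) NA_real_ else q,
               stringsAsFactors = FALSE),
    id = id, fdr_threshold = 0.25,
    class = c("pathway_profile", "data.frame"))
}

# tiny two-class dataset from explicit per-class value rows
mk_dataset <- function(case_rows, ctrl_rows) {
  stopifnot(nrow(case_rows) == nrow(ctrl_rows))
  m <- cbind(ctrl_rows, case_rows)
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  expression_dataset(m, rep(c("ctrl", "dis"),
                            c(ncol(ctrl_rows), ncol(case_rows))),
                     case = "dis")
}

# ranked list object from explicit genes/scores (descending order assumed)
mk_ranked <- function(scores, genes = sprintf("G%03d", seq_along(scores))) {
  structure(list(gene = genes, score = scores, N = length(scores)),
            class = "ranked_list")
}
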