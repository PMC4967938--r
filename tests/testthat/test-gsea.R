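test_that("signal-to-noise matches hand arithmetic, including SD floors", {
  # (4-2)/(1+1) = 1
  ds <- mk_dataset(case_rows = rbind(A = c(3, 4, 5)),
                   ctrl_rows = rbind(A = c(1, 2, 3)))
  expect_equal(signal_to_noise(ds)$score, 1.0)

  # constant classes: floors 0.2*|2| = 0.4 and 0.2*|1| = 0.2 -> 1/0.6
  ds <- mk_dataset(case_rows = rbind(A = c(2, 2, 2)),
                   ctrl_rows = rbind(A = c(1, 1, 1)))
  expect_equal(signal_to_noise(ds)$score, 1 / 0.6)

  # identical class distributions: s = 0
  ds <- mk_dataset(case_rows = rbind(A = c(1, 2, 3)),
                   ctrl_rows = rbind(A = c(1, 2, 3)))
  expect_equal(signal_to_noise(ds)$score, 0)
})

test_that("signal-to-noise sorts descending with symbol tie-break and needs n >= 2", {
  m <- rbind(B = c(1, 1, 5, 5), A = c(1, 1, 5, 5), C = c(5, 5, 1, 1))
  colnames(m) <- paste0("s", 1:4)
  ds <- expression_dataset(m, c("c", "c", "d", "d"), case = "d")
  r <- signal_to_noise(ds)
  expect_identical(r$gene, c("A", "B", "C"))  # A before B on equal scores
  expect_true(all(diff(r$score) <= 0))

  # a class with < 2 samples is rejected at construction already
  expect_error(expression_dataset(m[, c(1, 3, 4)], c("c", "d", "d"),
                                  case = "d"), ">= 2 samples")
})

test_that("enrichment score reproduces hand-walked profiles", {
  r <- mk_ranked(c(3, 2, 1, 1))
  # single member at rank 1
  sc <- enrichment_score(r, r$gene[1])
  expect_equal(sc$running, c(1, 2/3, 1/3, 0))
  expect_equal(sc$ES, 1.0)
  expect_identical(sc$leading_edge, r$gene[1])
  # members at ranks 2 and 4
  sc <- enrichment_score(r, r$gene[c(2, 4)])
  expect_equal(sc$running, c(-1/2, 1/6, -1/3, 0))
  expect_equal(sc$ES, -0.5)
  expect_identical(sc$leading_edge, r$gene[c(2, 4)])
  # full list has no misses and errors (no proper subset)
  expect_error(enrichment_score(r, r$gene), "entire list")
  # members absent from the list
  expect_error(enrichment_score(r, "NOPE"), "no set member")
})

test_that("all-zero hit scores fall back to uniform hit weights", {
  r <- mk_ranked(c(2, 0, 0, -1))
  sc <- enrichment_score(r, r$gene[2:3])
  expect_equal(sc$running, c(-1/2, 0, 1/2, 0))
  expect_equal(sc$ES, 0.5)
})

test_that("ES matches the brute-force walk on random lists and is scale-invariant", {
  set.seed(11)
  for (rep in 1:40) {
    N <- sample(5:40, 1)
    scores <- sort(round(rnorm(N, 0, 2), 2), decreasing = TRUE)
    r <- mk_ranked(scores)
    n_h <- sample(seq_len(N - 1), 1)
    members <- sample(r$gene, n_h)
    sc <- enrichment_score(r, members)
    is_hit <- r$gene %in% members
    expect_equal(sc$ES, brute_es(scores, is_hit), tolerance = 1e-12)
    expect_true(abs(sc$ES) <= 1)
    expect_lt(abs(sc$running[N]), 1e-9)
    # positive rescaling leaves ES unchanged at weight 1
    r2 <- mk_ranked(scores * 7.3)
    expect_equal(enrichment_score(r2, members)$ES, sc$ES, tolerance = 1e-12)
  }
})

test_that("internal fast ES path agrees with the full walk", {
  set.seed(12)
  for (rep in 1:60) {
    N <- sample(6:60, 1)
    scores <- sort(rnorm(N), decreasing = TRUE)
    r <- mk_ranked(scores)
    pos <- sort(sample(N, sample(1:(N - 1), 1)))
    full <- enrichment_score(r, r$gene[pos])$ES
    fast <- pathconcord:::.es_stat(pos, abs(scores[pos]), N)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("ES agrees with fgsea's statistic on a fixed ranked list", {
  set.seed(13)
  scores <- sort(rnorm(50), decreasing = TRUE)
  names(scores) <- sprintf("G%03d", 1:50)
  r <- mk_ranked(unname(scores), names(scores))
  for (n_h in c(3, 10, 25)) {
    pos <- sort(sample(50, n_h))
    ours <- enrichment_score(r, r$gene[pos])$ES
    ref <- fgsea::calcGseaStat(scores, pos, gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("permutation null is deterministic, bounded, and matches a brute resampler", {
  r <- mk_ranked(sort(rnorm(20, sd = 1.5), decreasing = TRUE))
  p <- gsea_params(n_perm = 200, seed = 42)
  null1 <- permutation_null(r, 5, p)
  null2 <- permutation_null(r, 5, p)
  expect_identical(null1, null2)
  expect_true(all(abs(null1) <= 1))

  # independent brute resampler at large n_perm: mean null ES near the
  # brute mean over the same distribution
  set.seed(99)
  brute <- replicate(20000, {
    is_hit <- rep(FALSE, 20)
    is_hit[sample(20, 5)] <- TRUE
    brute_es(r$score, is_hit)
  })
  big <- permutation_null(r, 5, gsea_params(n_perm = 20000, seed = 7))
  expect_lt(abs(mean(big) - mean(brute)), 4 * sd(brute) / sqrt(20000) * 2)
})

test_that("NES and nominal p follow the stated normalization rule", {
  # toy: null positives (0.2, 0.4), ES = 0.4 -> NES = 4/3, p = 2/3
  out <- normalize_and_test(0.4, c(0.2, 0.4, -0.3))
  expect_equal(out$NES, 0.4 / 0.3)
  expect_equal(out$p_nominal, 2 / 3)
  # ES equal to the mean of positive nulls -> NES = 1
  out <- normalize_and_test(0.3, c(0.2, 0.4, -0.5))
  expect_equal(out$NES, 1.0)
  # ES above every null -> guarded minimum p = 1/(n_pos + 1)
  out <- normalize_and_test(0.9, c(0.2, 0.4, -0.5))
  expect_equal(out$p_nominal, 1 / 3)
  # no same-signed null values -> not testable
  out <- normalize_and_test(-0.5, c(0.2, 0.4))
  expect_false(out$testable)
  expect_true(is.na(out$NES))
})

test_that("FDR q ratio matches an independent computation and clips to [0, 1]", {
  # brute ratio oracle on 5 observed NES and a pooled null
  obs <- c(2.1, 1.4, -1.1, -2.4, 0.6)
  pool <- c(rnorm(150, 0, 0.9), rnorm(100, 0, 1.1) * -1)
  set.seed(3); pool <- sample(pool)
  q <- pathconcord:::.fdr_q(obs, pool)
  for (i in seq_along(obs)) {
    nes <- obs[i]
    if (nes >= 0) {
      num <- mean(pool[pool >= 0] >= nes)
      den <- mean(obs[obs >= 0] >= nes)
    } else {
      num <- mean(pool[pool < 0] <= nes)
      den <- mean(obs[obs < 0] <= nes)
    }
    expect_equal(q[i], min(1, num / den), tolerance = 1e-12)
  }
  expect_true(all(q >= 0 & q <= 1))
  # no null value as extreme as the single observed set -> q = 0
  expect_equal(pathconcord:::.fdr_q(2.5, c(0.5, 1.0, -0.7)), 0)
})

test_that("run_gsea applies size filters, sorts by NES, and is deterministic", {
  sim <- simulate_dataset(simulation_design(n_genes = 500, n_sets = 8,
                                            set_size = 20, n_up = 2,
                                            n_down = 2, seed = 21))
  extra <- unclass(sim$sets)
  extra$TINY <- extra[[1]][1:5]
  extra$BIG <- sprintf("g%04d", 1:500)
  sets2 <- gene_sets(extra)
  fit <- gsea(sim$dataset, sets2, gsea_params(n_perm = 100, seed = 5))
  tab <- fit$table
  expect_identical(tab$status[tab$set == "TINY"], "too_small")
  expect_identical(tab$status[tab$set == "BIG"], "too_large")
  expect_true(all(is.na(tab$q_fdr[tab$status != "tested"])))
  tested <- tab[tab$status == "tested", ]
  expect_false(is.unsorted(rev(tested$NES)))
  expect_true(all(tested$ES >= -1 & tested$ES <= 1))
  # leading edge is a subset of the set's detectable members
  for (i in seq_len(nrow(tested))) {
    le <- strsplit(tested$leading_edge[i], ",")[[1]]
    expect_true(all(le %in% fit$members[[tested$set[i]]]))
    expect_lte(length(le), tested$size[i])
  }
  fit2 <- gsea(sim$dataset, sets2, gsea_params(n_perm = 100, seed = 5))
  expect_identical(fit$table, fit2$table)
})

test_that("planted upregulated pathways receive positive NES at delta = 2", {
  sim <- simulate_dataset(simulation_design(seed = 31))
  fit <- gsea(sim$dataset, sim$sets, gsea_params(n_perm = 100, seed = 32))
  tab <- fit$table
  expect_true(all(tab$NES[tab$set %in% sim$truth$up] > 0))
  expect_true(all(tab$NES[tab$set %in% sim$truth$down] < 0))
})
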