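test_that("predictive values match hand enumeration on the 10-pathway toy", {
  # Up1 = {P1,P2,P5}, Up2 = {P1,P2,P3,P4}; Down1 = {P6,P7}, Down2 = {P6,P8}
  s1 <- c("up", "up", "null", "null", "up", "down", "down", "null", "null", "null")
  s2 <- c("up", "up", "up", "up", "null", "down", "null", "down", "null", "null")
  p1 <- mk_profile(s1, "m1"); p2 <- mk_profile(s2, "m2")
  pv <- predictive_values(p1, p2)
  expect_equal(pv$PPV, 2 / 4)
  expect_equal(pv$NPV, 1 / 2)
  expect_equal(pv$mean_pv, 0.5)

  # contingency table of the same toy, by hand
  tab <- contingency_table(p1, p2)
  expect_identical(sum(tab), 10L)
  expect_identical(tab["up", "up"], 2L)
  expect_identical(tab["up", "null"], 1L)
  expect_identical(tab["down", "down"], 1L)
  expect_identical(tab["down", "null"], 1L)
  expect_identical(tab["null", "up"], 2L)
  expect_identical(tab["null", "down"], 1L)
  expect_identical(tab["null", "null"], 2L)
})

test_that("self-comparison gives perfect prediction; disjoint gives zero", {
  p <- mk_profile(rep(c("up", "down", "null"), c(3, 3, 4)), "m")
  pv <- predictive_values(p, p)
  expect_equal(pv$PPV, 1); expect_equal(pv$NPV, 1); expect_equal(pv$mean_pv, 1)
  q <- mk_profile(rep(c("null", "up", "down"), c(6, 2, 2)), "q")
  pv <- predictive_values(p, q)
  expect_equal(pv$PPV, 0); expect_equal(pv$NPV, 0)
})

test_that("zero denominators leave predictive values undefined, not zero", {
  p1 <- mk_profile(rep(c("up", "null"), c(2, 8)), "a")
  p2 <- mk_profile(rep("null", 10), "b")
  pv <- predictive_values(p1, p2)
  expect_true(is.na(pv$PPV) && is.na(pv$NPV) && is.na(pv$mean_pv))
  p3 <- mk_profile(rep(c("up", "null"), c(1, 9)), "c")
  pv <- predictive_values(p1, p3)
  expect_false(is.na(pv$PPV))
  expect_true(is.na(pv$NPV))
  expect_equal(pv$mean_pv, pv$PPV)
})

test_that("chance expectation is the caller's base rate of calls", {
  p <- mk_profile(rep(c("up", "null"), c(10, 90)), "m")
  ch <- chance_expectation(p)
  expect_equal(ch$E_PPV, 0.10)  # 10% up -> expected PPV 10%
  expect_equal(ch$E_NPV, 0)
})

test_that("shuffled profiles achieve the chance-expected PPV on average", {
  set.seed(77)
  s1 <- sample(rep(c("up", "down", "null"), c(20, 15, 65)))
  s2_base <- rep(c("up", "down", "null"), c(25, 10, 65))
  p1 <- mk_profile(s1, "a")
  ch <- chance_expectation(p1)
  sim <- replicate(4000, {
    pv <- predictive_values(p1, mk_profile(sample(s2_base), "b"))
    c(pv$PPV, pv$NPV)
  })
  se_ppv <- sd(sim[1, ]) / sqrt(ncol(sim))
  se_npv <- sd(sim[2, ]) / sqrt(ncol(sim))
  expect_lt(abs(mean(sim[1, ]) - ch$E_PPV), 3 * se_ppv)
  expect_lt(abs(mean(sim[2, ]) - ch$E_NPV), 3 * se_npv)
})

test_that("delta over chance is reported in percentage points", {
  pv <- list(PPV = 0.61, NPV = 0.61)
  ch <- list(E_PPV = 0.26, E_NPV = 0.26)
  expect_equal(delta_over_chance(pv, ch), 35)
  expect_equal(delta_over_chance(list(PPV = 0.3, NPV = 0.2),
                                 list(E_PPV = 0.3, E_NPV = 0.2)), 0)
  expect_equal(delta_over_chance(list(PPV = 0.5, NPV = NA_real_),
                                 list(E_PPV = 0.2, E_NPV = 0.1)), 30)
})

test_that("chi-squared matches the textbook formula and handles margins", {
  expect_equal(chi_squared_test(diag(c(10, 10, 10))),
               list(stat = 60, df = 4L,
                    p = stats::pchisq(60, 4, lower.tail = FALSE)))
  # proportional rows -> independence, stat 0, p 1
  tab <- outer(c(1, 2, 3), c(4, 5, 6))
  out <- chi_squared_test(tab)
  expect_equal(out$stat, 0); expect_equal(out$p, 1)
  # zero-margin row dropped with df adjusted
  tab <- rbind(c(5, 1, 2), c(0, 0, 0), c(1, 6, 3))
  out <- suppressMessages(chi_squared_test(tab))
  expect_identical(out$df, 2L)
  expect_equal(out$stat, brute_chi2(tab[c(1, 3), ]), tolerance = 1e-12)
  # single occupied cell is degenerate
  tab <- matrix(0, 3, 3); tab[2, 2] <- 12
  expect_warning(out <- chi_squared_test(tab), "degenerate")
  expect_equal(out$p, 1)
})

test_that("chi-squared agrees with stats::chisq.test on random full tables", {
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(sample(1:30, 9, replace = TRUE), 3, 3)
    ours <- chi_squared_test(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("pair comparison is direction-averaged and order-invariant", {
  set.seed(8)
  p1 <- mk_profile(sample(rep(c("up", "down", "null"), c(5, 4, 11))), "a")
  p2 <- mk_profile(sample(rep(c("up", "down", "null"), c(6, 3, 11))), "b")
  ab <- compare_pair(p1, p2)
  ba <- compare_pair(p2, p1)
  expect_equal(ab$mean_pv, ba$mean_pv)
  expect_equal(ab$delta_points, ba$delta_points)
  expect_equal(ab$chi2_stat, ba$chi2_stat)
  expect_equal(ab$PPV12, ba$PPV21)
  # the direction-averaged mean is the mean of the four defined values
  expect_equal(ab$mean_pv,
               mean(c(ab$PPV12, ab$NPV12, ab$PPV21, ab$NPV21), na.rm = TRUE))
})

test_that("compare_models enumerates pairs and species groups correctly", {
  set.seed(9)
  profs <- lapply(1:6, function(i)
    mk_profile(sample(rep(c("up", "down", "null"), c(5, 5, 10))),
               paste0("d", i)))
  names(profs) <- paste0("d", 1:6)
  species <- c("human", "human", "human", "mouse", "mouse", "mouse")
  cm <- compare_models(profs, species)
  expect_identical(nrow(cm$pairs), 15L)  # C(6,2)
  expect_identical(as.vector(table(cm$pairs$group)[c("hh", "hm", "mm")]),
                   c(3L, 9L, 3L))
  expect_true(isSymmetric(cm$mean_pv_matrix))
  expect_equal(unname(diag(cm$mean_pv_matrix)), rep(1, 6))
  # per-dataset significant-partner counts tally the pair table
  for (id in names(profs)) {
    inv <- cm$pairs$model1 == id | cm$pairs$model2 == id
    expect_identical(cm$n_significant[[id]],
                     sum(cm$pairs$significant[inv]))
  }
})

test_that("group-mean concordance rises with planted overlap (8h + 9m scale)", {
  # combinatorics of the full cohort: 8 human + 9 mouse
  expect_identical(choose(8, 2) + choose(9, 2) + 8 * 9, 136)
  profs <- c(lapply(1:3, function(i)
    mk_profile(rep(c("up", "down", "null"), c(4, 4, 12)), paste0("h", i))),
    lapply(1:3, function(i)
      mk_profile(rep(c("null", "up", "down"), c(12, 4, 4)), paste0("m", i))))
  names(profs) <- c(paste0("h", 1:3), paste0("m", 1:3))
  cm <- compare_models(profs, rep(c("human", "mouse"), each = 3))
  g <- cm$groups
  expect_equal(g$mean_pv[g$group == "hh"], 1)
  expect_equal(g$mean_pv[g$group == "mm"], 1)
  expect_equal(g$mean_pv[g$group == "hm"], 0)
})

test_that("shared regulation masks non-significant cells and finds shared sign", {
  p1 <- mk_profile(c("up", "up", "down", "null"), "a",
                   nes = c(2, 1.5, -2, 0.3), q = c(0.01, 0.2, 0.01, 0.7))
  p2 <- mk_profile(c("up", "down", "down", "null"), "b",
                   nes = c(1.8, -1.4, -1.9, -0.2), q = c(0.05, 0.1, 0.2, 0.9))
  sh <- shared_regulation(list(a = p1, b = p2))
  expect_identical(dim(sh$nes_matrix), c(4L, 2L))
  expect_true(is.na(sh$nes_matrix["P004", "a"]))  # null cell blanked
  expect_equal(sh$nes_matrix["P001", "b"], 1.8)
  # P001 up in both -> shared; P002 up vs down -> not shared
  expect_identical(sh$shared$pathway, c("P001", "P003"))
  expect_identical(sh$shared$direction, c("up", "down"))
  expect_error(shared_regulation(list()), "empty subgroup")
})

test_that("core genes require membership in >= k_min up-called leading edges", {
  mk_fit_le <- function(le) structure(
    list(table = NULL, leading_edges = list(PW = le)), class = "gsea")
  fits <- list(d1 = mk_fit_le(c("CD14", "TLR4", "LBP")),
               d2 = mk_fit_le(c("CD14", "TLR4")),
               d3 = mk_fit_le(c("CD14", "TLR2")))
  profs <- lapply(c("d1", "d2", "d3"), function(i)
    mk_profile("up", i))
  profs[[1]]$pathway <- profs[[2]]$pathway <- profs[[3]]$pathway <- "PW"
  out <- consistent_core_genes(fits, profs, "PW", k_min = 2)
  expect_identical(out$gene, c("CD14", "TLR4"))
  expect_identical(out$n_leading_edges, c(3L, 2L))
  expect_identical(attr(out, "n_up_datasets"), 3L)
  # k_min above the up-called count warns and returns empty
  expect_warning(out <- consistent_core_genes(fits, profs, "PW", k_min = 4),
                 "fewer than k_min")
  expect_identical(nrow(out), 0L)
})
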