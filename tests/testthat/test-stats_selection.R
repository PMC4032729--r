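# Length grouping, deviation statistics, proportions and the selection index.

test_that("buildPartition produces half-open intervals with closed top edge", {
  p <- buildPartition(100, 10)
  expect_equal(p@q, 10)
  iv <- partitionIntervals(p)
  expect_equal(iv$lower[3], 20)
  expect_equal(iv$upper[3], 30)
  # boundary lengths fall in the upper interval (half-open rule)
  expect_identical(partitionIndex(p, 10), 2L)
  expect_identical(partitionIndex(p, 9.999), 1L)
  expect_identical(partitionIndex(p, 100), 10L)  # closed at lmax
  expect_identical(partitionIndex(p, 101), NA_integer_)
  expect_error(buildPartition(-1, 10), "lmax")
  expect_error(buildPartition(100, 0), "n")
})

test_that("assignGroups bins every leaf once and excludes singleton groups", {
  leaves <- data.frame(leaf_id = c("a", "b", "c"), l_o = c(5, 7, 15))
  g <- assignGroups(leaves, buildPartition(20, 2))
  tab <- groupTable(g)
  expect_equal(tab$n_k, c(2L, 1L))
  expect_equal(tab$included, c(TRUE, FALSE))
  expect_equal(sum(tab$n_k), nrow(leaves))
  expect_setequal(groupedLeaves(g)$k, c(1L, 1L, 2L))

  out <- data.frame(leaf_id = "z", l_o = 25)
  expect_error(assignGroups(out, buildPartition(20, 2)), "z")
})

test_that("per-leaf errors are observed minus image values", {
  df <- data.frame(l_o = c(100, 50), h_o = c(5, 5),
                   l_d = c(90, 100), h_d = c(5, 5),
                   a_d = c(450, 500), a_mc = c(505, 240))
  e <- leafErrors(df)
  expect_equal(e$a_o, c(500, 250))
  expect_equal(e$e_l, c(10, -50))
  expect_equal(e$e_h, c(0, 0))
  expect_equal(e$e_a, c(50, -250))
  expect_equal(e$e_mc, c(-5, 10))
  expect_error(leafErrors(df[, -3]), "missing")
})

test_that("group deviations are arithmetic means; singletons are rejected", {
  df <- data.frame(k = c(1, 1, 2, 2), e_l = c(2, 4, -1, 1),
                   e_h = 0, e_a = 0)
  gd <- groupDeviations(df)
  expect_equal(gd$delta_l, c(3, 0))
  expect_equal(gd$n_k, c(2L, 2L))
  expect_error(groupDeviations(rbind(df, data.frame(k = 3, e_l = 1, e_h = 0, e_a = 0))),
               "fewer than 2")
})

test_that("cohort deviations pool within-group variance over sum(n_k - 1)", {
  df <- data.frame(k = c(1, 1, 2, 2), e_l = c(0, 2, 10, 14),
                   e_h = c(0, 2, 10, 14), e_a = 0)
  cd <- cohortDeviations(df)
  expect_equal(cd$delta_l_bar, 6.5)
  expect_equal(cd$sigma_dl, sqrt(5))  # ((0-1)^2+(2-1)^2+(10-12)^2+(14-12)^2)/2
  same <- data.frame(k = c(1, 1, 2, 2), e_l = 3, e_h = 3, e_a = 0)
  expect_equal(cohortDeviations(same)$sigma_dl, 0)
})

test_that("proportions follow the band-and-sign definition with complements", {
  # all groups pass, all areas underestimated: lambdas 1, complements 0
  allpass <- data.frame(k = c(1, 1, 2, 2), e_l = c(0, 1, 0.2, 0.8),
                        e_h = c(0, 1, 0.2, 0.8), e_a = 1, e_mc = 1)
  pp <- cohortProportions(allpass)
  expect_equal(pp$lambda_l, 1); expect_equal(pp$theta_l, 0)
  expect_equal(pp$lambda_h, 1); expect_equal(pp$theta_h, 0)
  expect_equal(pp$lambda_a, 1); expect_equal(pp$beta_a, 0)

  # a single included group always passes its own band
  single <- data.frame(k = 1, e_l = c(1, 3), e_h = c(1, 3),
                       e_a = c(1, -1), e_mc = c(1, 1))
  pp <- cohortProportions(single)
  expect_equal(pp$lambda_l, 1)
  expect_equal(pp$lambda_a, 0.5)  # one leaf overestimated
  expect_equal(pp$lambda_amc, 1)

  # two equal groups both passing bands; e_a splits them
  df <- data.frame(k = c(1, 1, 2, 2), e_l = c(0, 0.1, 0.1, 0),
                   e_h = c(0, 0.1, 0.1, 0),
                   e_a = c(1, 1, -1, -1), e_mc = c(-1, -1, 1, 1))
  pp <- cohortProportions(df)
  expect_equal(pp$lambda_a, 0.5)
  expect_equal(pp$beta_a, 0.5)
  expect_equal(pp$lambda_amc, 0.5)
})

test_that("proportions match an independent direct enumeration on seeded cases", {
  directProportions <- function(df) {
    ks <- sort(unique(df$k))
    dl <- sapply(ks, function(k) mean(df$e_l[df$k == k]))
    dh <- sapply(ks, function(k) mean(df$e_h[df$k == k]))
    nk <- sapply(ks, function(k) sum(df$k == k))
    sdl <- sqrt(sum(unlist(lapply(seq_along(ks), function(i)
      (df$e_l[df$k == ks[i]] - dl[i])^2))) / sum(nk - 1))
    sdh <- sqrt(sum(unlist(lapply(seq_along(ks), function(i)
      (df$e_h[df$k == ks[i]] - dh[i])^2))) / sum(nk - 1))
    passL <- abs(dl - mean(dl)) <= sdl
    passH <- abs(dh - mean(dh)) <= sdh
    N <- sum(nk)
    lamA <- 0
    for (i in seq_len(nrow(df))) {
      gi <- match(df$k[i], ks)
      if (passL[gi] && passH[gi] && df$e_a[i] >= 0) lamA <- lamA + 1
    }
    list(lambda_l = sum(nk[passL]) / N, lambda_a = lamA / N)
  }
  set.seed(101)
  for (rep in 1:10) {
    ng <- sample(3:6, 1)
    df <- do.call(rbind, lapply(seq_len(ng), function(k) {
      n <- sample(2:6, 1)
      data.frame(k = k, e_l = rnorm(n, sd = 3), e_h = rnorm(n, sd = 0.5),
                 e_a = rnorm(n, 5), e_mc = rnorm(n, 5))
    }))
    pp <- cohortProportions(df)
    dp <- directProportions(df)
    expect_equal(pp$lambda_l, dp$lambda_l)
    expect_equal(pp$lambda_a, dp$lambda_a)
    expect_equal(pp$lambda_l + pp$theta_l, 1)
    expect_equal(pp$lambda_h + pp$theta_h, 1)
    expect_equal(pp$lambda_a + pp$beta_a, 1)
    expect_equal(pp$lambda_amc + pp$beta_amc, 1)
  }
})

test_that("proportions and the index are invariant to replicating every group", {
  # group deviations sit well inside (or far outside) the +-sigma bands, so
  # the slight growth of the pooled SD under replication cannot flip a group
  df <- data.frame(k = c(1, 1, 2, 2, 3, 3),
                   e_l = c(-1, 1, -0.9, 1.1, -1.1, 0.9),
                   e_h = c(-0.5, 0.5, -0.4, 0.6, -0.6, 0.4),
                   e_a = c(1, -1, 2, 2, -3, 1), e_mc = c(1, 1, -2, 2, 3, -1))
  dup <- rbind(df, df, df)
  ppa <- cohortProportions(df)
  ppb <- cohortProportions(dup)
  for (f in c("lambda_l", "lambda_h", "lambda_a", "lambda_amc"))
    expect_equal(ppa[[f]], ppb[[f]])
  expect_equal(selectionIndex(ppa$lambda_a, ppa$beta_a),
               selectionIndex(ppb$lambda_a, ppb$beta_a))
})

test_that("selection index is beta/lambda with truncation convention", {
  expect_equal(truncate4(selectionIndex(0.6820, 0.3180)), 0.4662)
  expect_equal(truncate4(selectionIndex(0.7005, 0.2995)), 0.4275)
  expect_equal(selectionIndex(1, 0), 0)
  expect_equal(truncate4(selectionIndexMC(0.7197, 0.2803)), 0.3894)
  expect_equal(truncate4(selectionIndexMC(0.4917, 0.5083)), 1.0337)
  expect_error(selectionIndex(0, 1), "inadmissible")
  expect_error(selectionIndex(1.2, 0), "\\[0, 1\\]")
})

test_that("rmsd matches hand computations and validates input", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(1, 2), c(2, 3)), 1)
  expect_equal(rmsd(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_error(rmsd(1:3, 1:2), "equal length")
  expect_error(rmsd(numeric(0), numeric(0)), "nonempty")
})

test_that("selectOptimalST picks the smallest index, ties toward smaller x", {
  tab <- data.frame(x = c(68, 128, 192), IS = c(0.4662, 0.4275, 1.0072),
                    IS_mc = c(0.5016, 0.3894, 1.0337), admissible = TRUE)
  expect_equal(selectOptimalST(tab)$x_star, 128)
  one <- tab[1, ]
  expect_equal(selectOptimalST(one)$x_star, 68)
  tie <- data.frame(x = c(10, 5), IS = c(0.3, 0.3), IS_mc = 0.3,
                    admissible = TRUE)
  expect_equal(selectOptimalST(tie)$x_star, 5)
  bad <- data.frame(x = 1, IS = NA_real_, IS_mc = NA_real_, admissible = FALSE)
  expect_error(selectOptimalST(bad), "admissible")
})
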