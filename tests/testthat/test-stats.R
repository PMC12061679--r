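test_that("pearsonCor matches a brute-force moment computation", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(40); y <- 0.4 * x + rnorm(40)
    res <- pearsonCor(x, y)
    rBrute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res@r, rBrute, tolerance = 1e-12)
    expect_equal(res@p, cor.test(x, y)$p.value, tolerance = 1e-10)
  }
  res <- pearsonCor(1:10, 1:10)
  expect_equal(res@r, 1)
  expect_equal(res@strength, "very strong")
  expect_error(pearsonCor(1:10, rep(2, 10)), "zero variance")
  expect_error(pearsonCor(c(1, 2, NA), c(1, NA, 3)), "3 complete")
})

test_that("strength bands are exhaustive and mutually exclusive", {
  r <- seq(-1, 1, by = 0.001)
  s <- strengthCategory(r)
  expect_false(anyNA(s))
  expect_equal(unname(table(s)["negligible"]),
               sum(abs(r) <= 0.3))
  expect_equal(strengthCategory(c(0.3, 0.31, 0.5, 0.51, 0.7, 0.71, 0.9,
                                  0.91)),
               c("negligible", "weak", "weak", "moderate", "moderate",
                 "strong", "strong", "very strong"))
})

test_that("partial correlations match the residual construction", {
  set.seed(12)
  for (i in 1:5) {
    a <- rnorm(60); c <- 0.5 * a + rnorm(60); b <- 0.3 * c + rnorm(60)
    direct <- spectqct:::partialCor(cor(a, b), cor(a, c), cor(b, c))
    ra <- resid(lm(a ~ c)); rb <- resid(lm(b ~ c))
    expect_equal(direct, cor(ra, rb), tolerance = 1e-10)
  }
})

test_that("pooled cross-sectional correlations match the printed values", {
  tab <- studyTables()$visits
  r1 <- pearsonCor(tab$cv_total, tab$fsad_total)
  expect_equal(r1@n, 22L)
  expect_within(r1@r, 0.90, 0.05)
  expect_equal(r1@strength, "very strong")
  expect_within(pearsonCor(tab$cv_total, tab$emph_total)@r, 0.71, 0.05)
  expect_within(pearsonCor(tab$tc_max, tab$fsad_total)@r, 0.86, 0.05)
  expect_within(pearsonCor(tab$cv_total, tab$fev1pp)@r, -0.74, 0.05)
})

test_that("two-year delta correlations match the hand-derived oracle", {
  tab <- studyTables()$visits
  cm <- correlationMap(tab, "tc_max", c("fsad_total", "dhstar_slul"),
                       mode = "delta_v2_v0")
  # frozen oracle: Pearson r of the printed V2-V0 delta columns,
  # subjects 3..8 (computed once by hand from the study tables)
  expect_within(cm@r["tc_max", "fsad_total"], -0.6967, 0.001)
  expect_equal(cm@n["tc_max", "fsad_total"], 6)
  expect_within(cm@r["tc_max", "dhstar_slul"], -0.74, 0.05)
  expect_true(cm@highlighted["tc_max", "dhstar_slul"])
})

test_that("correlation maps pool rows, flag |r| > 0.7, and self-correlate", {
  tab <- studyTables()$visits
  cm <- correlationMap(tab, c("cv_total", "tc_max"),
                       c("fsad_total", "emph_total", "cv_total"))
  expect_equal(dim(cm@r), c(2L, 3L))
  expect_equal(cm@r["cv_total", "cv_total"], 1)
  expect_true(cm@highlighted["cv_total", "fsad_total"])
  expect_equal(cm@strength["tc_max", "emph_total"], "strong")
  # delta mode refuses tables without enough paired visits
  small <- tab[tab$subject %in% 1:2, ]
  expect_error(correlationMap(small, "cv_total", "fsad_total",
                              mode = "delta_v2_v0"), "fewer than 3")
})

test_that("parallel analysis retains true factors and rejects noise", {
  recovered <- vapply(1:20, function(s) {
    L <- matrix(0, 12, 3)
    L[1:4, 1] <- L[5:8, 2] <- L[9:12, 3] <- 0.8
    set.seed(s + 500)
    f <- matrix(rnorm(500 * 3), 500)
    x <- f %*% t(L) + matrix(rnorm(500 * 12), 500) %*%
      diag(sqrt(1 - rowSums(L^2)))
    parallelAnalysis(x, nReps = 100, seed = s)
  }, integer(1))
  expect_gte(mean(recovered == 3L), 0.95)
  set.seed(77)
  expect_equal(parallelAnalysis(matrix(rnorm(200 * 10), 200),
                                nReps = 200, seed = 4), 0L,
               ignore_attr = TRUE)
  expect_error(parallelAnalysis(matrix(rnorm(100), 20), nReps = 0),
               "nReps")
  xc <- cbind(rnorm(50), rep(1, 50))
  expect_error(parallelAnalysis(xc, nReps = 10), "constant")
})

test_that("Varimax EFA recovers disjoint variable blocks", {
  set.seed(4)
  f <- matrix(rnorm(400 * 2), 400)
  L <- matrix(0, 8, 2); L[1:4, 1] <- L[5:8, 2] <- 0.85
  x <- f %*% t(L) + matrix(rnorm(400 * 8), 400) %*%
    diag(sqrt(1 - rowSums(L^2)))
  colnames(x) <- paste0("v", 1:8)
  e <- efaVarimax(x, 2)
  blocks <- lapply(e@keyVariables, sort)
  expect_setequal(blocks[[1]], if ("v1" %in% blocks[[1]])
    paste0("v", 1:4) else paste0("v", 5:8))
  expect_setequal(unlist(blocks), paste0("v", 1:8))
  # single factor: rotation is the identity
  e1 <- efaVarimax(x, 1)
  expect_equal(abs(e1@rotation), diag(1))
  # orthogonal rotation preserves the communalities L L^T
  R <- cor(x); ev <- eigen(R, symmetric = TRUE)
  L0 <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  expect_equal(tcrossprod(e@loadings), tcrossprod(L0), tolerance = 1e-6,
               ignore_attr = TRUE)
  # column order / sign of the input does not change the solution
  e2 <- efaVarimax(x[, 8:1], 2)
  expect_equal(sort(abs(as.vector(e2@loadings))),
               sort(abs(as.vector(e@loadings))), tolerance = 1e-6)
  expect_error(efaVarimax(x, 9), "nFactors")
})

test_that("cross-lagged panel analysis flags degenerate panels", {
  x1 <- c(1, 2, 3, 4, 5, 7); y1 <- c(2, 1, 4, 3, 6, 5)
  r <- crossLaggedPanel(x1, x1, y1, y1)
  expect_true(any(grepl("undefined", r@flags)))
  expect_true(all(is.na(r@r[c("cross_xy", "cross_yx")])))
  expect_equal(unname(r@r["stab_x"]), 1)
  expect_error(crossLaggedPanel(1:3, 1:3, 1:3, 1:3), "4 complete")
})

test_that("the panel simulator calibrates power and type-I error", {
  power <- 0; falseDir <- 0
  for (i in 1:100) {
    d <- makePanelDataset(200, 0.5, seed = 1000 + i)
    r <- crossLaggedPanel(d$x1, d$x2, d$y1, d$y2)
    power <- power + (r@significant["cross_xy"] &&
                      !r@significant["cross_yx"])
    d0 <- makePanelDataset(200, 0, seed = 3000 + i)
    r0 <- crossLaggedPanel(d0$x1, d0$x2, d0$y1, d0$y2)
    falseDir <- falseDir + xor(r0@significant["cross_xy"],
                               r0@significant["cross_yx"])
  }
  expect_gte(power / 100, 0.8)
  expect_lte(falseDir / 100, 0.10)
})

test_that("with no cross-lagged effect neither lag is usually significant", {
  neither <- 0
  for (i in 1:100) {
    d0 <- makePanelDataset(5000, 0, seed = 7000 + i)
    r0 <- crossLaggedPanel(d0$x1, d0$x2, d0$y1, d0$y2)
    neither <- neither + (!r0@significant["cross_xy"] &&
                          !r0@significant["cross_yx"])
  }
  expect_gte(neither / 100, 0.9)
})
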