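test_that("community distances match hand computations", {
  counts <- rbind(a = c(2, 2, 0), b = c(1, 0, 1), c = c(2, 2, 0))
  dj <- as.matrix(community_distances(counts, "jaccard_binary"))
  db <- as.matrix(community_distances(counts, "bray_curtis"))
  expect_equal(dj["a", "c"], 0)
  expect_equal(db["a", "c"], 0)
  # shared type 1 only: Jaccard = 1 - 1/3
  expect_equal(dj["a", "b"], 2 / 3)
  # relative abundances (.5,.5,0) vs (.5,0,.5): Bray-Curtis = 0.5
  expect_equal(db["a", "b"], 0.5)
  disjoint <- rbind(x = c(3, 0), y = c(0, 5))
  expect_equal(as.numeric(community_distances(disjoint, "jaccard_binary")), 1)
  expect_equal(as.numeric(community_distances(disjoint, "bray_curtis")), 1)
  expect_error(community_distances(rbind(c(0, 0), c(1, 1))), "zero-sum")
  # bounds and symmetry on random tables
  set.seed(61)
  cts <- matrix(rpois(60, 3) + 1, 10, 6)
  for (metric in c("jaccard_binary", "bray_curtis")) {
    d <- as.matrix(community_distances(cts, metric))
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
  }
})

test_that("PCoA reconstructs genuinely Euclidean configurations", {
  set.seed(62)
  pts <- cbind(runif(4, 0, 10), runif(4, 0, 10)) # 4 planar points
  res <- pcoa(dist(pts))
  expect_equal(sum(res$eig > max(res$eig) * 1e-8), 2L)
  expect_equal(as.matrix(dist(res$points)), as.matrix(dist(pts)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # all-equal distances on 3 points: two equal eigenvalues
  d3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  r3 <- pcoa(d3)
  expect_equal(r3$eig[1], r3$eig[2], tolerance = 1e-10)
  # duplicated points collapse to zero coordinate distance
  pts2 <- rbind(pts, pts[1, ])
  r <- pcoa(dist(pts2))
  expect_lt(as.matrix(dist(r$points))[1, 5], 1e-8)
  expect_error(pcoa(dist(pts[1:2, ])), "at least 3")
})

test_that("one-way PERMANOVA on univariate Euclidean data equals classical ANOVA", {
  set.seed(63)
  for (i in 1:5) {
    y <- rnorm(15)
    g <- factor(rep(letters[1:3], each = 5))
    pm <- permanova(dist(y), data.frame(g = g), "g", permutations = 99, seed = 1)
    f_classic <- anova(lm(y ~ g))[["F value"]][1]
    expect_equal(pm$statistic, f_classic, tolerance = 1e-8)
  }
})

test_that("two-factor PERMANOVA returns a sequential per-term table", {
  set.seed(64)
  y <- matrix(rnorm(48), 12)
  design <- data.frame(f1 = rep(c("u", "v"), each = 6),
                       f2 = rep(c("x", "y", "z"), 4))
  pm <- permanova(dist(y), design, c("f1", "f2"), interaction = TRUE,
                  permutations = 199, seed = 2)
  expect_true(all(c("f1", "f2", "f1:f2", "Residual") %in% rownames(pm$table)))
  expect_equal(pm$table["f1", "Df"], 1)
  expect_true(all(na.omit(pm$table[["Pr(>F)"]]) > 0))
  # identical samples in identical groups leave no residual variation
  z <- rbind(matrix(1, 4, 2), matrix(2, 4, 2))
  expect_error(permanova(dist(z), data.frame(g = rep(c("a", "b"), each = 4)),
                         "g", permutations = 19), "undefined")
})

test_that("PERMANOVA and Mantel are bit-reproducible under a fixed seed", {
  set.seed(65)
  y <- matrix(rnorm(40), 10)
  d <- dist(y)
  design <- data.frame(g = rep(c("a", "b"), 5))
  p1 <- permanova(d, design, "g", permutations = 199, seed = 7)
  p2 <- permanova(d, design, "g", permutations = 199, seed = 7)
  expect_identical(p1$table, p2$table)
  d2 <- dist(matrix(rnorm(40), 10))
  m1 <- mantel_test(d, d2, permutations = 199, seed = 8)
  m2 <- mantel_test(d, d2, permutations = 199, seed = 8)
  expect_identical(m1$p_value, m2$p_value)
})

test_that("Mantel r is 1 for identical and affinely related matrices", {
  set.seed(66)
  d <- dist(matrix(rnorm(40), 10))
  expect_equal(mantel_test(d, d, permutations = 99, seed = 1)$statistic, 1)
  expect_equal(mantel_test(d, 2 * d + 1, permutations = 99, seed = 1)$statistic,
               1, tolerance = 1e-12)
  # independent matrices: small correlation
  d_ind <- dist(matrix(rnorm(40), 10))
  expect_lt(abs(mantel_test(d, d_ind, permutations = 99, seed = 1)$statistic), 0.6)
  expect_error(mantel_test(dist(rep(1, 10)), d), "constant")
})

test_that("PCNM vectors are orthogonal and separate two distant site pairs", {
  xy <- cbind(c(0, 0.2, 50, 50.2), c(0, 0, 0, 0))
  p <- pcnm_vectors(xy)
  v1 <- unname(p$vectors[, 1])
  expect_equal(sign(v1[1]), sign(v1[2]))
  expect_equal(sign(v1[3]), sign(v1[4]))
  expect_false(sign(v1[1]) == sign(v1[3]))
  # collinear equidistant points: first vector has a single sign change
  line <- cbind(1:10, rep(0, 10))
  pl <- pcnm_vectors(line)
  signs <- sign(pl$vectors[, 1])
  expect_equal(sum(diff(signs[signs != 0]) != 0), 1L)
  g <- crossprod(pl$vectors)
  expect_equal(g, diag(diag(g)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pcnm_vectors(matrix(0, 4, 2)), "identical")
})

test_that("vector fitting recovers exact and orthogonal relations", {
  set.seed(67)
  pts <- matrix(rnorm(40), 10)
  ord <- pcoa(dist(pts))
  v <- ord$points[, 1]
  fit <- envfit_vector(ord, v, permutations = 199, seed = 3, choices = 1:2)
  expect_equal(fit$statistic, 1, tolerance = 1e-8)
  expect_lt(fit$p_value, 0.05)
  # a variable residualized on the axes is orthogonal to them
  raw <- rnorm(10)
  resid_v <- residuals(lm(raw ~ ord$points[, 1:2]))
  fit0 <- envfit_vector(ord, resid_v, permutations = 199, seed = 3,
                        choices = 1:2)
  expect_lt(fit0$statistic, 1e-8)
  # noise degrades the fit monotonically
  r2 <- sapply(c(0, 2, 20), function(s) {
    envfit_vector(ord, v + rnorm(10, 0, s * sd(v)), permutations = 99,
                  seed = 4, choices = 1:2)$statistic
  })
  expect_true(all(diff(r2) < 0))
  expect_error(envfit_vector(ord, rep(1, 10)), "constant")
})
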