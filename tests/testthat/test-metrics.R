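test_that("psnr matches its closed form and caps at zero MSE", {
  a <- matrix(0.5, 10, 10)
  b <- a + 0.1                      # MSE = 0.01 against MAX = 1
  expect_equal(as.numeric(psnr(a, b, max_value = 1)), 20)
  same <- psnr(a, a)
  expect_equal(as.numeric(same), 99)
  expect_true(attr(same, "capped"))
  # joint rescaling of both matrices and MAX leaves the ratio unchanged
  expect_equal(as.numeric(psnr(3 * a, 3 * b, max_value = 3)),
               as.numeric(psnr(a, b, max_value = 1)))
  expect_error(psnr(a, matrix(1, 3, 3)), "shape")
})

test_that("psnr strictly decreases along a noise ladder", {
  set.seed(20)
  base <- rand_map(30, seed = 20)$matrix
  vals <- vapply(1:5, function(lev) {
    set.seed(100 + lev)
    noisy <- pmax(base + matrix(rnorm(length(base), sd = lev), nrow(base)), 0)
    as.numeric(psnr(base, noisy, max_value = max(base)))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ssim is 1 on identical input, symmetric, and matches Eq-style hand case", {
  x <- rand_map(15, seed = 21)$matrix
  y <- rand_map(15, seed = 22)$matrix
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))

  # global-window hand case: constants p = 0.5, q = 0.7, M = 0.7
  # variances and covariance vanish, so
  # SSIM = (2 p q + D1) / (p^2 + q^2 + D1), D1 = (0.01 M)^2
  p <- matrix(0.5, 2, 2); q <- matrix(0.7, 2, 2)
  d1 <- (0.01 * 0.7)^2
  hand <- (2 * 0.5 * 0.7 + d1) / (0.5^2 + 0.7^2 + d1)
  expect_equal(ssim(p, q, max_value = 0.7, window = 7), hand)
  expect_lt(hand, 1)
})

test_that("windowed ssim agrees with a naive sliding-window oracle", {
  set.seed(23)
  a <- matrix(runif(144, 0, 5), 12, 12)
  b <- pmax(a + matrix(rnorm(144, sd = 0.5), 12, 12), 0)
  w <- 5
  mx <- max(a, b)
  d1 <- (0.01 * mx)^2; d2 <- (0.03 * mx)^2
  naive <- mean(vapply(seq_len(12 - w + 1), function(i) {
    mean(vapply(seq_len(12 - w + 1), function(j) {
      schicsr:::ssim_window(a[i:(i + w - 1), j:(j + w - 1)],
                            b[i:(i + w - 1), j:(j + w - 1)], d1, d2)
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(ssim(a, b, window = w), naive, tolerance = 1e-12)
})

test_that("genomedisco reproduces hand-computed random-walk cases", {
  x <- rand_map(18, seed = 24)
  y <- rand_map(18, seed = 25)
  expect_equal(genomedisco(x, x), 1)
  expect_equal(genomedisco(x, y), genomedisco(y, x))

  # 2-bin hand case at t = 1: transitions are the swap and the identity;
  # |A - B| sums to 4, the nonzero-row denominator is 2, score = -1
  a <- contact_map(rbind(c(0, 1), c(1, 0)))
  b <- contact_map(rbind(c(1, 0), c(0, 1)))
  expect_equal(genomedisco(a, b, t_steps = 1), -1)
  expect_error(genomedisco(contact_map(matrix(0, 2, 2)),
                           contact_map(matrix(0, 2, 2))), "all-zero")
})

test_that("pearson matches the product-moment definition", {
  x <- c(1, 2, 3)
  expect_equal(pearson(x, 2 * x + 3), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(1, 3, 2)), 0.5)
  for (sd in 1:5) {
    set.seed(sd)
    u <- rnorm(50); v <- rnorm(50)
    expect_equal(pearson(u, v), pearson_bruteforce(u, v), tolerance = 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1:3, 1:4), "length")
})

test_that("superposition recovers rigid transforms", {
  s <- rand_structure(25, seed = 26)
  moved <- structure_3d(random_rigid(s$coords, seed = 27))
  sup <- superpose(s, moved)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(superpose(moved, s)$rmsd, sup$rmsd, tolerance = 1e-9)

  # pure translation: recovered exactly, zero RMSD
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  b <- a + 5
  supt <- superpose(a, b)
  expect_equal(supt$translation, c(-5, -5, -5))
  expect_lt(supt$rmsd, 1e-12)

  # mirror images superpose only when reflections are allowed
  mir <- s$coords %*% diag(c(-1, 1, 1))
  expect_lt(superpose(s$coords, mir)$rmsd, 1e-9)
  expect_gt(superpose(s$coords, mir, allow_reflection = FALSE)$rmsd, 0.1)
  expect_error(superpose(a, rbind(a, c(1, 1, 1))), "mismatch")
})

test_that("superposition agrees with an independent reference implementation", {
  library(bio3d)
  s <- rand_structure(20, seed = 28)
  moved <- structure_3d(random_rigid(s$coords, seed = 29) +
                          matrix(rnorm(60, sd = 0.3), 20, 3))
  ours <- superpose(s, moved, allow_reflection = FALSE)$rmsd
  fixed <- matrix(t(s$coords), nrow = 1)
  mobile <- matrix(t(moved$coords), nrow = 1)
  theirs <- bio3d::rmsd(fixed, mobile, fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("tm_score is 1 on identity, rigid-invariant, and exact at d0", {
  s <- rand_structure(30, seed = 30)
  expect_equal(tm_score(s, s), 1)
  moved <- structure_3d(random_rigid(s$coords, seed = 31))
  expect_gt(tm_score(s, moved), 1 - 1e-9)
  # symmetry under the equal-length convention
  s2 <- rand_structure(30, seed = 32)
  expect_equal(tm_score(s, s2), tm_score(s2, s), tolerance = 1e-8)

  # constructed pair with every deviation exactly d0 (= 0.5 for L <= 21):
  # plug into the formula: mean(1 / (1 + 1)) = 0.5
  a <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  b <- a + cbind(0, 0, c(0.5, 0.5, -0.5, -0.5))
  expect_equal(tm_score(a, b), 0.5, tolerance = 1e-9)
  expect_error(tm_score(a, rbind(a, c(0, 0, 1))), "mismatch")
})

test_that("insulation scores flag block boundaries and normalize to zero mean signal", {
  uni <- contact_map(matrix(3, 30, 30))
  sc <- insulation_scores(uni, window_bins = 4)
  expect_length(sc, 30 - 8)
  expect_true(all(abs(sc) < 1e-9))

  # two-block map: the minimum insulation sits at the block boundary
  m <- matrix(0.05, 40, 40)
  m[1:20, 1:20] <- 1
  m[21:40, 21:40] <- 1
  blocky <- contact_map(m)
  w <- 5
  sc2 <- insulation_scores(blocky, window_bins = w)
  centers <- w:(40 - w - 1)        # 0-based bin of each score
  expect_equal(centers[which.min(sc2)], 19)   # boundary between bins 19|20
  expect_error(insulation_scores(contact_map(matrix(1, 6, 6)), 3), "too small")
})

test_that("insulation L2 is a symmetric pseudometric on maps", {
  a <- rand_map(30, seed = 33)
  b <- rand_map(30, seed = 34)
  cc <- rand_map(30, seed = 35)
  expect_equal(insulation_l2(a, a), 0)
  expect_equal(insulation_l2(a, b), insulation_l2(b, a))
  expect_lte(insulation_l2(a, cc),
             insulation_l2(a, b) + insulation_l2(b, cc) + 1e-12)
  expect_error(insulation_l2(a, rand_map(20, seed = 1)), "mismatch")
})

test_that("evaluate_maps bundles metrics with their conventions", {
  a <- rand_map(30, seed = 36)
  rep <- evaluate_maps(a, a)
  expect_equal(rep$ssim, 1)
  expect_equal(rep$genomedisco, 1)
  expect_equal(rep$insulation_l2, 0)
  expect_equal(rep$psnr_db, 99)
  expect_equal(rep$disco_t, 3)
})
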