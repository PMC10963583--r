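test_that("random rotations are orthogonal, repeatable and sign-fixed", {
  for (d in c(2, 4, 6)) {
    q <- random_rotation(d, 11)
    expect_lt(max(abs(q %*% t(q) - diag(d))), 1e-10)
    expect_lt(abs(abs(det(q)) - 1), 1e-10)
  }
  expect_identical(random_rotation(2, 5), random_rotation(2, 5))
  expect_false(identical(random_rotation(2, 5), random_rotation(2, 6)))
})

test_that("energy distance is zero for identical samples and positive otherwise", {
  set.seed(1)
  x <- matrix(rnorm(200), 100, 2)
  expect_equal(energy_distance(x, x), 0, tolerance = 1e-12)
  y <- x + 2
  expect_gt(energy_distance(x, y), 0.5)
})

test_that("MBCn is the identity when model equals reference", {
  set.seed(4)
  x <- matrix(rnorm(300), 100, 3)
  out <- mbcn_correct(x, x, x, qdm_marginals = x)
  expect_equal(unclass(out)[seq_along(x)], as.numeric(x), tolerance = 1e-9)
})

test_that("MBCn output marginals equal the QDM marginals per group (multiset)", {
  set.seed(9)
  n <- 480
  keys <- rep(sprintf("g%d", 1:8), each = n / 8)
  ref <- matrix(rnorm(2 * n), n, 2)
  mh <- matrix(rnorm(2 * n, 1, 2), n, 2)
  mp <- matrix(rnorm(2 * n, 2, 2), n, 2)
  qm <- matrix(runif(2 * n), n, 2)   # arbitrary marginals to be reordered
  out <- mbcn_correct(ref, mh, mp, qm,
                      groups = list(ref = keys, hist = keys, proj = keys))
  for (k in unique(keys)) {
    i <- keys == k
    for (j in 1:2) {
      expect_identical(sort(out[i, j]), sort(qm[i, j]))
    }
  }
})

test_that("MBCn recovers the reference dependence on a Gaussian toy", {
  set.seed(2)
  n <- 2000
  z <- matrix(rnorm(2 * n), n, 2)
  ref <- cbind(z[, 1], 0.8 * z[, 1] + sqrt(1 - 0.8^2) * z[, 2])  # corr 0.8
  mh <- matrix(rnorm(2 * n), n, 2)                                # corr 0
  mp <- matrix(rnorm(2 * n), n, 2)
  qm_p <- cbind(as.numeric(qdm_correct(ref[, 1], mh[, 1], mp[, 1], kind = "additive")),
                as.numeric(qdm_correct(ref[, 2], mh[, 2], mp[, 2], kind = "additive")))
  qm_h <- cbind(as.numeric(qdm_correct(ref[, 1], mh[, 1], mh[, 1], kind = "additive")),
                as.numeric(qdm_correct(ref[, 2], mh[, 2], mh[, 2], kind = "additive")))
  out <- mbcn_correct(ref, mh, mp, qm_p, qdm_marginals_hist = qm_h)
  expect_lt(abs(cor(attr(out, "historical"))[1, 2] - 0.8), 0.1)
  expect_lt(abs(cor(out[, 1], out[, 2]) - 0.8), 0.15)
  expect_true(attr(out, "converged"))
})

test_that("misaligned inputs are rejected", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(mbcn_correct(x, x, x, qdm_marginals = x[1:10, ]), "align")
  expect_error(mbcn_correct(x, x[, 1, drop = FALSE], x, qdm_marginals = x),
               "columns")
})
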