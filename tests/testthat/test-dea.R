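test_that("envelopment LP reproduces hand-solvable frontier geometry", {
  # a DMU alone spans its own frontier
  p1 <- dea_problem(matrix(2), matrix(c(3, 4), 1), dmu_ids = "solo")
  s1 <- dea_score(p1, 1)
  expect_equal(s1$delta, 1, tolerance = 1e-9)
  expect_equal(unname(s1$lambda), 1, tolerance = 1e-8)

  # C reaches the frontier at the A-B midpoint: delta = 1.5
  toy <- toy_dea()
  sC <- dea_score(toy, 3)
  expect_equal(sC$delta, 1.5, tolerance = 1e-8)
  expect_equal(unname(sC$lambda[c("A", "B")]), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(dea_score_all(toy)$efficiency, c(1, 1, 2 / 3), tolerance = 1e-8)

  # output orientation ignores input slack: D uses twice the input of A
  # for A's outputs and still gets delta = 1
  p4 <- dea_problem(matrix(c(1, 1, 1, 2), 4),
                    rbind(c(2, 1), c(1, 2), c(1, 1), c(2, 1)))
  expect_equal(dea_score(p4, 4)$delta, 1, tolerance = 1e-8)

  # identical DMUs all sit on the frontier
  p5 <- dea_problem(matrix(rep(3, 6)), matrix(rep(c(5, 7), each = 6), 6))
  expect_true(all(abs(dea_score_all(p5)$delta - 1) < 1e-9))
})

test_that("LP solution agrees with the simplex-grid brute force on small instances", {
  cases <- expand.grid(n = 2:4, seed = 1:3)
  for (k in seq_len(nrow(cases))) {
    p <- rand_dea(cases$n[k], seed = 100 + k)
    i <- 1 + (k %% cases$n[k])
    lp <- dea_score(p, i)$delta
    grid <- dea_grid_search(p, i, resolution = 200)
    expect_lt(abs(lp - grid), 0.01)
    expect_gte(lp + 1e-9, grid) # grid is a restricted search: never above the LP
  }
})

test_that("envelopment LP agrees with a general-purpose LP solver", {
  for (k in 1:6) {
    n <- 2 + k
    p <- rand_dea(n, seed = 550 + k)
    for (i in c(1, n)) {
      # same program posed to pracma's simplex: variables (delta, lambda)
      cc <- c(-1, rep(0, n))
      A <- rbind(c(0, p$X[, 1]), cbind(p$Y[i, ], -t(p$Y)))
      b <- c(p$X[i, 1], 0, 0)
      ref <- tryCatch(
        -pracma::linprog(cc, A = A, b = b, Aeq = matrix(c(0, rep(1, n)), 1),
                         beq = 1, maxiter = 500)$fval,
        error = function(e) NA_real_)
      if (is.finite(ref)) {
        expect_equal(dea_score(p, i)$delta, ref, tolerance = 1e-6)
      }
    }
  }
})

test_that("DEA invariants: bounds, units invariance, monotonicity, VRS vs CRS", {
  for (s in 1:20) {
    p <- rand_dea(8, seed = 200 + s)
    sc <- dea_score_all(p)
    expect_true(all(sc$delta >= 1))
    expect_true(all(sc$efficiency > 0 & sc$efficiency <= 1))
    expect_lt(abs(min(sc$delta) - 1), 1e-6)
    expect_equal(sc$efficiency * sc$delta, rep(1, 8), tolerance = 1e-10)

    # rescaling one output column leaves every distance unchanged
    Y2 <- p$Y
    Y2[, 1 + s %% 2] <- Y2[, 1 + s %% 2] * 37.5
    p2 <- dea_problem(p$X, Y2)
    expect_equal(dea_score_all(p2)$delta, sc$delta, tolerance = 1e-8)

    # the percentage scale is immaterial: 0-1 instead of 0-100
    p3 <- dea_problem(p$X, p$Y * 0.01)
    expect_equal(dea_score_all(p3)$delta, sc$delta, tolerance = 1e-8)

    # appending a DMU never decreases any existing distance
    set.seed(900 + s)
    p4 <- dea_problem(rbind(p$X, runif(1, 1, 10)),
                      rbind(p$Y, cbind(runif(1, 1, 10), runif(1, 1, 10))))
    expect_true(all(dea_score_all(p4)$delta[1:8] >= sc$delta - 1e-9))

    # VRS frontier envelops tighter than CRS
    pc <- dea_problem(p$X, p$Y, rts = "crs")
    expect_true(all(sc$delta <= dea_score_all(pc)$delta + 1e-8))
  }
})

test_that("deleting a DMU that is nobody's peer leaves all scores unchanged", {
  for (s in 1:5) {
    p <- rand_dea(10, seed = 300 + s)
    sc <- dea_score_all(p, lambda = TRUE)
    L <- attr(sc, "lambda")
    # a non-peer: zero weight in every solution (and off the frontier itself)
    unused <- which(colSums(L >= 1e-9) == 0 & sc$delta > 1 + 1e-6)
    if (!length(unused)) next
    drop <- unused[1]
    p2 <- dea_problem(p$X[-drop, , drop = FALSE], p$Y[-drop, , drop = FALSE])
    expect_equal(dea_score_all(p2)$delta, sc$delta[-drop], tolerance = 1e-8)
  }
})

test_that("problem validation rejects ill-posed inputs", {
  expect_error(dea_problem(matrix(c(1, 0), 2), matrix(c(1, 1), 2)), "positive")
  expect_error(dea_problem(matrix(c(1, 1), 2), rbind(c(1, 2), c(0, 0))),
               "all-zero outputs")
  expect_error(dea_problem(matrix(1), matrix(c(1, 2), 2)), "row per DMU")
  # one zero output is fine: that constraint is trivially satisfied
  p <- dea_problem(matrix(c(1, 1), 2), rbind(c(2, 0), c(1, 1)))
  expect_true(all(dea_score_all(p)$delta >= 1))
})
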