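# ML pairwise evolutionary distances under the WAG / Poisson models.

test_that("identical sequences give distance ~ 0", {
  s <- paste(sample(mesoniv:::.AA20, 200, TRUE), collapse = "")
  expect_lt(wag_ml_distance(s, s, model = "WAG"), 1e-6)
  expect_lt(wag_ml_distance(s, s, model = "Poisson"), 1e-6)
})

test_that("Poisson-mode ML equals the closed form across p", {
  # closed form: d = -(19/20) ln(1 - (20/19) p)
  n <- 2000L
  for (p in c(0.01, 0.05, 0.1, 0.25, 0.5, 0.7, 0.9)) {
    k <- round(n * p)
    a <- strrep("A", n)
    b <- paste0(strrep("R", k), strrep("A", n - k))
    d <- wag_ml_distance(a, b, model = "Poisson")
    expect_lt(abs(d - (-(19 / 20) * log(1 - (20 / 19) * (k / n)))), 1e-6)
  }
})

test_that("distance is symmetric and monotone in mismatches", {
  set.seed(88)
  a <- paste(sample(mesoniv:::.AA20, 500, TRUE), collapse = "")
  b <- evolve_sequence(a, 0.2, "WAG-aa", seed = 2)
  expect_equal(wag_ml_distance(a, b), wag_ml_distance(b, a), tolerance = 1e-9)

  prev <- 0
  x <- strsplit(a, "")[[1]]
  for (k in c(10L, 40L, 120L)) {
    y <- x
    idx <- seq_len(k)
    y[idx] <- vapply(x[idx], function(r)
      sample(setdiff(mesoniv:::.AA20, r), 1), character(1))
    d <- wag_ml_distance(a, paste(y, collapse = ""))
    expect_gt(d, prev)
    prev <- d
  }
})

test_that("WAG estimates match phangorn's dist.ml", {
  skip_if_not_installed("phangorn")
  set.seed(99)
  a <- paste(sample(names(mesoniv:::.build_model("WAG")$pi), 800, TRUE,
                    prob = mesoniv:::.build_model("WAG")$pi), collapse = "")
  for (d_true in c(0.05, 0.4)) {
    b <- evolve_sequence(a, d_true, "WAG-aa", seed = round(100 * d_true))
    mine <- wag_ml_distance(a, b)
    pd <- phangorn::phyDat(rbind(a = strsplit(a, "")[[1]],
                                 b = strsplit(b, "")[[1]]), type = "AA")
    ref <- as.matrix(phangorn::dist.ml(pd, model = "WAG"))[1, 2]
    expect_equal(mine, ref, tolerance = 1e-4)
  }
})

test_that("too few comparable sites is a precision error", {
  expect_error(wag_ml_distance("MKLV", "MKLV"), "precision error")
})

test_that("unaligned inputs of unequal length are aligned internally", {
  set.seed(5)
  a <- paste(sample(mesoniv:::.AA20, 300, TRUE), collapse = "")
  b <- evolve_sequence(a, 0.1, "WAG-aa", seed = 1)
  b_del <- paste0(substr(b, 1, 100), substr(b, 111, 300))  # 10-aa deletion
  d_full <- wag_ml_distance(a, b)
  d_del <- wag_ml_distance(a, b_del)
  expect_lt(abs(d_del - d_full), 0.05)
})

test_that("transition matrices are stochastic and reversible", {
  for (model in c("WAG", "Poisson")) {
    P <- prob_matrix(0.3, model)
    expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-12)
    pi <- mesoniv:::.build_model(model)$pi
    # detailed balance: pi_a P_ab == pi_b P_ba
    expect_equal(sweep(P, 1, pi, "*"), t(sweep(P, 1, pi, "*")),
                 tolerance = 1e-12)
  }
})
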