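test_that("domain extraction recovers exact spans on the identity case", {
  sim <- canonical_sim()
  refset <- refset_of(sim)
  doms <- extract_domains(sim$truth$pp1ab, refset, taxon = "self")
  for (dn in rownames(sim$truth$domains)) {
    expect_equal(unname(doms$spans[dn, ]), unname(sim$truth$domains[dn, ]))
    expect_equal(doms$domains[[dn]], refset[[dn]])
  }
  expect_equal(doms$concat, paste(refset[c("3CLpro", "RdRp", "ZnHel1")],
                                  collapse = ""))
})

test_that("domain spans survive 5% substitution noise within 2 residues", {
  sim <- canonical_sim()
  refset <- refset_of(sim)
  noisy <- evolve_sequence(sim$truth$pp1ab, 0.052, "WAG-aa", seed = 8)
  # 5% observed substitutions roughly corresponds to d ~ 0.052
  doms <- extract_domains(noisy, refset, taxon = "noisy")
  for (dn in rownames(sim$truth$domains)) {
    expect_lte(max(abs(doms$spans[dn, ] - sim$truth$domains[dn, ])), 2L)
  }
})

test_that("a shuffled protein raises a domain-missing error", {
  sim <- canonical_sim()
  refset <- refset_of(sim)
  set.seed(4)
  shuffled <- paste(sample(strsplit(sim$truth$pp1ab, "")[[1]]), collapse = "")
  expect_error(extract_domains(shuffled, refset), "domain-missing")
})

test_that("cluster_species trivial thresholds and the pair example", {
  m <- matrix(c(0, 0.01, 0.5, 0.01, 0, 0.5, 0.5, 0.5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- cluster_species(m, t = 0.032)
  expect_equal(p$clusters, list(c("A", "B"), "C"))

  expect_length(cluster_species(m, t = Inf)$clusters, 1L)
  expect_length(cluster_species(m, t = 0)$clusters, 3L)
})

test_that("merging is monotone in the threshold (refinement property)", {
  set.seed(31)
  for (r in 1:10) {
    n <- sample(4:10, 1)
    d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    ts <- sort(runif(4))
    prev <- NULL
    for (t in ts) {
      memb <- cluster_species(d, t)$membership
      if (!is.null(prev)) {
        # every cluster at the smaller t is inside one cluster at larger t
        for (cl in split(names(prev), prev))
          expect_length(unique(memb[cl]), 1L)
      }
      prev <- memb
    }
    # single linkage: any pair with d <= t shares a cluster
    t <- ts[2]
    memb <- cluster_species(d, t)$membership
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (d[i, j] <= t) expect_equal(unname(memb[i]), unname(memb[j]))
  }
})

test_that("sliding windows: count, identity case, and a hand-computed profile", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AAAAAAAAAA",
           d = "AAAAAAAAAA")
  m <- matrix(0.5, 4, 4, dimnames = list(names(msa), names(msa)))
  diag(m) <- 0
  m["a", "b"] <- m["b", "a"] <- 0.01
  m["c", "d"] <- m["d", "c"] <- 0.01
  part <- cluster_species(m, 0.032)
  prof <- sliding_window_divergence(msa, part, w = 5, step = 2)
  expect_equal(nrow(prof), (10 - 5) %/% 2 + 1)
  expect_true(all(prof$within_mean == 0))
  expect_true(all(prof$between_mean == 0))

  # hand-built 3-sequence alignment with known mismatch positions
  msa2 <- c(x = "AAAAACCCCC", y = "AAAAACCCCD", z = "TTTAACCCCC")
  m2 <- matrix(0.5, 3, 3, dimnames = list(names(msa2), names(msa2)))
  diag(m2) <- 0
  m2["x", "y"] <- m2["y", "x"] <- 0.01
  p2 <- cluster_species(m2, 0.032)     # {x,y}, {z}
  prof2 <- sliding_window_divergence(msa2, p2, w = 5, step = 5)
  # window 1 (cols 1-5): x~y identical; z differs from both at 3 sites
  expect_equal(prof2$within_mean, c(0, 1 / 5))
  expect_equal(prof2$between_mean[1], mean(c(3 / 5, 3 / 5)))
  # window 2 (cols 6-10): x~y differ at 1 site; z equals x, differs y at 1
  expect_equal(prof2$between_mean[2], mean(c(0, 1 / 5)))
})

test_that("gap-only windows are missing, not zero", {
  msa <- c(a = "-----AAAAA", b = "-----AAAAA", c = "-----AAAAT")
  m <- matrix(0.5, 3, 3, dimnames = list(names(msa), names(msa)))
  diag(m) <- 0
  m["a", "b"] <- m["b", "a"] <- 0.0
  p <- cluster_species(m, 0.032)
  prof <- sliding_window_divergence(msa, p, w = 5, step = 5)
  expect_true(is.na(prof$within_mean[1]))
  expect_true(is.na(prof$between_mean[1]))
  expect_equal(prof$between_mean[2], mean(c(1 / 5, 1 / 5)))
})

test_that("simulated two-group set separates between from within everywhere", {
  set.seed(55)
  base <- paste(sample(mesoniv:::.AA20, 400, TRUE), collapse = "")
  anc2 <- evolve_sequence(base, 0.6, "WAG-aa", seed = 61)
  msa <- c(A1 = evolve_sequence(base, 0.005, "WAG-aa", 62),
           A2 = evolve_sequence(base, 0.005, "WAG-aa", 63),
           B1 = evolve_sequence(anc2, 0.005, "WAG-aa", 64),
           B2 = evolve_sequence(anc2, 0.005, "WAG-aa", 65))
  m <- distance_matrix(msa)
  part <- cluster_species(m, 0.032)
  expect_length(part$clusters, 2L)
  prof <- sliding_window_divergence(msa, part, w = 100, step = 25)
  expect_true(all(prof$between_mean > prof$within_mean))
})
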