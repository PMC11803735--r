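test_that("path fingerprints are deterministic and canonicalization-invariant", {
  f1 <- make_fingerprint("c1ccccc1O", "phenol")
  f2 <- make_fingerprint("c1ccccc1O", "phenol")
  expect_identical(unclass(f1), unclass(f2))
  f3 <- make_fingerprint("Oc1ccccc1", "phenol_alt")  # same molecule, other SMILES
  expect_identical(unclass(f1), unclass(f3))
  expect_equal(attr(f1, "params")$n_bits, 1024L)
  methane <- make_fingerprint("C")
  octane <- make_fingerprint("CCCCCCCC")
  expect_false(sum(methane) == sum(octane))
  expect_error(make_fingerprint("C1CC", "broken"), "broken")
})

test_that("tanimoto matches hand values and the set-based oracle", {
  a <- logical(10); a[c(1, 2, 3)] <- TRUE
  b <- logical(10); b[c(2, 3, 4)] <- TRUE
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1)
  d <- logical(10); d[8:10] <- TRUE
  expect_equal(tanimoto(a, d), 0)
  expect_equal(tanimoto(logical(10), logical(10)), 1)  # both-empty convention
  expect_error(tanimoto(a, logical(9)), "lengths differ")
  set.seed(8)
  for (i in 1:200) {
    x <- runif(64) < 0.3; y <- runif(64) < 0.3
    expect_identical(tanimoto(x, y), tanimoto_setwise(x, y))
    expect_identical(tanimoto(x, y), tanimoto(y, x))
    expect_true(tanimoto(x, y) >= 0 && tanimoto(x, y) <= 1)
    if (any(x) && tanimoto(x, y) == 1) expect_identical(x, y)
  }
})

test_that("tanimoto_matrix agrees with pairwise tanimoto", {
  fps <- gen_fingerprints(3, 3, n_bits = 128, seed = 9)
  s <- tanimoto_matrix(fps)
  for (i in 1:9) for (j in 1:9) {
    expect_equal(s[i, j], tanimoto(fps[[i]], fps[[j]]))
  }
})

test_that("threshold clustering has the contracted limiting behavior", {
  same <- gen_fingerprints(1, 6, within_sim = 1, seed = 1)
  expect_equal(cluster_compounds(same, 0.45)$k, 1L)
  # far-apart singleton prototypes: all pairwise similarities < 0.45
  apart <- gen_fingerprints(7, 1, proto_density = 0.05, seed = 2)
  a <- cluster_compounds(apart, 0.45)
  s <- a$similarity
  expect_true(max(s[upper.tri(s)]) < 0.45)
  expect_equal(a$k, 7L)
  expect_equal(unname(a$cluster), seq_len(7L))
  single <- cluster_compounds(apart[1], 0.45)
  expect_equal(single$k, 1L)
})

test_that("cluster labels are invariant to input order", {
  fps <- gen_fingerprints(4, 5, seed = 3)
  a <- cluster_compounds(fps, 0.45)
  set.seed(1)
  perm <- sample(length(fps))
  b <- cluster_compounds(fps[perm], 0.45)
  expect_identical(a$cluster[sort(names(a$cluster))],
                   b$cluster[sort(names(b$cluster))])
})

test_that("cluster count is monotone non-decreasing in the threshold", {
  fps <- gen_fingerprints(5, 4, within_sim = 0.7, seed = 4)
  ks <- vapply(seq(0.1, 0.9, by = 0.1), function(th) {
    cluster_compounds(fps, th)$k
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("representatives are intra-cluster medoids with stable ties", {
  fps <- gen_fingerprints(3, c(1, 4, 6), seed = 5)
  a <- cluster_compounds(fps, 0.45)
  reps <- pick_representatives(a)
  expect_equal(nrow(reps), a$k)
  # brute-force medoid check within each recovered cluster
  s <- a$similarity
  for (r in seq_len(nrow(reps))) {
    members <- sort(names(a$cluster)[a$cluster == reps$cluster[r]])
    if (length(members) == 1L) {
      expect_equal(reps$compound_id[r], members)
    } else {
      ms <- vapply(members, function(m) {
        mean(s[m, setdiff(members, m)])
      }, numeric(1))
      best <- members[ms == max(ms)][1]  # lexicographic among ties
      expect_equal(reps$compound_id[r], best)
    }
  }
})
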