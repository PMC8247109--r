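# Similarity layer: weighted edit distance, sequence similarity, semantic
# values and similarity, GIP kernels, integration, pair features.

test_that("edit_cost matches hand-derived values and basic contracts", {
  expect_identical(edit_cost("ACGT", "ACGT"), 0)
  expect_identical(edit_cost("ACGT", "ACGA"), 2)
  expect_identical(edit_cost("AA", ""), 2)
  expect_identical(edit_cost("", "AA"), 2)
  expect_identical(edit_cost("A", "G"), 2)
  # U and case folding: RNA and DNA spellings of the same molecule agree
  expect_identical(edit_cost("acgu", "ACGT"), 0)
  # symmetry on a few pairs
  for (p in list(c("ACGT", "AG"), c("A", "TTT"), c("GATTACA", "CAT"))) {
    expect_identical(edit_cost(p[1], p[2]), edit_cost(p[2], p[1]))
  }
})

test_that("edit_cost rejects non-alphabet characters, naming the position", {
  expect_error(edit_cost("ACNT", "ACGT"), "invalid character 'N' at position 3")
  expect_error(sequence_set(c(l1 = "ACGT", l2 = "AXA")),
               "'l2'.*invalid character 'X' at position 2")
})

test_that("edit_cost equals the exhaustive-recursion oracle on all short pairs", {
  strings <- all_strings(c("A", "C"), 6)
  mismatches <- 0L
  for (i in seq_along(strings)) {
    for (j in seq_len(i)) {
      got <- edit_cost(strings[i], strings[j])
      if (!identical(got, edit_oracle(strings[i], strings[j]))) {
        mismatches <- mismatches + 1L
      }
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("edit_cost satisfies the triangle inequality on random triples", {
  set.seed(11)
  for (rep in 1:40) {
    tri <- vapply(1:3, function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(0:8, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    ab <- edit_cost(tri[1], tri[2])
    bc <- edit_cost(tri[2], tri[3])
    ac <- edit_cost(tri[1], tri[3])
    expect_lte(ac, ab + bc)
  }
})

test_that("sequence_similarity reproduces the hand-computed entries", {
  s <- sequence_similarity(sequence_set(c(l1 = "ACGT", l2 = "ACGA",
                                          l3 = "A", l4 = "G")))
  expect_equal(s["l1", "l2"], 0.75, tolerance = 1e-12)
  expect_equal(s["l3", "l4"], 0, tolerance = 1e-12)
  expect_identical(unname(diag(unclass(s))), rep(1, 4))
  expect_true(all(unclass(s) >= 0 & unclass(s) <= 1))
  s2 <- sequence_similarity(sequence_set(c(l1 = "ACGT", l2 = "ACGT")))
  expect_identical(s2["l1", "l2"], 1)
})

test_that("semantic_values follows the decay-by-mu recursion", {
  onto <- disease_ontology(data.frame(parent = "p", child = "d"))
  expect_equal(semantic_values(onto, "d"), c(d = 1, p = 0.5))
  # isolated node
  onto_iso <- disease_ontology(nodes = "d")
  expect_equal(semantic_values(onto_iso, "d"), c(d = 1))
  # diamond r -> a -> d, r -> b -> d: both paths give r the same value
  onto_dia <- disease_ontology(data.frame(
    parent = c("r", "r", "a", "b"), child = c("a", "b", "d", "d")))
  prof <- semantic_values(onto_dia, "d")
  expect_equal(prof[["d"]], 1)
  expect_equal(prof[["a"]], 0.5)
  expect_equal(prof[["b"]], 0.5)
  expect_equal(prof[["r"]], 0.25)
  expect_error(semantic_values(onto_dia, "zzz"), "not a node")
})

test_that("semantic values on pure chains follow the closed form mu^depth", {
  for (depth in 1:5) {
    onto <- chain_ontology(depth)
    for (mu in c(0.3, 0.5, 0.8)) {
      prof <- semantic_values(onto, paste0("n", depth), mu = mu)
      for (k in 0:depth) {
        expect_equal(prof[[paste0("n", depth - k)]], mu^k, tolerance = 1e-12)
      }
    }
  }
})

test_that("semantic_similarity matches hand-enumerated profiles", {
  onto <- disease_ontology(data.frame(parent = "p", child = "d"))
  s <- semantic_similarity(onto, c("d", "p"))
  expect_equal(s["d", "p"], 0.6, tolerance = 1e-12)
  expect_identical(unname(diag(unclass(s))), c(1, 1))
  # two diseases under different roots share no ancestors
  onto2 <- disease_ontology(data.frame(parent = c("r1", "r2"),
                                       child = c("d1", "d2")))
  s2 <- semantic_similarity(onto2, c("d1", "d2"))
  expect_identical(s2["d1", "d2"], 0)
  # missing disease: singleton policy vs error policy
  expect_error(semantic_similarity(onto, c("d", "nope")), "not a node")
  s3 <- semantic_similarity(onto, c("d", "nope"), missing = "singleton")
  expect_identical(s3["d", "nope"], 0)
})

test_that("gip_kernel reproduces the hand-computed kernels and bandwidth", {
  A <- association_matrix(diag(2), disease_ids = c("d1", "d2"),
                          lncrna_ids = c("l1", "l2"))
  gkl <- gip_lncrna(A)
  expect_equal(attr(gkl, "lambda"), 1, tolerance = 1e-12)
  expect_equal(gkl["l1", "l2"], exp(-2), tolerance = 1e-12)
  gkd <- gip_disease(A)
  expect_equal(gkd["d1", "d2"], exp(-2), tolerance = 1e-12)
  # profiles (1,1,0) and (1,0,1): lambda = 1/2, entry exp(-1)
  p <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
  g <- gip_kernel(p)
  expect_equal(attr(g, "lambda"), 0.5, tolerance = 1e-12)
  expect_equal(g["a", "b"], exp(-1), tolerance = 1e-12)
  # identical profiles score exactly 1
  g2 <- gip_kernel(rbind(a = c(1, 0), b = c(1, 0)))
  expect_identical(g2["a", "b"], 1)
  # bandwidth self-consistency: lambda * mean squared norm == 1
  set.seed(3)
  for (rep in 1:10) {
    prof <- matrix(rbinom(60, 1, 0.4), nrow = 6)
    rownames(prof) <- paste0("p", 1:6)
    if (all(rowSums(prof) == 0)) next
    g3 <- gip_kernel(prof)
    expect_identical(attr(g3, "lambda") * attr(g3, "mean_sq_norm"), 1)
  }
  expect_error(gip_kernel(matrix(0, 2, 3)), "degenerate")
})

test_that("integrate_similarity is the element-wise mean with aligned ids", {
  seqs <- sequence_set(c(l1 = "ACGT", l2 = "ACGA"))
  L <- sequence_similarity(seqs)
  A <- association_matrix(diag(2), disease_ids = c("d1", "d2"),
                          lncrna_ids = c("l1", "l2"))
  G <- gip_lncrna(A)
  Ls <- integrate_similarity(L, G)
  expect_equal(Ls["l1", "l2"], (0.75 + exp(-2)) / 2, tolerance = 1e-9)
  expect_identical(attr(Ls, "kind"), "integrated_lncrna")
  # idempotent on equal inputs
  expect_equal(unclass(integrate_similarity(L, L)), unclass(L),
               tolerance = 1e-12, ignore_attr = TRUE)
  # id mismatch names the offending ids
  L2 <- sequence_similarity(sequence_set(c(l1 = "ACGT", lX = "ACGA")))
  expect_error(integrate_similarity(L, L2), "lX")
})

test_that("pair features concatenate the disease and lncRNA rows", {
  nd <- 3L; nl <- 4L
  A <- association_matrix(
    matrix(c(1, rep(0, 10), 1), nd, nl),
    disease_ids = paste0("d", 1:nd), lncrna_ids = paste0("l", 1:nl))
  Ds <- similarity_matrix(diag(nd), paste0("d", 1:nd), "integrated_disease")
  Ls <- similarity_matrix(diag(nl), paste0("l", 1:nl), "integrated_lncrna")
  pf <- build_pair_features(Ds, Ls, A)
  expect_identical(dim(pf$x), c(nd * nl, nd + nl))
  expect_identical(nrow(pf$pairs), nd * nl)
  expect_identical(sum(pf$pairs$label), sum(A))
  # vector is [disease row | lncRNA row]
  row <- pf$x[pf$pairs$disease_id == "d2" & pf$pairs$lncrna_id == "l3", ]
  expect_identical(row, c(unclass(Ds)["d2", ], unclass(Ls)["l3", ]))
  # label copied from A
  expect_identical(
    pf$pairs$label[pf$pairs$disease_id == "d1" & pf$pairs$lncrna_id == "l1"],
    1)
  # pure function: same inputs, bit-identical output
  expect_identical(pf$x, build_pair_features(Ds, Ls, A)$x)
  expect_error(build_pair_features(Ds, Ls, A,
                                   pairs = data.frame(disease_id = "dX",
                                                      lncrna_id = "l1")),
               "unknown id")
})

test_that("all six similarity matrices satisfy the matrix invariants", {
  ds <- small_dataset()
  pipe <- pair_feature_pipeline(ds$sequences, ds$ontology, ds$associations)
  for (nm in c("L_sim", "D_sim", "GKL", "GKD", "Ls", "Ds")) {
    m <- unclass(pipe[[nm]])
    expect_lt(max(abs(m - t(m))), 1e-9)
    expect_lt(max(abs(diag(m) - 1)), 1e-9)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("lncRNAs without sequences fall back to identity sequence rows", {
  ds <- small_dataset()
  seqs_partial <- ds$sequences[-c(2, 7)]
  class(seqs_partial) <- "sequence_set"
  pipe <- pair_feature_pipeline(seqs_partial, ds$ontology, ds$associations)
  missing_id <- names(ds$sequences)[2]
  row <- unclass(pipe$L_sim)[missing_id, ]
  expect_identical(unname(row[missing_id]), 1)
  expect_identical(unname(row[setdiff(names(row), missing_id)]),
                   rep(0, length(row) - 1))
})
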