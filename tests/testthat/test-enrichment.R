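test_that("the hypergeometric upper tail matches exact enumeration", {
  # drawing all 5 annotated genes in 5 draws from 20: 1 / C(20,5)
  expect_equal(hypergeomPValue(5, 5, 5, 20), 1 / 15504, tolerance = 1e-12)
  expect_equal(hypergeomPValue(0, 5, 5, 20), 1)       # whole support
  expect_equal(hypergeomPValue(1, 1, 7, 20), 7 / 20)  # single draw
  # EASE-style variant replaces k with k - 1
  expect_equal(hypergeomPValue(5, 5, 5, 20, ease = TRUE),
               exactHyperTail(4, 5, 5, 20), tolerance = 1e-12)

  # exhaustive check against rational enumeration for moderate N
  worst <- 0
  for (N in c(5, 11, 18, 25)) {
    for (n in seq(1, N, by = 3)) {
      for (K in seq(0, N, by = 4)) {
        for (k in 0:min(n, K)) {
          expected <- exactHyperTail(k, n, K, N)
          got <- hypergeomPValue(k, n, K, N)
          worst <- max(worst, abs(got - expected) / expected)
        }
      }
    }
  }
  expect_lt(worst, 1e-12)

  expect_error(hypergeomPValue(6, 5, 5, 20), "k must")
  expect_error(hypergeomPValue(2, 25, 5, 20), "exceed N")
})

test_that("fold enrichment is the query-to-background frequency ratio", {
  expect_equal(foldEnrichment(5, 5, 5, 20), 4)
  expect_equal(foldEnrichment(2, 10, 4, 20), 1)      # k/n == K/N
  expect_equal(foldEnrichment(3, 10, 6, 100), 5)
  expect_true(is.na(foldEnrichment(0, 10, 6, 100)))  # undefined at k = 0
})

test_that("Benjamini-Hochberg adjustment follows the step-up formula", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustBH(0.2), 0.2)                 # m = 1
  expect_equal(adjustBH(rep(0.05, 4)), rep(0.05, 4))  # ties unchanged
  # hand-computed step-up: q = cummin over ranks of m p / i
  p <- c(0.005, 0.009, 0.05, 0.2, 0.9)
  expect_equal(adjustBH(p), pmin(1, rev(cummin(rev(5 * p / 1:5)))))
  expect_error(adjustBH(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(adjustBH(c(0.1, 1.2)), "\\(0, 1\\]")
})

test_that("q-values are order-invariant, capped at 1 and monotone in rank", {
  set.seed(31)
  for (rep in 1:10) {
    p <- runif(20)
    perm <- sample(20)
    q <- adjustBH(p)
    expect_equal(q[perm], adjustBH(p[perm]))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
})

mkAnnotation <- function(ids, members, names = ids) {
  f <- writeTempTSV(vapply(seq_along(ids), function(i)
    paste(c(ids[i], names[i], members[[i]]), collapse = "\t"), character(1)))
  readGeneSets(f)
}

test_that("enrich computes k, n, K, N per term and sorts by p-value", {
  # query identical to one term, annotation of disjoint equal-sized terms
  ann <- mkAnnotation(c("T1", "T2", "T3"),
                      list(c("A1", "A2", "A3"), c("B1", "B2", "B3"),
                           c("C1", "C2", "C3")))
  res <- enrich(c("a1", "a2", "a3"), ann, minHits = 2)
  expect_equal(nrow(res), 1)  # other terms have k = 0 and are untested
  expect_equal(res$term_id, "T1")
  expect_equal(res$k, 3L); expect_equal(res$n, 3L)
  expect_equal(res$K, 3L); expect_equal(res$N, 9L)
  expect_equal(res$fold_enrichment, 3)
  expect_equal(res$p_value, 1 / choose(9, 3), tolerance = 1e-12)

  # disjoint query cannot be tested at all
  expect_error(enrich(c("Z1", "Z2"), ann), "no overlap")

  # the planted fixture term attains the smallest p-value, confirmed by
  # a brute-force scan over every term
  fx <- defaultFixture()
  query <- union(unique(fx@chemRecords$target_id), fx@diseaseTargets)
  res <- enrich(query, fx@annotations)
  expect_equal(res$term_id[1], fx@groundTruth$planted_term)
  universe <- backgroundSymbols(fx@annotations)
  eff <- intersect(toupper(query), universe)
  brute <- vapply(termMembers(fx@annotations), function(m)
    exactHyperTail(length(intersect(eff, m)), length(eff), length(m),
                   backgroundSize(fx@annotations)), numeric(1))
  expect_equal(names(which.min(brute)), fx@groundTruth$planted_term)
  expect_equal(res$p_value[1], unname(min(brute)), tolerance = 1e-9)
})

test_that("enrichment p-values are calibrated under the null", {
  # no planted structure: random queries against random terms should
  # reject at close to the nominal rate
  set.seed(32)
  universe <- sprintf("G%03d", 1:200)
  terms <- lapply(1:20, function(i) sample(universe, sample(10:30, 1)))
  ann <- mkAnnotation(sprintf("T%02d", 1:20), terms)
  n_sim <- 200
  m_terms <- length(termIds(ann))
  hits <- matrix(1, n_sim, m_terms)
  for (s in seq_len(n_sim)) {
    q <- sample(universe, 15)
    res <- enrich(q, ann, minHits = 1)
    hits[s, seq_len(nrow(res))] <- res$p_value
  }
  for (alpha in c(0.01, 0.05)) {
    prop <- mean(hits <= alpha)
    se <- sqrt(alpha * (1 - alpha) / length(hits))
    expect_lte(prop, alpha + 3 * se)
  }
})
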