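test_that("hypergeometric upper tail matches hand enumeration", {
  # C(4,3)C(6,2) + C(4,4)C(6,1) over C(10,5) = 66/252
  expect_equal(hypergeomUpperTail(10, 4, 5, 3), 66 / 252,
               tolerance = 1e-12)
  expect_identical(hypergeomUpperTail(10, 4, 5, 0), 1.0)
  expect_equal(hypergeomUpperTail(3800, 171, 20, 7),
               hyperTailOracle(3800, 171, 20, 7), tolerance = 1e-12)
})

test_that("upper tail agrees with the enumeration oracle on random tuples", {
  set.seed(101)
  for (i in 1:200) {
    N <- sample(1:60, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    p <- hypergeomUpperTail(N, K, n, k)
    o <- hyperTailOracle(N, K, n, k)
    expect_equal(p, o, tolerance = 1e-12)
    # duality: roles of the category and the draw are exchangeable
    expect_equal(p, hypergeomUpperTail(N, n, K, k), tolerance = 1e-12)
  }
})

test_that("upper tail rejects out-of-bounds inputs", {
  expect_error(hypergeomUpperTail(10, 11, 5, 3), "<=")
  expect_error(hypergeomUpperTail(10, 4, 5, 5), "<=")
  expect_error(hypergeomUpperTail(10, 4, 11, 0), "<=")
  expect_error(hypergeomUpperTail(10.5, 4, 5, 3), "integer")
})

makeAnnotation <- function(universeSize = 50) {
  uni <- sprintf("g%02d", seq_len(universeSize))
  AnnotationSet(data.frame(
    category = rep(c("C1", "C2", "C3"), times = c(5, 8, 4)),
    gene = c(uni[1:5], uni[10:17], uni[40:43])), universe = uni)
}

test_that("enrichment flags overrepresented categories and sorts by p", {
  ann <- makeAnnotation()
  res <- enrichCategories(c("g01", "g02", "g03", "g04", "g20"), ann)
  expect_equal(res$category[1], "C1")
  expect_true(res$flagged[1])
  expect_true(all(diff(res$p) >= 0))
  c1 <- res[res$category == "C1", ]
  expect_equal(c1$p, hyperTailOracle(50, 5, 5, 4), tolerance = 1e-12)
  # disjoint category: k = 0, p = 1, never flagged
  c3 <- res[res$category == "C3", ]
  expect_equal(c3$k, 0L)
  expect_equal(c3$p, 1)
  expect_false(c3$flagged)
})

test_that("boundary significant sets behave as drawing everything/nothing", {
  ann <- makeAnnotation()
  expect_equal(nrow(enrichCategories(character(), ann)), 0L)
  res <- enrichCategories(universe(ann), ann)
  expect_true(all(res$k == res$K))
  expect_true(all(res$p == 1))
})

test_that("enrichment p-values are invariant to gene relabeling", {
  set.seed(23)
  uni <- sprintf("g%03d", 1:100)
  memb <- data.frame(category = rep(c("A", "B"), each = 10),
                     gene = sample(uni, 20))
  sig <- sample(uni, 15)
  p1 <- enrichCategories(sig, AnnotationSet(memb, uni))$p
  # relabel every gene with a bijection
  relab <- stats::setNames(sample(sprintf("h%03d", 1:100)), uni)
  memb2 <- data.frame(category = memb$category, gene = relab[memb$gene])
  p2 <- enrichCategories(relab[sig], AnnotationSet(memb2, relab[uni]))$p
  expect_equal(p1, p2, tolerance = 1e-14)
})

test_that("significant genes outside the universe are dropped with warning", {
  ann <- makeAnnotation()
  expect_warning(res <- enrichCategories(c("g01", "zz9"), ann), "dropped")
  expect_true(all(res$n == 1))
})

test_that("explicit multiple-testing correction is applied, never silently", {
  ann <- makeAnnotation()
  sig <- c("g01", "g02", "g03", "g04", "g20")
  raw <- enrichCategories(sig, ann)
  bonf <- enrichCategories(sig, ann, correction = "bonferroni")
  expect_equal(raw$p, raw$pAdjusted)
  expect_equal(bonf$pAdjusted, pmin(bonf$p * 3, 1))
})

test_that("overlap significance reproduces the tail computation", {
  uni <- sprintf("g%04d", 1:3800)
  setA <- uni[1:171]
  setB <- c(uni[1:7], uni[200:212])   # 20 genes, 7 overlapping
  res <- overlapSignificance(setA, setB, uni)
  expect_equal(res$k, 7L)
  expect_equal(res$p, hyperTailOracle(3800, 171, 20, 7), tolerance = 1e-12)
  # disjoint sets
  d <- overlapSignificance(uni[1:10], uni[100:120], uni)
  expect_equal(d$k, 0L)
  expect_equal(d$p, 1)
  # nested sets: the single surviving tail term
  nest <- overlapSignificance(uni[1:30], uni[5:10], uni[1:100])
  expect_equal(nest$p, hyperTailOracle(100, 30, 6, 6), tolerance = 1e-12)
  expect_error(overlapSignificance("a", "b", character()), "empty")
  expect_error(overlapSignificance("zz", uni[1], uni), "subsets")
})
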