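test_that("normalizeMembrane divides by the membrane mean", {
  expect_equal(as.numeric(normalizeMembrane(c(2, 4, 6))), c(0.5, 1.0, 1.5))
  expect_equal(as.numeric(normalizeMembrane(rep(3.7, 8))), rep(1, 8))
  expect_equal(as.numeric(normalizeMembrane(5)), 1)
})

test_that("non-positive wells are excluded, flagged and returned as NA", {
  out <- normalizeMembrane(c(2, 0, -3, 4), membraneId = "M1")
  expect_true(is.na(out[2]) && is.na(out[3]))
  expect_equal(attr(out, "nExcluded"), 2L)
  expect_equal(mean(out[c(1, 4)]), 1)
  expect_error(normalizeMembrane(c(0, -1), membraneId = "M9"), "M9")
})

test_that("normalization is idempotent, scale- and order-invariant", {
  for (s in 1:5) {
    set.seed(s)
    x <- rlnorm(96, 0, 0.4)
    n1 <- as.numeric(normalizeMembrane(x))
    # idempotence: a normalized membrane has mean 1 already
    expect_equal(as.numeric(normalizeMembrane(n1)), n1, tolerance = 1e-12)
    expect_equal(mean(n1), 1, tolerance = 1e-12)
    # scale invariance: the day-to-day correction
    expect_equal(as.numeric(normalizeMembrane(x * 17.3)), n1,
                 tolerance = 1e-12)
    # permutation invariance of the resulting per-well values
    p <- sample(96)
    expect_equal(as.numeric(normalizeMembrane(x[p])), n1[p],
                 tolerance = 1e-12)
  }
})

# Membranes engineered so strain "x" has normalized values 1, 2 and 4:
# each membrane's filler wells bring its mean to exactly 1.
xReplicates124 <- function() {
  rbind(
    data.frame(strain = c("x", "f1"), membrane_id = "M1", replicate = 1,
               raw_intensity = c(1, 1)),
    data.frame(strain = c("x", "f1", "f2", "f3"), membrane_id = "M2",
               replicate = 2, raw_intensity = c(2, 2/3, 2/3, 2/3)),
    data.frame(strain = c("x", paste0("f", 1:7)), membrane_id = "M3",
               replicate = 3, raw_intensity = c(4, rep(4/7, 7)))
  )
}

test_that("scoreStrains averages on the linear scale then takes log10", {
  res <- scoreStrains(xReplicates124())
  x <- res$scores[res$scores$strain == "x", ]
  expect_equal(x$nReplicates, 3L)
  expect_equal(x$meanLinear, 7 / 3)
  expect_equal(x$log10Score, log10(7 / 3))    # ~0.36798
  expect_equal(x$cv, sd(c(1, 2, 4)) / (7 / 3)) # ~0.65465
})

test_that("a symmetric pair of normalized replicates scores zero", {
  m <- rbind(
    data.frame(strain = c("a", "b"), membrane_id = "M1", replicate = 1,
               raw_intensity = c(0.8, 1.2)),
    data.frame(strain = c("a", "b"), membrane_id = "M2", replicate = 2,
               raw_intensity = c(1.2, 0.8)))
  res <- scoreStrains(m)
  a <- res$scores[res$scores$strain == "a", ]
  expect_equal(a$meanLinear, 1.0)
  expect_equal(a$log10Score, 0.0)
})

test_that("insufficient replicates are rejected with a reason", {
  m <- rbind(xReplicates124(),
             data.frame(strain = "solo", membrane_id = "M4", replicate = 1,
                        raw_intensity = 5))
  res <- scoreStrains(m)
  expect_false("solo" %in% res$scores$strain)
  expect_equal(res$rejects$reason[res$rejects$strain == "solo"],
               "insufficient replicates")
  # a strain whose second replicate was a non-positive well is also rejected
  m2 <- rbind(
    data.frame(strain = c("a", "b"), membrane_id = "M1", replicate = 1,
               raw_intensity = c(1, 1)),
    data.frame(strain = c("a", "b"), membrane_id = "M2", replicate = 2,
               raw_intensity = c(0, 2)))
  res2 <- scoreStrains(m2)
  expect_true("a" %in% res2$rejects$strain)
})

test_that("duplicate (strain, membrane, replicate) rows are an error", {
  m <- rbind(xReplicates124(),
             data.frame(strain = "x", membrane_id = "M1", replicate = 1,
                        raw_intensity = 2))
  expect_error(scoreStrains(m), "duplicate")
})

test_that("log averaging mode takes the mean of log10 values", {
  res <- scoreStrains(xReplicates124(), average = "log")
  x <- res$scores[res$scores$strain == "x", ]
  expect_equal(x$log10Score, mean(log10(c(1, 2, 4))))
  expect_equal(x$meanLinear, 10^x$log10Score)
})

test_that("well order within a membrane does not affect scores", {
  s <- smallScreen(nGenes = 96, seed = 21)
  blot <- s$blot
  set.seed(1)
  shuffled <- blot[sample(nrow(blot)), ]
  a <- scoreStrains(blot)$scores
  b <- scoreStrains(shuffled)$scores
  b <- b[match(a$strain, b$strain), ]
  expect_equal(a$log10Score, b$log10Score, tolerance = 1e-12)
})

test_that("collectionCV averages per-strain CVs over the included strains", {
  s <- data.frame(strain = c("a", "b", "c"), cv = c(0, 0, 0))
  expect_equal(collectionCV(s), 0)
  s2 <- data.frame(strain = c("a", "b"), cv = c(0.2, 0.3))
  expect_equal(collectionCV(s2), 0.25)
  expect_equal(collectionCV(s2, include = "b"), 0.3)
  expect_error(collectionCV(s2, include = "zz"), "no strains")
})

test_that("collection mean CV on default noise sits in the expected band", {
  # sample-sd CV at 2 replicates underestimates the generative 27.8%
  s <- smallScreen(nGenes = 480, seed = 31)
  sc <- scoreStrains(s$blot)$scores
  mcv <- collectionCV(sc)
  expect_gt(mcv, 0.22)
  expect_lt(mcv, 0.30)
})
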