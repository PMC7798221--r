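test_that("worked 3-feature example reproduces hand-derived matrices", {
  x <- worked_set()
  cm <- corm(x)
  expect_identical(cm$set_size, 4)
  expect_equal(cm$values, rbind(c(3, 2, 1), c(2, 2, 0), c(1, 0, 2)))

  cp <- as_coprm(cm)
  expect_equal(cp$values, rbind(c(.75, .5, .25), c(.5, .5, 0), c(.25, 0, .5)))

  pm <- as_pmirm(cp)
  expect_equal(pm$values[1, 2], log2(0.5 / 0.375))   # +0.415
  expect_equal(pm$values[1, 3], log2(0.25 / 0.375))  # -0.585
  expect_true(is.na(pm$values[2, 3]))                # never co-occur
  expect_false(pm$defined[2, 3])
  expect_equal(diag(pm$values), c(0, 0, 0))          # text convention

  zm <- as_zpmirm(pm)
  expect_equal(unname(zm$stats["mu"]), (log2(4 / 3) + log2(2 / 3)) / 2)
  expect_equal(unname(zm$stats["sigma"]), 0.5)
  expect_equal(zm$values[1, 2], 1)
  expect_equal(zm$values[1, 3], -1)
  expect_equal(zm$values[1, 1], -((log2(4 / 3) + log2(2 / 3)) / 2) / 0.5)
  expect_true(is.na(zm$values[2, 3]))
})

test_that("corm accumulation equals the naive nested-loop oracle", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(1:50, 1); d <- sample(2:16, 1)
    x <- rand_fpset(n, d, p = stats::runif(1, 0.05, 0.8))
    expect_equal(corm(x)$values, naive_corm(x$bits))
  }
})

test_that("single vector and all-zero vectors give their outer products", {
  one <- fpset(c(1, 0, 1), fingerprint_spec("custom", length = 3))
  expect_equal(corm(one)$values, rbind(c(1, 0, 1), c(0, 0, 0), c(1, 0, 1)))
  zero <- fpset(matrix(0L, 3, 4), fingerprint_spec("custom", length = 4))
  expect_equal(corm(zero)$values, matrix(0, 4, 4))
  expect_error(corm(fpset(matrix(integer(), 0, 3),
                          fingerprint_spec("custom", length = 3),
                          ids = character())),
               "empty")
})

test_that("matrix invariants hold on random instances", {
  set.seed(7)
  for (rep in 1:20) {
    x <- rand_fpset(sample(3:60, 1), sample(3:12, 1),
                    p = stats::runif(1, 0.2, 0.7))
    cm <- corm(x)
    expect_equal(cm$values, t(cm$values))
    # CORM bound: pair count cannot exceed either single-feature count
    d <- diag(cm$values)
    expect_true(all(cm$values <= pmin(outer(d, d, pmin) + 1e-9, Inf)))
    cp <- as_coprm(cm)
    expect_true(all(cp$values >= 0 & cp$values <= 1))
    pm <- as_pmirm(cp)
    expect_equal(pm$values, t(pm$values))
    # PMI upper bound from p_ij <= min(p_ii, p_jj)
    p <- cp$values; dd <- diag(p)
    for (i in seq_along(dd)) for (j in seq_along(dd)) {
      if (i != j && isTRUE(pm$defined[i, j]))
        expect_lte(pm$values[i, j], -log2(max(dd[i], dd[j])) + 1e-12)
    }
    zm <- tryCatch(as_zpmirm(pm), error = function(e) NULL)
    if (!is.null(zm)) {
      v <- zm$values[upper.tri(zm$values) & zm$defined]
      expect_lt(abs(mean(v)), 1e-9)
      expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
    }
  }
})

test_that("compound order does not change the CORM; duplication doubles it", {
  set.seed(11)
  x <- rand_fpset(30, 8)
  shuffled <- x[sample.int(30)]
  expect_equal(corm(x)$values, corm(shuffled)$values)

  doubled <- fp_rbind(x, x)
  expect_equal(corm(doubled)$values, 2 * corm(x)$values)
  expect_equal(as_coprm(corm(doubled))$values, as_coprm(corm(x))$values)
  expect_equal(as_pmirm(corm(doubled))$values, as_pmirm(corm(x))$values)
})

test_that("merging CORMs of disjoint streams equals one accumulation", {
  set.seed(3)
  a <- rand_fpset(20, 10); b <- rand_fpset(35, 10)
  merged <- corm_merge(corm(a), corm(b))
  expect_equal(merged$values, corm(fp_rbind(a, b))$values)
  expect_identical(merged$set_size, 55)
  expect_equal(corm_merge(corm(b), corm(a))$values, merged$values)
  # adding an all-zero CORM leaves values unchanged
  z <- corm(fpset(matrix(0L, 5, 10), fingerprint_spec("custom", length = 10)))
  expect_equal(corm_merge(corm(a), z)$values, corm(a)$values)
  expect_equal((corm(a) + corm(b))$values, merged$values)
  bad <- rand_fpset(5, 9)
  expect_error(corm_merge(corm(a), corm(bad)), "mismatch")
})

test_that("PMI semantics: ubiquitous, twice-expected and half-expected pairs", {
  # both features in every compound: p(x,y)=p(x)=p(y)=1 -> PMI 0
  ubiq <- fpset(matrix(1L, 10, 2), fingerprint_spec("custom", length = 2))
  expect_equal(as_pmirm(corm(ubiq))$values[1, 2], 0)
  # p(x)=p(y)=0.5, p(x,y)=0.5 -> PMI 1 (co-occur twice as often as expected)
  twice <- fpset(rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0)),
                 fingerprint_spec("custom", length = 2))
  expect_equal(as_pmirm(corm(twice))$values[1, 2], 1)
  # p(x)=p(y)=0.5, p(x,y)=0.125 -> PMI -1 (half as often as expected)
  half <- fpset(rbind(c(1, 1), c(1, 0), c(1, 0), c(1, 0),
                      c(0, 1), c(0, 1), c(0, 1), c(0, 0)),
                fingerprint_spec("custom", length = 2))
  expect_equal(as_pmirm(corm(half))$values[1, 2], -1)
  # never-observed feature: undefined row/column including diagonal
  absent <- fpset(rbind(c(1, 0), c(1, 0)), fingerprint_spec("custom", length = 2))
  pm <- as_pmirm(corm(absent))
  expect_true(is.na(pm$values[2, 2]) && is.na(pm$values[1, 2]))
  expect_equal(pm$values[1, 1], 0)
})

test_that("standardization refuses a degenerate (constant-PMI) profile", {
  # all three columns identical -> every defined off-diagonal PMI equals 1
  x <- fpset(rbind(c(1, 1, 1), c(0, 0, 0)), fingerprint_spec("custom", length = 3))
  expect_error(as_zpmirm(as_pmirm(corm(x))), "sigma = 0")
  # a single defined pair is also degenerate
  y <- fpset(rbind(c(1, 1), c(0, 0)), fingerprint_spec("custom", length = 2))
  expect_error(as_zpmirm(as_pmirm(corm(y))), "degenerate")
})

test_that("relation-matrix containers round-trip through save/load", {
  x <- worked_set()
  path <- withr::local_tempfile(fileext = ".rm")
  cm <- corm(x, label = "worked")
  save_relmat(cm, path)
  cm2 <- load_relmat(path)
  expect_identical(cm2$values, cm$values)
  expect_identical(cm2$variant, "corm")
  expect_identical(cm2$set_size, cm$set_size)
  expect_true(spec_equal <- identical(format(cm2$spec), format(cm$spec)))

  zm <- as_zpmirm(cm)
  save_relmat(zm, path)
  zm2 <- load_relmat(path)
  expect_equal(zm2$values, zm$values, tolerance = 1e-12)
  expect_equal(zm2$stats, zm$stats, tolerance = 1e-15)
  expect_identical(zm2$defined, zm$defined)

  bad <- withr::local_tempfile(fileext = ".rm")
  writeLines("{ not json", bad)
  expect_error(load_relmat(bad), "corrupt")
  jsonlite::write_json(list(format = "something-else"), bad, auto_unbox = TRUE)
  expect_error(load_relmat(bad), "not a relation-matrix container")
})
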