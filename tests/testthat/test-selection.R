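test_that("mutual information closed forms", {
  x <- rep(c(0, 1), 50)
  # perfectly dependent two-level pair: 1 bit raw, 1 normalized
  expect_equal(mutual_information(x, x), 1)
  expect_equal(mutual_information(x, x, normalized = TRUE), 1)
  set.seed(4)
  a <- rnorm(200)
  expect_equal(mutual_information(a, a, normalized = TRUE), 1,
               tolerance = 1e-12)
  expect_error(mutual_information(1:4, 1:5), "equal length")
  expect_warning(z <- mutual_information(rep(1, 10), rnorm(10),
                                         normalized = TRUE), "entropy")
  expect_equal(z, 0)
  expect_warning(z1 <- mutual_information(rep(1, 10), rep(1, 10),
                                          normalized = TRUE), "entropy")
  expect_equal(z1, 1)
})

test_that("MI is symmetric, non-negative and bounded by marginal entropies", {
  set.seed(9)
  for (i in 1:25) {
    n <- 300
    a <- rnorm(n)
    b <- 0.5 * a + rnorm(n, sd = runif(1, 0.2, 2))
    mab <- mutual_information(a, b)
    expect_identical(mab, mutual_information(b, a))
    expect_gte(mab, 0)
    ha <- -sum(prop.table(table(facialemg:::bin_indices(a, 10))) *
                 log2(prop.table(table(facialemg:::bin_indices(a, 10)))))
    hb <- -sum(prop.table(table(facialemg:::bin_indices(b, 10))) *
                 log2(prop.table(table(facialemg:::bin_indices(b, 10)))))
    expect_lte(mab, min(ha, hb) + 1e-12)
  }
})

test_that("independent samples have small estimated MI; noise cannot raise MI much", {
  set.seed(11)
  a <- runif(10000); b <- runif(10000)
  expect_lte(mutual_information(a, b, bins = 10), 0.05)
  # data-processing sanity: degrading b with independent noise never raises
  # MI beyond estimator tolerance
  x <- rnorm(2000)
  y <- x + rnorm(2000, sd = 0.5)
  mi_clean <- mutual_information(x, y)
  for (s in 1:5) {
    set.seed(100 + s)
    y_noisy <- y + rnorm(2000, sd = 1)
    expect_lte(mutual_information(x, y_noisy), mi_clean + 0.05)
  }
})

test_that("monotone transforms keep high normalized MI through binning", {
  set.seed(13)
  v <- rnorm(1170)
  # oracle: exact discrete MI of a binned pair
  binned_nmi <- function(a, b) {
    joint <- table(facialemg:::bin_indices(a, 10),
                   facialemg:::bin_indices(b, 10)) / length(a)
    pa <- rowSums(joint); pb <- colSums(joint)
    nz <- joint > 0
    mi <- sum(joint[nz] * log2(joint[nz] / outer(pa, pb)[nz]))
    h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
    mi / sqrt(h(pa) * h(pb))
  }
  # affine increasing maps preserve the equal-width binning exactly
  expect_equal(mutual_information(v, 2 * v + 3, bins = 10,
                                  normalized = TRUE), 1, tolerance = 1e-12)
  # a nonlinear monotone map re-bins the data; the estimate must equal the
  # exact discrete MI of the binned pair and remain strongly dependent
  u <- runif(1170)
  nmi <- mutual_information(u, u^2, bins = 10, normalized = TRUE)
  expect_equal(nmi, binned_nmi(u, u^2), tolerance = 1e-12)
  expect_gte(nmi, 0.7)
})

test_that("MI matrix averages subjects, is symmetric with unit diagonal", {
  ds <- preprocess_dataset(small_dataset(seed = 17, trials = 1,
                                         duration = 2000))
  sets <- build_all_feature_sets(ds, c("MAV", "RMS", "MPV", "WL"))
  mm <- mi_matrix(sets, bins = 8)
  expect_true(isSymmetric(mm$values))
  expect_equal(unname(diag(mm$values)), rep(1, 4))
  expect_true(all(mm$values >= 0))
  # two identical feature sets give off-diagonal 1
  twin <- list(A = sets$MAV, B = sets$MAV)
  names(twin$B$matrix) <- NULL
  mm2 <- mi_matrix(twin, bins = 8)
  expect_equal(mm2$values["A", "B"], 1, tolerance = 1e-12)
  # averaging over two subjects equals the mean of per-subject matrices
  ds2 <- preprocess_dataset(small_dataset(seed = 18, trials = 1,
                                          duration = 2000))
  sets2 <- build_all_feature_sets(ds2, c("MAV", "RMS", "MPV", "WL"))
  m_avg <- mi_matrix(list(sets, sets2), bins = 8)
  expect_equal(m_avg$values,
               (mi_matrix(sets, bins = 8)$values +
                  mi_matrix(sets2, bins = 8)$values) / 2, tolerance = 1e-12)
  expect_equal(m_avg$subjects_averaged, 2)
})

test_that("greedy mRMR ordering matches hand evaluation and brute force", {
  rel <- c(f1 = 0.9, f2 = 0.8, f3 = 0.79)
  red <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.1,
                  0.1, 0.1, 1), 3, 3,
                dimnames = list(names(rel), names(rel)))
  rk <- mrmr_rank(rel, red)
  expect_equal(rk$order, c("f1", "f3", "f2"))
  # set-level scores per prefix (Eqs for D and R)
  expect_equal(rk$scores$D[1], 0.9)
  expect_equal(rk$scores$R[2], mean(red[c("f1", "f3"), c("f1", "f3")]))
  # zero redundancy reduces to relevance sort
  red0 <- diag(3); dimnames(red0) <- dimnames(red)
  expect_equal(mrmr_rank(rel, red0 * 0)$order, c("f1", "f2", "f3"))
  # single candidate
  expect_equal(mrmr_rank(c(only = 0.5),
                         matrix(1, 1, 1,
                                dimnames = list("only", "only")))$order,
               "only")
  expect_error(mrmr_rank(numeric(0), red), "empty")
  # brute-force re-check of every greedy step on random instances
  set.seed(31)
  for (i in 1:20) {
    p <- 6
    nm <- paste0("f", 1:p)
    rr <- stats::setNames(runif(p), nm)
    m <- matrix(runif(p * p), p, p, dimnames = list(nm, nm))
    m <- (m + t(m)) / 2; diag(m) <- 1
    rk <- mrmr_rank(rr, m)
    sel <- character(0)
    for (step in seq_len(p)) {
      expect_identical(rk$order[step], brute_mrmr_step(rr, m, sel))
      sel <- c(sel, rk$order[step])
    }
  }
})

test_that("RA ranking sorts by accuracy with alphabetical ties", {
  expect_equal(ra_rank(c(MPV = 87.1, MAV = 86.0))$order, c("MPV", "MAV"))
  expect_equal(ra_rank(c(Z = 50))$order, "Z")
  expect_equal(ra_rank(c(B = 70, A = 70, C = 80))$order, c("C", "A", "B"))
  rk <- ra_rank(c(A = 90, B = 85, C = 85, D = 10))
  expect_true(all(diff(rk$scores$accuracy) <= 0))
})
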