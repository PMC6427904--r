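# mrmr_selection: discretization, mutual information, greedy ranking,
# dimension-sweep mechanics.

test_that("discretize splits at mu +/- sigma into three levels", {
  set.seed(77)
  z <- rnorm(20000)
  d <- discretize(z)
  props <- as.vector(table(factor(d, 1:3))) / length(z)
  # CDF oracle: P(Z < -1), P(-1 <= Z <= 1), P(Z > 1) at the sample sigma
  expect_equal(props, c(pnorm(-1), pnorm(1) - pnorm(-1), pnorm(-1)),
               tolerance = 0.02)
  expect_warning(d1 <- discretize(rep(4, 10)), "zero-variance")
  expect_identical(length(unique(d1)), 1L)
  d3 <- discretize(c(-10, 0, 10))           # sigma ~ 8.16
  expect_identical(d3, c(1L, 2L, 3L))
  expect_identical(discretize(c(-10, 0, 10)), oracle_discretize(c(-10, 0, 10)))
})

test_that("mutual_information matches hand/entropy oracles and properties", {
  # independent with exact product counts -> 0 bits
  x <- rep(1:2, each = 4); y <- rep(rep(1:2, each = 2), 2)
  expect_equal(mutual_information(x, y), 0)
  # identical balanced binary -> 1 bit
  b <- rep(1:2, 50)
  expect_equal(mutual_information(b, b), 1)
  # joint counts [[2,1],[1,2]] -> explicit plug-in summation
  x <- c(1, 1, 1, 2, 2, 2); y <- c(1, 1, 2, 1, 2, 2)
  p <- matrix(c(2, 1, 1, 2) / 6, 2)
  expected <- sum(p * log2(p / (rowSums(p) %o% colSums(p))))
  expect_equal(mutual_information(x, y), expected, tolerance = 1e-12)
  expect_error(mutual_information(1:3, 1:4), "length")
  # symmetry, nonnegativity, entropy upper bound on random tables
  set.seed(12)
  for (i in 1:20) {
    x <- sample(1:3, 200, TRUE); y <- sample(1:4, 200, TRUE)
    mi <- mutual_information(x, y)
    expect_equal(mi, mutual_information(y, x), tolerance = 1e-12)
    expect_gte(mi, 0)
    H <- function(v) { p <- table(v) / length(v); -sum(p * log2(p)) }
    expect_lte(mi, min(H(x), H(y)) + 1e-12)
    expect_equal(mi, oracle_mi(x, y), tolerance = 1e-10)
  }
})

test_that("mrmr_rank: single feature, duplicate penalty, registry tie-break", {
  set.seed(3)
  c3 <- sample(0:2, 300, TRUE)
  tab <- cbind(A = tri(c3))
  r <- mrmr_rank(tab, c3)
  expect_identical(r$order, "A")
  expect_equal(r$score[1], oracle_mi(oracle_discretize(tri(c3)), c3),
               tolerance = 1e-10)
  # duplicate of a selected feature is fully redundant
  tab <- cbind(A = tri(c3), A_dup = tri(c3),
               N1 = tri(sample(0:2, 300, TRUE)),
               N2 = tri(sample(0:2, 300, TRUE)))
  r <- mrmr_rank(tab, c3)
  expect_identical(r$order[1], "A")
  expect_gt(which(r$order == "N1"), 1)
  dup_step <- which(r$order == "A_dup")
  expect_equal(r$redundancy[dup_step],
               mean(vapply(seq_len(dup_step - 1), function(s)
                 oracle_mi(oracle_discretize(tab[, r$order[s]]),
                           oracle_discretize(tab[, "A_dup"])), numeric(1))),
               tolerance = 1e-10)
  expect_error(mrmr_rank(tab, c3, k = 10), "exceeds")
  expect_error(mrmr_rank(tab[0, , drop = FALSE], integer(0)), "empty")
})

test_that("a duplicate never precedes an equally relevant independent feature", {
  # c = 3u + v with u, v independent balanced ternary codes; x1 and x2 both
  # encode u (x2 duplicates x1), x3 encodes v with equal relevance log2(3)
  grid <- expand.grid(u = 0:2, v = 0:2)
  u <- rep(grid$u, each = 20); v <- rep(grid$v, each = 20)
  cls <- 3 * u + v
  tab <- cbind(x1 = tri(u), x2 = tri(u), x3 = tri(v))
  r <- mrmr_rank(tab, cls)
  expect_identical(r$order, c("x1", "x3", "x2"))
  expect_equal(r$relevance[1], log2(3), tolerance = 1e-10)
  # duplicate's phi = log2(3) - mean(log2(3), 0)
  expect_equal(r$score[3], log2(3) / 2, tolerance = 1e-10)
})

test_that("a label-determining feature always ranks first (20 seeds)", {
  for (seed in 1:20) {
    set.seed(seed)
    cls <- sample(0:2, 150, TRUE)
    tab <- cbind(noise1 = tri(sample(0:2, 150, TRUE)),
                 det = tri(cls),
                 noise2 = rnorm(150),
                 noise3 = tri(sample(0:2, 150, TRUE)))
    r <- mrmr_rank(tab, cls)
    expect_identical(r$order[1], "det")
    # step 1 equals plain max-relevance
    rel <- vapply(colnames(tab), function(j)
      oracle_mi(oracle_discretize(tab[, j]), cls), numeric(1))
    expect_identical(r$order[1], names(which.max(rel)))
  }
})

test_that("greedy order equals the exhaustive per-step oracle (20 seeds)", {
  for (seed in 1:20) {
    set.seed(100 + seed)
    n <- 120
    cls <- sample(0:2, n, TRUE)
    p <- sample(3:6, 1)
    tab <- sapply(seq_len(p), function(j) {
      mix <- runif(1)
      ifelse(runif(n) < mix, tri(cls), tri(sample(0:2, n, TRUE)))
    })
    colnames(tab) <- paste0("f", seq_len(p))
    r <- mrmr_rank(tab, cls)
    o <- oracle_mrmr_greedy(tab, cls)
    # compare achieved objective step by step (robust to exact ties)
    for (step in seq_len(p)) {
      expect_lt(abs(r$score[step] - max(o$phis[[step]])), 1e-9)
      expect_lt(abs(o$phis[[step]][r$order[step]] - max(o$phis[[step]])), 1e-9)
    }
  }
})

test_that("sweep_f_list and rank_sum_select implement the selection rules", {
  expect_identical(sweep_f_list(),
                   as.integer(c(62, 57, 52, 47, 42, 37, 32, 27, 22, 17, 12, 7, 2)))
  # identical metrics everywhere -> smaller feature set wins
  m <- matrix(0.9, nrow = 3, ncol = 4,
              dimnames = list(c("62", "12", "7"), NULL))
  expect_identical(rank_sum_select(m)$f_m, 7L)
  # hand-computed toy: ranks col1 = (1.5, 1.5, 3), col2 = (1, 2.5, 2.5)
  toy <- matrix(c(0.9, 0.9, 0.8, 0.8, 0.7, 0.7), nrow = 3,
                dimnames = list(c("10", "5", "2"), c("m1", "m2")))
  sel <- rank_sum_select(toy)
  expect_equal(unname(sel$rank_sum), c(2.5, 4.0, 5.5))
  expect_identical(sel$f_m, 10L)
  # NA columns (undefined LGG cells) are dropped from the ranking
  toy_na <- cbind(toy, m3 = c(NA, 0.5, 0.9))
  sel2 <- rank_sum_select(toy_na)
  expect_identical(sel2$n_cells, 2L)
  expect_identical(sel2$f_m, 10L)
})
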