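test_that("decile scores follow the empirical quantile bins", {
  expect_identical(as.integer(quantile_scores(seq(10, 100, by = 10))), 0:9)
  # rank invariance under strictly increasing transforms
  set.seed(3)
  x <- rnorm(200)
  s1 <- as.integer(quantile_scores(x))
  expect_identical(as.integer(quantile_scores(exp(x))), s1)
  expect_identical(as.integer(quantile_scores(3 * x + 100)), s1)
  # degenerate constant column
  expect_warning(s0 <- quantile_scores(rep(2.5, 50)), "degenerate")
  expect_true(all(s0 == 0L))
  expect_error(quantile_scores(1:5, q = 10L), "at least")
  expect_error(quantile_scores(c(1, NA, 3)), "finite")
})

test_that("scores match a brute-force sort-and-count oracle", {
  brute <- function(x, q) {
    cuts <- quantile(x, probs = seq(0, 1, length.out = q + 1), type = 7,
                     names = FALSE)
    # v sits in the right-closed bin (c_k, c_{k+1}]; count cut points
    # strictly below v and clamp to the score range
    vapply(x, function(v)
      max(0L, min(q - 1L, sum(cuts < v) - 1L)), integer(1))
  }
  set.seed(17)
  for (rep in 1:6) {
    n <- sample(50:1000, 1)
    q <- sample(c(4L, 10L), 1)
    x <- switch(rep %% 3 + 1,
                rnorm(n),
                rlnorm(n),
                sample(round(rnorm(n), 1), n, replace = TRUE))  # ties
    expect_identical(as.integer(quantile_scores(x, q = q)), brute(x, q),
                     info = paste("rep", rep))
  }
})

test_that("marginal decile distributions are balanced within rounding", {
  set.seed(5)
  for (n in c(100, 237, 1000)) {
    s <- quantile_scores(rnorm(n))
    counts <- tabulate(s + 1L, nbins = 10L)
    expect_lte(max(abs(counts - n / 10)), 1)
  }
})

test_that("frozen cut points give splits the same decile meaning", {
  set.seed(9)
  expo <- data.frame(id = 1:300, a = rlnorm(300), b = rnorm(300))
  dec <- quantile_transform(expo)
  cuts <- attr(dec, "cuts")
  sub <- expo[31:60, ]
  dec_sub <- quantile_transform(sub, cuts = cuts)
  expect_identical(dec_sub$a, dec$a[31:60])
  expect_identical(dec_sub$b, dec$b[31:60])
})

test_that("mixture index is the exact weighted decile sum", {
  D <- rbind(0:9, rep(4, 10), 9:0)
  colnames(D) <- paste0("c", 1:10)
  w1 <- c(1, rep(0, 9))
  expect_equal(mixture_index(D, w1), D[, 1])
  # all deciles equal d gives index d for any simplex w
  set.seed(2)
  w <- rexp(10); w <- w / sum(w)
  expect_equal(mixture_index(matrix(4, 3, 10), w), rep(4, 3))
  # hand-computed dot product under uniform weights
  expect_equal(mixture_index(D, rep(0.1, 10))[1], sum(0:9) / 10)
  # moving one constituent by +1 decile moves the index by exactly w_i
  idx <- mixture_index(D, w)
  D2 <- D; D2[2, 3] <- D2[2, 3] + 1
  expect_equal(mixture_index(D2, w)[2] - idx[2], w[3])
  expect_error(mixture_index(D, w[1:4]), "mismatch")
})

test_that("train/validation split is reproducible and exhaustive", {
  s <- split_cohort(1:100, train_fraction = 0.4, seed = 10L)
  expect_identical(length(s$train), 40L)
  expect_identical(length(s$validation), 60L)
  expect_identical(sort(c(s$train, s$validation)), 1:100)
  s2 <- split_cohort(1:100, train_fraction = 0.4, seed = 10L)
  expect_identical(s$assignment, s2$assignment)
  s3 <- split_cohort(1:1000, 0.4, seed = 1L)
  s4 <- split_cohort(1:1000, 0.4, seed = 2L)
  expect_false(identical(s3$assignment, s4$assignment))
  expect_error(split_cohort(1:10, 0), "between 0 and 1")
  expect_error(split_cohort(1:10, 1), "between 0 and 1")
})
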