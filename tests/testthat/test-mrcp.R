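test_that("grand averages and their confidence bands behave", {
  # two opposite trials average to zero everywhere
  v <- sin(seq(0, 8 * pi, length.out = 400))
  ep <- make_epochs(2, NULL, sigma = 0, labels = c("a", "a"))
  ep$data[1, 1, ] <- v; ep$data[2, 1, ] <- -v
  ga <- grand_average(ep)
  expect_lt(max(abs(ga$mean["a", 1, ])), 1e-12)
  # identical trials give zero-width intervals
  ep2 <- make_epochs(5, NULL, sigma = 0, labels = rep("a", 5))
  for (i in 1:5) ep2$data[i, 1, ] <- v
  ga2 <- grand_average(ep2)
  expect_lt(max(ga2$upper - ga2$lower), 1e-12)
  expect_true(all(ga2$lower <= ga2$mean + 1e-15 &
                    ga2$mean <= ga2$upper + 1e-15))
  expect_error(grand_average(make_epochs(1, NULL, 1, labels = "a")),
               "at least 2")
})

test_that("the grand average recovers a known template under noise", {
  fs <- 100; n <- 80; sigma <- 2
  tmpl <- 5 * exp(-(seq(-1.5, 2.49, by = 0.01))^2)
  ep <- make_epochs(n, tmpl, sigma = sigma, labels = rep("g", n), seed = 4)
  ga <- grand_average(ep)
  dev <- abs(ga$mean["g", 1, ] - tmpl)
  expect_gte(mean(dev < 3 * sigma / sqrt(n)), 0.99)
})

test_that("confidence bands shrink as 1/sqrt(n)", {
  ep <- make_epochs(100, NULL, sigma = 1, labels = rep("a", 100), seed = 2)
  ga_all <- grand_average(ep)
  ep25 <- ep
  ep25$data <- ep$data[1:25, , , drop = FALSE]
  ep25$labels <- ep$labels[1:25]
  ep25$kept <- ep$kept[1:25]
  ep25$reject_reason <- ep25$reject_reason[1:25]
  ga25 <- grand_average(ep25)
  ratio <- mean(ga25$upper - ga25$lower) / mean(ga_all$upper - ga_all$lower)
  expect_gt(ratio, 1.6)      # expected ~2 with estimator noise
  expect_lt(ratio, 2.6)
})

test_that("rank-sum p-values match exact enumeration oracles", {
  # the textbook extreme arrangement
  expect_equal(mrcpgrasp:::exact_ranksum_p(0L, 3L, 3L), 0.1)
  # against the stats oracle across many small configurations
  set.seed(1)
  for (i in 1:25) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    u <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
    p_pkg <- mrcpgrasp:::exact_ranksum_p(as.integer(round(u)), n1, n2)
    p_oracle <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }
})

test_that("the normal approximation agrees with enumeration within 0.01", {
  # group sizes just above the exact-path cutoff (total > 20)
  n <- 12L
  mu <- n * n / 2; sig2 <- n * n * (2 * n + 1) / 12
  devs <- sapply(0:(n * n), function(u) {
    pe <- mrcpgrasp:::exact_ranksum_p(as.integer(u), n, n)
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
    abs(pe - min(1, 2 * pnorm(-abs(z))))
  })
  expect_lt(max(devs), 0.01)
})

test_that("sample-wise tracks flag no differences for identical groups", {
  ep <- make_epochs(12, NULL, sigma = 1, labels = rep("a", 12), seed = 6)
  A <- ep$data[1:6, 1, ]
  tr <- samplewise_ranksum(A, A)
  expect_true(all(!tr$significant))
  expect_true(all(tr$p >= 0.999))
  # all-tied samples give p = 1
  tr2 <- samplewise_ranksum(matrix(1, 6, 10), matrix(1, 7, 10))
  expect_true(all(tr2$p == 1))
  expect_error(samplewise_ranksum(matrix(1, 3, 5), matrix(1, 8, 5)),
               "at least 5")
})

test_that("separated groups are detected after onset only", {
  tmplA <- c(numeric(150), rep(3, 250))      # post-onset offset
  epA <- make_epochs(15, tmplA, sigma = 1, labels = rep("a", 15), seed = 7)
  epB <- make_epochs(15, NULL, sigma = 1, labels = rep("b", 15), seed = 8)
  tr <- samplewise_ranksum(epA$data[, 1, ], epB$data[, 1, ])
  expect_gt(mean(tr$significant[151:400]), 0.9)
  expect_lt(mean(tr$significant[1:150]), 0.2)
})

test_that("null condition contrasts stay near the nominal alpha level", {
  fracs <- sapply(1:20, function(s) {
    epA <- make_epochs(15, NULL, sigma = 1, labels = rep("a", 15),
                       seed = 300 + s)
    epB <- make_epochs(15, NULL, sigma = 1, labels = rep("b", 15),
                       seed = 600 + s)
    mean(samplewise_ranksum(epA$data[, 1, ], epB$data[, 1, ])$significant)
  })
  expect_lte(mean(fracs), 0.08)
})

test_that("topographic frames average the stated window per channel", {
  fx <- desk_subject()
  ga <- grand_average(fx$pp$epochs)
  # a single-sample window equals that sample of the grand average
  t1 <- ga$time_axis[200]
  fr1 <- topographic_frame(ga, c(t1, t1), condition = "palmar")
  expect_equal(fr1$amplitude_uv, unname(ga$mean["palmar", , 200]))
  expect_error(topographic_frame(ga, c(9, 10)), "empty time window")
  # peri-onset grasp map: minimum over the central motor cortex
  fr <- topographic_frame(ga, c(-0.2, 0.2), condition = "palmar")
  expect_true(fr$label[which.min(fr$amplitude_uv)] %in% c("FCz", "Cz", "C1"))
  # contralateral dominance: C1 more negative than C2
  expect_lt(fr$amplitude_uv[fr$label == "C1"],
            fr$amplitude_uv[fr$label == "C2"])
})
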