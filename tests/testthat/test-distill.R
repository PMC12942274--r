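test_that("generalized_softmax is a stabilized tempered softmax", {
  # constant logits are uniform at any temperature
  for (tau in c(0.5, 1, 10)) {
    expect_equal(generalized_softmax(rep(3.7, 6), tau), rep(1 / 6, 6))
  }
  # tau = 1 equals the standard softmax
  z <- c(0.3, -1.2, 2.5, 0.0)
  expect_equal(generalized_softmax(z, 1), exp(z) / sum(exp(z)),
               tolerance = 1e-12)
  # sums to 1 and matches a direct exp/sum oracle at tau = 10
  set.seed(1)
  for (i in 1:100) {
    z <- rnorm(8, sd = 5)
    p <- generalized_softmax(z, 10)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, exp(z / 10) / sum(exp(z / 10)), tolerance = 1e-12)
  }
  # extreme logits do not overflow
  expect_equal(sum(generalized_softmax(c(1e4, 0, -1e4), 1)), 1)
  expect_error(generalized_softmax(c(1, 2), 0), "tau")
  expect_error(generalized_softmax(c(1, NA), 1), "finite")
})

test_that("tempering never decreases entropy", {
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  set.seed(2)
  taus <- c(0.5, 1, 2, 5, 10, 20)
  for (i in 1:100) {
    z <- rnorm(8, sd = 3)
    ent <- vapply(taus, function(tau) entropy(generalized_softmax(z, tau)),
                  numeric(1))
    expect_true(all(diff(ent) >= -1e-12))
  }
})

test_that("ld_loss is a per-edge tempered KL with the expected zeros", {
  cfg <- distill_config()
  z <- matrix(rnorm(32), 4, 8)
  # identical student and teacher -> exactly 0
  expect_equal(ld_loss(z, z, cfg), 0)

  # two-bin teacher point mass vs uniform student -> log 2 per edge
  zt <- matrix(c(1e4, -1e4), 4, 2, byrow = TRUE)
  zs <- matrix(0, 4, 2)
  cfg2 <- distill_config(tau_square_rescale = FALSE)
  # teacher tempered at tau = 10 softens the point mass, so use tau = 1
  cfg1 <- distill_config(temperature = 1, tau_square_rescale = FALSE)
  expect_equal(ld_loss(zs, zt, cfg1), 4 * log(2), tolerance = 1e-6)

  # random pairs match a direct KL summation oracle; loss >= 0
  set.seed(3)
  for (i in 1:100) {
    s <- matrix(rnorm(32, sd = 2), 4, 8)
    t <- matrix(rnorm(32, sd = 2), 4, 8)
    direct <- 0
    for (e in 1:4) {
      pt <- generalized_softmax(t[e, ], cfg$temperature)
      ps <- generalized_softmax(s[e, ], cfg$temperature)
      direct <- direct + sum(pt * log(pt / ps))
    }
    direct <- direct * cfg$temperature^2
    expect_equal(ld_loss(s, t, cfg), direct, tolerance = 1e-9)
    expect_gte(ld_loss(s, t, cfg), 0)
  }

  # tau^2 rescale flag
  s <- matrix(rnorm(32), 4, 8); t <- matrix(rnorm(32), 4, 8)
  expect_equal(ld_loss(s, t, distill_config(tau_square_rescale = FALSE)) * 100,
               ld_loss(s, t, distill_config()), tolerance = 1e-12)

  expect_error(ld_loss(matrix(0, 4, 8), matrix(0, 4, 6)), "bin count")
})

test_that("kd_class_loss mirrors the tempered-KL convention", {
  expect_equal(kd_class_loss(rnorm(5) -> z, z), 0)
  # teacher one-hot limit vs uniform student over C classes -> log C
  C <- 6
  expect_equal(kd_class_loss(rep(0, C), c(1e5, rep(-1e5, C - 1)), tau = 1,
                             tau_square_rescale = FALSE),
               log(C), tolerance = 1e-6)
  set.seed(4)
  for (i in 1:50) {
    s <- rnorm(10); t <- rnorm(10)
    pt <- generalized_softmax(t, 10); ps <- generalized_softmax(s, 10)
    expect_equal(kd_class_loss(s, t, 10), 100 * sum(pt * log(pt / ps)),
                 tolerance = 1e-9)
  }
  expect_error(kd_class_loss(rnorm(3), rnorm(4)), "classes")
})

test_that("select_regions partitions anchors exactly like a brute-force scan", {
  cfg <- distill_config(alpha_pos = 0.7, gamma = 0.5)

  # gamma = 1: the VLR band [alpha, alpha) is empty for any input
  set.seed(5)
  a <- random_boxes(50); g <- random_boxes(3)
  r1 <- select_regions(a, g, distill_config(gamma = 1))
  expect_equal(sum(r1$region == "vlr"), 0L)

  # all scores below gamma*alpha -> both sets empty
  far_a <- boxes(0, 0, 1, 1)
  far_g <- boxes(60, 60, 63, 63)
  r2 <- select_regions(far_a, far_g, cfg)
  expect_true(all(r2$region == "none"))

  # empty gt: sentinel scores, empty regions
  r3 <- select_regions(a, boxes(numeric(), numeric(), numeric(), numeric()),
                       cfg)
  expect_true(all(r3$score == -1))
  expect_true(all(r3$region == "none"))

  # oracle equivalence: exhaustive double loop over anchors x gt
  for (rep in 1:20) {
    set.seed(600 + rep)
    anchors <- random_boxes(200)
    gt <- random_boxes(5)
    got <- select_regions(anchors, gt, cfg)
    for (k in seq_len(200)) {
      scores <- vapply(seq_len(5), function(j) diou(anchors[k, ], gt[j, ]),
                       numeric(1))
      xk <- max(scores)
      expect_equal(got$score[k], xk, tolerance = 1e-12)
      expect_equal(got$gt_index[k], which.max(scores))
      want <- if (xk >= 0.7) "main" else if (xk >= 0.35) "vlr" else "none"
      expect_identical(got$region[k], want)
    }
    expect_length(intersect(which(got$region == "main"),
                            which(got$region == "vlr")), 0L)
  }
})

test_that("select_regions is stable under anchor reordering", {
  set.seed(6)
  a <- random_boxes(80)
  g <- random_boxes(4)
  cfg <- distill_config(alpha_pos = 0.5, gamma = 0.6)
  r <- select_regions(a, g, cfg)
  perm <- sample(80)
  rp <- select_regions(a[perm, ], g, cfg)
  expect_equal(rp$score, r$score[perm])
  expect_identical(rp$region, r$region[perm])
})

test_that("total_distill_loss is the region-weighted sum of Eq-style terms", {
  set.seed(7)
  a <- random_boxes(30); g <- random_boxes(2)
  cfg <- distill_config(alpha_pos = 0.3, gamma = 0.3)
  assign <- select_regions(a, g, cfg)
  ld <- abs(rnorm(30))

  # weights zero -> detection loss alone
  cfg0 <- distill_config(lambda_main = 0, lambda_vlr = 0)
  expect_equal(total_distill_loss(1.5, ld, assign, cfg0), 1.5)

  # empty regions -> detection loss alone
  none <- select_regions(boxes(0, 0, 1, 1), boxes(50, 50, 60, 60), cfg)
  expect_equal(total_distill_loss(2.2, 0.7, none, cfg), 2.2)

  # hand summation with lambda = 1
  main <- which(assign$region == "main"); vlr <- which(assign$region == "vlr")
  expect_equal(total_distill_loss(0.4, ld, assign, distill_config()),
               0.4 + sum(ld[main]) + sum(ld[vlr]))

  # linear in the lambdas
  cfg_a <- distill_config(lambda_main = 2, lambda_vlr = 3)
  expect_equal(total_distill_loss(0, ld, assign, cfg_a),
               2 * sum(ld[main]) + 3 * sum(ld[vlr]))

  # missing LD values inside a region are rejected
  ld_na <- ld; ld_na[main[1]] <- NA
  if (length(main)) {
    expect_error(total_distill_loss(0, ld_na, assign, distill_config()),
                 "available")
  }
})

test_that("distill_config validates and round-trips through YAML", {
  expect_error(distill_config(temperature = 0), "temperature")
  expect_error(distill_config(gamma = 0), "gamma")
  expect_error(distill_config(alpha_pos = 1.2), "alpha_pos")
  expect_error(distill_config(lambda_main = -1), ">= 0")
  cfg <- distill_config(temperature = 5, gamma = 0.8)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(list(distill = cfg), path)
  back <- read_config(path)$distill
  expect_equal(unclass(back), unclass(cfg))
})
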