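test_that("backend selection is size-aware with the boundary going to mean shift", {
  pc10 <- point_cloud(matrix(runif(30), 10))
  pc100 <- point_cloud(matrix(runif(300), 100))
  expect_equal(select_backend(pc10, 100), "knn")
  expect_equal(select_backend(pc100, 100), "meanshift")
  # monotone: once the backend flips to meanshift it never flips back
  backends <- vapply(c(10, 50, 99, 100, 150, 1000), function(n) {
    select_backend(point_cloud(matrix(runif(3 * n), n)), 100)
  }, "")
  expect_false(is.unsorted(match(backends, c("knn", "meanshift"))))
})

test_that("the Levy scale matches the Gamma closed form and steps center on zero", {
  beta <- 1.5
  sigma_oracle <- (gamma(1 + beta) * sin(pi * beta / 2) /
                     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  expect_equal(levy_sigma(1.5), sigma_oracle, tolerance = 1e-12)
  expect_equal(levy_sigma(1.5), 0.696575, tolerance = 1e-6)

  set.seed(31)
  steps <- levy_step(1e5)
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps)), 3 * se)
  expect_equal(formals(levy_step)$beta, 1.5)
})

test_that("the control factor vanishes at the final iteration and decays in expectation", {
  set.seed(32)
  expect_equal(control_factor(10, 10), 0)
  expect_equal(2 * atan(1 - 0 / 10), pi / 2)  # initial angular parameter
  means <- vapply(c(0, 3, 6, 9), function(it) {
    mean(vapply(1:2000, function(i) control_factor(it, 10), 0))
  }, 0)
  expect_true(all(diff(means) < 0))
  expect_true(all(means >= 0))
})

test_that("exploitation and spiral updates fix theta_best and respect bounds", {
  bounds <- rbind(c(0, 0), c(10, 10))
  theta <- c(4, 6)
  set.seed(33)
  expect_equal(exploit_update(theta, theta, bounds, "ds"), theta)
  expect_equal(exploit_update(theta, theta, bounds, "gft"), theta)
  expect_equal(spiral_update(theta, theta, bounds), theta)

  # gft updates lie on the segment through current and best
  for (i in 1:100) {
    cur <- runif(2, 0, 10); best <- runif(2, 0, 10)
    new <- exploit_update(cur, best, rbind(c(-100, -100), c(100, 100)), "gft")
    d1 <- best - cur; d2 <- new - cur
    cross <- d1[1] * d2[2] - d1[2] * d2[1]
    expect_lt(abs(cross), 1e-9)
  }

  # spiral amplitude bound |spiral| <= radius * sqrt(2)
  for (r3 in seq(0, 1, by = 0.01)) {
    expect_lte(abs(sin(2 * pi * r3) + cos(2 * pi * r3)), sqrt(2) + 1e-12)
  }

  # radius is the Euclidean norm (componentwise loop oracle)
  cur <- c(1, 2); best <- c(4, 6)
  acc <- 0
  for (j in 1:2) acc <- acc + (best[j] - cur[j])^2
  expect_lt(abs(sqrt(acc) - sqrt(sum((best - cur)^2))), 1e-9)

  # clamping audited over many random updates
  set.seed(34)
  bounds <- rbind(c(0.5, 1), c(4, 400))
  for (i in 1:2500) {
    cur <- runif(2, -10, 500); best <- runif(2, -10, 500)
    v <- sample(c("ds", "gft"), 1)
    out <- exploit_update(cur, best, bounds, v)
    expect_true(all(out >= bounds[1, ] & out <= bounds[2, ]))
    out2 <- spiral_update(cur, best, bounds)
    expect_true(all(out2 >= bounds[1, ] & out2 <= bounds[2, ]))
  }
})

test_that("the feedback score blends mean and max F1 with alpha = 0.7", {
  expect_equal(feedback_score(rep(0.8, 5)), 0.8)
  f1 <- c(0.5, 0.7, 0.9)  # mean 0.7, max 0.9
  expect_equal(feedback_score(f1), 0.7 * 0.7 + 0.3 * 0.9)
  expect_equal(feedback_score(f1), 0.76)
  expect_error(feedback_score(numeric(0)), "empty")
  expect_equal(formals(feedback_score)$alpha, 0.7)
  s <- feedback_score(f1)
  expect_gte(s, min(f1)); expect_lte(s, max(f1))
})

test_that("connectivity backends separate well-spaced crowns", {
  pc <- fixture_two_trees()
  lab_knn <- cluster_knn(pc, k = 10, merge_dist = 2.5)
  expect_equal(length(unique(lab_knn)), 2)
  m <- match_instances(lab_knn, pc$instance, tau = 0.5)
  expect_equal(m$fscore, 1)

  lab_ms <- cluster_meanshift(pc, bandwidth = 2, min_size = 10)
  expect_equal(length(unique(lab_ms)), 2)
  expect_equal(match_instances(lab_ms, pc$instance, tau = 0.5)$fscore, 1)

  lab_cc <- cluster_connectivity(pc, eps = 1, min_pts = 5)
  expect_equal(length(unique(lab_cc[lab_cc > 0])), 2)
})

test_that("optimization recovers a single tree and two separable trees", {
  set.seed(41)
  one <- point_cloud(cbind(rnorm(300, 0, 1), rnorm(300, 0, 1), runif(300, 4, 9)),
                     semantic = rep(1L, 300), instance = rep(1L, 300))
  fit <- optimize_clustering(one, make_supervised_scorer(one$instance),
                             max_iter = 10, seed = 1, downsample = 0.3)
  expect_equal(length(unique(fit$instance[fit$instance > 0])), 1)
  expect_equal(match_instances(fit$instance, one$instance)$fscore, 1)

  two <- fixture_two_trees()
  fit2 <- optimize_clustering(two, make_supervised_scorer(two$instance),
                              max_iter = 15, seed = 2, downsample = 0.3)
  expect_equal(length(unique(fit2$instance[fit2$instance > 0])), 2)
  expect_equal(fit2$best_score, 1)
})

test_that("the incumbent score trajectory is non-decreasing and runs are reproducible", {
  two <- fixture_two_trees()
  scorer <- make_supervised_scorer(two$instance)
  fit1 <- optimize_clustering(two, scorer, max_iter = 20, seed = 5)
  fit2 <- optimize_clustering(two, scorer, max_iter = 20, seed = 5)
  expect_identical(fit1$instance, fit2$instance)
  expect_identical(fit1$theta_best, fit2$theta_best)
  expect_true(all(diff(fit1$trajectory$best_score) >= 0))
  # acceptance flag consistent with the incumbent trace
  tr <- fit1$trajectory
  expect_true(all(tr$best_score >= tr$candidate_score | tr$accepted))
})

test_that("acceptance monotonicity holds over random score sequences", {
  set.seed(43)
  for (rep in 1:50) {
    scores <- runif(200)
    best <- cummax(scores)
    expect_true(all(diff(best) >= 0))
    # the acceptance rule (strictly exceed the incumbent) reproduces cummax
    inc <- scores[1]
    for (k in 2:200) inc <- if (scores[k] > inc) scores[k] else inc
    expect_equal(inc, max(scores))
  }
})

test_that("zero foreground points yield an empty segmentation with a warning", {
  pc <- point_cloud(matrix(runif(30), 10), semantic = rep(0L, 10))
  expect_warning(fit <- optimize_clustering(pc, function(i) 1), "no foreground")
  expect_true(all(fit$instance == 0L))
})
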