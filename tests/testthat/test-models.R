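test_that("presets give the published layer shapes", {
  m1 <- init_mlp(mlp_spec("m1"), seed = 1)
  dims <- t(vapply(m1$w, dim, integer(2)))
  expect_equal(dims, cbind(c(2, 10, 10, 8, 5), c(10, 10, 8, 5, 2)))
  expect_equal(mlp_spec("m2")$widths, c(2, 8, 8, 4, 4, 2))
  expect_equal(mlp_spec("m3")$widths, c(2, 6, 8, 6, 2))
  expect_equal(mlp_spec("m3_wide")$widths, c(2, 6, 8, 8, 6, 2))
  expect_error(mlp_spec(widths = c(3, 4, 2)), "width")
})

test_that("Kaiming-uniform init has variance 2/fan_in, zero biases, seeded", {
  spec <- mlp_spec(widths = c(2, 1000, 60, 2))
  m <- init_mlp(spec, seed = 11)
  w <- m$w[[2]]  # fan_in = 1000
  expect_equal(nrow(w), 1000)
  v <- var(as.numeric(w))
  expect_lt(abs(v - 2 / 1000), 0.1 * 2 / 1000)
  b <- sqrt(6 / 1000)
  expect_lte(max(abs(w)), b)
  expect_true(all(vapply(m$b, function(x) all(x == 0), logical(1))))
  expect_identical(init_mlp(spec, seed = 11)$w, m$w)
  expect_false(identical(init_mlp(spec, seed = 12)$w[[1]], m$w[[1]]))
})

test_that("forward pass matches pencil-and-paper arithmetic on a 2-2-2 net", {
  m <- init_mlp(mlp_spec(widths = c(2, 2, 2)), seed = 1)
  m$w[[1]] <- matrix(c(1, 0.5, -1, 2), 2)    # columns = hidden neurons
  m$b[[1]] <- c(0.1, -0.2)
  m$w[[2]] <- matrix(c(0.3, -0.4, 1, 0.25), 2)
  m$b[[2]] <- c(0, 0.5)

  # x = (1, 2): hidden = relu(2.1, 2.8); logits = (-0.49, 3.3)
  p <- mlp_forward(m, c(1, 2))
  z <- c(-0.49, 3.3)
  expect_equal(as.numeric(p), exp(z) / sum(exp(z)), tolerance = 1e-12)

  # x = (-1, -1): hidden clips to (0, 0); logits = biases (0, 0.5)
  p2 <- mlp_forward(m, c(-1, -1))
  z2 <- c(0, 0.5)
  expect_equal(as.numeric(p2), exp(z2) / sum(exp(z2)), tolerance = 1e-12)
})

test_that("softmax outputs are probabilities for any weights", {
  set.seed(3)
  m <- init_mlp(mlp_spec("m1"), seed = 3)
  x <- matrix(rnorm(40), 20, 2)
  p <- mlp_forward(m, x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-9)

  # all-zero weights: indifferent (0.5, 0.5)
  m0 <- m
  m0$w <- lapply(m0$w, function(w) w * 0)
  expect_equal(as.numeric(mlp_forward(m0, c(1, -1))), c(0.5, 0.5))
})

test_that("analytic gradients match central finite differences", {
  set.seed(4)
  m <- init_mlp(mlp_spec(widths = c(2, 3, 2)), seed = 4)
  x <- matrix(rnorm(16), 8, 2)
  y <- fnirsbluff:::label_onehot(sample(c("lie", "truth"), 8, TRUE))
  g <- fnirsbluff:::mlp_gradients(m, x, y)
  loss_at <- function(model) {
    fnirsbluff:::cross_entropy(mlp_forward(model, x), y)
  }
  h <- 1e-6
  worst <- 0
  for (l in seq_along(m$w)) {
    for (i in seq_along(m$w[[l]])) {
      mp <- m; mp$w[[l]][i] <- mp$w[[l]][i] + h
      mm <- m; mm$w[[l]][i] <- mm$w[[l]][i] - h
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      an <- g$gw[[l]][i]
      worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
    }
    for (i in seq_along(m$b[[l]])) {
      mp <- m; mp$b[[l]][i] <- mp$b[[l]][i] + h
      mm <- m; mm$b[[l]][i] <- mm$b[[l]][i] - h
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
      worst <- max(worst, abs(fd - g$gb[[l]][i]) / max(abs(fd), 1e-8))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training is deterministic, runs 50 epochs, and fits separable data", {
  tab <- separable_table()
  cfg <- train_config(seed = 21)
  m <- train_mlp(init_mlp(mlp_spec("m3"), seed = 21), tab, cfg)
  expect_equal(nrow(m$history), 50)
  expect_lt(m$history$train_loss[50], m$history$train_loss[1])
  pred <- predict(m, tab)
  expect_equal(mean(pred$label == tab$label), 1)

  m2 <- train_mlp(init_mlp(mlp_spec("m3"), seed = 21), tab, cfg)
  expect_identical(m$w, m2$w)

  one_class <- tab[tab$label == "lie", ]
  expect_error(train_mlp(init_mlp(mlp_spec("m3"), seed = 1), one_class, cfg),
               "single class")
})

test_that("repeated training produces the configured number of distinct runs", {
  tab <- separable_table()
  runs <- train_mlp_repeated(mlp_spec("m3"), tab, train_config(seed = 31))
  expect_length(runs, 5)
  expect_false(identical(runs[[1]]$w, runs[[2]]$w))
  expect_true(all(vapply(runs, function(r) nrow(r$history) == 50, logical(1))))
})

test_that("label swap mirrors the decision function on wide-margin data", {
  tab <- separable_table()
  swapped <- tab
  swapped$label <- ifelse(tab$label == "lie", "truth", "lie")
  cfg <- train_config(seed = 8)
  m_orig <- train_mlp(init_mlp(mlp_spec("m3"), seed = 8), tab, cfg)
  m_swap <- train_mlp(init_mlp(mlp_spec("m3"), seed = 8), swapped, cfg)
  p1 <- predict(m_orig, tab)
  p2 <- predict(m_swap, tab)
  expect_true(all(p1$label != p2$label))
})

test_that("KNN with k = 1 memorizes its training points", {
  tab <- separable_table(n_per_class = 15)
  knn1 <- train_baseline(baseline_spec("knn", k = 1), tab)
  pred <- predict(knn1, tab)
  expect_equal(pred$label, tab$label)
  expect_true(all(pred$score %in% c(0, 1)))
})

test_that("linear SVM separates wide margins; quadratic kernel solves XOR", {
  tab <- separable_table()
  lin <- train_baseline("svm_linear", tab)
  expect_equal(mean(predict(lin, tab)$label == tab$label), 1)

  xtab <- xor_table()
  lin_xor <- train_baseline("svm_linear", xtab)
  quad_xor <- train_baseline("svm_quadratic", xtab)
  acc_lin <- mean(predict(lin_xor, xtab)$label == xtab$label)
  acc_quad <- mean(predict(quad_xor, xtab)$label == xtab$label)
  # a linear rule can carve off at most 3 of the 4 XOR corners (75%)
  expect_lte(acc_lin, 0.8)
  expect_gt(acc_quad, 0.9)
  expect_gt(acc_quad, acc_lin)
})

test_that("fitted SVM decision values equal the explicit polynomial kernel expansion", {
  tab <- xor_table()
  fit <- train_baseline("svm_quadratic", tab)$fit
  x <- as.matrix(tab[, c("sm", "ss")])
  new <- matrix(c(0.3, -0.8, -1.2, 0.9), 2, byrow = TRUE)
  # manual expansion: f(z) = sum_i a_i (sv_i . z + 1)^2 - rho
  sv <- as.matrix(fit$SV)
  coefs <- fit$coefs[, 1]
  manual <- apply(new, 1, function(z) {
    sum(coefs * (sv %*% z + 1)^2) - fit$rho
  })
  got <- attr(predict(fit, new, decision.values = TRUE),
              "decision.values")[, 1]
  expect_equal(unname(got), unname(manual), tolerance = 1e-9)
})

test_that("trees respect their complexity presets", {
  tab <- extract_features(simulate_experiment(sim_config(seed = 3)))
  simple <- train_baseline("tree_simple", tab)$fit
  complexx <- train_baseline("tree_complex", tab)$fit
  n_splits <- function(fit) sum(fit$frame$var != "<leaf>")
  expect_lte(n_splits(simple), 3)
  expect_gte(n_splits(complexx), n_splits(simple))
  expect_error(train_baseline("boosting", tab), "unknown baseline")
})
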