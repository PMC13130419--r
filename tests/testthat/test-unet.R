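test_that("parameter count matches the hand-computed closed form for a tiny net", {
  # levels = 1, base = 1, growth 2, 2 output channels, kernel 3:
  #   enc: conv 1->1 (27+1), conv 1->1 (28)
  #   bottleneck: conv 1->2 (54+2), conv 2->2 (108+2)
  #   dec: up-projection 1x1x1 2->1 (2+1), conv 2->1 (54+1), conv 1->1 (28)
  #   final 1x1x1: 1->2 (2+2); no deep-supervision heads at one level
  cfg <- unet_config(levels = 1, base_filters = 1, out_channels = 2)
  expect_equal(unet_param_count(cfg), 28 + 28 + 56 + 110 + 3 + 55 + 28 + 4)
  # doubling base filters roughly quadruples the parameter count
  r <- unet_param_count(unet_config(base_filters = 32)) /
    unet_param_count(unet_config(base_filters = 16))
  expect_gt(r, 3.5); expect_lt(r, 4.5)
  # count is a deterministic function of the configuration
  m <- build_unet(cfg)
  expect_equal(m$n_params, sum(vapply(seq_along(m$weights), function(i)
    length(m$weights[[i]]) + length(m$biases[[i]]), numeric(1))))
})

test_that("forward pass honours the shape contract and rejects bad grids", {
  ph <- fast_phantom(seed = 81)
  cfg <- unet_config(levels = 2, base_filters = 2, max_epochs = 1, patience = 0)
  m <- build_unet(cfg)
  m$code_table <- MUSCLE_CODES
  pred <- predict_unet(m, ph$dixon)
  expect_s3_class(pred, "label_map")
  expect_equal(dim(pred$labels), ph$dixon$geometry$shape)
  expect_true(all(unique(as.vector(pred$labels)) %in% 0:8))
  # a grid not divisible by 2^levels reports the required padding
  bad <- generate_phantom(phantom_spec(geom = geometry(c(30, 30, 10), c(2, 2, 3)),
                                       deformation_amplitude = 0))
  expect_error(predict_unet(build_unet(unet_config(levels = 3)), bad$dixon),
               "divisible|multiple")
})

test_that("analytic gradients match finite differences on a tiny network", {
  set.seed(7)
  cfg <- unet_config(levels = 2, base_filters = 2, out_channels = 3, seed = 2)
  m <- build_unet(cfg)
  vol <- array(runif(8 * 8 * 8), c(8, 8, 8))
  lab <- array(sample(0:2, 512, TRUE), c(8, 8, 8))
  storage.mode(lab) <- "integer"
  lg <- function(W, B, AW = m$aux_weights, AB = m$aux_biases, want = FALSE)
    ldq:::.unet_lossgrad_cpp(W, B, AW, AB, cfg, vol, lab, want)
  g <- lg(m$weights, m$biases, want = TRUE)
  # directional derivative along the analytic gradient: a small descent step
  # of size s must change the loss by about -s * ||g||^2
  gnorm2 <- sum(vapply(g$grad_weights, function(x) sum(x^2), 0)) +
    sum(vapply(g$grad_biases, function(x) sum(x^2), 0)) +
    sum(vapply(g$grad_aux_weights, function(x) sum(x^2), 0)) +
    sum(vapply(g$grad_aux_biases, function(x) sum(x^2), 0))
  s <- 0.002
  W2 <- lapply(seq_along(m$weights), function(i) m$weights[[i]] - s * g$grad_weights[[i]])
  B2 <- lapply(seq_along(m$biases), function(i) m$biases[[i]] - s * g$grad_biases[[i]])
  A2 <- lapply(seq_along(m$aux_weights), function(i)
    m$aux_weights[[i]] - s * g$grad_aux_weights[[i]])
  Ab2 <- lapply(seq_along(m$aux_biases), function(i)
    m$aux_biases[[i]] - s * g$grad_aux_biases[[i]])
  l2 <- lg(W2, B2, A2, Ab2)$loss
  expect_equal(l2 - g$loss, -s * gnorm2, tolerance = 0.1)
  # pointwise finite differences on a sample of weights
  for (li in c(1, 4, 8)) {
    q <- 5
    h <- 2e-3
    Wp <- m$weights; Wp[[li]][q] <- Wp[[li]][q] + h
    Wm <- m$weights; Wm[[li]][q] <- Wm[[li]][q] - h
    num <- (lg(Wp, m$biases)$loss - lg(Wm, m$biases)$loss) / (2 * h)
    expect_equal(g$grad_weights[[li]][q], num,
                 tolerance = max(0.05, 5e-5 / max(abs(num), 1e-8)))
  }
})

test_that("training overfits a simple volume and early stopping restores the best epoch", {
  # two-class sphere task: loss must drop steeply and Dice reach 1
  set.seed(1)
  n <- 16
  co <- (1:n) - 8.5
  d <- sqrt(outer(co^2, outer(co^2, co^2, "+"), "+"))
  lab <- array(as.integer(d < 5), c(n, n, n))
  vol <- array(0.3, c(n, n, n)); vol[lab == 1L] <- 1
  vol <- abs(vol + array(rnorm(n^3, 0, 0.02), c(n, n, n)))
  g <- geometry(c(n, n, n), c(1, 1, 1))
  dv <- dixon_volume(vol, vol / 2, vol / 2, g, "a")
  lm <- label_map(lab, g, c(FG = 1L))
  cfg <- unet_config(levels = 2, base_filters = 4, out_channels = 2,
                     lr = 0.01, max_epochs = 150, patience = 0, seed = 3)
  m <- build_unet(cfg)
  tr <- list(list(dixon = dv, labels = lm))
  va <- tr; va[[1]]$dixon$subject_id <- "val-copy"
  m <- train_unet(m, tr, va)
  expect_lt(m$history$train_loss[5], m$history$train_loss[1])
  expect_lt(m$history$train_loss[50], m$history$train_loss[5])
  expect_gte(dice(predict_unet(m, dv), lm, 1), 0.90)
  # determinism: identical history under the same seed
  m2 <- train_unet(build_unet(cfg), tr, va)
  expect_identical(m2$history, m$history)
  expect_equal(m$best_epoch, which.min(m$history$val_loss))
})

test_that("leakage guard blocks shared subjects between train and validation", {
  ph <- fast_phantom(seed = 91)
  s <- list(dixon = ph$dixon, labels = ph$labels)
  m <- build_unet(unet_config(levels = 1, base_filters = 1))
  expect_error(train_unet(m, list(s), list(s)), "leakage")
})

test_that("mc_cross_validate pools n_folds x n_val validation segmentations", {
  # structural test on a tiny configuration (2 folds x 2 validation)
  dataset <- lapply(1:5, function(s) {
    p <- fast_phantom(seed = 300 + s)
    list(dixon = p$dixon, labels = p$labels)
  })
  cfg <- unet_config(levels = 1, base_filters = 2, lr = 0.01,
                     max_epochs = 2, patience = 0)
  cv <- mc_cross_validate(dataset, n_folds = 3, n_val = 2, config = cfg,
                          seed = 4)
  expect_equal(length(cv$models), 3)
  expect_equal(sum(lengths(cv$predictions)), 6)
  expect_equal(nrow(cv$pooled), 6 * 8)
  for (f in cv$plan$folds) expect_length(f$train, 3)
})
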