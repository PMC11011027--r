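# Model assembly, loss closed forms, optimiser groups and schedule.

test_that("cross-entropy reproduces its closed forms and stays finite", {
  expect_equal(cross_entropy(rep(0.25, 4), c(0, 1, 0, 0)), log(4),
               tolerance = 1e-12)
  expect_equal(cross_entropy(c(0, 0, 1), 3), 0)
  expect_equal(cross_entropy(c(0.7, 0.2, 0.1), 1), -log(0.7),
               tolerance = 1e-12)
  # clamped log: zero probability at the true class stays finite
  expect_true(is.finite(cross_entropy(c(0, 0.5, 0.5), 1)))
  # batch form averages the per-row losses
  p <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  expect_equal(cross_entropy(p, c(1L, 2L)),
               mean(c(-log(0.7), -log(0.8))), tolerance = 1e-12)
})

test_that("softmax rows are normalised and descriptors are deterministic in eval mode", {
  set.seed(41)
  z <- matrix(rnorm(40, sd = 3), 8, 5)
  p <- tr$softmax_rows(z)
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
  model <- reid_model(4, profile = "micro", seed = 42)
  img <- array(runif(64 * 128 * 3), c(64, 128, 3))
  x <- tr$normalize_images(list(img, img))
  fw <- reid_forward(model, x)
  expect_equal(fw$descriptor[1, ], fw$descriptor[2, ], tolerance = 1e-12)
})

test_that("descriptor widths follow the ablation ladder", {
  # desk profile: stage-4 width 256, so concat descriptor is 512
  m_desk <- reid_model(4, profile = "desk", seed = 43)
  x <- array(0.2, c(64, 128, 3, 1))
  fw <- reid_forward(m_desk, x)
  expect_identical(ncol(fw$descriptor), 512L)
  expect_identical(ncol(fw$f_global), 256L)
  expect_identical(ncol(fw$f_local), 256L)
  rm(m_desk)
  # full profile: backbone-only 2048, + pyramid 2048, + local branch 4096
  dims <- c(backbone = NA_integer_, ifpm = NA_integer_, full = NA_integer_)
  cfgs <- list(backbone = c(FALSE, FALSE), ifpm = c(TRUE, FALSE),
               full = c(TRUE, TRUE))
  for (nm in names(cfgs)) {
    m <- reid_model(4, profile = "full", use_ifpm = cfgs[[nm]][1],
                    use_laem = cfgs[[nm]][2], seed = 44)
    fw <- reid_forward(m, array(0.1, c(64, 128, 3, 1)))
    dims[nm] <- ncol(fw$descriptor)
    rm(m, fw); gc(verbose = FALSE)
  }
  expect_identical(unname(dims), c(2048L, 2048L, 4096L))
})

test_that("unset or invalid label space raises a configuration error", {
  expect_error(reid_model(0, profile = "micro"), "n_classes")
  m <- reid_model(2, profile = "micro", seed = 45)
  ds <- list(images = list(array(0.5, c(64, 128, 3))), labels = 3L)
  expect_error(train_reid(m, ds, cfg = train_config(epochs = 1)), "labels")
  expect_error(train_reid(m, list(images = list(), labels = integer(0))),
               "empty")
})

test_that("optimiser keeps two rate groups under the step schedule", {
  cfg <- train_config()
  expect_equal(unname(lr_at_epoch(cfg, 99)), c(0.002, 0.02))
  expect_equal(unname(lr_at_epoch(cfg, 100)), c(0.0002, 0.002))
  expect_equal(unname(lr_at_epoch(cfg, 149)), c(0.0002, 0.002))
  cfg_flat <- train_config(lr_decay_factor = 1)
  expect_equal(lr_at_epoch(cfg_flat, 0), lr_at_epoch(cfg_flat, 140))
  model <- reid_model(3, profile = "micro", seed = 46)
  opt <- make_optimizer(model, cfg)
  groups <- vapply(opt$entries, function(e) e$group, character(1))
  expect_identical(sort(unique(groups)), c("base", "classifier"))
  # exactly the classifier weight matrix and bias sit in the fast group
  expect_identical(sum(groups == "classifier"), 2L)
})

test_that("a single SGD step on one example decreases its loss", {
  set.seed(47)
  model <- reid_model(3, profile = "micro", seed = 48)
  x <- array(rnorm(64 * 128 * 3, 0, 0.5), c(64, 128, 3, 1))
  y <- 2L
  loss_of <- function() {
    fw <- reid_forward(model, x, train = TRUE)
    cross_entropy(fw$probs, y)
  }
  cfg <- train_config(lr_base = 1e-3, lr_classifier = 1e-3, momentum = 0,
                      weight_decay = 0, epochs = 1, lr_decay_epoch = 1,
                      lr_decay_factor = 1)
  opt <- make_optimizer(model, cfg)
  tr$zero_model_grads(model)
  fw <- reid_forward(model, x, train = TRUE)
  l0 <- cross_entropy(fw$probs, y)
  dl <- fw$probs; dl[1, y] <- dl[1, y] - 1
  tr$reid_backward(model, dl)
  optimizer_step(opt, 0)
  expect_lt(loss_of(), l0)
})

test_that("identical inputs with distinct labels floor the loss at ln K", {
  # with identical rows the output distribution is shared, so the batch
  # cross-entropy is minimised by the uniform distribution at ln K
  set.seed(49)
  model <- reid_model(2, profile = "micro", seed = 50)
  img <- array(runif(64 * 128 * 3), c(64, 128, 3))
  ds <- list(images = list(img, img), labels = c(1L, 2L))
  cfg <- train_config(epochs = 5, batch_size = 2, aug_prob = 0,
                      lr_decay_epoch = 100, seed = 3)
  res <- train_reid(model, ds, cfg = cfg)
  expect_true(all(res$log$loss >= log(2) - 1e-9))
})
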