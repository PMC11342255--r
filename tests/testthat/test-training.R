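test_that("cohort splits are disjoint, exhaustive, reproducible and sized 6:2:2", {
  eco <- tiny_embedded_cohort(n_bags = 10)
  sp <- split_cohort(eco, c(6, 2, 2), seed = 3)
  sizes <- vapply(sp$indices, length, integer(1))
  expect_equal(unname(sizes), c(6L, 2L, 2L))
  all_idx <- sort(unname(unlist(sp$indices)))
  expect_equal(all_idx, 1:10)
  sp2 <- split_cohort(eco, c(6, 2, 2), seed = 3)
  expect_identical(sp$indices, sp2$indices)
  sp3 <- split_cohort(eco, c(6, 2, 2), seed = 4)
  expect_false(identical(sp$indices, sp3$indices))
})

test_that("stratified splits keep class proportions within one bag", {
  eco <- tiny_embedded_cohort(n_bags = 20)  # 10 per class
  for (seed in 1:5) {
    sp <- split_cohort(eco, c(6, 2, 2), seed = seed)
    for (part in c("train", "val", "test")) {
      labs <- eco$labels[sp$indices[[part]]]
      expect_lte(abs(sum(labs == 0) - sum(labs == 1)), 1)
    }
  }
  expect_error(split_cohort(eco, c(0, 0, 0)), "positive")
})

test_that("training is deterministic given the seed and inert at zero learning rate", {
  eco <- tiny_embedded_cohort(n_bags = 8, k = 4, d = 6, seed = 2)
  sp <- split_cohort(eco, c(2, 1, 1), seed = 1)
  cfg <- cme_config(embed_dim = 6, bag_size = 4)
  tc <- train_config(max_epochs = 5, patience = 5, batch_size = 8L, seed = 9)
  f1 <- cme_train(sp$train, sp$val, cfg, tc)
  f2 <- cme_train(sp$train, sp$val, cfg, tc)
  expect_identical(f1$history$epochs, f2$history$epochs)
  expect_identical(tcrmil:::params_flatten(f1$params),
                   tcrmil:::params_flatten(f2$params))
  ## lr = 0 and weight_decay = 0 leave the parameters untouched
  tc0 <- train_config(learning_rate = 0, weight_decay = 0, max_epochs = 3,
                      patience = 3, batch_size = 8L, seed = 9)
  p0 <- cme_params_init(cfg, seed = 9)
  f0 <- cme_train(sp$train, sp$val, cfg, tc0, init_params = p0)
  expect_equal(tcrmil:::params_flatten(f0$params),
               tcrmil:::params_flatten(p0), tolerance = 1e-12)
})

test_that("early stopping obeys the patience rule and never selects a later epoch", {
  eco <- tiny_embedded_cohort(n_bags = 8, k = 4, d = 6, seed = 3)
  sp <- split_cohort(eco, c(2, 1, 1), seed = 2)
  cfg <- cme_config(embed_dim = 6, bag_size = 4)
  ## patience 0: stops at the first epoch whose validation objective fails
  ## to improve on the running best
  f <- cme_train(sp$train, sp$val, cfg,
                 train_config(max_epochs = 50, patience = 0, batch_size = 8L, seed = 4))
  h <- f$history
  if (h$stop_reason == "early_stopping") {
    obj <- h$epochs$val_loss  # proxy: the stop epoch did not improve
    expect_lte(nrow(h$epochs), 50L)
  }
  expect_lte(h$best_epoch, nrow(h$epochs))
  ## a longer patience trains at least as many epochs
  f2 <- cme_train(sp$train, sp$val, cfg,
                  train_config(max_epochs = 50, patience = 10, batch_size = 8L, seed = 4))
  expect_gte(nrow(f2$history$epochs), nrow(f$history$epochs))
})

test_that("training reduces the training loss on a learnable toy problem", {
  ## two classes of bags with orthogonal constant embeddings: trivially separable
  set.seed(41)
  mk <- function(lab, n) {
    lapply(seq_len(n), function(i) {
      base <- if (lab == 1) c(2, rep(0, 5)) else c(0, 2, rep(0, 4))
      m <- matrix(rep(base, each = 10), 10, 6) + matrix(rnorm(60, sd = 0.1), 10, 6)
      eb <- pad_and_stack(list(m, m), k = 2, Lmax = 24)
      eb$label <- as.integer(lab); eb$sample_id <- sprintf("t%d_%d", lab, i)
      eb
    })
  }
  bags <- c(mk(1, 10), mk(0, 10))
  eco <- structure(list(bags = bags,
                        labels = vapply(bags, `[[`, integer(1), "label"),
                        sample_ids = vapply(bags, `[[`, character(1), "sample_id"),
                        fingerprint = list()), class = "embedded_cohort")
  sp <- split_cohort(eco, c(3, 1, 0), seed = 5)
  cfg <- cme_config(embed_dim = 6, bag_size = 2, dropout_rate = 0)
  fit <- cme_train(sp$train, sp$val, cfg,
                   train_config(max_epochs = 40, patience = 40, batch_size = 2L, seed = 6))
  h <- fit$history$epochs
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
  expect_gte(fit$val_metric, 0.9)  # separable toy reaches high validation AUC
})

test_that("restarts return the best validation metric and reduce to train() at 1", {
  eco <- tiny_embedded_cohort(n_bags = 8, k = 4, d = 6, seed = 7)
  sp <- split_cohort(eco, c(2, 1, 1), seed = 3)
  cfg <- cme_config(embed_dim = 6, bag_size = 4)
  tc <- train_config(max_epochs = 3, patience = 3, batch_size = 8L, seed = 11)
  single <- cme_train_restarts(sp$train, sp$val, cfg, tc, n_restarts = 1)
  tc_d <- tc; tc_d$seed <- tcrmil:::derive_seed(11L, 0L)
  direct <- cme_train(sp$train, sp$val, cfg, tc_d)
  expect_equal(single$val_metric, direct$val_metric)
  expect_identical(tcrmil:::params_flatten(single$params),
                   tcrmil:::params_flatten(direct$params))
  ## the winner attains the max across restart metrics; monotone in n
  multi <- cme_train_restarts(sp$train, sp$val, cfg, tc, n_restarts = 3)
  expect_equal(multi$val_metric, max(multi$restart_metrics))
  expect_gte(multi$val_metric, single$val_metric)
})

test_that("a rigged restart seed with better validation wins", {
  eco <- tiny_embedded_cohort(n_bags = 12, k = 4, d = 6, seed = 8)
  sp <- split_cohort(eco, c(2, 1, 1), seed = 4)
  cfg <- cme_config(embed_dim = 6, bag_size = 4)
  tc <- train_config(max_epochs = 4, patience = 4, batch_size = 8L)
  fit <- cme_train_restarts(sp$train, sp$val, cfg, tc, n_restarts = 2,
                            seeds = c(101L, 202L))
  expect_true(fit$best_seed %in% c(101L, 202L))
  m <- fit$restart_metrics
  expect_equal(fit$val_metric, max(m))
  ## explicit check against the two single runs
  tc1 <- tc; tc1$seed <- 101L
  tc2 <- tc; tc2$seed <- 202L
  r1 <- cme_train(sp$train, sp$val, cfg, tc1)
  r2 <- cme_train(sp$train, sp$val, cfg, tc2)
  want <- if (r2$val_metric > r1$val_metric) 202L else 101L
  expect_equal(fit$best_seed, want)
})

test_that("divergence is caught with a diagnostic", {
  eco <- tiny_embedded_cohort(n_bags = 4, k = 4, d = 6, seed = 9)
  sp <- split_cohort(eco, c(1, 1, 0), seed = 5)
  cfg <- cme_config(embed_dim = 6, bag_size = 4, dropout_rate = 0)
  p0 <- cme_params_init(cfg, seed = 1)
  p0$b_bag[] <- 1e400  # Inf bias forces a non-finite loss immediately
  expect_error(cme_train(sp$train, sp$val, cfg,
                         train_config(max_epochs = 2, patience = 2, batch_size = 8L),
                         init_params = p0),
               "diverged")
})

test_that("the tcrmil() modelling interface fits, predicts and exposes methods", {
  cfg <- sim_config(n_per_class = 8, clones_per_sample = 14, k = 10,
                    total_reads = 500, seed = 43)
  cohort <- generate_cohort(cfg)
  be <- mini_encoder(d_model = 8, n_layers = 1, n_heads = 2, seed = 3)
  fit <- tcrmil(cohort, backend = be,
                config = cme_config(bag_size = 10, embed_dim = 8),
                training = train_config(max_epochs = 6, patience = 6,
                                        batch_size = 20L, seed = 2))
  expect_s3_class(fit, "tcrmil")
  expect_output(print(fit), "CME repertoire classifier")
  expect_output(print(summary(fit)), "trainable parameters")
  expect_s3_class(coef(fit), "cme_params")
  expect_length(fitted(fit), fit$n_train)
  expect_length(residuals(fit), fit$n_train)
  pr <- predict(fit, cohort)
  expect_equal(nrow(pr), 16L)
  expect_true(all(pr$cancer_score > 0 & pr$cancer_score < 1))
  expect_equal(pr$health_score, 1 - pr$cancer_score)
  expect_equal(pr$decision, as.integer(pr$cancer_score > 0.5))
  ## score/class/health types agree with the response frame
  expect_equal(predict(fit, cohort, type = "score"), pr$cancer_score)
  expect_equal(predict(fit, cohort, type = "class"), pr$decision)
  ## checkpoints round-trip and predict identically
  f <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, f)
  back <- read_checkpoint(f)
  expect_equal(predict(back, cohort)$cancer_score, pr$cancer_score)
})

test_that("the multiclass variant trains, predicts valid classes and is deterministic", {
  cfg <- sim_config(n_per_class = 6, clones_per_sample = 25, k = 20,
                    n_classes = 3, seed = 9)
  cohort <- generate_cohort(cfg)
  be <- mini_encoder(d_model = 8, n_layers = 1, n_heads = 2, seed = 4)
  eco <- embed_cohort(cohort, be)
  parts <- split_cohort(eco, c(2, 1, 1), seed = 3)
  mc <- cme_config(embed_dim = 8, bag_size = 20, task = "multiclass", n_classes = 3)
  tc <- train_config(seed = 2, max_epochs = 8, batch_size = 40L)
  fit <- cme_train(parts$train, parts$val, mc, tc)
  cmp <- tcrmil:::cme_compile(parts$test, mc)
  ev <- tcrmil:::cme_eval(cmp, fit$params, mc)
  expect_true(all(ev$class %in% 0:2))
  expect_equal(dim(ev$probs), c(cmp$nb, 3L))
  expect_equal(rowSums(ev$probs), rep(1, cmp$nb), tolerance = 1e-12)
  em <- evaluate_multiclass(cmp$labels, ev$class, n_classes = 3)
  expect_equal(sum(em$confusion_matrix), cmp$nb)
  fit2 <- cme_train(parts$train, parts$val, mc, tc)
  expect_identical(tcrmil:::params_flatten(fit$params),
                   tcrmil:::params_flatten(fit2$params))
})
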