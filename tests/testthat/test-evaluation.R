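test_that("confusion counts scan positions correctly", {
  truth <- c("I", "N", "I", "N")
  expect_equal(confusion_counts(truth, truth)$fp, 0)
  expect_equal(confusion_counts(truth, truth)$fn, 0)
  allN <- rep("N", 4)
  cc <- confusion_counts(allN, truth)
  expect_equal(cc$tp, 0); expect_equal(cc$fp, 0); expect_equal(cc$fn, 2)
  expect_error(confusion_counts(c("I", "N"), truth), "length")
  set.seed(20)
  p <- sample(c("I", "N"), 30, TRUE); y <- sample(c("I", "N"), 30, TRUE)
  cc2 <- confusion_counts(p, y)
  expect_equal(cc2$tp, sum(p == "I" & y == "I"))
  expect_equal(cc2$tn, sum(p == "N" & y == "N"))
  expect_equal(cc2$tp + cc2$fn, sum(y == "I"))
})

test_that("metrics reproduce the published enhancement table to 3 decimals", {
  path <- system.file("extdata", "prescont_enhancement_planedimers.tsv",
                      package = "surfcrf")
  tab <- utils::read.delim(path, comment.char = "#")
  # fixed surface totals across every row: parsing self-test of the fixture
  expect_true(all(tab$tp + tab$fn == 3595))
  expect_true(all(tab$tn + tab$fp == 27327))
  met <- classification_metrics(tab)
  expect_equal(round(met$specificity, 3), tab$specificity)
  expect_equal(round(met$sensitivity, 3), tab$sensitivity)
  expect_equal(round(met$mcc, 3), tab$mcc)
  # the enhancer's sensitivity beats the matched threshold row at every theta
  wide <- split(tab, tab$theta)
  for (w in wide) {
    expect_gt(w$sensitivity[w$method == "enhance"],
              w$sensitivity[w$method == "prescont"])
  }
  # degenerate counts: no association
  expect_equal(classification_metrics(list(tp = 25, tn = 25, fp = 25, fn = 25))$mcc, 0)
  expect_true(is.na(classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 0))$sensitivity))
})

test_that("threshold prediction is strict and AUC is rank-based", {
  expect_true(all(threshold_predict(runif(10), 1) == "N"))
  expect_true(all(threshold_predict(runif(10) + 1e-6, 0) == "I"))
  expect_equal(threshold_predict(c(0.2, 0.5, 0.7), 0.5), c("N", "N", "I"))
  expect_equal(threshold_auc(rep(0.5, 10), rep(c("I", "N"), 5)), 0.5)
  expect_equal(threshold_auc(c(0.9, 0.8, 0.2, 0.1), c("I", "I", "N", "N")), 1)
  # oracle: trapezoid over the sweep of all distinct thresholds
  set.seed(33)
  sc <- round(runif(200), 2)
  y <- sample(c("I", "N"), 200, TRUE)
  sweep_auc <- local({
    ts <- sort(unique(c(-1e-9, sc, 1 + 1e-9)))
    pts <- t(vapply(ts, function(t) {
      p <- sc > t
      c(fpr = sum(p & y == "N") / sum(y == "N"),
        tpr = sum(p & y == "I") / sum(y == "I"))
    }, c(0, 0)))
    pts <- pts[order(pts[, 1], pts[, 2]), ]
    sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2)
  })
  expect_equal(threshold_auc(sc, y), sweep_auc, tolerance = 1e-12)
  # second independent route: pROC's rank AUC
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = sc, levels = c("N", "I"), direction = "<",
    quiet = TRUE)))
  expect_equal(threshold_auc(sc, y), proc_auc, tolerance = 1e-12)
  expect_true(is.na(threshold_auc(sc, rep("N", 200))))
})

test_that("surface AUC ratio is the plain quotient", {
  expect_equal(surface_auc_ratio(0.8, 0.8), 1)
  expect_equal(surface_auc_ratio(0.84, 0.80), 1.05)
})

test_that("matched-specificity search equals an exhaustive sweep", {
  set.seed(41)
  sc <- runif(100); y <- sample(c("I", "N"), 100, TRUE)
  res <- matched_specificity_threshold(sc, y, 0.9)
  # oracle sweep
  ts <- sort(unique(c(sc, -1, 2)))
  best <- NULL
  for (t in ts) {
    p <- sc > t
    spec <- sum(!p & y == "N") / sum(y == "N")
    sens <- sum(p & y == "I") / sum(y == "I")
    if (is.null(best) || abs(spec - 0.9) < abs(best$spec - 0.9) - 1e-12 ||
        (abs(spec - 0.9) <= abs(best$spec - 0.9) + 1e-12 && sens > best$sens)) {
      best <- list(spec = spec, sens = sens)
    }
  }
  expect_equal(res$specificity, best$spec)
  expect_equal(res$sensitivity, best$sens)
  # extremes
  expect_equal(matched_specificity_threshold(sc, y, 1)$specificity, 1)
  expect_equal(matched_specificity_threshold(sc, y, 0)$sensitivity, 1)
})

test_that("kappa operating points match plain decoding and brute force", {
  set.seed(52)
  ins <- instance_set(2, n = 10, seed = 13)
  model <- train_pcrf(instance_set(4, n = 30, seed = 14), train_config())
  roc <- enhancer_operating_points(model, ins, kappas = c(0.5, 1, 2))
  # kappa = 1 reproduces plain decoding's pooled counts
  cc1 <- purrr::map_dfr(ins, function(x) {
    pot <- build_potentials(model, x$scores, x$graph)
    confusion_counts(viterbi_decode(x$graph, pot)$labels, x$labels)
  }) |> dplyr::summarise(dplyr::across(dplyr::everything(), sum))
  row1 <- roc$points[roc$points$kappa == 1, c("tp", "tn", "fp", "fn")]
  expect_equal(as.data.frame(row1), as.data.frame(cc1))
  # every operating point matches exhaustive MAP decoding at that kappa
  for (k in c(0.5, 2)) {
    cck <- purrr::map_dfr(ins, function(x) {
      pot <- build_potentials(model, x$scores, x$graph, kappa = k)
      mapy <- brute_force_map(pot)$y
      confusion_counts(surfcrf:::.int2lab(mapy), x$labels)
    }) |> dplyr::summarise(dplyr::across(dplyr::everything(), sum))
    rowk <- roc$points[roc$points$kappa == k, c("tp", "tn", "fp", "fn")]
    expect_equal(as.data.frame(rowk), as.data.frame(cck))
  }
  expect_error(enhancer_operating_points(model, ins, kappas = numeric(0)),
               "empty")
})

test_that("perfectly separated scores give a perfect enhancer AUC", {
  ins <- lapply(1:3, function(k) {
    s <- synthetic_surface(40, 6, 0.25, seed = 70 + k)
    list(graph = s$graph, labels = s$labels,
         scores = ifelse(s$labels == "I", 0.95, 0.05))
  })
  model <- suppressWarnings(train_pcrf(ins, train_config(delta = 1)))
  roc <- enhancer_operating_points(model, ins, kappas = c(0.1, 1, 10))
  expect_equal(roc$auc, 1.0, tolerance = 1e-10)
})

test_that("enhance-above-theta refits bins on the surviving scores only", {
  ins <- instance_set(1, n = 40, seed = 17)[[1]]
  model <- train_pcrf(instance_set(4, n = 40, seed = 18), train_config())
  theta <- 0.5
  dec <- enhance_above(model, ins$graph, ins$scores, theta)
  expect_length(dec$labels, 40)
  # oracle: the node-characteristic bins equal a filtered fit_bins call
  z <- ifelse(ins$scores <= theta, 0, ins$scores)
  expected_bins <- suppressWarnings(fit_bins(z[z > 0], gamma = model$bins$score$n_bins))
  refit <- surfcrf:::.refit_spec(z[z > 0], model, "score")
  expect_equal(refit$boundaries[seq_along(expected_bins$boundaries)],
               expected_bins$boundaries)
  # theta below every score: identical to plain decoding with instance bins
  dec0 <- enhance_above(model, ins$graph, ins$scores, theta = 0)
  refit_model <- model
  refit_model$bins$score <- surfcrf:::.refit_spec(ins$scores, model, "score")
  ev <- as.matrix(ins$graph$edges[, c("i", "j")])
  for (ch in model$edge_characteristics) {
    f <- surfcrf:::.characteristic_registry$edge[[ch]]
    vals <- vapply(seq_len(nrow(ev)), function(k) f(ins$scores, ev[k, 1], ev[k, 2]), 0)
    refit_model$bins[[ch]] <- surfcrf:::.refit_spec(vals, model, ch)
  }
  plain <- viterbi_decode(ins$graph,
                          build_potentials(refit_model, ins$scores, ins$graph))
  expect_equal(dec0$labels, plain$labels)
  # theta = 1 zeroes everything
  expect_warning(d1 <- enhance_above(model, ins$graph, ins$scores, 1), "all-N")
  expect_true(all(d1$labels == "N"))
})

test_that("cross-validation folds are seeded, balanced and reproducible", {
  ins <- instance_set(7, n = 25, seed = 23)
  cv1 <- cross_validate(ins, k = 7, config = train_config(),
                        kappas = c(0.5, 1, 2), seed = 11)   # leave-one-out
  expect_equal(nrow(cv1$folds), 7)
  expect_true(all(cv1$folds$n_test == 1))
  cv2 <- cross_validate(ins, k = 3, config = train_config(),
                        kappas = c(0.5, 1, 2), seed = 11)
  expect_lte(diff(range(cv2$folds$n_test)), 1)
  cv3 <- cross_validate(ins, k = 3, config = train_config(),
                        kappas = c(0.5, 1, 2), seed = 11)
  expect_equal(cv2$folds, cv3$folds)
  expect_error(cross_validate(ins, k = 9, seed = 1), "exceed")
  expect_s3_class(glance(cv2), "tbl_df")
  expect_equal(tidy(cv2), cv2$folds)
})

test_that("metric identities hold on arbitrary counts", {
  set.seed(61)
  for (r in 1:25) {
    cc <- list(tp = rpois(1, 20), tn = rpois(1, 50),
               fp = rpois(1, 10), fn = rpois(1, 10))
    met <- classification_metrics(cc)
    if (!is.na(met$specificity)) expect_true(met$specificity >= 0 && met$specificity <= 1)
    if (!is.na(met$sensitivity)) expect_true(met$sensitivity >= 0 && met$sensitivity <= 1)
    if (!is.na(met$mcc)) {
      expect_true(met$mcc >= -1 && met$mcc <= 1)
      expect_equal(sign(met$mcc), sign(cc$tp * cc$tn - cc$fp * cc$fn))
    }
  }
})

test_that("roc autoplot returns a ggplot", {
  pts <- tibble::tibble(kappa = c(0.5, 1, 2), tp = c(1, 2, 3), tn = c(8, 7, 5),
                        fp = c(1, 2, 4), fn = c(3, 2, 1),
                        fpr = c(1, 2, 4) / 9, tpr = c(1, 2, 3) / 4)
  roc <- surfcrf:::new_roc_curve(pts, "kappa")
  expect_s3_class(ggplot2::autoplot(roc), "ggplot")
  expect_true(roc$auc >= 0 && roc$auc <= 1)
})
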