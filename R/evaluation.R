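#' Confusion counts over surface positions
#'
#' @param predicted,truth Character label vectors over `{"I","N"}` of equal
#'   length (surface positions only; the enhancer operates on the surface).
#' @return A tibble with one row: `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and true labelings differ in length")
  }
  p <- .lab2int(predicted); y <- .lab2int(truth)
  tibble::tibble(tp = sum(p == 1 & y == 1), tn = sum(p == 0 & y == 0),
                 fp = sum(p == 1 & y == 0), fn = sum(p == 0 & y == 1))
}

#' Specificity, sensitivity and Matthews correlation from counts
#'
#' `specificity = tn/(tn+fp)`, `sensitivity = tp/(tp+fn)`,
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. A metric
#' with a zero denominator is reported as `NA` (undefined), not an error.
#'
#' @param counts A one-row tibble (or list) with `tp`, `tn`, `fp`, `fn`.
#' @return A tibble with `specificity`, `sensitivity`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- ifelse(den > 0, (tp * tn - fp * fn) / sqrt(den), NA_real_)
  tibble::tibble(specificity = spec, sensitivity = sens, mcc = mcc)
}

#' Threshold predictor
#'
#' The baseline the enhancer is compared against: label `I` iff the score
#' strictly exceeds the threshold.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param t Threshold in `[0, 1]`.
#' @return Character label vector.
#' @export
threshold_predict <- function(scores, t) {
  stopifnot(t >= 0, t <= 1)
  .int2lab(as.integer(scores > t))
}

#' Rank-based AUC of the threshold predictor
#'
#' Mann-Whitney AUC of scores for interface versus non-interface residues
#' (midranks for ties): the probability that a random interface residue
#' outscores a random non-interface residue. Equals the trapezoid area under
#' the threshold predictor's ROC curve over all distinct thresholds.
#'
#' @param scores Pooled surface scores.
#' @param truth Pooled true labels over `{"I","N"}`.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
threshold_auc <- function(scores, truth) {
  y <- .lab2int(truth)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default kappa grid for the enhancer ROC sweep
#'
#' @param length_out Number of grid points.
#' @return Log-spaced positive values in `[1e-3, 1e3]`.
#' @export
kappa_grid <- function(length_out = 41L) {
  10^seq(-3, 3, length.out = length_out)
}

#' Operating points of the enhancer under kappa scaling
#'
#' For each `kappa`, rebuilds the potentials with the `(I,I)` edge entries
#' scaled by `kappa`, decodes every instance, pools the confusion counts and
#' records one (FPR, TPR) operating point. The curve is completed with
#' (0,0) and (1,1) and integrated by the trapezoid rule after sorting by FPR
#' (ties keep the larger TPR); no convex-hull correction is applied.
#'
#' @param model A fitted `pcrf_model`.
#' @param instances List of instances (`graph`, `scores`, `labels`).
#' @param kappas Positive kappa grid.
#' @param beam A [beam_config()] for decoding.
#' @return A `roc_curve`: list with `points` (tibble `kappa`, `fpr`, `tpr`,
#'   plus pooled counts) and `auc`.
#' @export
enhancer_operating_points <- function(model, instances, kappas = kappa_grid(),
                                      beam = beam_config()) {
  if (!length(kappas)) stop("empty kappa grid")
  stopifnot(all(kappas > 0))
  orders <- purrr::map(instances, ~ elimination_order(.x$graph)$order)
  pts <- purrr::map_dfr(kappas, function(k) {
    cc <- purrr::map2_dfr(instances, orders, function(ins, ord) {
      pot <- build_potentials(model, ins$scores, ins$graph, kappa = k)
      dec <- viterbi_decode(ins$graph, pot, beam = beam, order = ord)
      confusion_counts(dec$labels, ins$labels)
    }) |> dplyr::summarise(dplyr::across(dplyr::everything(), sum))
    dplyr::mutate(cc, kappa = k,
                  fpr = .data$fp / (.data$fp + .data$tn),
                  tpr = .data$tp / (.data$tp + .data$fn))
  })
  new_roc_curve(pts, parameter = "kappa")
}

new_roc_curve <- function(points, parameter) {
  pts <- dplyr::arrange(points, .data$fpr, dplyr::desc(.data$tpr))
  hull <- dplyr::bind_rows(tibble::tibble(fpr = 0, tpr = 0),
                           pts[, c("fpr", "tpr")],
                           tibble::tibble(fpr = 1, tpr = 1)) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  auc <- sum(diff(hull$fpr) * (utils::head(hull$tpr, -1) + utils::tail(hull$tpr, -1)) / 2)
  structure(list(points = points, hull = hull, auc = auc,
                 parameter = parameter),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", nrow(x$points), " operating points over ", x$parameter,
      ", AUC = ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' ROC curve plot
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$hull, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$points) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f (%s-parameterized)",
                                  object$auc, object$parameter)) +
    ggplot2::theme_minimal()
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' Surface AUC Ratio
#'
#' `Gamma = AUC_enhancer / AUC_threshold`, both restricted to surface
#' residues. A value above 1 means the enhancement was successful; the
#' larger, the greater the success.
#'
#' @param enhancer_auc,threshold_auc AUC values.
#' @return The ratio.
#' @export
surface_auc_ratio <- function(enhancer_auc, threshold_auc) {
  stopifnot(threshold_auc > 0)
  enhancer_auc / threshold_auc
}

#' Enhance above a score threshold
#'
#' For score distributions that are unimodal only above some threshold
#' `theta`: all scores `<= theta` are set to zero, the bin boundaries for
#' this decode are re-fitted excluding the zero-score residues, and all
#' surface residues are then re-labeled by the pCRF. Zeroed residues keep
#' their node features (evaluated at score 0, the lowest bin); only the bin
#' fitting ignores them.
#'
#' @param model A fitted `pcrf_model`.
#' @param graph A `surface_graph`.
#' @param scores Observation scores.
#' @param theta Threshold in `[0, 1]`.
#' @param kappa,beam Decoding options.
#' @return A `pcrf_decode`.
#' @export
enhance_above <- function(model, graph, scores, theta, kappa = 1,
                          beam = beam_config()) {
  stopifnot(theta >= 0, theta <= 1)
  z <- ifelse(scores <= theta, 0, scores)
  if (all(z == 0)) {
    warning("all scores zeroed at theta = ", theta, "; returning all-N")
    return(structure(list(labels = rep("N", n_positions(graph)),
                          score = 0, exact = TRUE, order = NULL),
                     class = "pcrf_decode"))
  }
  keep <- which(z > 0)
  refit <- model
  gamma <- model$bins[[model$node_characteristic]]$n_bins
  refit$bins[[model$node_characteristic]] <- .refit_spec(z[keep], model,
                                                         model$node_characteristic)
  ev <- as.matrix(graph$edges[, c("i", "j")])
  nz_edge <- if (nrow(ev)) which(z[ev[, 1]] > 0 & z[ev[, 2]] > 0) else integer(0)
  for (ch in model$edge_characteristics) {
    f <- .characteristic_registry$edge[[ch]]
    vals <- if (length(nz_edge)) {
      vapply(nz_edge, function(k) f(z, ev[k, 1], ev[k, 2]), 0)
    } else z[keep]
    refit$bins[[ch]] <- .refit_spec(vals, model, ch)
  }
  pot <- build_potentials(refit, z, graph, kappa = kappa)
  viterbi_decode(graph, pot, beam = beam)
}

# refit a bin spec at the model's nominal bin count, preserving weight-vector
# compatibility: collapsed boundaries are padded back so the spec keeps the
# weight layout (n_bins must match the trained vectors)
.refit_spec <- function(values, model, ch) {
  target <- model$bins[[ch]]$n_bins
  spec <- suppressWarnings(fit_bins(values, gamma = target))
  if (spec$n_bins < target) {
    # pad with epsilon-spaced boundaries above the largest to keep the layout;
    # the extra bins are simply never hit
    extra <- max(spec$boundaries) + seq_len(target - spec$n_bins) * 1e-9
    spec$boundaries <- c(spec$boundaries, extra)
    spec$n_bins <- target
  }
  spec
}

#' Threshold with specificity closest to a target
#'
#' Sweeps all distinct observed scores (plus sentinels below the minimum and
#' above the maximum) as thresholds and returns the one whose specificity is
#' closest to the target; ties prefer the higher sensitivity.
#'
#' @param scores Pooled scores.
#' @param truth Pooled true labels.
#' @param target Target specificity in `[0, 1]`.
#' @return A list with `t`, `specificity`, `sensitivity`.
#' @export
matched_specificity_threshold <- function(scores, truth, target) {
  stopifnot(target >= 0, target <= 1)
  y <- .lab2int(truth)
  cand <- sort(unique(c(scores, min(scores) - 1e-9, max(scores) + 1e-9, 0, 1)))
  cand <- cand[cand >= 0 - 1e-9]
  stats_at <- purrr::map_dfr(cand, function(t) {
    p <- as.integer(scores > t)
    tibble::tibble(t = t,
                   specificity = sum(p == 0 & y == 0) / max(1, sum(y == 0)),
                   sensitivity = sum(p == 1 & y == 1) / max(1, sum(y == 1)))
  })
  stats_at <- dplyr::arrange(stats_at, abs(.data$specificity - target),
                             dplyr::desc(.data$sensitivity))
  as.list(stats_at[1, ])
}

#' Cross-validated evaluation of the pCRF enhancer
#'
#' Partitions the instances into `k` folds by a seeded shuffle (instance
#' level, fold sizes differing by at most 1). Per fold: train on the other
#' `k - 1` folds, then on the held-out instances compute the pooled
#' threshold-predictor AUC, the kappa-parameterized enhancer ROC/AUC, the
#' Surface AUC Ratio, and the matched-specificity comparison of the plain
#' (`kappa = 1`) enhancer against thresholding. Pooled results recompute the
#' AUCs over all folds' test residues together; fold averages are also
#' reported.
#'
#' @param instances List of instances.
#' @param k Number of folds (default 5).
#' @param config A [train_config()].
#' @param kappas Kappa grid for the enhancer ROC.
#' @param beam Decoding beam.
#' @param seed Integer seed for the fold shuffle.
#' @return A `pcrf_cv`: list with `folds` (tibble of per-fold metrics),
#'   `pooled` (one-row tibble), and the pooled `roc` curve.
#' @export
cross_validate <- function(instances, k = 5, config = train_config(),
                           kappas = kappa_grid(), beam = beam_config(),
                           seed = 1) {
  m <- length(instances)
  if (k > m) stop("k = ", k, " folds exceed ", m, " instances")
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k), m))
  fold_rows <- list()
  pooled_pts <- list()
  pooled_scores <- numeric(0); pooled_truth <- character(0)
  pooled_enh <- character(0); pooled_enh_truth <- character(0)
  for (f in seq_len(k)) {
    train_ins <- instances[fold_of != f]
    test_ins <- instances[fold_of == f]
    model <- train_pcrf(train_ins, config)
    roc_f <- enhancer_operating_points(model, test_ins, kappas, beam)
    sc <- unlist(purrr::map(test_ins, "scores"))
    tr <- unlist(purrr::map(test_ins, "labels"))
    t_auc <- threshold_auc(sc, tr)
    # plain enhancer (kappa = 1) for the matched-specificity comparison
    enh <- purrr::map(test_ins, function(ins) {
      pot <- build_potentials(model, ins$scores, ins$graph, kappa = 1)
      viterbi_decode(ins$graph, pot, beam = beam)$labels
    })
    enh_lab <- unlist(enh)
    cc <- confusion_counts(enh_lab, tr)
    met <- classification_metrics(cc)
    match_t <- matched_specificity_threshold(sc, tr, met$specificity)
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n_test = length(test_ins)),
      cc, met,
      tibble::tibble(threshold_auc = t_auc, enhancer_auc = roc_f$auc,
                     gamma_ratio = surface_auc_ratio(roc_f$auc, t_auc),
                     matched_t = match_t$t,
                     matched_specificity = match_t$specificity,
                     matched_sensitivity = match_t$sensitivity))
    pooled_pts[[f]] <- roc_f$points
    pooled_scores <- c(pooled_scores, sc)
    pooled_truth <- c(pooled_truth, tr)
    pooled_enh <- c(pooled_enh, enh_lab)
  }
  folds <- dplyr::bind_rows(fold_rows)
  pooled_counts <- dplyr::bind_rows(pooled_pts) |>
    dplyr::group_by(.data$kappa) |>
    dplyr::summarise(dplyr::across(c("tp", "tn", "fp", "fn"), sum),
                     .groups = "drop") |>
    dplyr::mutate(fpr = .data$fp / (.data$fp + .data$tn),
                  tpr = .data$tp / (.data$tp + .data$fn))
  roc_pooled <- new_roc_curve(pooled_counts, parameter = "kappa")
  t_auc_pooled <- threshold_auc(pooled_scores, pooled_truth)
  cc_p <- confusion_counts(pooled_enh, pooled_truth)
  met_p <- classification_metrics(cc_p)
  match_p <- matched_specificity_threshold(pooled_scores, pooled_truth,
                                           met_p$specificity)
  pooled <- dplyr::bind_cols(
    cc_p, met_p,
    tibble::tibble(threshold_auc = t_auc_pooled, enhancer_auc = roc_pooled$auc,
                   gamma_ratio = surface_auc_ratio(roc_pooled$auc, t_auc_pooled),
                   mean_fold_gamma = mean(folds$gamma_ratio),
                   matched_t = match_p$t,
                   matched_specificity = match_p$specificity,
                   matched_sensitivity = match_p$sensitivity))
  structure(list(folds = folds, pooled = pooled, roc = roc_pooled,
                 k = k, seed = seed),
            class = "pcrf_cv")
}

#' @export
print.pcrf_cv <- function(x, ...) {
  cat("<pcrf_cv> ", x$k, "-fold cross-validation\n", sep = "")
  cat(sprintf("  pooled Surface AUC Ratio: %.4f (enhancer %.4f / threshold %.4f)\n",
              x$pooled$gamma_ratio, x$pooled$enhancer_auc, x$pooled$threshold_auc))
  cat(sprintf("  matched specificity %.4f: enhancer sensitivity %.4f vs threshold %.4f\n",
              x$pooled$specificity, x$pooled$sensitivity,
              x$pooled$matched_sensitivity))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `pcrf_cv`.
#' @param ... Unused.
#' @export
tidy.pcrf_cv <- function(x, ...) x$folds

#' @rdname cross_validate
#' @export
glance.pcrf_cv <- function(x, ...) x$pooled
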