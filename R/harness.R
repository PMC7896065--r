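#' Split a dataset manifest into training and test subsets
#'
#' Random 7:3 (by default) split, performed at source-image level: every
#' record whose `source_id` matches a source stays on that source's side,
#' so augmented derivatives never straddle the split (no augmented test
#' leakage). For manifests without derivatives the training side has
#' exactly `floor(ratio * n)` records; with derivatives, whole source
#' groups are assigned greedily until the training side reaches that
#' target.
#'
#' @param manifest data.frame; uses `source_id` if present (else each
#'   record is its own source).
#' @param ratio training fraction (scalar in (0,1)) or length-2 vector
#'   like `c(7, 3)`.
#' @param seed integer seed.
#' @return `list(train =, test =)` of disjoint, exhaustive row subsets.
#' @export
split_dataset <- function(manifest, ratio = c(7, 3), seed = 1L) {
  if (is.null(manifest) || nrow(manifest) == 0L) {
    stop("split_dataset: empty manifest", call. = FALSE)
  }
  r <- if (length(ratio) == 2L) ratio[1] / sum(ratio) else ratio
  stopifnot(r > 0, r < 1)
  src <- if (!is.null(manifest$source_id)) manifest$source_id
         else seq_len(nrow(manifest))
  n <- nrow(manifest)
  target <- floor(r * n)
  set.seed(seed)
  sources <- sample(unique(src))
  sizes <- table(src)[as.character(sources)]
  cum <- cumsum(sizes)
  n_train_sources <- sum(cum <= target)
  # greedy: add the next source if it gets us closer to the target
  if (n_train_sources < length(sources)) {
    reached <- if (n_train_sources == 0L) 0L else cum[n_train_sources]
    nxt <- cum[n_train_sources + 1L]
    if (abs(nxt - target) < abs(reached - target)) {
      n_train_sources <- n_train_sources + 1L
    }
  }
  train_src <- sources[seq_len(n_train_sources)]
  in_train <- src %in% train_src
  list(train = manifest[in_train, , drop = FALSE],
       test = manifest[!in_train, , drop = FALSE])
}

#' Confusion counts for binary diagnosis
#'
#' The abnormal (metastasis) class is positive: TP are abnormal images
#' predicted abnormal, TN normal predicted normal, FP normal predicted
#' abnormal, FN abnormal predicted normal.
#'
#' @param predictions,truths vectors of equal length (character, factor
#'   or logical with `TRUE` = positive).
#' @param positive the positive-class label (default `"metastasis"`;
#'   `"abnormal"` is treated as the same class).
#' @return A `confusion_counts` list: `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(predictions, truths, positive = "metastasis") {
  if (length(predictions) != length(truths)) {
    stop("confusion_counts: predictions and truths differ in length",
         call. = FALSE)
  }
  # positive iff the label equals `positive`, or either generic abnormal
  # alias when `positive` is one of them
  aliases <- unique(c(positive, if (positive %in% c("metastasis", "abnormal"))
    c("metastasis", "abnormal")))
  to_pos <- function(x) {
    if (is.logical(x)) x else tolower(as.character(x)) %in% tolower(aliases)
  }
  p <- to_pos(predictions); t <- to_pos(truths)
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' F-1 score from precision and recall
#'
#' `F1 = 2 * Prec * Rec / (Prec + Rec)` (harmonic mean).
#' @param prec,rec precision and recall in `[0, 1]`.
#' @return F-1 score; `NA` when both are zero.
#' @export
f1_score <- function(prec, rec) {
  ifelse(prec + rec == 0, NA_real_, 2 * prec * rec / (prec + rec))
}

#' Diagnostic metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall (sensitivity)
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F-1 (harmonic mean of
#' precision and recall) and false-positive rate `FP/(FP+TN)`. A metric
#' whose denominator is zero is reported as `NA` and listed in
#' `undefined` rather than raising an error. `fpr + spe = 1` whenever
#' both are defined.
#'
#' @param counts a [confusion_counts()].
#' @return A `metrics_report` list: `acc`, `prec`, `rec`, `spe`, `f1`,
#'   `fpr`, `counts`, `undefined`.
#' @export
metrics_report <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0L) stop("metrics_report: no evaluated images", call. = FALSE)
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    acc <- (TP + TN) / total
    prec <- safe(TP, TP + FP)
    rec <- safe(TP, TP + FN)
    spe <- safe(TN, TN + FP)
    fpr <- safe(FP, FP + TN)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
      f1_score(prec, rec)
    vals <- c(acc = acc, prec = prec, rec = rec, spe = spe, f1 = f1, fpr = fpr)
    structure(c(as.list(vals),
                list(counts = counts, undefined = names(vals)[is.na(vals)])),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("acc %.4f  prec %.4f  rec %.4f  spe %.4f  f1 %.4f  fpr %.4f\n",
              x$acc, x$prec, x$rec, x$spe, x$f1, x$fpr))
  invisible(x)
}

#' ROC curve and AUC
#'
#' The AUC is computed as the probability that a randomly chosen positive
#' image is scored higher than a randomly chosen negative one (ties count
#' one half), via midranks. The ROC curve sweeps the decision threshold
#' over the observed scores; its trapezoidal area equals the
#' rank-probability AUC to numerical precision.
#'
#' @param scores positive-class probabilities (higher = more abnormal).
#' @param truths labels; positive per `positive`.
#' @param positive positive-class label (logical truths also accepted).
#' @return A list: `auc` (rank probability), `auc_trapezoid`, and `roc`
#'   (data.frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truths, positive = "metastasis") {
  pos <- if (is.logical(truths)) truths else
    tolower(as.character(truths)) %in% tolower(c(positive, "abnormal"))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc: both classes must be present in the truth labels",
         call. = FALSE)
  }
  # rank-probability AUC with midranks (ties counted one half)
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1))
  roc <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  auc_trap <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, auc_trapezoid = auc_trap, roc = roc)
}

#' Train a classifier from an architecture spec
#'
#' Realizes the architecture with Gaussian initialization and trains it
#' end-to-end with mini-batch gradient descent (see [train_network()]).
#'
#' @param spec a `network_spec`.
#' @param images list of input matrices.
#' @param labels class labels.
#' @param config a [train_config()].
#' @param seed drives initialization and shuffling.
#' @return A trained `network` with `training_log`.
#' @export
train_classifier <- function(spec, images, labels, config = train_config(),
                             seed = 1L) {
  net <- build_network(spec, seed = seed)
  train_network(net, images, labels, config = config, seed = seed + 1L)
}

#' Evaluate a model repeatedly and average the metrics
#'
#' Runs the evaluation `repeats` times with a fresh seed per repetition
#' (each forwarded to `predict_fn`, which may use it for any stochastic
#' component: evaluation order, stochastic layers, or retraining when the
#' caller closes over a training routine). For a deterministic model all
#' repetitions are identical and the mean equals a single run. The
#' reported result for each metric is the average over the repetitions.
#'
#' @param predict_fn `function(images, seed)` returning a probability
#'   matrix with the positive class in column `positive_col`, or a vector
#'   of positive-class probabilities.
#' @param images list of test images.
#' @param truths test labels.
#' @param repeats number of repetitions (default 10).
#' @param seed base seed; repetition `i` receives `seed + i`.
#' @param positive positive-class label.
#' @param positive_col column of the probability matrix holding the
#'   positive class.
#' @param threshold decision threshold on the positive probability
#'   (argmax of the 2-way softmax = 0.5).
#' @return A list: `mean` (named metric means incl. `auc`), `sd`, `runs`
#'   (per-run data.frame), `undefined_runs` (count of runs with any
#'   undefined metric).
#' @export
repeat_evaluate <- function(predict_fn, images, truths, repeats = 10L,
                            seed = 1L, positive = "metastasis",
                            positive_col = 2L, threshold = 0.5) {
  stopifnot(repeats >= 1L)
  runs <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    scores <- predict_fn(images, seed + i)
    if (is.matrix(scores)) scores <- scores[, positive_col]
    pred <- scores >= threshold
    truth_pos <- if (is.logical(truths)) truths else
      tolower(as.character(truths)) %in% tolower(c(positive, "abnormal"))
    m <- metrics_report(confusion_counts(pred, truth_pos, positive = positive))
    auc <- roc_auc(scores, truth_pos, positive = positive)$auc
    runs[[i]] <- data.frame(run = i, acc = m$acc, prec = m$prec, rec = m$rec,
                            spe = m$spe, f1 = m$f1, fpr = m$fpr, auc = auc)
  }
  runs <- do.call(rbind, runs)
  metric_cols <- setdiff(names(runs), "run")
  list(mean = colMeans(runs[metric_cols]),
       sd = apply(runs[metric_cols], 2, stats::sd),
       runs = runs,
       undefined_runs = sum(!stats::complete.cases(runs)))
}

#' Published benchmark scores shipped with the package
#'
#' Test-set metrics reported from a clinical evaluation of this
#' classification pipeline family (seven classifiers on the original,
#' augmented-normalized and augmented datasets). Shipped to support the
#' metric-consistency audit: recomputing F-1 from each row's precision
#' and recall must reproduce the printed F-1.
#'
#' @return A data.frame: `dataset`, `classifier`, `acc`, `prec`, `rec`,
#'   `spe`, `f1`, `auc`.
#' @export
benchmark_scores <- function() {
  read.csv(system.file("extdata", "benchmark_metrics.csv",
                       package = "spectmets"), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Scaled-down end-to-end study on phantom crops
## ---------------------------------------------------------------------------

#' Generate a set of phantom thoracic crops for training experiments
#'
#' Generates `n` whole-body phantoms (half normal, half metastasized),
#' runs the full cropping pipeline on each, and downscales the 256 x 256
#' thoracic crops to `input_size` (block means), returning images scaled
#' to `[0, 1]` by the 16-bit range.
#'
#' @param n number of scans.
#' @param seed cohort seed.
#' @param input_size output image side.
#' @param normalize per-image min-max normalization of the crops
#'   (default); otherwise images are scaled by the 16-bit range.
#' @return `list(images =, labels =, manifest =)`.
#' @export
phantom_crop_set <- function(n = 300L, seed = 1L, input_size = 64L,
                             normalize = TRUE) {
  n_met <- n %/% 2L
  manifest <- generate_cohort(n - n_met, n_met, seed = seed)
  images <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    g <- cohort_scan(manifest, i)
    cp <- crop_pipeline(g$scan, crop_params(rng_seed = manifest$rng_seed[i]))
    m <- downscale_image(cp$thoracic, input_size)
    images[[i]] <- if (normalize) minmax_normalize(m) else m / 65535
  }
  list(images = images, labels = manifest$label, manifest = manifest)
}

#' Scaled-down end-to-end benchmark: reduced-width VGG-7 on phantom crops
#'
#' The desk-scale analogue of the full study: a reduced-width VGG-7 is
#' trained on 64 x 64, per-image min-max-normalized phantom thoracic
#' crops, with or without geometric augmentation of the training subset
#' (the augmented arm mirrors the augmented-dataset protocol: the test
#' subset is never augmented), and evaluated on the held-out 30%.
#' Both arms share the same cohort, split and preprocessing; they differ
#' only in the augmented training copies.
#'
#' @param seed experiment seed (cohort, split, initialization, shuffling).
#' @param augmented add one random augmented copy per training image.
#' @param n number of phantom scans.
#' @param input_size network input side.
#' @param width_multiplier channel-width reduction of VGG-7.
#' @param epochs,learning_rate,momentum training parameters for the
#'   scaled task.
#' @param data optional precomputed [phantom_crop_set()] (so the two arms
#'   can share one cohort).
#' @return A list: `metrics` (test [metrics_report()] values + `auc`),
#'   `model`, `n_train`, `n_test`.
#' @export
run_scaled_benchmark <- function(seed = 1L, augmented = FALSE, n = 300L,
                                 input_size = 64L, width_multiplier = 1 / 16,
                                 epochs = 35L, learning_rate = 0.01,
                                 momentum = 0.9, data = NULL) {
  if (is.null(data)) data <- phantom_crop_set(n, seed, input_size)
  manifest <- data$manifest
  manifest$source_id <- manifest$scan_id
  sp <- split_dataset(manifest, c(7, 3), seed = seed + 1000L)
  idx_train <- match(sp$train$scan_id, manifest$scan_id)
  idx_test <- match(sp$test$scan_id, manifest$scan_id)
  train_imgs <- data$images[idx_train]
  train_labels <- data$labels[idx_train]
  if (augmented) {
    # translation limits scaled to the reduced resolution (10/4 px at 256
    # is ~2/1 px at 64); rotation is resolution-free
    spec_aug <- augment_spec(t_T_horizontal = max(1L, round(10 * input_size / 256)),
                             t_T_vertical = max(1L, round(4 * input_size / 256)),
                             copies_per_image = 1L, rng_seed = seed + 2000L)
    # augmentation operates on dosage-scale images; these are already in
    # [0,1], so rotation runs in real-valued mode
    set.seed(spec_aug$rng_seed)
    extra <- lapply(train_imgs, function(m) {
      a <- random_augment_real(m, spec_aug)
      a$img
    })
    train_imgs <- c(train_imgs, extra)
    train_labels <- c(train_labels, train_labels)
  }
  spec <- build_vgg(7L, width_multiplier = width_multiplier,
                    input_shape = c(input_size, input_size, 1L))
  cfg <- train_config(learning_rate = learning_rate, batch_size = 32L,
                      epochs = epochs, momentum = momentum)
  model <- train_classifier(spec, train_imgs, factor(train_labels,
                              levels = c("metastasis", "normal")),
                            config = cfg, seed = seed + 3000L)
  probs <- predict_network(model, data$images[idx_test])
  # factor levels: column 1 = metastasis (positive)
  ev <- repeat_evaluate(function(images, s) probs, data$images[idx_test],
                        data$labels[idx_test], repeats = 1L, seed = seed,
                        positive_col = 1L)
  list(metrics = ev$mean, model = model,
       n_train = length(train_imgs), n_test = length(idx_test))
}

# real-valued variant of the augmentation chain (images already in [0,1])
random_augment_real <- function(m, spec) {
  ops <- character()
  if (runif(1) < spec$mirror_prob) { m <- mirror_image(m); ops <- c(ops, "mirror") }
  axis <- sample(c("horizontal", "vertical"), 1L)
  lim <- if (axis == "horizontal") spec$t_T_horizontal else spec$t_T_vertical
  t <- sample(0:lim, 1L) * sample(c(-1L, 1L), 1L)
  m2 <- matrix(0, nrow(m), ncol(m))
  if (axis == "horizontal") {
    src <- seq_len(ncol(m)) - t; ok <- src >= 1L & src <= ncol(m)
    m2[, which(ok)] <- m[, src[ok], drop = FALSE]
  } else {
    src <- seq_len(nrow(m)) - t; ok <- src >= 1L & src <= nrow(m)
    m2[which(ok), ] <- m[src[ok], , drop = FALSE]
  }
  r <- sample(0:spec$r_T, 1L) * sample(c(-1L, 1L), 1L)
  m2 <- rotate_image(m2, r, limit = spec$r_T, round_int = FALSE)
  list(img = m2, ops = paste(c(ops, sprintf("t(%s,%+d)", axis, t),
                               sprintf("r(%+d)", r)), collapse = ";"))
}
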