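# Evaluation metrics (ROC/AUC with bootstrap uncertainty, threshold
# confusion tables), the end-to-end training pipeline and the ablation
# harness comparing the full pipeline against its simplified variants and a
# random-forest baseline.

#' Area under the ROC curve
#'
#' The Mann-Whitney concordance probability: the probability that a
#' randomly chosen positive (staff) score exceeds a randomly chosen
#' negative (elderly) score, ties counting one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = positive class).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile 2.5/97.5 interval from a stratified bootstrap (resampling
#' within each class), seeded.
#'
#' @param scores,labels as in [roc_auc()].
#' @param n_boot bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return Numeric `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  labels <- as.integer(labels)
  if (n_boot < 100L) stop("`n_boot` must be at least 100", call. = FALSE)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  if (!length(i1) || !length(i0))
    stop("both classes must be present", call. = FALSE)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    roc_auc(scores[idx], labels[idx])
  }, 0))
  unname(stats::quantile(reps, c(0.025, 0.975)))
}

#' Confusion table at a threshold
#'
#' Counts of classified-staff / classified-elderly per (true status x
#' activity label) cell, using the inclusive `score >= tau` staff rule.
#'
#' @param scores probabilities of staff activity.
#' @param statuses true statuses (`"staff"` / `"elderly"`).
#' @param activities activity labels (`"single"`, `"multi"`, `"other"`).
#' @param tau threshold in `[0, 1]`.
#' @return A 2 x 6 integer matrix (rows classified staff/elderly, columns
#'   status x activity).
#' @export
confusion_at <- function(scores, statuses, activities, tau) {
  pred <- classify_scores(scores, tau)
  cols <- as.vector(outer(c("single", "multi", "other"),
                          c("staff", "elderly"),
                          function(a, s) paste(s, a, sep = ".")))
  truth <- paste(statuses, activities, sep = ".")
  m <- matrix(0L, 2L, length(cols),
              dimnames = list(c("classified_staff", "classified_elderly"),
                              cols))
  for (j in seq_along(cols)) {
    in_col <- truth == cols[j]
    m[1, j] <- sum(in_col & pred == "staff")
    m[2, j] <- sum(in_col & pred == "elderly")
  }
  m
}

roc_points <- function(scores, labels) {
  thr <- sort(unique(c(-Inf, scores, Inf)), decreasing = TRUE)
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[labels == 1] >= t), 0),
    fpr = vapply(thr, function(t) mean(scores[labels == 0] >= t), 0))
}

#' Evaluation report
#'
#' Global AUC with a bootstrap interval, per-activity ROC curves (staff vs
#' elderly within each activity label, where both occur), and confusion
#' tables at the requested thresholds.
#'
#' @param scores probabilities of staff activity.
#' @param statuses true statuses.
#' @param activities activity labels (`single` / `multi` / `other`).
#' @param taus thresholds for confusion tables (default 0.2 and 0.4).
#' @param n_boot bootstrap replicates for the AUC interval.
#' @param seed integer seed for the bootstrap.
#' @return An object of class `eval_report`.
#' @export
evaluate_scores <- function(scores, statuses, activities,
                            taus = c(0.2, 0.4), n_boot = 1000L, seed = 1L) {
  y <- as.integer(statuses == "staff")
  auc <- roc_auc(scores, y)
  ci <- auc_ci(scores, y, n_boot, seed)
  per_label <- lapply(c(single = "single", multi = "multi", other = "other"),
                      function(a) {
    sel <- activities == a
    if (length(unique(y[sel])) < 2L) return(NULL)
    list(auc = roc_auc(scores[sel], y[sel]),
         roc = roc_points(scores[sel], y[sel]))
  })
  conf <- lapply(stats::setNames(taus, paste0("tau_", taus)), function(tau)
    confusion_at(scores, statuses, activities, tau))
  structure(list(auc = auc, auc_ci = ci, per_label = per_label,
                 confusion = conf, n = length(scores), scores = scores,
                 statuses = statuses, activities = activities),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  AUC=%.3f (95%% CI %.3f-%.3f)\n",
              x$n, x$auc, x$auc_ci[1], x$auc_ci[2]))
  for (nm in names(x$per_label))
    if (!is.null(x$per_label[[nm]]))
      cat(sprintf("  %s walks AUC=%.3f\n", nm, x$per_label[[nm]]$auc))
  invisible(x)
}

# ---------------------------------------------------------------------------
# End-to-end pipeline

#' Pipeline configuration helper
#'
#' Desk-scale defaults for the staged training; the atom count (3), atom
#' duration (0.7 s), sparsity weight (5) and network schedule are the
#' method's published settings, while `dict_iters` and `max_epochs` control
#' how long the solvers run.
#'
#' @param m atoms (default 3).
#' @param atom_sec atom duration (default 0.7 s).
#' @param lam sparsity weight (default 5).
#' @param dict_iters dictionary-learning alternations (default 150).
#' @param spn_cfg,net_cfg [train_config()]s for the two networks.
#' @param tau decision threshold (default 0.4).
#' @param seed master seed.
#' @return A list, class `pipeline_config`.
#' @export
pipeline_config <- function(m = 3L, atom_sec = 0.7, lam = 5,
                            dict_iters = 150L, spn_cfg = NULL,
                            net_cfg = NULL, tau = 0.4, seed = 1L) {
  structure(list(
    m = m, atom_sec = atom_sec, lam = lam, dict_iters = dict_iters,
    spn_cfg = spn_cfg %||% train_config(max_epochs = 300L,
                                        seed = derive_seed(seed, 1L)),
    # the classifier stage: gradients of the per-signal cross-entropy are
    # O(1)-bounded (tanh trunk, sigmoid head), so the step-detection rate
    # of 1e-5 -- which acts on an anchor-summed loss two orders of
    # magnitude larger -- is replaced by an equivalent effective step size
    net_cfg = net_cfg %||% train_config(lr = 1e-3, max_epochs = 300L,
                                        seed = derive_seed(seed, 2L)),
    tau = tau, seed = as.integer(seed)), class = "pipeline_config")
}

pipeline_inputs <- function(ds) {
  monos <- lapply(ds$recordings, preprocess_recording)
  list(monos = monos,
       status = vapply(ds$recordings, function(r) r$annotation$person_status,
                       ""),
       event = vapply(ds$recordings, function(r) r$annotation$event_class,
                      ""),
       boxes = lapply(ds$recordings, function(r) r$annotation$step_boxes))
}

#' Fit the full staged pipeline
#'
#' (1) Preprocess every training recording to a mono signal; (2) learn the
#' step dictionary on the staff single walks (the signals that are almost
#' entirely walk related); (3) embed all signals by convolution with the
#' atoms; (4) train the step-proposal network on the embedded staff single
#' walks with their step boxes; (5) transfer and freeze its blocks into the
#' activity classifier and train on all signals (staff = 1, elderly = 0).
#'
#' @param train_ds a [floor_dataset()].
#' @param cfg a [pipeline_config()].
#' @return An object of class `activity_pipeline`.
#' @export
fit_pipeline <- function(train_ds, cfg = pipeline_config()) {
  pin <- pipeline_inputs(train_ds)
  is_dict <- pin$event == "walk_single" & pin$status == "staff"
  if (!any(is_dict)) stop("no staff single walks to learn the dictionary on",
                          call. = FALSE)
  fit <- learn_dictionary(pin$monos[is_dict], m = cfg$m,
                          atom_sec = cfg$atom_sec, lam = cfg$lam,
                          iters = cfg$dict_iters, seed = cfg$seed)
  dict <- fit$dictionary
  emb <- lapply(pin$monos, embed_signal, dict = dict)
  spn <- train_spn(emb[is_dict], pin$boxes[is_dict], cfg$spn_cfg)
  net <- build_activity_net(spn, cfg$net_cfg)
  emb_pad <- lapply(emb, pad_or_crop, target_len = cfg$net_cfg$input_len)
  net <- train_activity_net(net, emb_pad, as.integer(pin$status == "staff"),
                            cfg$net_cfg)
  structure(list(dict = dict, spn = spn, net = net, cfg = cfg),
            class = "activity_pipeline")
}

#' Score a dataset with a fitted pipeline
#'
#' @param pipe an [fit_pipeline()] result.
#' @param ds a [floor_dataset()].
#' @return Numeric vector of staff probabilities, one per recording.
#' @export
predict_pipeline <- function(pipe, ds) {
  monos <- lapply(ds$recordings, preprocess_recording)
  emb <- lapply(monos, embed_signal, dict = pipe$dict)
  emb <- lapply(emb, pad_or_crop, target_len = pipe$net$input_len)
  predict_activity(pipe$net, emb)
}

# ---------------------------------------------------------------------------
# Ablation harness

ABLATION_VARIANTS <- c("full", "no_spn_pretrain", "raw_cnn", "rf_baseline")

#' Train and evaluate one ablation variant
#'
#' Variants: `full` = the staged pipeline (dictionary embedding + frozen
#' pre-trained trunk); `no_spn_pretrain` = same architecture on embedded
#' input, all layers trainable from Gaussian init; `raw_cnn` = the
#' architecture applied to the raw preprocessed mono signal (1 input
#' channel), no embedding, no pre-training; `rf_baseline` = a random forest
#' on the flattened 3 x `input_len` embedded signal. All variants share the
#' identical train/test split derived from `seed` (paired comparison).
#'
#' @param variant one of `full`, `no_spn_pretrain`, `raw_cnn`,
#'   `rf_baseline`.
#' @param ds a [floor_dataset()].
#' @param cfg a [pipeline_config()].
#' @param seed split/bootstrap seed (default `cfg$seed`).
#' @param test_fraction held-out fraction (default 0.3).
#' @param ntree random-forest size (default 500).
#' @return A list with `test` and `all` [evaluate_scores()] reports plus
#'   `variant` and the test AUC `auc_test`.
#' @export
run_ablation <- function(variant, ds, cfg = pipeline_config(), seed = NULL,
                         test_fraction = 0.3, ntree = 500L) {
  variant <- match.arg(variant, ABLATION_VARIANTS)
  seed <- seed %||% cfg$seed
  sp <- stratified_split(ds, test_fraction, seed = derive_seed(seed, 11L))
  tr <- pipeline_inputs(sp$train)
  y_tr <- as.integer(tr$status == "staff")

  score_sets <- function(score_fn) {
    list(test = score_fn(sp$test), all = score_fn(ds))
  }

  if (variant == "full") {
    pipe <- fit_pipeline(sp$train, cfg)
    scores <- score_sets(function(d) predict_pipeline(pipe, d))
  } else if (variant == "no_spn_pretrain") {
    is_dict <- tr$event == "walk_single" & tr$status == "staff"
    fit <- learn_dictionary(tr$monos[is_dict], m = cfg$m,
                            atom_sec = cfg$atom_sec, lam = cfg$lam,
                            iters = cfg$dict_iters, seed = cfg$seed)
    emb <- lapply(tr$monos, embed_signal, dict = fit$dictionary)
    emb <- lapply(emb, pad_or_crop, target_len = cfg$net_cfg$input_len)
    net <- build_activity_net(NULL, cfg$net_cfg, in_ch = 3L)
    net <- train_activity_net(net, emb, y_tr, cfg$net_cfg)
    scores <- score_sets(function(d) {
      monos <- lapply(d$recordings, preprocess_recording)
      e <- lapply(monos, embed_signal, dict = fit$dictionary)
      predict_activity(net, lapply(e, pad_or_crop,
                                   target_len = net$input_len))
    })
  } else if (variant == "raw_cnn") {
    raw <- lapply(tr$monos, function(mv) matrix(mv$s, nrow = 1L))
    raw <- lapply(raw, pad_or_crop, target_len = cfg$net_cfg$input_len)
    net <- build_activity_net(NULL, cfg$net_cfg, in_ch = 1L)
    net <- train_activity_net(net, raw, y_tr, cfg$net_cfg)
    scores <- score_sets(function(d) {
      monos <- lapply(d$recordings, preprocess_recording)
      r <- lapply(monos, function(mv) matrix(mv$s, nrow = 1L))
      predict_activity(net, lapply(r, pad_or_crop,
                                   target_len = net$input_len))
    })
  } else {                                   # rf_baseline
    is_dict <- tr$event == "walk_single" & tr$status == "staff"
    fit <- learn_dictionary(tr$monos[is_dict], m = cfg$m,
                            atom_sec = cfg$atom_sec, lam = cfg$lam,
                            iters = cfg$dict_iters, seed = cfg$seed)
    featurise <- function(d) {
      monos <- lapply(d$recordings, preprocess_recording)
      e <- lapply(monos, embed_signal, dict = fit$dictionary)
      e <- lapply(e, pad_or_crop, target_len = cfg$net_cfg$input_len)
      do.call(rbind, lapply(e, function(x) as.vector(x$channels)))
    }
    X <- featurise(sp$train)
    rf <- with_seed(derive_seed(seed, 13L),
                    randomForest::randomForest(
                      x = X, y = factor(y_tr, levels = c(0, 1)),
                      ntree = ntree))
    scores <- score_sets(function(d)
      as.numeric(stats::predict(rf, featurise(d), type = "prob")[, "1"]))
  }

  rep_for <- function(d, s) {
    st <- vapply(d$recordings, function(r) r$annotation$person_status, "")
    ac <- activity_label(vapply(d$recordings,
                                function(r) r$annotation$event_class, ""))
    evaluate_scores(s, st, ac, seed = derive_seed(seed, 23L))
  }
  out <- list(variant = variant,
              test = rep_for(sp$test, scores$test),
              all = rep_for(ds, scores$all))
  out$auc_test <- out$test$auc
  out
}
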