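#' Pipeline configuration
#'
#' One document holding every stage's tunables, with defaults emulating a
#' short four-activity muscle-activity protocol (20 synthetic participants,
#' 70 s each). Round-trips through JSON serialization.
#'
#' @param profile `"pad"` (4 activities, 70 s) or `"gotov"` (16 activities).
#' @param n_recordings number of synthetic participants.
#' @param recording_seeds per-recording generator seeds (default
#'   `0:(n_recordings - 1)`).
#' @param seconds recording length for the gotov profile.
#' @param still_interval calibration still interval (s).
#' @param beta orientation filter gain.
#' @param bessel_order,bessel_cutoff physiological filter settings.
#' @param duration,overlap windowing settings.
#' @param tau pattern-decision threshold.
#' @param optimizer `"qda"` or `"ofnda"`.
#' @param classifier `"rls"`, `"laprls"` or `"nystrom"`.
#' @param labeled_fraction fraction of training windows whose labels the
#'   classifier may see.
#' @param test_fraction fraction of recordings held out (subject-wise split).
#' @param split_seed seed for the subject and label splits.
#' @param gamma_A,gamma_I,graph_k classifier settings.
#' @param exclude_impure drop training windows whose majority label covers
#'   less than 80 percent of samples.
#' @return A `phm_config` list.
#' @export
phm_config <- function(profile = "pad", n_recordings = 20,
                       recording_seeds = NULL, seconds = 320,
                       still_interval = c(0, 5), beta = 0.1,
                       bessel_order = 4, bessel_cutoff = 40,
                       duration = 2, overlap = 0.5, tau = PATTERN_TAU,
                       optimizer = "qda", classifier = "laprls",
                       labeled_fraction = 0.5, test_fraction = 0.3,
                       split_seed = 0, gamma_A = 1e-3, gamma_I = 1e-2,
                       graph_k = 7, exclude_impure = TRUE) {
  if (is.null(recording_seeds)) recording_seeds <- seq_len(n_recordings) - 1
  stopifnot(profile %in% c("pad", "gotov"),
            optimizer %in% c("qda", "ofnda"),
            classifier %in% c("rls", "laprls", "nystrom"))
  structure(as.list(environment()), class = "phm_config")
}

config_schedule <- function(config) {
  if (config$profile == "pad") pad_schedule() else gotov_schedule(config$seconds)
}

#' Build the featurized synthetic corpus for a configuration
#'
#' Runs simulate -> preprocess -> fuse -> window -> pattern decision for
#' every recording and pre-computes the split-independent feature blocks
#' (static MSST/HMRF features, kinematic Gaussian-field moments). DTW
#' features depend on the training template bank and are added per run.
#'
#' @param config a [phm_config()].
#' @param progress print per-recording progress.
#' @return A `phm_corpus` list.
#' @export
phm_corpus <- function(config = phm_config(), progress = FALSE) {
  schedule <- config_schedule(config)
  bspec <- bessel_spec(config$bessel_order, config$bessel_cutoff)
  recs <- lapply(config$recording_seeds, function(sd) {
    if (progress) message("recording seed ", sd)
    gen <- generate_recording(schedule, sensor_config(), seed = sd)
    pp <- preprocess_recording(gen$imu, gen$phy, config$still_interval,
                               beta = config$beta, bessel = bspec)
    fus <- fuse_streams(pp$imu, pp$phy)
    ws <- make_windows(fus, config$duration, config$overlap)
    ws <- decide_patterns(ws, tau = config$tau)
    regimes <- setNames(schedule$regime, schedule$activity)
    feats <- lapply(ws$windows, function(w) {
      if (identical(w$pattern, "kinematic"))
        list(kind = "kinematic",
             gmrf = gmrf_features(w$data, ws$channel_meta))
      else
        list(kind = "static",
             static = static_features(w, ws$channel_meta, ws$rate))
    })
    list(seed = sd, windows = ws, feats = feats,
         truth_regime = unname(regimes[vapply(ws$windows, `[[`,
                                              character(1), "label")]))
  })
  structure(list(recordings = recs, config = config,
                 schedule = schedule),
            class = "phm_corpus")
}

#' @export
print.phm_corpus <- function(x, ...) {
  nw <- sum(vapply(x$recordings, function(r) length(r$windows$windows),
                   numeric(1)))
  cat(sprintf("<phm_corpus> %d recordings (%s profile), %d windows\n",
              length(x$recordings), x$config$profile, nw))
  invisible(x)
}

# assemble the union feature table: pattern indicator + DTW block (kinematic
# rows) + GMRF block (kinematic rows) + MSST/HMRF block (static rows); the
# block a window's pattern does not own is structurally zero
assemble_features <- function(corpus, bank) {
  rows <- list(); meta <- list()
  dtw_names <- NULL; gmrf_names <- NULL; static_names <- NULL
  for (ri in seq_along(corpus$recordings)) {
    rec <- corpus$recordings[[ri]]
    ws <- rec$windows
    for (wi in seq_along(ws$windows)) {
      w <- ws$windows[[wi]]
      f <- rec$feats[[wi]]
      if (f$kind == "kinematic") {
        dtwf <- kinematic_dtw_block(w, bank, ws$channel_meta)
        if (is.null(dtw_names)) dtw_names <- names(dtwf)
        if (is.null(gmrf_names)) gmrf_names <- names(f$gmrf)
        rows[[length(rows) + 1L]] <- list(kin = c(dtwf, f$gmrf), sta = NULL)
      } else {
        if (is.null(static_names)) static_names <- names(f$static)
        rows[[length(rows) + 1L]] <- list(kin = NULL, sta = f$static)
      }
      meta[[length(meta) + 1L]] <- data.frame(
        recording = ri, window = wi, start = w$start, label = w$label,
        purity = w$purity, pattern = w$pattern,
        regime = rec$truth_regime[wi], stringsAsFactors = FALSE)
    }
  }
  kin_names <- c(dtw_names, gmrf_names)
  n <- length(rows)
  X <- matrix(0, n, 1 + length(kin_names) + length(static_names),
              dimnames = list(NULL, c("pattern_kinematic", kin_names,
                                      static_names)))
  for (i in seq_len(n)) {
    if (!is.null(rows[[i]]$kin)) {
      X[i, "pattern_kinematic"] <- 1
      X[i, kin_names] <- rows[[i]]$kin[kin_names]
    } else {
      X[i, static_names] <- rows[[i]]$sta[static_names]
    }
  }
  list(X = X, meta = do.call(rbind, meta))
}

kinematic_dtw_block <- function(w, bank, channel_meta) {
  gs <- lapply(window_group_series(w$data, channel_meta),
               function(s) decimate_series(zscore(s), bank$downsample))
  feats <- numeric(0)
  for (ch in bank$channels) for (act in bank$activities) {
    cost <- dtw(gs[[ch]], bank$bank[[ch]][[act]])$cost
    feats <- c(feats, setNames(cost, paste0("dtw.", ch, ".",
                                            gsub(" ", "_", act))))
  }
  feats
}

# median/MAD column standardization with clamping, fitted on training rows
robust_scaler <- function(Ztr, clamp = 4) {
  med <- apply(Ztr, 2, median)
  s <- apply(Ztr, 2, mad)
  s[!is.finite(s) | s < 1e-12] <- 1
  function(Z) {
    Zs <- sweep(sweep(Z, 2, med), 2, s, "/")
    pmin(pmax(Zs, -clamp), clamp)
  }
}

# stratified labeled subset: every class keeps at least two labeled windows
split_labels <- function(labels, fraction, seed) {
  with_seed(seed, {
    keep <- logical(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      k <- min(length(idx), max(2L, round(fraction * length(idx))))
      keep[sample(idx, k)] <- TRUE
    }
    keep
  })
}

#' Run the full pipeline for one configuration
#'
#' Orchestrates simulate -> preprocess -> fuse/window -> pattern decision ->
#' pattern-specific features -> optimization -> semi-supervised training ->
#' evaluation. Recordings are split subject-wise into train and test; within
#' the training windows only `labeled_fraction` of the labels are shown to
#' the optimizer and classifier, the rest enter the Laplacian as unlabeled
#' points. Kinematic and static feature tables are concatenated row-wise
#' with a pattern indicator column before optimization.
#'
#' @param config a [phm_config()].
#' @param corpus optional pre-built [phm_corpus()] (must match `config`'s
#'   generator settings); built on the fly if missing.
#' @param out_dir optional directory; when given, the feature table, pattern
#'   calls, evaluation report and a run manifest are written there.
#' @return A `phm_run` object: `report` (an `evaluation_report`), `split`
#'   bookkeeping, the fitted `model` and `optimizer` objects.
#' @export
phm_run <- function(config = phm_config(), corpus = NULL, out_dir = NULL) {
  if (is.null(corpus)) corpus <- phm_corpus(config)
  n_rec <- length(corpus$recordings)
  n_test <- max(1L, round(config$test_fraction * n_rec))
  test_rec <- with_seed(config$split_seed,
                        sort(sample.int(n_rec, n_test)))
  train_rec <- setdiff(seq_len(n_rec), test_rec)
  # template bank from labeled kinematic training windows only
  bank <- training_bank(corpus, train_rec, seed = config$split_seed)
  asm <- assemble_features(corpus, bank)
  X <- asm$X; meta <- asm$meta
  is_train <- meta$recording %in% train_rec
  trainable <- is_train &
    (!config$exclude_impure | meta$purity >= 0.8)
  lab_keep <- logical(nrow(meta))
  lab_keep[trainable] <- split_labels(meta$label[trainable],
                                      config$labeled_fraction,
                                      config$split_seed + 1L)
  X_lab <- X[lab_keep, , drop = FALSE]
  y_lab <- meta$label[lab_keep]
  X_unl <- X[trainable & !lab_keep, , drop = FALSE]
  X_test <- X[!is_train, , drop = FALSE]
  y_test <- meta$label[!is_train]
  # optimization branch
  if (config$optimizer == "qda") {
    opt <- fit_qda(X_lab, y_lab)
    tf <- function(M) qda_transform(opt, M)
  } else {
    opt <- fit_ofnda(X_lab, y_lab)
    tf <- function(M) ofnda_transform(opt, M)
  }
  Z_lab <- tf(X_lab); Z_unl <- tf(X_unl); Z_test <- tf(X_test)
  # robust-standardize the optimized features on training statistics:
  # discriminant scores are unbounded below (off-class Mahalanobis terms
  # explode), which would swamp the RBF kernel geometry
  sc <- robust_scaler(rbind(Z_lab, Z_unl))
  Z_lab <- sc(Z_lab); Z_unl <- sc(Z_unl); Z_test <- sc(Z_test)
  model <- switch(config$classifier,
    rls = fit_rls(Z_lab, y_lab, gamma_A = config$gamma_A),
    laprls = fit_laprls(Z_lab, y_lab, Z_unl, gamma_A = config$gamma_A,
                        gamma_I = config$gamma_I,
                        spec = graph_spec(config$graph_k)),
    nystrom = fit_nystrom_laprls(Z_lab, y_lab, Z_unl,
                                 gamma_A = config$gamma_A,
                                 gamma_I = config$gamma_I,
                                 spec = graph_spec(config$graph_k),
                                 seed = config$split_seed))
  pred <- predict(model, Z_test)
  report <- evaluate_predictions(pred$labels, y_test, pred$scores)
  # score RMSE on the unlabeled training partition: the semi-supervised
  # learning-curve quantity (how well the +/-1 targets are recovered on the
  # windows whose labels the classifier never saw)
  y_unl <- meta$label[trainable & !lab_keep]
  report$rmse_unlabeled <- if (length(y_unl)) {
    sc_unl <- predict(model, Z_unl)$scores
    Tg <- matrix(-1, length(y_unl), length(model$classes))
    colnames(Tg) <- model$classes
    for (cl in model$classes) Tg[y_unl == cl, cl] <- 1
    sqrt(mean((sc_unl[, model$classes, drop = FALSE] - Tg)^2))
  } else NA_real_
  run <- structure(list(report = report, model = model, optimizer = opt,
                        bank = bank, config = config,
                        split = list(train = train_rec, test = test_rec,
                                     n_labeled = sum(lab_keep),
                                     n_unlabeled = sum(trainable & !lab_keep),
                                     n_test = length(y_test)),
                        meta = meta),
                   class = "phm_run")
  if (!is.null(out_dir)) write_run_artifacts(run, asm, out_dir)
  run
}

training_bank <- function(corpus, train_rec, seed = 0) {
  first <- corpus$recordings[[train_rec[1]]]$windows
  pooled <- first
  pooled$windows <- do.call(c, lapply(train_rec, function(ri)
    corpus$recordings[[ri]]$windows$windows))
  build_template_bank(pooled, seed = seed)
}

write_run_artifacts <- function(run, asm, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cbind(asm$meta, asm$X), file.path(out_dir, "features.csv"),
            row.names = FALSE)
  write.csv(asm$meta[, c("start", "pattern", "regime")],
            file.path(out_dir, "pattern_calls.csv"), row.names = FALSE)
  rep <- run$report
  jsonlite::write_json(
    list(accuracy = rep$accuracy, macro_accuracy = rep$macro_accuracy,
         macro_precision = rep$macro_precision,
         macro_recall = rep$macro_recall, macro_f1 = rep$macro_f1,
         rmse = rep$rmse, rmse_unlabeled = rep$rmse_unlabeled,
         confusion = as.data.frame.matrix(rep$confusion)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  cfg <- run$config; class(cfg) <- NULL
  jsonlite::write_json(
    list(config = cfg, split = run$split,
         package_version = as.character(utils::packageVersion("harpipe"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.phm_run <- function(x, ...) {
  cat(sprintf("<phm_run> %s + %s | %d labeled / %d unlabeled train windows, %d test\n",
              x$config$optimizer, x$config$classifier, x$split$n_labeled,
              x$split$n_unlabeled, x$split$n_test))
  print(x$report)
  invisible(x)
}

#' Sweep the labeled fraction across algorithms
#'
#' For every (fraction, seed, algorithm) triple: split the labels, train,
#' and evaluate held-out accuracy plus the score RMSE on the unlabeled
#' training partition; aggregate mean and SD per (fraction, algorithm)
#' cell. Mirrors the learning-curve experiments that
#' probe semi-supervised behaviour as the labeled share grows.
#'
#' @param config a [phm_config()].
#' @param fractions labeled fractions in (0, 1).
#' @param seeds split seeds.
#' @param algorithms classifier subset to sweep.
#' @param corpus optional pre-built corpus.
#' @return Data frame with one row per (fraction, algorithm).
#' @export
sweep_labeled_fraction <- function(config = phm_config(),
                                   fractions = seq(0.1, 0.9, by = 0.2),
                                   seeds = 0:4,
                                   algorithms = c("rls", "laprls"),
                                   corpus = NULL) {
  stopifnot(all(fractions > 0 & fractions < 1))
  if (is.null(corpus)) corpus <- phm_corpus(config)
  rows <- list()
  for (fr in fractions) for (algo in algorithms) {
    accs <- c(); rmses <- c()
    for (sd in seeds) {
      cfg <- config
      cfg$labeled_fraction <- fr
      cfg$classifier <- algo
      cfg$split_seed <- sd
      run <- phm_run(cfg, corpus = corpus)
      accs <- c(accs, run$report$accuracy)
      rmses <- c(rmses, run$report$rmse_unlabeled)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      fraction = fr, algorithm = algo,
      mean_acc = mean(accs), sd_acc = sd(accs),
      mean_rmse = mean(rmses), sd_rmse = sd(rmses))
  }
  do.call(rbind, rows)
}
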