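# Full-study orchestration: generate (or load) a cohort, run every
# method x segmentation x speed x session cell under grouped CV, and build
# the between-method significance table.

#' Configure a full study
#'
#' @param protocol A [protocol_spec()].
#' @param truth A [ground_truth()] template (ignored when `recordings` is
#'   given).
#' @param bank A [filter_bank()] for the filter-bank methods.
#' @param broad_band Broadband filter for preprocessing and classic CSP.
#' @param n_pairs CSP pairs (per band for FBCSP / FBCSSP layer 1).
#' @param k_selected FBCSP features kept after mutual-information selection.
#' @param n_pairs_l2 FBCSSP layer-2 pairs.
#' @param methods Subset of `c("csp", "fbcsp", "fbcssp")`.
#' @param segmentations Subset of `c("tw0", "tw3")`.
#' @param tw0_window_s,tw0_overlap Sliding-window parameters.
#' @param tw3_start_s,tw3_end_s Static-crop interval (seconds from onset).
#' @param baseline_pseudo_s Baseline pseudo-trial length, seconds.
#' @param k_folds Cross-validation folds.
#' @param refit Refit the whole method (filters, selection, LDA) on the
#'   training groups of every fold (the full cross-trial protocol; default).
#'   With `refit = FALSE` spatial filters are fitted once per condition on
#'   all trials and only the LDA is cross-validated.
#' @param n_subjects Cohort size (synthetic mode).
#' @param seed Master seed; every random stage derives its seed from it.
#' @param recordings Optional list of subjects as returned by
#'   [generate_cohort()] (or built from [load_recordings()] output); when
#'   given, no data are simulated.
#' @param verbose Emit one progress line per condition.
#' @return A `study_config` list.
#' @export
study_config <- function(protocol = protocol_spec(),
                         truth = default_ground_truth(protocol),
                         bank = filter_bank(),
                         broad_band = mu_beta_band(),
                         n_pairs = 3, k_selected = 6, n_pairs_l2 = 3,
                         methods = c("csp", "fbcsp", "fbcssp"),
                         segmentations = c("tw0", "tw3"),
                         tw0_window_s = 1.0, tw0_overlap = 0.5,
                         tw3_start_s = 1.0, tw3_end_s = 6.0,
                         baseline_pseudo_s = 10,
                         k_folds = 5, n_subjects = 10, seed = 1L,
                         refit = TRUE,
                         recordings = NULL, verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  segmentations <- match.arg(segmentations, several.ok = TRUE)
  if (is.null(seed)) abort("a study seed is mandatory")
  validate_protocol_spec(protocol)
  structure(list(protocol = protocol, truth = truth, bank = bank,
                 broad_band = broad_band, n_pairs = n_pairs,
                 k_selected = k_selected, n_pairs_l2 = n_pairs_l2,
                 methods = methods, segmentations = segmentations,
                 tw0_window_s = tw0_window_s, tw0_overlap = tw0_overlap,
                 tw3_start_s = tw3_start_s, tw3_end_s = tw3_end_s,
                 baseline_pseudo_s = baseline_pseudo_s,
                 k_folds = k_folds, n_subjects = n_subjects,
                 seed = as.integer(seed), refit = isTRUE(refit),
                 recordings = recordings,
                 verbose = verbose),
            class = "study_config")
}

# preprocess one recording into per-segmentation, per-band trial sets
prepare_session_sets <- function(recording, config) {
  bands <- c(list(config$broad_band), config$bank$bands)
  per_band <- lapply(bands, function(b) {
    filt <- bandpass_zero_phase(recording, b)
    mi <- epoch_mi_trials(filt)
    base <- epoch_baseline(filt, config$baseline_pseudo_s)
    bind_trial_sets(mi, base)
  })
  out <- list()
  for (seg in config$segmentations) {
    out[[seg]] <- lapply(per_band, function(ts) {
      if (seg == "tw0") {
        segment_tw0(ts, config$tw0_window_s, config$tw0_overlap)
      } else {
        segment_tw3(ts, config$tw3_start_s, config$tw3_end_s)
      }
    })
  }
  out
}

# fit the requested method on (already filtered/segmented) trials
fit_condition_model <- function(method, broad_set, band_sets, config) {
  switch(method,
    csp = fit_csp_trials(broad_set, n_pairs = config$n_pairs),
    fbcsp = fit_fbcsp(broad_set, config$bank, n_pairs = config$n_pairs,
                      k_selected = config$k_selected, band_sets = band_sets),
    fbcssp = fit_fbcssp(broad_set, config$bank,
                        n_pairs_l1 = config$n_pairs,
                        n_pairs_l2 = config$n_pairs_l2,
                        band_sets = band_sets),
    abort("unknown method '%s'", method))
}

# fit the method once on all trials and extract its features
condition_features <- function(method, broad_set, band_sets, config) {
  model <- fit_condition_model(method, broad_set, band_sets, config)
  extract_features(model, broad_set, band_sets = band_sets)
}

#' Cross-trial validation with per-fold method refitting
#'
#' The full cross-trial protocol: folds partition trial groups (stratified
#' by class, seeded); in each fold the entire method — spatial filters,
#' feature selection, and the LDA — is fitted on the training groups only
#' and scored on the held-out groups, so no test trial influences any fitted
#' stage. Windows are scored individually; per-fold ACC/FPR are averaged
#' arithmetically.
#'
#' @param method `"csp"`, `"fbcsp"`, or `"fbcssp"`.
#' @param broad_set Broadband-filtered, segmented [trial_set()].
#' @param band_sets List of bank-band-filtered copies aligned with
#'   `config$bank$bands`.
#' @param config A [study_config()] (supplies `n_pairs`, `k_selected`,
#'   `n_pairs_l2`, `bank`).
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @return An `eval_result`, as from [cross_validate()].
#' @export
cross_validate_refit <- function(method, broad_set, band_sets, config,
                                 k = 5, seed = 1L) {
  fold_of_group <- make_group_folds(broad_set$groups, broad_set$labels,
                                    k, seed)
  row_fold <- fold_of_group[broad_set$groups]
  per_fold <- lapply(seq_len(k), function(f) {
    tr <- which(row_fold != f)
    te <- which(row_fold == f)
    broad_tr <- subset_trials(broad_set, tr)
    bands_tr <- lapply(band_sets, subset_trials, idx = tr)
    model <- fit_condition_model(method, broad_tr, bands_tr, config)
    feats_tr <- extract_features(model, broad_tr, band_sets = bands_tr)
    broad_te <- subset_trials(broad_set, te)
    bands_te <- lapply(band_sets, subset_trials, idx = te)
    feats_te <- extract_features(model, broad_te, band_sets = bands_te)
    lda <- fit_lda(feats_tr)
    pred <- predict(lda, feats_te)
    cnt <- confusion_counts(feats_te$label, pred, lda$positive_label)
    m <- confusion_metrics(cnt)
    data.frame(fold = f, acc = m[["ACC"]], fpr = m[["FPR"]],
               tp = cnt$TP, tn = cnt$TN, fp = cnt$FP, fn = cnt$FN)
  })
  per_fold <- do.call(rbind, per_fold)
  structure(list(per_fold = per_fold,
                 mean_acc = mean(per_fold$acc),
                 mean_fpr = mean(per_fold$fpr),
                 fold_of_group = fold_of_group,
                 k = as.integer(k),
                 seed = as.integer(seed)),
            class = "eval_result")
}

#' Run the full study
#'
#' For every subject and session: band-pass the recording (broadband for
#' CSP, per bank band for the filter-bank methods), epoch MI trials and
#' baseline pseudo-trials, apply each temporal segmentation, build the two
#' binary problems (baseline vs MI at each speed; both share the session's
#' baseline pseudo-trials), fit each method on the session's features and
#' evaluate it under grouped k-fold cross-validation. Finally the
#' between-method significance table is computed across subjects.
#'
#' @param config A [study_config()].
#' @return A `study_result`: `eval` (flat per-fold table), `significance`
#'   (comparison cells), `matrices` (per-session mark matrices),
#'   `erd_check` (realized generator attenuation per subject, synthetic mode
#'   only), `config`, `package_version`.
#' @export
run_study <- function(config) {
  subjects <- config$recordings
  erd_check <- NULL
  if (is.null(subjects)) {
    subjects <- generate_cohort(config$protocol, config$truth,
                                n_subjects = config$n_subjects,
                                base_seed = config$seed)
    erd_check <- t(vapply(subjects, function(s) {
      measure_ground_truth_erd(s$sessions[[1]], s$truth, config$protocol)
    }, numeric(length(config$protocol$speeds))))
  }
  speeds <- names(config$protocol$speeds)
  rows <- list()
  for (subj in subjects) {
    for (sess in subj$sessions) {
      sets <- prepare_session_sets(sess, config)
      for (seg in config$segmentations) {
        broad_all <- sets[[seg]][[1]]
        band_all <- sets[[seg]][-1]
        for (sp in speeds) {
          keep <- broad_all$labels == "baseline" |
            (broad_all$labels == "mi" & broad_all$speeds == sp)
          broad_set <- subset_trials(broad_all, keep)
          band_sets <- lapply(band_all, subset_trials, idx = keep)
          for (method in config$methods) {
            cv_seed <- derive_seed(config$seed, subj$subject_id,
                                   sess$session_id,
                                   match(seg, c("tw0", "tw3")),
                                   match(sp, speeds),
                                   match(method, c("csp", "fbcsp", "fbcssp")))
            res <- if (config$refit) {
              cross_validate_refit(method, broad_set, band_sets, config,
                                   k = config$k_folds, seed = cv_seed)
            } else {
              feats <- condition_features(method, broad_set, band_sets,
                                          config)
              cross_validate(feats, k = config$k_folds, seed = cv_seed)
            }
            if (isTRUE(config$verbose)) {
              message(sprintf(
                "subject %s session %s %s %s %s: ACC %.3f FPR %.3f",
                subj$subject_id, sess$session_id, seg, sp, method,
                res$mean_acc, res$mean_fpr))
            }
            rows[[length(rows) + 1L]] <- cbind(
              data.frame(subject = subj$subject_id,
                         session = sess$session_id,
                         method = method, segmentation = seg, speed = sp,
                         stringsAsFactors = FALSE),
              res$per_fold)
          }
        }
      }
    }
  }
  eval_rows <- do.call(rbind, rows)
  if (length(unique(eval_rows$subject)) >= 2 &&
      length(unique(eval_rows$method)) >= 2) {
    sig <- build_significance_table(eval_rows)
    matrices <- lapply(sort(unique(sig$session)), function(s) {
      render_significance_matrix(sig, s)
    })
    names(matrices) <- paste0("session", sort(unique(sig$session)))
  } else {
    sig <- NULL          # between-method tests need at least two subjects
    matrices <- NULL
  }
  structure(list(eval = eval_rows,
                 significance = sig,
                 matrices = matrices,
                 erd_check = erd_check,
                 config = config[setdiff(names(config), "recordings")],
                 package_version = as.character(utils::packageVersion("cspmi"))),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d eval rows | %d comparison cells\n",
              nrow(x$eval),
              if (is.null(x$significance)) 0L else nrow(x$significance)))
  agg <- stats::aggregate(cbind(acc, fpr) ~ method, data = x$eval, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-7s mean ACC %.3f  mean FPR %.3f\n",
                agg$method[i], agg$acc[i], agg$fpr[i]))
  }
  invisible(x)
}
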