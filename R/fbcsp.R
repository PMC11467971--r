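# Filter-bank CSP (with mutual-information feature selection) and the
# two-layer spatial-spectral variant (FBCSSP).

#' A bank of band-pass filters
#'
#' Default: the three sub-bands 8-15, 15-22 and 22-30 Hz covering the
#' sensorimotor mu and beta rhythms.
#'
#' @param bands List of [band_spec()] objects.
#' @export
filter_bank <- function(bands = list(band_spec(8, 15), band_spec(15, 22),
                                     band_spec(22, 30))) {
  if (length(bands) == 0) abort("filter bank must contain at least one band")
  for (b in bands) {
    if (!inherits(b, "band_spec")) abort("every bank entry must be a band_spec")
  }
  structure(list(bands = bands), class = "filter_bank")
}

# class pair used for fitting: (positive/MI first, baseline second) when
# present, otherwise the labels in order of first appearance.
infer_classes <- function(labels) {
  u <- unique(labels)
  if (length(u) != 2) abort("need exactly two classes, got: %s",
                            paste(u, collapse = ", "))
  if (all(c("mi", "baseline") %in% u)) c("mi", "baseline") else u
}

#' Fit a CSP model directly from an epoched trial set
#'
#' Convenience wrapper: estimates the two trace-normalized class covariances
#' with [class_covariance()] and calls [fit_csp()]. With `"mi"` and
#' `"baseline"` labels the MI class is class a.
#'
#' @param trials A two-class [trial_set()] (already filtered to the band of
#'   interest).
#' @param n_pairs Filter pairs to retain.
#' @param class_order Optional explicit class pair (a, b).
#' @param normalization Covariance normalization, `"trace"` (default) or
#'   `"none"`; see [class_covariance()].
#' @export
fit_csp_trials <- function(trials, n_pairs = 3, class_order = NULL,
                           normalization = "trace") {
  if (is.null(class_order)) class_order <- infer_classes(trials$labels)
  fit_csp(class_covariance(trials, class_order[1], normalization),
          class_covariance(trials, class_order[2], normalization),
          n_pairs = n_pairs, class_order = class_order)
}

# band-filter a trial set once per bank band
band_filter_sets <- function(trials, bank) {
  lapply(bank$bands, function(b) bandpass_zero_phase(trials, b))
}

#' Assemble a feature table
#'
#' @param features Numeric matrix, one row per trial/window.
#' @param labels,speeds,groups Per-row metadata.
#' @param feature_names Column names for the features.
#' @return A data frame (class `feature_table`) with the feature columns
#'   followed by `label`, `speed`, `group`.
#' @export
feature_table <- function(features, labels, speeds, groups,
                          feature_names = NULL) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) abort("feature table contains non-finite values")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- feature_names
  df <- data.frame(features, check.names = FALSE)
  df$label <- as.character(labels)
  df$speed <- as.character(speeds)
  df$group <- as.character(groups)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Numeric feature matrix of a feature table
#' @param ft A [feature_table()].
#' @export
feature_matrix <- function(ft) {
  as.matrix(ft[, setdiff(names(ft), c("label", "speed", "group")), drop = FALSE])
}

#' Mutual information between each feature and a binary label
#'
#' Plug-in estimate in bits: each feature is discretized into `bins`
#' equal-frequency bins (quantile breaks; degenerate features collapse to
#' fewer bins) and the empirical mutual information between bin index and
#' label is computed. A constant feature scores 0; a feature that copies a
#' balanced binary label scores 1 bit.
#'
#' @param features Numeric matrix or [feature_table()].
#' @param labels Binary label per row.
#' @param bins Number of equal-frequency bins.
#' @return Numeric vector of MI scores, one per feature column.
#' @export
mutual_information_scores <- function(features, labels, bins = 10) {
  if (inherits(features, "feature_table")) features <- feature_matrix(features)
  features <- as.matrix(features)
  if (nrow(features) < 2) abort("need at least two rows")
  if (length(unique(labels)) < 2) abort("label is constant; MI undefined")
  apply(features, 2, function(x) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                 names = FALSE, type = 7))
    if (length(br) < 2) return(0)
    bin <- cut(x, breaks = br, include.lowest = TRUE)
    p <- table(bin, labels) / length(x)
    prow <- rowSums(p)
    pcol <- colSums(p)
    terms <- p * log2(p / outer(prow, pcol))
    sum(terms[p > 0])
  })
}

#' Fit a filter-bank CSP model
#'
#' Per bank band: zero-phase band-pass the trials and fit a CSP; training
#' features are the per-band log-variance features concatenated across bands
#' (`n_bands * 2 * n_pairs` columns), of which the `k_selected` with the
#' highest mutual information with the class label are retained (ties broken
#' toward the lower column index).
#'
#' @param trials A two-class [trial_set()].
#' @param bank A [filter_bank()].
#' @param n_pairs CSP pairs per band.
#' @param k_selected Features kept by the mutual-information selection.
#' @param band_sets Optional list of already band-filtered copies of
#'   `trials`, aligned with `bank$bands` (lets callers filter at the
#'   recording level instead of per window).
#' @return An `fbcsp_model` with `per_band_models`, `selected_indices`,
#'   `mi_scores`, `bank`, `class_order`.
#' @export
fit_fbcsp <- function(trials, bank, n_pairs = 3, k_selected = 6,
                      band_sets = NULL) {
  class_order <- infer_classes(trials$labels)
  if (is.null(band_sets)) band_sets <- band_filter_sets(trials, bank)
  models <- lapply(band_sets, fit_csp_trials, n_pairs = n_pairs,
                   class_order = class_order)
  feats <- fb_feature_matrix(models, band_sets)
  n_feat <- ncol(feats)
  if (k_selected > n_feat) {
    abort("k_selected = %d exceeds the %d concatenated features",
          k_selected, n_feat)
  }
  mi <- mutual_information_scores(feats, trials$labels)
  sel <- order(-mi, seq_along(mi))[seq_len(k_selected)]
  structure(list(per_band_models = models,
                 selected_indices = sort(sel),
                 k_selected = as.integer(k_selected),
                 mi_scores = mi,
                 bank = bank,
                 class_order = class_order),
            class = "fbcsp_model")
}

# concatenated per-band log-variance features for aligned band sets
fb_feature_matrix <- function(models, band_sets) {
  n <- n_trials(band_sets[[1]])
  per_band <- lapply(seq_along(models), function(bi) {
    t(vapply(seq_len(n), function(i) {
      log_variance_features(
        apply_spatial_filter(models[[bi]], get_trial(band_sets[[bi]], i)))
    }, numeric(nrow(models[[bi]]$weights))))
  })
  out <- do.call(cbind, per_band)
  colnames(out) <- unlist(lapply(seq_along(models), function(bi) {
    sprintf("b%d_c%d", bi, seq_len(nrow(models[[bi]]$weights)))
  }))
  out
}

#' Fit a two-layer spatial-spectral (FBCSSP) model
#'
#' Layer 1 is the per-band CSP of the filter bank (no feature selection).
#' Every trial is band-filtered and projected per band and the projected
#' component signals are stacked into one surrogate trial
#' (`n_bands * 2 * n_pairs_l1` surrogate channels); layer 2 is a CSP fitted
#' on those surrogate trials. Features are the log-variance of the layer-2
#' output (`2 * n_pairs_l2` values).
#'
#' Layer 2 averages the surrogate covariances without per-trial trace
#' normalization: layer 1 already calibrates every component's scale
#' (`w' (Ca + Cb) w = 1`), and renormalizing per surrogate trial would
#' scramble the relative band powers layer 2 is meant to weigh. It also
#' makes the construction exactly consistent: with an invertible layer 1
#' the layer-2 eigenvalue spectrum equals the single-layer spectrum
#' computed under the same (unnormalized) covariance estimator.
#'
#' @param trials A two-class [trial_set()].
#' @param bank A [filter_bank()].
#' @param n_pairs_l1,n_pairs_l2 CSP pairs in layers 1 and 2.
#' @param band_sets Optional pre-filtered trial sets (see [fit_fbcsp()]).
#' @return An `fbcssp_model` with `layer1` (list of `csp_model`), `layer2`,
#'   `bank`, `class_order`.
#' @export
fit_fbcssp <- function(trials, bank, n_pairs_l1 = 3, n_pairs_l2 = 3,
                       band_sets = NULL) {
  class_order <- infer_classes(trials$labels)
  if (is.null(band_sets)) band_sets <- band_filter_sets(trials, bank)
  layer1 <- lapply(band_sets, fit_csp_trials, n_pairs = n_pairs_l1,
                   class_order = class_order)
  p_total <- sum(vapply(layer1, function(m) nrow(m$weights), numeric(1)))
  if (p_total < 2 * n_pairs_l2) {
    abort("stacked layer-1 output (%d) too small for %d layer-2 pairs",
          p_total, n_pairs_l2)
  }
  surrogate <- stack_projections(layer1, band_sets)
  layer2 <- fit_csp_trials(surrogate, n_pairs = n_pairs_l2,
                           class_order = class_order,
                           normalization = "none")
  structure(list(layer1 = layer1, layer2 = layer2, bank = bank,
                 class_order = class_order),
            class = "fbcssp_model")
}

# stack per-band layer-1 projections into a surrogate-channel trial set
stack_projections <- function(layer1, band_sets) {
  n <- n_trials(band_sets[[1]])
  t_len <- dim(band_sets[[1]]$trials)[3]
  p_each <- vapply(layer1, function(m) nrow(m$weights), numeric(1))
  arr <- array(NA_real_, c(n, sum(p_each), t_len))
  for (i in seq_len(n)) {
    at <- 0L
    for (bi in seq_along(layer1)) {
      proj <- apply_spatial_filter(layer1[[bi]], get_trial(band_sets[[bi]], i))
      arr[i, at + seq_len(p_each[bi]), ] <- proj
      at <- at + p_each[bi]
    }
  }
  ref <- band_sets[[1]]
  trial_set(arr, ref$labels, ref$speeds, ref$groups, ref$sampling_rate,
            ref$session_id, ref$subject_id, NULL)
}

#' Extract classifier features from a fitted spatial-filter model
#'
#' Uniform front end: runs the method-appropriate pipeline (band-filter ->
#' project -> log-variance -> select) per trial/window and returns one
#' feature row each, with labels, speeds and group ids carried through in
#' input order.
#'
#' @param model A `csp_model`, `fbcsp_model`, or `fbcssp_model`.
#' @param trials A [trial_set()]; for a `csp_model` it must already be
#'   filtered to the model's band.
#' @param band_sets Optional pre-filtered trial sets for the filter-bank
#'   models.
#' @return A [feature_table()].
#' @export
extract_features <- function(model, trials, band_sets = NULL) {
  UseMethod("extract_features")
}

#' @export
extract_features.csp_model <- function(model, trials, band_sets = NULL) {
  n <- n_trials(trials)
  f <- t(vapply(seq_len(n), function(i) {
    log_variance_features(apply_spatial_filter(model, get_trial(trials, i)))
  }, numeric(nrow(model$weights))))
  feature_table(f, trials$labels, trials$speeds, trials$groups,
                paste0("csp_c", seq_len(ncol(f))))
}

#' @export
extract_features.fbcsp_model <- function(model, trials, band_sets = NULL) {
  if (is.null(band_sets)) band_sets <- band_filter_sets(trials, model$bank)
  feats <- fb_feature_matrix(model$per_band_models, band_sets)
  feature_table(feats[, model$selected_indices, drop = FALSE],
                trials$labels, trials$speeds, trials$groups,
                colnames(feats)[model$selected_indices])
}

#' @export
extract_features.fbcssp_model <- function(model, trials, band_sets = NULL) {
  if (is.null(band_sets)) band_sets <- band_filter_sets(trials, model$bank)
  surrogate <- stack_projections(model$layer1, band_sets)
  n <- n_trials(surrogate)
  f <- t(vapply(seq_len(n), function(i) {
    log_variance_features(
      apply_spatial_filter(model$layer2, get_trial(surrogate, i)))
  }, numeric(nrow(model$layer2$weights))))
  feature_table(f, trials$labels, trials$speeds, trials$groups,
                paste0("cssp_c", seq_len(ncol(f))))
}

#' @export
extract_features.default <- function(model, trials, band_sets = NULL) {
  abort("extract_features: model of class '%s' is not a fitted spatial-filter model",
        paste(class(model), collapse = "/"))
}
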