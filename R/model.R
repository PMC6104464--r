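# Multivariate modelling protocol: Spearman-gated feature reduction,
# stratified 72/13-style splits, leave-one-out gmean assessment over
# repeated sessions, stepwise backward network selection and the final
# averaged ensemble.

#' Tie-aware Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. A constant vector has undefined rank
#' correlation; 0 is returned with attribute `undefined = TRUE`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (max(x) - min(x) < 1e-15 || max(y) - min(y) < 1e-15) {
    return(structure(0, undefined = TRUE))
  }
  cor(rank(x), rank(y))
}

#' @param p_threshold univariate significance gate (default 0.01).
#' @param rho_threshold redundancy gate on |Spearman rho| vs already
#'   selected features (default 0.85).
#' @rdname reduce_features
#' @export
reduction_config <- function(p_threshold = 0.01, rho_threshold = 0.85) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            rho_threshold > 0, rho_threshold <= 1)
  structure(list(p_threshold = p_threshold, rho_threshold = rho_threshold),
            class = "reduction_config")
}

#' Spearman-gated greedy feature reduction
#'
#' Starting from the feature with the smallest univariate p-value (and
#' largest AUC on ties), features are admitted in order of increasing
#' p-value if they pass the significance gate (`p <= p_threshold`) and are
#' not redundant with any already-selected feature
#' (`max |rho| < rho_threshold`).
#'
#' @param univariate a [screen_all()] result (sorted by p-value).
#' @param cohort the cohort the statistics were computed on (for the
#'   correlations).
#' @param config a [reduction_config()].
#' @return character vector of selected feature names, in admission order
#'   (empty, with a warning, if nothing passes the gate).
#' @export
reduce_features <- function(univariate, cohort,
                            config = reduction_config()) {
  u <- as.data.frame(univariate)
  u <- u[order(u$p_value, -u$auc, u$feature), ]
  u <- u[u$p_value <= config$p_threshold & !u$constant, , drop = FALSE]
  if (!nrow(u)) {
    warning("no feature passes p <= ", config$p_threshold)
    return(character(0))
  }
  fm <- cohort_features(cohort)
  selected <- u$feature[1]
  for (f in u$feature[-1]) {
    rhos <- vapply(selected, function(s) abs(spearman(fm[, f], fm[, s])),
                   numeric(1))
    if (max(rhos) < config$rho_threshold) selected <- c(selected, f)
  }
  selected
}

#' Stratified training/validation split
#'
#' Splits a cohort of exactly `train_n + val_n` patients so that the
#' positive-class percentage is maintained in both parts: the validation
#' set receives `round(val_n * prevalence)` positives (at least 1 left to
#' each side when possible) and the remainder goes to training.
#' Reproducible from `seed`.
#'
#' @param cohort the cohort to split.
#' @param train_n,val_n part sizes (default 72/13).
#' @param seed integer seed.
#' @return `list(train=, validation=)` of cohorts.
#' @export
make_split <- function(cohort, train_n = 72, val_n = 13, seed = 1) {
  n <- nrow(cohort)
  if (n != train_n + val_n) {
    stop("cohort size ", n, " != train_n + val_n = ", train_n + val_n)
  }
  y <- cohort$ln_histology
  n_pos <- sum(y == 1)
  if (n_pos == 0 || n_pos == n) stop("both classes required for a split")
  val_pos <- floor(val_n * n_pos / n + 0.5)
  val_pos <- min(max(val_pos, 0), n_pos)
  if (n_pos - val_pos < 1) val_pos <- n_pos - 1  # keep a positive in training
  val_neg <- val_n - val_pos
  if ((n - n_pos) - val_neg < 1) {
    val_neg <- (n - n_pos) - 1
    val_pos <- val_n - val_neg
  }
  with_seed_local(seed, {
    vi <- c(sample(which(y == 1), val_pos), sample(which(y == 0), val_neg))
    list(train = cohort[-vi, , drop = FALSE],
         validation = cohort[vi, , drop = FALSE])
  })
}

#' Geometric mean of sensitivity and specificity
#'
#' @param sens,spec rates in `[0, 1]`.
#' @return `sqrt(sens * spec)`.
#' @export
gmean <- function(sens, spec) sqrt(sens * spec)

#' Leave-one-out gmean assessment of a network specification
#'
#' Per session: every patient is held out in turn, the remaining patients
#' are split into stratified training and validation parts (72/13 for an
#' 86-patient cohort), a network is trained and the held-out patient is
#' classified; the session's confusion gives sensitivity, specificity and
#' their geometric mean. Mean and sd over `n_sessions` sessions are
#' reported; each session re-seeds both the split and the initialization.
#'
#' @param cohort a cohort with extracted features.
#' @param spec a [model_spec()].
#' @param n_sessions number of LOO sessions (default 20).
#' @param seed master seed.
#' @param val_frac validation share of each fold's remaining patients
#'   (default 13/85).
#' @param max_epochs,patience passed to [train_network()].
#' @return `list(mean=, sd=, sessions=)` where `mean`/`sd` are named
#'   vectors over `sensitivity`, `specificity`, `gmean`.
#' @export
loo_gmean <- function(cohort, spec, n_sessions = 20, seed = 1,
                      val_frac = 13 / 85, max_epochs = 500, patience = 25) {
  n <- nrow(cohort)
  y <- cohort$ln_histology
  if (length(unique(y)) < 2) stop("cohort must contain both classes")
  val_n <- max(2L, floor((n - 1) * val_frac + 0.5))
  session_seeds <- with_seed_local(seed,
                                   sample.int(.Machine$integer.max - 1L,
                                              n_sessions))
  sessions <- lapply(seq_len(n_sessions), function(s) {
    fold_seeds <- with_seed_local(session_seeds[s],
                                  sample.int(.Machine$integer.max - 1L,
                                             2L * n))
    pred <- integer(n)
    for (i in seq_len(n)) {
      rest <- cohort[-i, , drop = FALSE]
      sp <- make_split(rest, train_n = nrow(rest) - val_n, val_n = val_n,
                       seed = fold_seeds[2 * i - 1])
      net <- train_network(sp$train, sp$validation, spec,
                           seed = fold_seeds[2 * i],
                           max_epochs = max_epochs, patience = patience)
      pred[i] <- predict(net, cohort[i, , drop = FALSE], type = "class")
    }
    rep_ <- confusion(pred, y)
    c(sensitivity = rep_$sensitivity, specificity = rep_$specificity,
      gmean = rep_$gmean)
  })
  m <- do.call(rbind, sessions)
  list(mean = colMeans(m), sd = apply(m, 2, sd), sessions = m)
}

#' Stepwise backward model selection
#'
#' Starting from the full candidate feature set, every single-feature
#' removal is evaluated at every hidden-layer size via [loo_gmean()]; the
#' best configuration is kept and removal continues while the mean gmean
#' strictly improves. Ties break toward fewer inputs, then fewer neurons,
#' then lexicographically smaller feature sets.
#'
#' @param cohort a cohort with extracted features.
#' @param candidate_features character vector (e.g. from
#'   [reduce_features()]).
#' @param hidden_options hidden-layer sizes to assess (default `2:5`).
#' @param positive_weight passed to [model_spec()].
#' @param ... passed to [loo_gmean()] (`n_sessions`, `seed`, `max_epochs`,
#'   `patience`).
#' @return the selected [model_spec()], with attribute `"gmean"` (its mean
#'   LOO gmean) and `"trace"` (the evaluation log).
#' @export
select_model <- function(cohort, candidate_features, hidden_options = 2:5,
                         positive_weight = 4, ...) {
  stopifnot(length(candidate_features) >= 1)
  evaluate <- function(features, h) {
    spec <- model_spec(features, hidden_neurons = h,
                       positive_weight = positive_weight)
    loo_gmean(cohort, spec, ...)$mean[["gmean"]]
  }
  trace <- list()
  score_set <- function(feature_sets) {
    grid <- expand.grid(fs = seq_along(feature_sets), h = hidden_options)
    res <- vapply(seq_len(nrow(grid)), function(r) {
      evaluate(feature_sets[[grid$fs[r]]], grid$h[r])
    }, numeric(1))
    ord <- order(-res,
                 lengths(feature_sets)[grid$fs],
                 grid$h,
                 vapply(feature_sets[grid$fs],
                        function(f) paste(sort(f), collapse = ","),
                        character(1)))
    trace[[length(trace) + 1]] <<- data.frame(
      features = vapply(feature_sets[grid$fs], paste, character(1),
                        collapse = "+"),
      hidden = grid$h, gmean = res)
    list(features = feature_sets[[grid$fs[ord[1]]]],
         h = grid$h[ord[1]], gmean = res[ord[1]])
  }
  current <- score_set(list(candidate_features))
  repeat {
    if (length(current$features) <= 1) break
    removals <- lapply(seq_along(current$features),
                       function(i) current$features[-i])
    cand <- score_set(removals)
    if (cand$gmean > current$gmean + 1e-12) current <- cand else break
  }
  spec <- model_spec(current$features, hidden_neurons = current$h,
                     positive_weight = positive_weight)
  attr(spec, "gmean") <- current$gmean
  attr(spec, "trace") <- do.call(rbind, trace)
  spec
}

#' Train the final averaged network ensemble
#'
#' The selected network is trained `n_runs` times on the whole cohort, each
#' run on a fresh seeded stratified training/validation subdivision; the
#' ensemble output for a patient is the mean of the member outputs,
#' thresholded at `spec$output_threshold`.
#'
#' @param cohort the full training cohort.
#' @param spec a [model_spec()].
#' @param n_runs ensemble size (default 200).
#' @param seed master seed.
#' @param val_frac validation share of the cohort per run (default 13/86).
#' @param max_epochs,patience passed to [train_network()].
#' @return an object of class `rad_ensemble` with `predict()`, `print()`
#'   and `summary()` methods.
#' @export
train_final_ensemble <- function(cohort, spec, n_runs = 200, seed = 1,
                                 val_frac = 13 / 86, max_epochs = 500,
                                 patience = 25) {
  n <- nrow(cohort)
  val_n <- max(2L, floor(n * val_frac + 0.5))
  run_seeds <- with_seed_local(seed,
                               sample.int(.Machine$integer.max - 1L,
                                          2L * n_runs))
  members <- lapply(seq_len(n_runs), function(r) {
    sp <- make_split(cohort, train_n = n - val_n, val_n = val_n,
                     seed = run_seeds[2 * r - 1])
    train_network(sp$train, sp$validation, spec, seed = run_seeds[2 * r],
                  max_epochs = max_epochs, patience = patience)
  })
  structure(list(members = members, spec = spec, seed = seed),
            class = "rad_ensemble")
}

#' @export
predict.rad_ensemble <- function(object, newdata,
                                 type = c("response", "class"), ...) {
  type <- match.arg(type)
  outs <- vapply(object$members, predict, numeric(nrow(newdata)),
                 newdata = newdata, type = "response")
  avg <- if (nrow(newdata) == 1) mean(outs) else rowMeans(outs)
  if (type == "class") {
    as.integer(avg >= object$spec$output_threshold)
  } else {
    avg
  }
}

#' @export
print.rad_ensemble <- function(x, ...) {
  cat("Averaged network ensemble:", length(x$members), "members\n")
  print(x$spec)
  invisible(x)
}

#' @export
summary.rad_ensemble <- function(object, ...) {
  ep <- vapply(object$members, `[[`, numeric(1), "epochs")
  vl <- vapply(object$members, `[[`, numeric(1), "val_loss")
  cat("Averaged network ensemble:", length(object$members), "members,",
      n_parameters(object$spec), "parameters each\n")
  cat("Training epochs: median", median(ep), "(range", min(ep), "-",
      max(ep), ")\n")
  cat("Validation loss: median", format(median(vl), digits = 4), "\n")
  invisible(object)
}
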