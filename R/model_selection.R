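# Evaluate expr with a local RNG stream, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cross-validation configuration
#'
#' Defaults: 10 folds, thresholds -2..3 in steps of 0.1, offsets -8..-1 in
#' steps of 0.5 (a grid wide enough to bracket all trained MMP optima), 2:1
#' train/test split.
#'
#' @param k_folds number of CV folds.
#' @param grid_offsets candidate offset penalties (log2 units), sorted.
#' @param grid_thresholds candidate decision cutoffs (log2 units), sorted.
#' @param seed integer seed driving all randomisation.
#' @param split_fraction train share for the internal-test split.
#' @param background_mode passed to [compute_frequencies()].
#' @return a `cv_config` list.
#' @export
cv_config <- function(k_folds = 10L,
                      grid_offsets = seq(-8, -1, by = 0.5),
                      grid_thresholds = seq(-2, 3, by = 0.1),
                      seed = 1L,
                      split_fraction = 2 / 3,
                      background_mode = "pooled") {
  stopifnot(k_folds >= 2L, length(grid_offsets) > 0L,
            length(grid_thresholds) > 0L,
            !is.unsorted(grid_offsets), !is.unsorted(grid_thresholds))
  if (!(split_fraction > 0 && split_fraction < 1))
    stop("split_fraction must lie strictly between 0 and 1", call. = FALSE)
  cfg <- list(k_folds = as.integer(k_folds), grid_offsets = grid_offsets,
              grid_thresholds = grid_thresholds, seed = as.integer(seed),
              split_fraction = split_fraction,
              background_mode = background_mode)
  class(cfg) <- "cv_config"
  cfg
}

#' Split substrates into train and test sets
#'
#' Random substrate-level split, approximately `fraction` : `1 - fraction`
#' (default 2:1). Reproducible under `seed`.
#'
#' @param substrates a `substrate_set` data frame.
#' @param fraction train share, strictly between 0 and 1.
#' @param seed integer seed.
#' @return list with `train` and `test` substrate sets.
#' @export
split_train_test <- function(substrates, fraction = 2 / 3, seed = 1L) {
  n <- nrow(substrates)
  if (n < 3L) stop("need at least 3 substrates to split", call. = FALSE)
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  n_train <- round(fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = substrates[sort(idx), , drop = FALSE],
       test = substrates[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Partition substrates into k folds
#'
#' Substrate-level partition with fold sizes differing by at most one; a
#' substrate's positive and negative bonds therefore always share a fold.
#'
#' @param n number of substrates (or a `substrate_set`, whose rows are counted).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold assignments in `1..k`, length `n`.
#' @export
kfold_partition <- function(n, k, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n)
  if (n < k) stop("fewer substrates (", n, ") than folds (", k, ")",
                  call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Confusion-derived classification metrics
#'
#' Standard definitions: sensitivity (TPR) = tp/(tp+fn), specificity =
#' tn/(tn+fp), fpr = 1 - specificity, precision = tp/(tp+fp), accuracy,
#' Matthews correlation coefficient, and F1 (harmonic mean of precision and
#' sensitivity). A metric whose denominator is zero is reported as 0 and
#' listed in the `undefined` attribute.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return a `metric_set` list with the counts, the seven metrics, and an
#'   `undefined` character vector naming flagged metrics.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("negative confusion counts", call. = FALSE)
  undef <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(0) }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  acc <- safe_div(tp + tn, tp + fp + tn + fn, "accuracy")
  fpr <- if ("specificity" %in% undef) { undef <- c(undef, "fpr"); 0 } else 1 - spec
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { undef <- c(undef, "mcc"); 0 }
         else (tp * tn - fp * fn) / mcc_den
  f1 <- if (prec + sens == 0) { undef <- c(undef, "f1"); 0 }
        else 2 * prec * sens / (prec + sens)
  m <- list(tp = tp, fp = fp, tn = tn, fn = fn,
            sensitivity = sens, specificity = spec, accuracy = acc,
            precision = prec, fpr = fpr, mcc = mcc, f1 = f1,
            undefined = unique(undef))
  class(m) <- "metric_set"
  m
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set> tp %d fp %d tn %d fn %d | TPR %.3f spec %.3f acc %.3f prec %.3f FPR %.3f MCC %.3f F1 %.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$accuracy,
    x$precision, x$fpr, x$mcc, x$f1))
  if (length(x$undefined))
    cat("  undefined (reported 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# Decompose each test bond's score into its finite log-ratio part plus the
# number of unobserved (offset-substituted) cells it touches, so that
# score(offset) = finite + n_zero * offset without rebuilding the matrix.
bond_decomposition <- function(freq, substrates) {
  B <- ifelse(freq$P > 0, log2(freq$P / freq$Pbckgr), 0)
  Z <- freq$P == 0
  out <- vector("list", nrow(substrates))
  for (i in seq_len(nrow(substrates))) {
    s <- substrates$sequence[[i]]
    ci <- substrates$cleavage_index[[i]]
    n <- nchar(s)
    if (n < 5L) next
    pos <- 3:(n - 2L)
    win <- window_at(s, pos)
    finite <- numeric(length(pos))
    nz <- integer(length(pos))
    ok <- logical(length(pos))
    for (p in seq_along(pos)) {
      idx <- match(strsplit(win[[p]], "")[[1]], AA_ALPHABET)
      if (anyNA(idx)) next
      cells <- cbind(idx, 1:5)
      finite[p] <- sum(B[cells])
      nz[p] <- sum(Z[cells])
      ok[p] <- TRUE
    }
    out[[i]] <- data.frame(finite = finite[ok], n_zero = nz[ok],
                           label = as.integer(pos[ok] == ci))
  }
  do.call(rbind, out)
}

confusion_at <- function(score, label, threshold) {
  pred <- score >= threshold
  c(tp = sum(pred & label == 1L), fp = sum(pred & label == 0L),
    tn = sum(!pred & label == 0L), fn = sum(!pred & label == 1L))
}

#' Offset x threshold grid search under k-fold cross-validation
#'
#' For every grid cell the PWM is re-derived on each fold's training
#' substrates with the cell's offset and evaluated on the held-out fold's
#' labelled bonds (annotated bond positive, every other scorable bond of the
#' peptide negative) with the cell's threshold. The optimum is the cell with
#' the maximal mean F1 across folds; ties prefer the higher threshold, then
#' the larger (less negative) offset — the more conservative model.
#'
#' @param substrates a `substrate_set` for one enzyme.
#' @param background a `background_set`.
#' @param config a [cv_config()].
#' @return A `grid_result`: `best_offset`, `best_threshold`, `f1_grid`
#'   (offsets x thresholds mean-F1 matrix), `fold_metrics` (list of
#'   `metric_set` per fold at the optimum), `summary` (mean and sample sd of
#'   each metric across folds), `pwm` (final model trained on all substrates
#'   at the optimum), and the `config`.
#' @export
grid_search_cv <- function(substrates, background, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  offs <- config$grid_offsets
  thrs <- config$grid_thresholds
  folds <- kfold_partition(nrow(substrates), config$k_folds,
                           seed = config$seed + 1L)

  # per-fold held-out bond decompositions
  fold_bonds <- vector("list", config$k_folds)
  for (f in seq_len(config$k_folds)) {
    train <- substrates[folds != f, , drop = FALSE]
    test <- substrates[folds == f, , drop = FALSE]
    freq <- compute_frequencies(train, background,
                                background_mode = config$background_mode,
                                quiet = TRUE)
    fold_bonds[[f]] <- bond_decomposition(freq, test)
  }
  usable <- vapply(fold_bonds, function(b) !is.null(b) && sum(b$label) > 0,
                   logical(1))
  if (!any(usable)) stop("no fold contains a positive bond", call. = FALSE)
  if (!all(usable))
    warning(sum(!usable), " fold(s) without positives were flagged and excluded")

  f1_grid <- matrix(NA_real_, length(offs), length(thrs),
                    dimnames = list(sprintf("%g", offs), sprintf("%g", thrs)))
  fold_f1 <- array(NA_real_, c(length(offs), length(thrs), config$k_folds))
  for (f in which(usable)) {
    b <- fold_bonds[[f]]
    for (oi in seq_along(offs)) {
      sc <- b$finite + offs[[oi]] * b$n_zero
      ord <- order(sc)
      sc_s <- sc[ord]; lab_s <- b$label[ord]
      npos <- sum(lab_s); nneg <- length(lab_s) - npos
      # cumulative counts below each candidate threshold
      for (ti in seq_along(thrs)) {
        below <- findInterval(thrs[[ti]] - 1e-12, sc_s)
        fn <- sum(lab_s[seq_len(below)] == 1L)
        tn <- below - fn
        m <- compute_metrics(npos - fn, nneg - tn, tn, fn)
        fold_f1[oi, ti, f] <- m$f1
      }
    }
  }
  for (oi in seq_along(offs))
    for (ti in seq_along(thrs))
      f1_grid[oi, ti] <- mean(fold_f1[oi, ti, usable])

  best <- which(f1_grid == max(f1_grid), arr.ind = TRUE)
  # ties: highest threshold, then largest offset
  best <- best[order(best[, 2], best[, 1], decreasing = TRUE), , drop = FALSE][1, ]
  best_offset <- offs[[best[[1]]]]
  best_threshold <- thrs[[best[[2]]]]

  fold_metrics <- vector("list", config$k_folds)
  for (f in which(usable)) {
    b <- fold_bonds[[f]]
    sc <- b$finite + best_offset * b$n_zero
    cm <- confusion_at(sc, b$label, best_threshold)
    fold_metrics[[f]] <- compute_metrics(cm[["tp"]], cm[["fp"]],
                                         cm[["tn"]], cm[["fn"]])
  }
  fold_metrics <- fold_metrics[usable]

  metric_names <- c("sensitivity", "specificity", "accuracy", "precision",
                    "fpr", "mcc", "f1")
  summ <- t(vapply(metric_names, function(mn) {
    vals <- vapply(fold_metrics, `[[`, numeric(1), mn)
    c(mean = mean(vals), sd = stats::sd(vals))
  }, numeric(2)))

  freq_all <- compute_frequencies(substrates, background,
                                  background_mode = config$background_mode,
                                  quiet = TRUE)
  final <- build_pwm(freq_all, offset = best_offset,
                     threshold = best_threshold,
                     enzyme = substrates$enzyme[[1]])

  res <- list(best_offset = best_offset, best_threshold = best_threshold,
              f1_grid = f1_grid, fold_metrics = fold_metrics,
              summary = summ, pwm = final, config = config,
              folds_used = sum(usable))
  class(res) <- "grid_result"
  res
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> optimum threshold %.2f / offset %.2f  mean CV F1 %.3f (%d folds)\n",
              x$best_threshold, x$best_offset,
              x$summary["f1", "mean"], x$folds_used))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Threshold sweep over the distinct observed scores; AUC by the trapezoid
#' rule, which equals the Mann-Whitney probability that a random positive
#' outscores a random negative (ties counted one half).
#'
#' @param score numeric scores.
#' @param label 0/1 (or logical) labels, 1 = positive.
#' @return list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(score, label) {
  label <- as.integer(label)
  stopifnot(length(score) == length(label), all(label %in% c(0L, 1L)))
  npos <- sum(label == 1L); nneg <- sum(label == 0L)
  if (npos == 0L || nneg == 0L)
    stop("ROC requires both positive and negative labels", call. = FALSE)
  thr <- sort(unique(score), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    c(fpr = sum(score >= t & label == 0L) / nneg,
      tpr = sum(score >= t & label == 1L) / npos)
  }, numeric(2)))
  points <- data.frame(threshold = c(Inf, thr),
                       fpr = c(0, pts[, "fpr"]), tpr = c(0, pts[, "tpr"]))
  r <- rank(score)
  auc <- (sum(r[label == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  list(points = points, auc = auc)
}

#' Two-sample Kolmogorov-Smirnov separation
#'
#' The D statistic: maximal absolute difference between the empirical
#' cumulative distribution functions of the two score samples.
#'
#' @param scores_pos,scores_neg non-empty numeric samples.
#' @return D in `[0, 1]`.
#' @export
ks_separation <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  grid <- sort(unique(c(scores_pos, scores_neg)))
  ep <- stats::ecdf(scores_pos)
  en <- stats::ecdf(scores_neg)
  max(abs(ep(grid) - en(grid)))
}

#' Sample protein-level negatives at a fixed positive:negative ratio
#'
#' Scores all bonds of the given protein substrates, labels the annotated
#' cleavage positions positive, and samples `ratio` negatives per positive
#' without replacement from the remaining scorable bonds. If fewer negatives
#' exist than requested, all are taken with a warning.
#'
#' @param x a [pwm].
#' @param sequences named character vector of protein sequences.
#' @param positives data frame with `sequence_id` and `p1_position` of the
#'   annotated cleavage sites.
#' @param ratio negatives per positive (default 100).
#' @param seed integer seed.
#' @return data frame `sequence_id`, `p1_position`, `score`, `label`.
#' @export
sample_protein_negatives <- function(x, sequences, positives, ratio = 100L,
                                     seed = 1L) {
  stopifnot(!is.null(names(sequences)), nrow(positives) > 0L)
  all_sites <- do.call(rbind, lapply(names(sequences), function(id)
    suppressWarnings(scan_sequence(x, sequences[[id]], sequence_id = id))))
  key <- paste(all_sites$sequence_id, all_sites$p1_position)
  pos_key <- paste(positives$sequence_id, positives$p1_position)
  missing_pos <- setdiff(pos_key, key)
  if (length(missing_pos) > 0L)
    warning(length(missing_pos), " annotated site(s) have no scorable window ",
            "and were dropped")
  is_pos <- key %in% pos_key
  pos_df <- all_sites[is_pos, , drop = FALSE]
  neg_df <- all_sites[!is_pos, , drop = FALSE]
  want <- ratio * nrow(pos_df)
  if (nrow(neg_df) < want) {
    warning("only ", nrow(neg_df), " negatives available (wanted ", want,
            "); sampling all")
    take <- seq_len(nrow(neg_df))
  } else {
    take <- with_seed(seed + 2L, sample.int(nrow(neg_df), want))
  }
  neg_df <- neg_df[take, , drop = FALSE]
  out <- rbind(
    data.frame(sequence_id = pos_df$sequence_id,
               p1_position = pos_df$p1_position, score = pos_df$score,
               label = 1L),
    data.frame(sequence_id = neg_df$sequence_id,
               p1_position = neg_df$p1_position, score = neg_df$score,
               label = 0L))
  rownames(out) <- NULL
  out
}

#' Refine reported cleavage positions against the PWM
#'
#' Experimentally reported cleavage positions can be off by a few bonds. A
#' reported bond scoring below the PWM threshold is reassigned to the
#' highest-scoring above-threshold bond within `max_shift` bonds of it (ties
#' to the smaller shift); otherwise it is kept. Reported bonds already at or
#' above threshold are never moved.
#'
#' @param x a [pwm].
#' @param sequences named character vector of protein sequences.
#' @param reported data frame with `sequence_id` and `p1_position`.
#' @param max_shift maximal reassignment distance in bonds (default 4).
#' @return data frame `sequence_id`, `reported_position`, `corrected_position`,
#'   `reported_score`, `corrected_score`, `reassigned`; attribute
#'   `n_reassigned`.
#' @export
refine_cleavage_positions <- function(x, sequences, reported, max_shift = 4L) {
  stopifnot(!is.null(names(sequences)))
  scans <- lapply(sequences, function(s)
    suppressWarnings(scan_sequence(x, s)))
  out <- reported[, c("sequence_id", "p1_position")]
  names(out) <- c("sequence_id", "reported_position")
  out$corrected_position <- out$reported_position
  out$reported_score <- NA_real_
  out$corrected_score <- NA_real_
  out$reassigned <- FALSE
  for (i in seq_len(nrow(out))) {
    sites <- scans[[out$sequence_id[[i]]]]
    p <- out$reported_position[[i]]
    at <- match(p, sites$p1_position)
    sc <- if (is.na(at)) -Inf else sites$score[[at]]
    out$reported_score[[i]] <- if (is.finite(sc)) sc else NA_real_
    out$corrected_score[[i]] <- out$reported_score[[i]]
    if (sc >= x$threshold) next
    near <- sites[abs(sites$p1_position - p) <= max_shift &
                    sites$p1_position != p &
                    sites$score >= x$threshold, , drop = FALSE]
    if (nrow(near) == 0L) next
    near <- near[order(-near$score, abs(near$p1_position - p)), , drop = FALSE]
    out$corrected_position[[i]] <- near$p1_position[[1]]
    out$corrected_score[[i]] <- near$score[[1]]
    out$reassigned[[i]] <- TRUE
  }
  attr(out, "n_reassigned") <- sum(out$reassigned)
  out
}
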