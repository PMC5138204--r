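# Accuracy-vs-averaging evaluation protocol: cross-validated command
# accuracy for 1..5 averaged ERPs, MDM vs SWLDA with rank-sum comparisons,
# chance levels, and grand-average ERP summaries.

#' Average k consecutive same-code epochs
#'
#' Within each (block, stimulus code) group, consecutive disjoint runs of
#' `k` epochs are averaged into one; labels are preserved and leftover
#' epochs (fewer than `k`) are discarded.  Averaging across trials is the
#' classical way to raise ERP signal-to-noise; the evaluation protocol
#' sweeps `k` to measure how quickly each classifier reaches a usable
#' accuracy.
#'
#' @param epochs An [epoch_set()].
#' @param k Averaging depth (k = 1 returns the input trials unchanged).
#' @return An [epoch_set()] of averaged trials; field `group` indexes the
#'   sub-round of each averaged trial within its block.
#' @export
average_erps <- function(epochs, k) {
  stopifnot(inherits(epochs, "epoch_set"), k >= 1)
  k <- as.integer(k)
  d <- dim(epochs$epochs)
  keys <- split(
    seq_len(d[1]),
    list(block = epochs$block_ids, code = epochs$stimulus_codes),
    drop = TRUE
  )
  deficient <- names(keys)[vapply(keys, length, 1L) < k]
  if (length(deficient) > 0) {
    stop(sprintf(
      "averaging depth k = %d exceeds available repetitions in group(s): %s",
      k, paste(deficient, collapse = ", ")
    ))
  }

  out_epochs <- list()
  out_lab <- integer(0)
  out_code <- integer(0)
  out_block <- integer(0)
  out_group <- integer(0)
  for (idx in keys) {
    ng <- length(idx) %/% k
    for (g in seq_len(ng)) {
      members <- idx[((g - 1) * k + 1):(g * k)]
      lab <- unique(epochs$labels[members])
      stopifnot(length(lab) == 1)
      m <- epochs$epochs[members, , , drop = FALSE]
      avg <- if (k == 1) m[1, , ] else apply(m, c(2, 3), mean)
      dim(avg) <- d[2:3]
      out_epochs[[length(out_epochs) + 1L]] <- avg
      out_lab <- c(out_lab, lab)
      out_code <- c(out_code, epochs$stimulus_codes[members[1]])
      out_block <- c(out_block, epochs$block_ids[members[1]])
      out_group <- c(out_group, g)
    }
  }
  n <- length(out_epochs)
  arr <- array(0, dim = c(n, d[2], d[3]))
  for (i in seq_len(n)) arr[i, , ] <- out_epochs[[i]]
  ord <- order(out_block, out_group, out_code)
  epoch_set(arr[ord, , , drop = FALSE], epochs$fs, out_lab[ord],
            out_code[ord], out_block[ord],
            channel_names = epochs$channel_names, group = out_group[ord],
            window = epochs$window)
}

#' Two-sided Wilcoxon rank-sum comparison of accuracy samples
#'
#' Exact enumeration is used for small untied samples (the sizes that arise
#' from per-fold accuracies), the normal approximation with tie correction
#' otherwise — the behaviour of [stats::wilcox.test()].
#'
#' @param acc_a,acc_b Numeric vectors of per-fold (or per-subject)
#'   accuracies.
#' @return The two-sided p-value.
#' @export
ranksum_compare <- function(acc_a, acc_b) {
  if (length(acc_a) == 0 || length(acc_b) == 0) {
    stop("both accuracy samples must be non-empty")
  }
  # rank variance of zero (e.g. both classifiers at 100% in every fold)
  # makes the normal approximation 0/0; there is no evidence either way
  if (stats::sd(c(acc_a, acc_b)) == 0) return(1)
  p <- suppressWarnings(stats::wilcox.test(acc_a, acc_b))$p.value
  if (is.nan(p)) 1 else p
}

#' Chance level of a K-command selection
#'
#' @param K Number of commands, >= 2.
#' @return Chance accuracy in percent (100/K), rounded to one decimal.
#' @export
chance_level <- function(K) {
  if (K < 2) stop("a decision problem needs at least 2 commands")
  round(100 / K, 1)
}

#' Grand-average ERP with standard-error bands
#'
#' Per-class (target / non-target) mean waveform per channel with the
#' per-sample standard error SD/sqrt(n), the summary conventionally plotted
#' to show the P300 deflection.
#'
#' @param epochs An [epoch_set()] with at least 2 trials per class.
#' @return An object of class `grand_average` with `target` and
#'   `nontarget` components (each carrying `mean`, `se`, `n`).
#' @export
grand_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  one_class <- function(k) {
    idx <- which(epochs$labels == k)
    if (length(idx) < 2) {
      stop(sprintf("class %d has %d trial(s); need at least 2", k,
                   length(idx)))
    }
    m <- epochs$epochs[idx, , , drop = FALSE]
    list(mean = apply(m, c(2, 3), mean),
         se = apply(m, c(2, 3), stats::sd) / sqrt(length(idx)),
         n = length(idx))
  }
  structure(
    list(target = one_class(1L), nontarget = one_class(2L),
         fs = epochs$fs, channel_names = epochs$channel_names,
         window = epochs$window),
    class = "grand_average"
  )
}

#' @export
print.grand_average <- function(x, ...) {
  cat(sprintf(
    "<grand_average: %d channels, %d target / %d non-target trials @ %g Hz>\n",
    nrow(x$target$mean), x$target$n, x$nontarget$n, x$fs
  ))
  invisible(x)
}

# classify every selection of a test epoch set (already averaged at depth
# k) and return the fraction correct, in percent
score_selections <- function(test_k, attended, model,
                             prototypes = NULL, loading = 1e-10) {
  K <- max(test_k$stimulus_codes)
  cells <- split(seq_len(n_trials(test_k)),
                 list(block = test_k$block_ids, group = test_k$group),
                 drop = TRUE)
  correct <- 0L
  total <- 0L
  for (idx in cells) {
    codes <- test_k$stimulus_codes[idx]
    if (!setequal(codes, seq_len(K))) {
      stop("selection round does not contain every stimulus code exactly once")
    }
    idx <- idx[order(codes)]
    block <- test_k$block_ids[idx[1]]
    if (inherits(model, "mdm_model")) {
      covs <- lapply(idx, function(i) {
        supertrial_covariance(build_super_trial(get_epoch(test_k, i),
                                                prototypes), loading)
      })
      dec <- command_select(model, covs)
    } else {
      feats <- swlda_features(subset_epochs(test_k, idx))
      dec <- command_select(model, feats)
    }
    correct <- correct + as.integer(dec$decided_command ==
                                      attended[as.character(block)])
    total <- total + 1L
  }
  list(accuracy = 100 * correct / total, n = total)
}

#' Cross-validated command accuracy vs number of averaged ERPs
#'
#' Reproduces the offline evaluation protocol: selection blocks are split
#' into cross-validation folds; per fold the class prototypes and both
#' classifiers are fit on the training blocks, and every test selection is
#' decided at each averaging depth `k`.  Training trials are averaged at
#' the same depth as the test trials so both classifiers see features of
#' matched signal-to-noise.  Accuracies are aggregated to mean +/- SD over
#' folds, with a two-sided rank-sum p-value comparing MDM and SWLDA at
#' each `k`.
#'
#' @param epochs An [epoch_set()] with block structure (e.g. from
#'   [simulate_epochs()] or [extract_epochs()]).
#' @param classifiers Character subset of `c("mdm", "swlda")`.
#' @param k_range Averaging depths to sweep (default 1:5).
#' @param n_folds Number of cross-validation folds over blocks (default 5).
#' @param seed Seed for the fold assignment.
#' @param loading Covariance diagonal-loading floor.
#' @return An object of class `accuracy_table`: `table` (classifier, k,
#'   mean, sd), `p_values` (k, rank-sum p, when both classifiers are run),
#'   `fold_accuracies`, `chance_percent` and protocol metadata.
#' @export
evaluate_accuracy <- function(epochs, classifiers = c("mdm", "swlda"),
                              k_range = 1:5, n_folds = 5L, seed = NULL,
                              loading = 1e-10) {
  stopifnot(inherits(epochs, "epoch_set"))
  classifiers <- match.arg(classifiers, c("mdm", "swlda"), several.ok = TRUE)
  blocks <- sort(unique(epochs$block_ids))
  nb <- length(blocks)
  if (nb < n_folds) {
    stop(sprintf("fewer blocks (%d) than folds (%d)", nb, n_folds))
  }
  K <- max(epochs$stimulus_codes)
  attended <- attended_commands(epochs)

  fold_of <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = nb)))
  acc <- array(NA_real_,
               dim = c(n_folds, length(k_range), length(classifiers)),
               dimnames = list(NULL, paste0("k", k_range), classifiers))
  n_sel <- 0L

  for (f in seq_len(n_folds)) {
    test_blocks <- blocks[fold_of == f]
    train_idx <- which(!(epochs$block_ids %in% test_blocks))
    test_idx <- which(epochs$block_ids %in% test_blocks)
    train <- subset_epochs(epochs, train_idx)
    test <- subset_epochs(epochs, test_idx)
    prototypes <- class_prototypes(train)

    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      train_k <- average_erps(train, k)
      test_k <- average_erps(test, k)
      for (cl in classifiers) {
        model <- if (cl == "mdm") {
          mdm_fit(supertrial_covariances(train_k, prototypes, loading),
                  train_k$labels)
        } else {
          swlda_fit(swlda_features(train_k), train_k$labels)
        }
        sc <- score_selections(test_k, attended, model, prototypes, loading)
        acc[f, ki, cl] <- sc$accuracy
        n_sel <- n_sel + sc$n
      }
    }
  }

  rows <- do.call(rbind, lapply(classifiers, function(cl) {
    data.frame(classifier = cl, k = k_range,
               mean = apply(acc[, , cl, drop = FALSE], 2, mean),
               sd = apply(acc[, , cl, drop = FALSE], 2, stats::sd),
               row.names = NULL)
  }))
  p_values <- NULL
  if (all(c("mdm", "swlda") %in% classifiers)) {
    p_values <- data.frame(
      k = k_range,
      p = vapply(seq_along(k_range), function(ki) {
        ranksum_compare(acc[, ki, "mdm"], acc[, ki, "swlda"])
      }, numeric(1))
    )
  }
  structure(
    list(table = rows, p_values = p_values, fold_accuracies = acc,
         chance_percent = chance_level(K), K = K, n_folds = n_folds,
         k_range = k_range, seed = seed, n_selections_scored = n_sel,
         aggregation = "mean +/- SD over cross-validation folds"),
    class = "accuracy_table"
  )
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat(sprintf("Command accuracy vs number of averaged ERPs (chance %.1f%%)\n",
              x$chance_percent))
  for (cl in unique(x$table$classifier)) {
    rows <- x$table[x$table$classifier == cl, ]
    cat(sprintf("  %-5s  %s\n", toupper(cl),
                paste(sprintf("k=%d: %5.1f+/-%4.1f", rows$k, rows$mean,
                              rows$sd), collapse = "  ")))
  }
  if (!is.null(x$p_values)) {
    cat("  rank-sum p (MDM vs SWLDA): ",
        paste(sprintf("k=%d: %.3g", x$p_values$k, x$p_values$p),
              collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}
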