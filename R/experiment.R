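#' Configuration of a full synthetic study
#'
#' Bundles everything needed to rerun the study analog end to end: number of
#' synthetic subjects, paradigm, generator parameters, modalities,
#' transition-exclusion sweep, subsampled variants, SVM and permutation-test
#' settings, and the master seed from which all per-subject seeds derive.
#'
#' @param n_subjects Number of synthetic subjects (default 10).
#' @param p A [paradigm()] (default: five 30-s task/rest cycles, 300 s).
#' @param params A [synth_params()].
#' @param modalities Modalities to simulate and analyze.
#' @param k_sweep Transition-exclusion counts to evaluate (default `0:3`).
#' @param subsample_variants Also analyze stride-2 subsampled BOLD/AVAST
#'   ("sbold"/"savast") runs.
#' @param C SVM trade-off parameter.
#' @param fwhm Smoothing kernel FWHM, mm.
#' @param mask_rule Brain-mask rule (see [brain_mask()]).
#' @param do_permutation Run the weight-map permutation test per subject and
#'   modality (at `k_ignore = perm_k`).
#' @param n_perm,alpha,perm_statistic,perm_k Permutation-test settings.
#'   `perm_k` defaults to 3: the weight map is estimated from the
#'   transition-excluded examples, since frames acquired during the
#'   hemodynamic ramp carry the previous state's signal and act as label
#'   noise that de-localizes the weight map.
#' @param master_seed Master seed; subject seeds are drawn from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_subjects = 10L, p = paradigm(30, 5),
                              params = synth_params(),
                              modalities = c("bold", "asl", "avast"),
                              k_sweep = 0:3, subsample_variants = FALSE,
                              C = 1, fwhm = 8, mask_rule = "above_mean",
                              do_permutation = FALSE, n_perm = 200L,
                              alpha = 0.01, perm_statistic = "absolute",
                              perm_k = 3L, master_seed = 1L) {
  stopifnot(n_subjects >= 1, all(k_sweep >= 0), inherits(p, "paradigm"),
            inherits(params, "synth_params"),
            all(modalities %in% names(params$tr)))
  structure(list(n_subjects = as.integer(n_subjects), p = p,
                 params = params, modalities = modalities,
                 k_sweep = as.integer(k_sweep),
                 subsample_variants = subsample_variants, C = C,
                 fwhm = fwhm, mask_rule = mask_rule,
                 do_permutation = do_permutation,
                 n_perm = as.integer(n_perm), alpha = alpha,
                 perm_statistic = perm_statistic, perm_k = as.integer(perm_k),
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Run the full synthetic study
#'
#' For every subject: generate two runs per modality sharing ground truth,
#' preprocess each run (surround subtraction for control/tag contrasts,
#' smoothing, voxel-wise normalization; brain mask from the unsmoothed
#' first run), then for every transition-exclusion count `k` evaluate
#' cross-run classification in both directions (run 1 trains / run 2 tests,
#' and vice versa). Optionally analyzes stride-2 subsampled BOLD/AVAST
#' variants and runs the weight-map permutation test.
#'
#' Per-subject seeds are drawn from `master_seed` by a single seeded draw,
#' so any subject can be regenerated independently and the whole table is
#' bit-reproducible.
#'
#' @param cfg An [experiment_config()].
#' @return A `bs_experiment` list: `accuracy` (tibble: subject, modality,
#'   k_ignore, direction, accuracy), `curve` (the [accuracy_curve()]
#'   aggregate), `perm` (named list of `perm_result` with ground-truth Dice,
#'   or `NULL`), `manifest` (tibble of runs), `errors` (tibble of failed
#'   cells, if any) and `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  subject_seeds <- with_local_seed(cfg$master_seed,
                                   sample.int(.Machine$integer.max,
                                              cfg$n_subjects))
  acc <- list(); manifest <- list(); perms <- list(); errors <- list()
  for (si in seq_len(cfg$n_subjects)) {
    subj <- generate_subject(cfg$params, subject_seeds[si], p = cfg$p,
                             modalities = cfg$modalities)
    for (mod in cfg$modalities) {
      res <- tryCatch(
        analyze_modality(subj, mod, cfg, si),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        errors[[length(errors) + 1L]] <-
          tibble::tibble(subject = si, modality = mod,
                         message = conditionMessage(res))
        next
      }
      acc[[length(acc) + 1L]] <- res$acc
      manifest[[length(manifest) + 1L]] <- res$manifest
      if (!is.null(res$perm)) {
        perms[[paste0("s", si, "_", mod)]] <- res$perm
      }
    }
  }
  accuracy <- do.call(rbind, acc)
  class(accuracy) <- c("accuracy_table", class(accuracy))
  structure(list(accuracy = accuracy,
                 curve = accuracy_curve(accuracy),
                 perm = if (length(perms)) perms else NULL,
                 manifest = do.call(rbind, manifest),
                 errors = if (length(errors)) do.call(rbind, errors) else NULL,
                 config = cfg, subject_seeds = subject_seeds),
            class = "bs_experiment")
}

# One subject x modality cell: preprocess, sweep k, optional variants and
# permutation test.
analyze_modality <- function(subj, mod, cfg, si) {
  r1 <- subj$runs[[mod]]$run1
  r2 <- subj$runs[[mod]]$run2
  mask <- compute_brain_mask(r1, cfg$mask_rule)
  p1 <- preprocess_run(r1, cfg$fwhm)
  p2 <- preprocess_run(r2, cfg$fwhm)

  variants <- list(list(name = mod, a = p1, b = p2))
  if (cfg$subsample_variants && mod %in% c("bold", "avast")) {
    variants[[2]] <- list(name = paste0("s", mod),
                          a = subsample_run(p1, 2L),
                          b = subsample_run(p2, 2L))
  }
  rows <- list()
  perm <- NULL
  for (v in variants) {
    for (k in cfg$k_sweep) {
      e1 <- build_examples(v$a, cfg$p, mask, k_ignore = k)
      e2 <- build_examples(v$b, cfg$p, mask, k_ignore = k)
      a12 <- cross_run_accuracy(e1, e2, C = cfg$C)
      a21 <- cross_run_accuracy(e2, e1, C = cfg$C)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject = si, modality = v$name, k_ignore = k,
        direction = c("1->2", "2->1"), accuracy = c(a12, a21))
    }
  }
  if (isTRUE(cfg$do_permutation)) {
    e1 <- build_examples(p1, cfg$p, mask, k_ignore = cfg$perm_k)
    pr <- permutation_null(e1, C = cfg$C, n_perm = cfg$n_perm,
                           seed = subj$subject_seed %% 1000003L,
                           statistic = cfg$perm_statistic,
                           alpha = cfg$alpha)
    gt <- subj$roi_mask[e1$voxel_index]
    pr$dice_vs_truth <- dice_coefficient(pr$significant_mask, gt)
    pr$truth_in_mask <- gt
    perm <- pr
  }
  list(
    acc = do.call(rbind, rows),
    manifest = tibble::tibble(
      subject = si, modality = mod, run = c(1L, 2L),
      tr = r1$tr, n_frames = c(n_frames(r1), n_frames(r2)),
      subject_seed = subj$subject_seed, avast_tr = subj$avast_tr),
    perm = perm
  )
}

#' Aggregate an accuracy table into mean +/- SE curves
#'
#' Averages the two train/test directions within each subject first, then
#' across subjects, giving one mean and standard error per
#' (modality, k_ignore) cell — the quantity plotted against the number of
#' ignored transition points.
#'
#' @param tbl The `accuracy` tibble of a [run_experiment()] result (columns
#'   subject, modality, k_ignore, direction, accuracy).
#' @return Tibble with columns `modality`, `k_ignore`, `mean_accuracy`,
#'   `se` (`NA` for a single subject) and `n_subjects`.
#' @export
accuracy_curve <- function(tbl) {
  stopifnot(nrow(tbl) > 0)
  per_subj <- stats::aggregate(accuracy ~ subject + modality + k_ignore,
                               data = tbl, FUN = mean)
  agg <- stats::aggregate(accuracy ~ modality + k_ignore, data = per_subj,
                          FUN = function(a) c(mean = mean(a),
                                              sd = stats::sd(a),
                                              n = length(a)))
  out <- tibble::tibble(
    modality = agg$modality,
    k_ignore = agg$k_ignore,
    mean_accuracy = agg$accuracy[, "mean"],
    se = ifelse(agg$accuracy[, "n"] > 1,
                agg$accuracy[, "sd"] / sqrt(agg$accuracy[, "n"]), NA_real_),
    n_subjects = as.integer(agg$accuracy[, "n"])
  )
  out[order(out$modality, out$k_ignore), ]
}

#' @export
print.bs_experiment <- function(x, ...) {
  cat(sprintf("<bs_experiment> %d subjects, modalities: %s\n",
              x$config$n_subjects,
              paste(unique(x$manifest$modality), collapse = ", ")))
  print(x$curve)
  invisible(x)
}
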