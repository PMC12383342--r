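#' Run the full prediction study on a cohort
#'
#' Convenience driver that strings the whole pipeline together on a
#' (typically synthetic) cohort: stratified train/test split; whole-ROI
#' (Intra) and habitat-aggregated (Habitat) radiomic feature tables; 2.5D
#' slice stacks, slice-model fitting and MIL feature fusion; the selection
#' cascade per chain (the habitat and MIL chains skip the ICC stage); one
#' signature model per chain; the clinicoradiological logistic signature;
#' and the fusion nomogram over age, treatment, MLNSD and the Habitat/MIL
#' signature scores. Returns per-signature train/test scores and AUCs.
#'
#' @param cohort A [generate_cohort()] result (or compatible list).
#' @param train_frac Fraction of patients in the training split.
#' @param bank A [filter_bank()] for the radiomic chains.
#' @param algorithms Model-zoo subset passed to [train_signature()].
#' @param folds Cross-validation folds.
#' @param seed Seed for the split, CV folds and stochastic learners.
#' @param signatures Which radiomic chains to run.
#' @return A `study_result` list: `split`, `signatures` (per-chain fitted
#'   models, scores, AUCs), `clinic`, `nomogram`, and an `auc` summary
#'   tibble.
#' @export
run_study <- function(cohort, train_frac = 0.7, bank = filter_bank(),
                      algorithms = "rf", folds = 5L, seed = 1L,
                      signatures = c("intra", "habitat", "mil")) {
  labels <- cohort_labels(cohort)
  clin <- cohort_clinical(cohort)
  set.seed(seed)
  idx_tr <- unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, round(train_frac * length(idx)))
  }))
  idx_tr <- sort(idx_tr)
  idx_te <- setdiff(seq_along(cohort), idx_tr)

  chains <- list()
  if ("intra" %in% signatures || "habitat" %in% signatures) {
    for (mode in intersect(c("intra", "habitat"), signatures)) {
      tab <- cohort_feature_table(cohort, mode, bank,
                                  hcfg = habitat_config(seed = seed))
      chains[[mode]] <- list(train = tab[idx_tr, ], test = tab[idx_te, ])
    }
  }
  if ("mil" %in% signatures) {
    stacks <- lapply(cohort, function(p)
      build_stack(clip_hu(p$ct), p$mask, id = p$id))
    sm <- fit_slice_models(stacks[idx_tr], labels[idx_tr],
                           config = slice_train_config(seed = seed))
    pm_tr <- predict_matrix(sm, stacks[idx_tr])
    pm_te <- predict_matrix(sm, stacks[idx_te])
    bw <- bow_features(pm_tr, pm_te)
    mil_tr <- fuse_mil(plh_features(pm_tr), bw$train)
    mil_te <- fuse_mil(plh_features(pm_te), bw$test)
    chains$mil <- list(train = mil_tr, test = mil_te,
                       slice_models = sm)
  }

  out_sigs <- list()
  for (ch in intersect(c("intra", "habitat", "mil"), names(chains))) {
    sel <- select_features(chains[[ch]]$train, labels[idx_tr],
                           selection_config(seed = seed),
                           test = chains[[ch]]$test)
    sig <- train_signature(sel$train, labels[idx_tr],
                           algorithms = algorithms, folds = folds,
                           seed = seed)
    sc_tr <- predict(sig, sel$train)
    sc_te <- predict(sig, sel$test)
    out_sigs[[ch]] <- list(
      selection = sel, model = sig,
      scores_train = sc_tr, scores_test = sc_te,
      auc_train = auc_mw(sc_tr, labels[idx_tr]),
      auc_test = auc_mw(sc_te, labels[idx_te]),
      cv_auc = sig$fits[[sig$best]]$cv_auc)
  }

  clin_vars <- dplyr::select(clin, -dplyr::any_of(c("patient_id", "label")))
  cl_sig <- clinic_signature(clin_vars[idx_tr, ], labels[idx_tr])
  cl_tr <- predict(cl_sig, clin_vars[idx_tr, ])
  cl_te <- predict(cl_sig, clin_vars[idx_te, ])
  cl_cv <- cv_auc_logistic(
    clin_vars[idx_tr, cl_sig$variables, drop = FALSE],
    labels[idx_tr], folds, seed)

  nomo_inputs <- function(rows, hab, mil) {
    tibble::tibble(age = clin$age[rows],
                   treatment = clin$treatment[rows],
                   MLNSD_mm = clin$MLNSD_mm[rows],
                   habitat_score = hab, mil_score = mil)
  }
  nomo <- NULL; nomo_auc <- c(train = NA_real_, test = NA_real_)
  nomo_cv <- NA_real_
  if (all(c("habitat", "mil") %in% names(out_sigs))) {
    ntr <- nomo_inputs(idx_tr, out_sigs$habitat$scores_train,
                       out_sigs$mil$scores_train)
    nte <- nomo_inputs(idx_te, out_sigs$habitat$scores_test,
                       out_sigs$mil$scores_test)
    nomo <- build_nomogram(ntr, labels[idx_tr])
    p_tr <- apply_nomogram(nomo, ntr)$probability
    p_te <- apply_nomogram(nomo, nte)$probability
    nomo_auc <- c(train = auc_mw(p_tr, labels[idx_tr]),
                  test = auc_mw(p_te, labels[idx_te]))
    nomo_cv <- cv_auc_logistic(ntr, labels[idx_tr], folds, seed)
  }

  auc_tbl <- dplyr::bind_rows(
    lapply(names(out_sigs), function(ch)
      tibble::tibble(signature = ch,
                     auc_train = out_sigs[[ch]]$auc_train,
                     auc_test = out_sigs[[ch]]$auc_test,
                     cv_auc = out_sigs[[ch]]$cv_auc)),
    list(tibble::tibble(signature = "clinic",
                        auc_train = auc_mw(cl_tr, labels[idx_tr]),
                        auc_test = auc_mw(cl_te, labels[idx_te]),
                        cv_auc = cl_cv),
         tibble::tibble(signature = "nomogram",
                        auc_train = nomo_auc[["train"]],
                        auc_test = nomo_auc[["test"]],
                        cv_auc = nomo_cv)))

  structure(list(split = list(train = idx_tr, test = idx_te),
                 labels = labels,
                 signatures = out_sigs,
                 clinic = list(model = cl_sig, scores_train = cl_tr,
                               scores_test = cl_te, cv_auc = cl_cv),
                 nomogram = nomo,
                 auc = auc_tbl),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$auc)
  invisible(x)
}

#' @export
tidy.study_result <- function(x, ...) x$auc

# stratified k-fold CV AUC of a plain logistic model over a small input table
cv_auc_logistic <- function(data, labels, folds = 5L, seed = 1L) {
  if (ncol(data) == 0L) return(NA_real_)
  fold <- stratified_folds(labels, folds, seed + 31L)
  d <- data.frame(y = labels, data)
  aucs <- vapply(seq_len(folds), function(f) {
    fit <- suppressWarnings(stats::glm(y ~ ., data = d[fold != f, ],
                                       family = stats::binomial()))
    p <- stats::predict(fit, newdata = d[fold == f, ], type = "response")
    auc_mw(p, labels[fold == f])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}
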