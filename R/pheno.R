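# Xenograft response phenotyping: fold change of final tumor weight,
# t-test, three-way categorization, and phenotype-covariate
# association.

#' Fold change in tumor weight with a two-sample t-test
#'
#' `fold_change = mean(treated) / mean(control)`; the p-value comes
#' from a two-sided two-sample t-test (Welch by default, pooled
#' variance optionally, matching a classical "student's t-test").
#' Identical constant arms are degenerate and reported with p = 1.
#'
#' @param treated,control Positive final tumor weights, >= 2 per arm.
#' @param var_equal Use the pooled-variance t-test instead of Welch?
#' @return List with `fold_change` and `p_value`.
#' @export
compute_fold_change <- function(treated, control, var_equal = FALSE) {
  if (length(treated) < 2 || length(control) < 2) {
    stop("need at least 2 weights per arm")
  }
  if (any(!is.finite(c(treated, control))) || any(c(treated, control) <= 0)) {
    stop("tumor weights must be positive")
  }
  fc <- mean(treated) / mean(control)
  if (stats::sd(treated) == 0 && stats::sd(control) == 0) {
    p <- if (mean(treated) == mean(control)) 1 else 0
  } else {
    p <- stats::t.test(treated, control, var.equal = var_equal)$p.value
  }
  list(fold_change = fc, p_value = p)
}

#' Categorize an atRA response from fold change and significance
#'
#' `sensitive` when the treated arm is significantly smaller
#' (p < alpha, FC < 1), `promoted` when significantly larger, and
#' `resistant` otherwise. Raising the p-value can only move a label
#' into `resistant`, never out of it.
#'
#' @param fold_change Positive treated/control weight ratio(s).
#' @param p_value P-value(s) from [compute_fold_change()].
#' @param alpha Significance level.
#' @return Character vector over
#'   `{sensitive, resistant, promoted}`.
#' @export
categorize_response <- function(fold_change, p_value, alpha = 0.05) {
  if (any(fold_change <= 0)) stop("fold_change must be positive")
  ifelse(p_value < alpha & fold_change < 1, "sensitive",
         ifelse(p_value < alpha & fold_change > 1, "promoted", "resistant"))
}

#' Phenotype every model in a growth table
#'
#' Applies [compute_fold_change()] and [categorize_response()] per
#' model and derives the binary supervision contrast (sensitive vs
#' all other).
#'
#' @param growth Growth table data.frame with columns `model_id`,
#'   `arm` (`control`/`treated`), `final_weight`.
#' @param alpha Significance level for categorization.
#' @param var_equal Pooled-variance t-test instead of Welch?
#' @return data.frame: `model_id`, `fold_change`, `p_value`,
#'   `category`, `supervision_class`.
#' @export
label_models <- function(growth, alpha = 0.05, var_equal = FALSE) {
  models <- unique(growth$model_id)
  rows <- lapply(models, function(m) {
    g <- growth[growth$model_id == m, ]
    fc <- compute_fold_change(g$final_weight[g$arm == "treated"],
                              g$final_weight[g$arm == "control"],
                              var_equal = var_equal)
    data.frame(model_id = m, fold_change = fc$fold_change,
               p_value = fc$p_value,
               category = categorize_response(fc$fold_change, fc$p_value, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$supervision_class <- ifelse(out$category == "sensitive",
                                  "sensitive", "other")
  out
}

#' Fisher's exact association between phenotype and a binary covariate
#'
#' Builds the 2x2 table of supervision class against the covariate and
#' tests it with a two-sided Fisher's exact test.
#'
#' @param labels Named character vector (or factor) of supervision
#'   classes (`sensitive`/`other`) per model.
#' @param covariate Named logical (or two-level) vector per model; the
#'   names must match `labels` exactly (any order).
#' @return List with `table` (2x2 contingency table) and `p_value`.
#' @export
association_test <- function(labels, covariate) {
  if (is.null(names(labels)) || is.null(names(covariate)) ||
      !setequal(names(labels), names(covariate)) ||
      anyDuplicated(names(labels)) || anyDuplicated(names(covariate))) {
    stop("labels and covariate must be named by the same model ids")
  }
  covariate <- covariate[names(labels)]
  tab <- table(class = factor(labels, levels = c("sensitive", "other")),
               covariate = covariate)
  if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    # a zero margin carries no information: p = 1 by convention
    return(list(table = tab, p_value = 1))
  }
  list(table = tab, p_value = stats::fisher.test(tab)$p.value)
}
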