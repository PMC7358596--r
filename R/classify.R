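## Ligand classification: the frozen published rule (single G-alpha-GDP
## energy cutoffs), an alternative Gaussian-posterior classifier matching
## the behaviour of standard discriminant-analysis classification tables,
## and evaluation against reference labels.

#' The frozen published discriminant rule
#'
#' Returns the published constants as a ready-to-use model and cutoff
#' set: score = 0.010 x dG(GPCR(L)-Galpha-GDP) + 7.895, with score
#' cutoffs 1.231 (antagonist / partial agonist) and -0.978 (partial
#' agonist / agonist), corresponding to energy cutoffs of -666 and -887
#' kcal/mol. These constants are frozen as printed (the energy cutoffs at
#' integer precision, as applied in the original validation work); they
#' are not refitted.
#'
#' @return list with elements `model` (a frozen `discriminant_model`
#'   without centroids) and `cutoffs` (a `cutoff_set`).
#' @export
#' @examples
#' rule <- published_rule()
#' rule$cutoffs$energy_antago_pa   # -666
published_rule <- function() {
  model <- structure(list(
    features = "dg_gdp",
    coefficients = c(dg_gdp = 0.010),
    constant = 7.895,
    class_centroids = NULL,
    class_counts = NULL,
    training_n = NA_integer_,
    grand_mean = c(dg_gdp = -789.5),
    eigenvalues = NULL,
    class_field = "bib_class",
    n_excluded = NA_integer_,
    frozen = TRUE
  ), class = "discriminant_model")
  list(model = model,
       cutoffs = cutoff_set(theta_antago_pa = 1.231, theta_pa_ago = -0.978,
                            energy_antago_pa = -666, energy_pa_ago = -887))
}

#' Classify ligands by their G-alpha-GDP binding energy
#'
#' The frozen three-class rule on the energy scale: an absent energy (no
#' docking solution) is a `non_interactor`; otherwise energies at or below
#' the partial-agonist/agonist cutoff are `agonist`, energies at or below
#' the antagonist/partial-agonist cutoff are `partial_agonist`, and the
#' rest are `antagonist`. Boundary ties go to the more-active side (a
#' value exactly at a cutoff takes the stronger-binding class).
#'
#' @param dg_gdp numeric vector of liganded-receptor / G-alpha-GDP binding
#'   free energies in kcal/mol (`NA` = absent).
#' @param cutoffs a `cutoff_set` with energy cutoffs; defaults to the
#'   published ones.
#' @return character vector of classes.
#' @export
#' @examples
#' classify_energy(c(-896.5, -663, -736.2, NA))
classify_energy <- function(dg_gdp, cutoffs = published_rule()$cutoffs) {
  if (is.na(cutoffs$energy_antago_pa) || is.na(cutoffs$energy_pa_ago)) {
    stop("cutoff set has no energy-scale cutoffs", call. = FALSE)
  }
  out <- rep("non_interactor", length(dg_gdp))
  present <- !is.na(dg_gdp)
  out[present & dg_gdp <= cutoffs$energy_pa_ago] <- "agonist"
  out[present & dg_gdp > cutoffs$energy_pa_ago &
        dg_gdp <= cutoffs$energy_antago_pa] <- "partial_agonist"
  out[present & dg_gdp > cutoffs$energy_antago_pa] <- "antagonist"
  out
}

#' Posterior (normal-density) classification on the discriminant axis
#'
#' Assigns each record the class maximising the normal density of its
#' discriminant score around the class centroid (unit within-group
#' variance) times a class prior. With proportional priors (training
#' class counts) this mirrors the classification-table behaviour of
#' standard discriminant-analysis software; with equal priors the 1-D
#' decision boundaries are the centroid midpoints. Exact posterior ties
#' break toward the less-active class (antagonist over partial agonist
#' over agonist). Records missing a model feature are `non_interactor`.
#'
#' @param model a `discriminant_model` with class centroids and counts.
#' @param table an [energy_table()].
#' @param priors `"proportional"` (training class counts) or `"equal"`.
#' @return data frame with columns `ligand_id`, `receptor_id`, `score`,
#'   `predicted`.
#' @export
classify_posterior <- function(model, table,
                               priors = c("proportional", "equal")) {
  priors <- match.arg(priors)
  if (is.null(model$class_centroids)) {
    stop("model carries no class centroids (frozen rule?); ",
         "fit one with fit_lda()", call. = FALSE)
  }
  cen <- model$class_centroids
  pri <- if (priors == "proportional") {
    model$class_counts / sum(model$class_counts)
  } else {
    stats::setNames(rep(1 / length(cen), length(cen)), names(cen))
  }
  scores <- discriminant_scores(model, table)
  ## less-active-first priority for exact ties
  priority <- c(antagonist = 3L, partial_agonist = 2L, agonist = 1L,
                unknown = 0L)
  ord <- names(cen)[order(-priority[names(cen)])]
  predicted <- vapply(scores, function(s) {
    if (is.na(s)) return("non_interactor")
    logpost <- log(pri[ord]) + stats::dnorm(s, cen[ord], 1, log = TRUE)
    ## near-exact posterior ties resolve by the priority order of `ord`
    ord[logpost >= max(logpost) - 1e-9][1L]
  }, "")
  data.frame(ligand_id = table$ligand_id, receptor_id = table$receptor_id,
             score = scores, predicted = predicted,
             stringsAsFactors = FALSE)
}

#' Evaluate predictions against reference labels
#'
#' Builds a three-class classification report: per-record predictions, a
#' 3x3 confusion matrix (reference x predicted, fixed class order
#' agonist / partial_agonist / antagonist), per-class agreement rates and
#' the overall rate. Records whose reference or prediction is
#' `non_interactor` or `unknown` are excluded from the confusion matrix
#' and counted separately.
#'
#' @param table an [energy_table()].
#' @param predicted either the name of a label column of `table` (e.g.
#'   `"model_class"`) or a character vector of predictions, one per
#'   record.
#' @param reference_field reference label column, `"bib_class"` or
#'   `"model_class"`.
#' @return An object of class `classification_report`: `predictions`,
#'   `confusion`, `per_class_rate`, `overall` (n_correct, n_total,
#'   fraction), and `n_excluded`.
#' @export
#' @examples
#' rep <- evaluate(load_fixture("training_all"), "model_class", "bib_class")
#' rep$overall$fraction   # 0.875
evaluate <- function(table, predicted,
                     reference_field = c("bib_class", "model_class")) {
  reference_field <- match.arg(reference_field)
  pred <- if (length(predicted) == 1L && predicted %in% names(table)) {
    table[[predicted]]
  } else {
    stopifnot(length(predicted) == nrow(table))
    as.character(predicted)
  }
  ref <- table[[reference_field]]
  usable <- ref %in% .pharm_classes & pred %in% .pharm_classes
  if (!any(usable)) {
    stop("no records with both a reference and a predicted ",
         "pharmacological class", call. = FALSE)
  }
  rf <- factor(ref[usable], levels = .pharm_classes)
  pf <- factor(pred[usable], levels = .pharm_classes)
  confusion <- base::table(reference = rf, predicted = pf)
  correct <- diag(confusion)
  row_n <- rowSums(confusion)
  per_class <- ifelse(row_n > 0, correct / row_n, NA_real_)
  n_correct <- sum(correct)
  n_total <- sum(confusion)
  structure(list(
    predictions = data.frame(ligand_id = table$ligand_id,
                             receptor_id = table$receptor_id,
                             reference = ref, predicted = pred,
                             stringsAsFactors = FALSE),
    confusion = unclass(confusion),
    per_class_rate = stats::setNames(as.numeric(per_class),
                                     .pharm_classes),
    overall = list(n_correct = as.integer(n_correct),
                   n_total = as.integer(n_total),
                   fraction = n_correct / n_total),
    n_excluded = sum(!usable)
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report: %d/%d correct (%.1f%%), %d excluded\n",
              x$overall$n_correct, x$overall$n_total,
              100 * x$overall$fraction, x$n_excluded))
  print(x$confusion)
  cat("Per-class agreement:\n")
  for (lev in names(x$per_class_rate)) {
    cat(sprintf("  %-16s %.3f\n", lev, x$per_class_rate[[lev]]))
  }
  invisible(x)
}

#' Serialise a classification report to JSON
#'
#' @param report a `classification_report`.
#' @param provenance optional list describing the classifier that produced
#'   the predictions (frozen-rule constants or fitted-model summary).
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
report_to_json <- function(report, provenance = NULL, path = NULL) {
  payload <- list(
    schema = "gpcrtriage/classification_report/1",
    predictions = report$predictions,
    confusion = report$confusion,
    per_class_rate = as.list(report$per_class_rate),
    overall = report$overall,
    n_excluded = report$n_excluded
  )
  if (!is.null(provenance)) payload$classifier <- provenance
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
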