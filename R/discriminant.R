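## Canonical linear discriminant analysis over docking free-energy
## features, with Wilks-lambda backward elimination and weighted-centroid
## class cutoffs. This is the package's core statistical machinery and is
## implemented from first principles.
##
## Scaling convention (the "unstandardized canonical discriminant function
## coefficients" convention): the first canonical axis v is scaled so that
## v' S_W v = 1, where S_W is the pooled within-group covariance with
## divisor n - g, and the constant is minus the inner product of v with the
## count-weighted grand mean. Training scores therefore have unit pooled
## within-group variance and zero count-weighted mean. The axis sign is
## normalised so the dg_gdp coefficient (or, failing that, the first
## feature's) is positive, which places agonists -- the strongest G-alpha-GDP
## binders, i.e. the most negative energies -- at the lowest scores.

## Rows used for fitting: features all present, class label one of the
## three pharmacological classes. Returns list(x, cls, excluded).
.fit_rows <- function(table, features, class_field) {
  stopifnot(class_field %in% c("bib_class", "model_class"))
  bad <- setdiff(features, .energy_features)
  if (length(bad) > 0L) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(as.data.frame(table)[, features, drop = FALSE])
  cls <- table[[class_field]]
  keep <- stats::complete.cases(x) & cls %in% .pharm_classes
  list(
    x = x[keep, , drop = FALSE],
    cls = droplevels(factor(cls[keep], levels = .pharm_classes)),
    excluded = sum(!keep)
  )
}

## Within-group and total scatter (sums of squares and cross-products).
.scatter <- function(x, cls) {
  p <- ncol(x)
  w <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (lev in levels(cls)) {
    xi <- x[cls == lev, , drop = FALSE]
    d <- sweep(xi, 2L, colMeans(xi))
    w <- w + crossprod(d)
  }
  d <- sweep(x, 2L, colMeans(x))
  list(within = w, total = crossprod(d))
}

#' Fit a canonical linear discriminant to an energy table
#'
#' Computes the first canonical discriminant axis for the docking
#' free-energy features, using the pooled within-group covariance
#' \eqn{S_W} (divisor \eqn{n - g}) and the between-group scatter of the
#' class means. The axis is scaled to unit pooled within-group score
#' variance (\eqn{v' S_W v = 1}) and the constant is
#' \eqn{-v' \bar{x}}{-v . xbar} with \eqn{\bar{x}}{xbar} the count-weighted
#' grand mean, so training scores are centred at zero. For a single feature
#' this reduces to coefficient \eqn{1/s} and constant \eqn{-\bar{x}/s}
#' with \eqn{s} the pooled within-group standard deviation.
#'
#' Records with any missing feature, or without one of the three
#' pharmacological class labels, are excluded listwise; the count is kept
#' in the returned model (`n_excluded`).
#'
#' @param table an [energy_table()].
#' @param features character vector of features to use, a subset of
#'   `dg_ligand`, `dg_gdp`, `dg_gtp`.
#' @param class_field which label column defines the groups.
#' @return An object of class `discriminant_model`: retained features,
#'   named `coefficients`, `constant`, per-class score `class_centroids`
#'   and `class_counts`, `training_n`, per-feature `grand_mean`, the
#'   canonical `eigenvalues`, and `n_excluded`.
#' @export
#' @examples
#' fit <- fit_lda(load_fixture("training_all"), features = "dg_gdp")
#' round(unname(fit$coefficients), 3)   # 0.010
#' round(fit$constant, 3)               # 7.895
fit_lda <- function(table, features = "dg_gdp",
                    class_field = c("bib_class", "model_class")) {
  class_field <- match.arg(class_field)
  rows <- .fit_rows(table, features, class_field)
  x <- rows$x
  cls <- rows$cls
  counts <- base::table(cls)
  if (length(counts) < 2L) {
    stop("need at least 2 classes with data; got ", length(counts),
         call. = FALSE)
  }
  if (any(counts < 2L)) {
    stop("degenerate class(es) with fewer than 2 records: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  n <- nrow(x)
  g <- length(counts)
  p <- ncol(x)
  sc <- .scatter(x, cls)
  s_w <- sc$within / (n - g)
  ## between-group scatter of class means about the grand mean
  grand <- colMeans(x)
  b <- matrix(0, p, p, dimnames = dimnames(s_w))
  for (lev in levels(cls)) {
    d <- colMeans(x[cls == lev, , drop = FALSE]) - grand
    b <- b + counts[[lev]] * tcrossprod(d)
  }
  ## generalized eigenproblem B v = lambda S_W v via Cholesky whitening;
  ## chol() failing or a tiny pivot means collinear features
  u <- tryCatch(chol(s_w), error = function(e) NULL)
  if (is.null(u) || min(diag(u))^2 < 1e-12 * max(diag(s_w))) {
    stop("pooled within-group covariance is singular; ",
         "collinear feature set: ", paste(features, collapse = ", "),
         call. = FALSE)
  }
  m <- backsolve(u, t(backsolve(u, b, transpose = TRUE)), transpose = TRUE)
  es <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- backsolve(u, es$vectors[, 1L])
  v <- v / sqrt(drop(crossprod(v, s_w %*% v)))  # v' S_W v = 1
  names(v) <- colnames(x)
  ## sign convention: positive dg_gdp coefficient (or first feature)
  anchor <- if ("dg_gdp" %in% names(v)) "dg_gdp" else names(v)[1L]
  if (v[[anchor]] < 0) v <- -v
  constant <- -drop(v %*% grand)
  scores <- drop(x %*% v) + constant
  centroids <- vapply(levels(cls), function(lev) mean(scores[cls == lev]),
                      0)
  structure(list(
    features = colnames(x),
    coefficients = v,
    constant = constant,
    class_centroids = centroids,
    class_counts = stats::setNames(as.integer(counts), names(counts)),
    training_n = n,
    grand_mean = grand,
    eigenvalues = pmax(es$values, 0),
    class_field = class_field,
    n_excluded = rows$excluded
  ), class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat("Canonical linear discriminant (unit pooled within-group variance)\n")
  eq <- paste(sprintf("%.4g x %s", x$coefficients, x$features),
              collapse = " + ")
  cat(sprintf("  score = %s + %.4g\n", eq, x$constant))
  cat(sprintf("  fitted on %d records (%d excluded), classes by %s\n",
              x$training_n, x$n_excluded, x$class_field))
  for (lev in names(x$class_centroids)) {
    cat(sprintf("  centroid %-16s %8.3f  (n = %d)\n", lev,
                x$class_centroids[[lev]], x$class_counts[[lev]]))
  }
  invisible(x)
}

#' Discriminant scores for an energy table
#'
#' Applies a fitted (or frozen) discriminant function to each record.
#' Records missing any of the model's features score `NA`.
#'
#' @param model a `discriminant_model`.
#' @param table an [energy_table()].
#' @return numeric vector of scores, one per record.
#' @export
discriminant_scores <- function(model, table) {
  x <- as.matrix(as.data.frame(table)[, model$features, drop = FALSE])
  out <- rep(NA_real_, nrow(x))
  ok <- stats::complete.cases(x)
  out[ok] <- drop(x[ok, , drop = FALSE] %*% model$coefficients) +
    model$constant
  out
}

## Wilks' lambda for a feature subset: det(W_S) / det(T_S), with the empty
## set scoring 1 (no discrimination).
.wilks_lambda <- function(x, cls, features) {
  if (length(features) == 0L) return(1)
  xs <- x[, features, drop = FALSE]
  sc <- .scatter(xs, cls)
  det(sc$within) / det(sc$total)
}

#' Backward elimination of discriminant features by partial F
#'
#' Starting from the full feature list, repeatedly removes the feature
#' with the smallest F-to-remove -- the partial F computed from the change
#' in Wilks' lambda when that feature is dropped conditional on the others,
#' \eqn{F_j = \frac{1 - \Lambda_j}{\Lambda_j} \cdot \frac{n-g-p+1}{g-1}}
#' with \eqn{\Lambda_j = \Lambda(S)/\Lambda(S \setminus j)} -- as long as
#' that F falls below `f_to_remove`. Ties break deterministically by
#' feature-list order. The default threshold 2.71 is the common stepwise
#' default.
#'
#' @inheritParams fit_lda
#' @param f_to_remove removal threshold on the partial F.
#' @return A list of class `backward_elimination` with `retained` (feature
#'   names, possibly empty), `trace` (one row per removal: feature,
#'   partial F, Wilks' lambda before/after), `f_to_remove`, and
#'   `empty_model` flag.
#' @export
backward_eliminate <- function(table, features = .energy_features,
                               class_field = c("bib_class", "model_class"),
                               f_to_remove = 2.71) {
  class_field <- match.arg(class_field)
  rows <- .fit_rows(table, features, class_field)
  x <- rows$x
  cls <- rows$cls
  counts <- base::table(cls)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("each class needs at least 2 records for elimination",
         call. = FALSE)
  }
  n <- nrow(x)
  g <- length(counts)
  current <- colnames(x)
  trace <- data.frame(step = integer(), feature_removed = character(),
                      partial_f = numeric(), lambda_before = numeric(),
                      lambda_after = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > 0L) {
    p <- length(current)
    lam_full <- .wilks_lambda(x, cls, current)
    partial_f <- vapply(current, function(f) {
      lam_red <- .wilks_lambda(x, cls, setdiff(current, f))
      lam_j <- lam_full / lam_red
      (1 - lam_j) / lam_j * (n - g - p + 1) / (g - 1)
    }, 0)
    if (min(partial_f) >= f_to_remove) break
    drop_f <- current[which.min(partial_f)]  # which.min: first = list order
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, feature_removed = drop_f,
      partial_f = partial_f[[drop_f]], lambda_before = lam_full,
      lambda_after = .wilks_lambda(x, cls, setdiff(current, drop_f)),
      stringsAsFactors = FALSE))
    current <- setdiff(current, drop_f)
  }
  structure(list(retained = current, trace = trace,
                 f_to_remove = f_to_remove,
                 empty_model = length(current) == 0L),
            class = "backward_elimination")
}

#' @export
print.backward_elimination <- function(x, ...) {
  cat("Backward elimination (F-to-remove threshold", x$f_to_remove, ")\n")
  if (nrow(x$trace) == 0L) cat("  no features removed\n")
  else print(x$trace, row.names = FALSE)
  cat("  retained:", if (x$empty_model) "(none)"
      else paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Class centroids of discriminant scores
#'
#' Per-class arithmetic mean of the discriminant scores of `table`'s
#' records (records with missing features or without a pharmacological
#' class label are skipped).
#'
#' @param model a `discriminant_model`.
#' @param table an [energy_table()].
#' @param class_field label column defining the groups; defaults to the
#'   one the model was fitted with.
#' @return data frame with columns `class`, `centroid`, `n`.
#' @export
centroids <- function(model, table, class_field = model$class_field) {
  scores <- discriminant_scores(model, table)
  cls <- table[[class_field]]
  keep <- !is.na(scores) & cls %in% .pharm_classes
  cls <- droplevels(factor(cls[keep], levels = .pharm_classes))
  data.frame(
    class = levels(cls),
    centroid = vapply(levels(cls),
                      function(lev) mean(scores[keep][cls == lev]), 0),
    n = as.integer(base::table(cls)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Count-weighted mean of two group centroids
#'
#' The class-boundary estimator: \eqn{(m_1 n_1 + m_2 n_2) / (n_1 + n_2)}.
#'
#' @param mean1,mean2 group means.
#' @param n1,n2 group sizes (>= 1).
#' @return the weighted mean.
#' @export
weighted_mean_cutoff <- function(mean1, n1, mean2, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  (mean1 * n1 + mean2 * n2) / (n1 + n2)
}

#' Derive class cutoffs from a fitted discriminant
#'
#' Computes the two boundaries of the three pharmacological classes as
#' count-weighted means of adjacent class centroids on the discriminant
#' axis: antagonist/partial-agonist and partial-agonist/agonist. When the
#' model retains a single feature the score cutoffs are also mapped back
#' to the energy scale through [score_to_energy()].
#'
#' @param model a `discriminant_model` fitted on all three classes.
#' @param table optional [energy_table()]; when given, centroids and
#'   counts are recomputed on it instead of using the training ones.
#' @return An object of class `cutoff_set` with score cutoffs
#'   `theta_antago_pa` and `theta_pa_ago` and (single-feature models only)
#'   energy cutoffs `energy_antago_pa` and `energy_pa_ago` in kcal/mol.
#' @export
derive_cutoffs <- function(model, table = NULL) {
  if (is.null(table)) {
    cen <- model$class_centroids
    cnt <- model$class_counts
  } else {
    cc <- centroids(model, table)
    cen <- stats::setNames(cc$centroid, cc$class)
    cnt <- stats::setNames(cc$n, cc$class)
  }
  if (!all(.pharm_classes %in% names(cen))) {
    stop("cutoff derivation requires all three classes; present: ",
         paste(names(cen), collapse = ", "), call. = FALSE)
  }
  th_apa <- weighted_mean_cutoff(cen[["antagonist"]], cnt[["antagonist"]],
                                 cen[["partial_agonist"]],
                                 cnt[["partial_agonist"]])
  th_pa <- weighted_mean_cutoff(cen[["partial_agonist"]],
                                cnt[["partial_agonist"]],
                                cen[["agonist"]], cnt[["agonist"]])
  single <- length(model$features) == 1L
  cutoff_set(
    theta_antago_pa = th_apa, theta_pa_ago = th_pa,
    energy_antago_pa = if (single) score_to_energy(model, th_apa)
                       else NA_real_,
    energy_pa_ago = if (single) score_to_energy(model, th_pa)
                    else NA_real_
  )
}

#' Construct a cutoff set
#'
#' @param theta_antago_pa,theta_pa_ago score-space boundaries (the
#'   antagonist/partial-agonist one must be the larger).
#' @param energy_antago_pa,energy_pa_ago energy-space boundaries in
#'   kcal/mol, `NA` when the discriminant is not single-feature.
#' @return An object of class `cutoff_set`.
#' @export
cutoff_set <- function(theta_antago_pa, theta_pa_ago,
                       energy_antago_pa = NA_real_,
                       energy_pa_ago = NA_real_) {
  stopifnot(theta_pa_ago < theta_antago_pa)
  if (!is.na(energy_antago_pa) && !is.na(energy_pa_ago)) {
    stopifnot(energy_pa_ago < energy_antago_pa)
  }
  structure(list(theta_antago_pa = unname(theta_antago_pa),
                 theta_pa_ago = unname(theta_pa_ago),
                 energy_antago_pa = unname(energy_antago_pa),
                 energy_pa_ago = unname(energy_pa_ago)),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("Class cutoffs\n")
  cat(sprintf("  antagonist | partial agonist: score %8.3f", x$theta_antago_pa))
  if (!is.na(x$energy_antago_pa))
    cat(sprintf("  (dG %8.1f kcal/mol)", x$energy_antago_pa))
  cat("\n")
  cat(sprintf("  partial agonist | agonist:     score %8.3f", x$theta_pa_ago))
  if (!is.na(x$energy_pa_ago))
    cat(sprintf("  (dG %8.1f kcal/mol)", x$energy_pa_ago))
  cat("\n")
  invisible(x)
}

#' Invert a single-feature discriminant at a score
#'
#' Maps a discriminant score back to the energy scale,
#' \eqn{(score - constant)/coefficient}. Only defined for models with
#' exactly one retained feature.
#'
#' @param model a single-feature `discriminant_model`.
#' @param score numeric score(s).
#' @return energy value(s) in kcal/mol.
#' @export
score_to_energy <- function(model, score) {
  if (length(model$features) != 1L || model$coefficients[[1L]] == 0) {
    stop("score_to_energy requires a single-feature model with a ",
         "nonzero coefficient", call. = FALSE)
  }
  (score - model$constant) / model$coefficients[[1L]]
}

#' Leave-k-out search for the training subset behind published constants
#'
#' The training tables carry 80 records, but the discriminant the method
#' was developed with is described as fitted on 78 compounds, without
#' naming the excluded pair. This diagnostic refits the single-feature
#' discriminant on every subset obtained by dropping `n_drop` records and
#' reports the subset whose derived score cutoffs best match a reference
#' pair (by default the frozen published cutoffs), together with the full
#' parameter set of that fit.
#'
#' @param table an [energy_table()] with the three classes labelled.
#' @param n_drop how many records to leave out (1 or 2).
#' @param reference a `cutoff_set` to match; default [published_rule()]'s.
#' @param feature single feature name, default `dg_gdp`.
#' @param class_field label column, default `bib_class`.
#' @return list with `dropped` (ligand ids), `coefficient`, `constant`,
#'   `theta_antago_pa`, `theta_pa_ago`, and the total absolute cutoff
#'   `deviation` from the reference.
#' @export
training_subset_diagnostic <- function(table, n_drop = 2,
                                       reference = published_rule()$cutoffs,
                                       feature = "dg_gdp",
                                       class_field = "bib_class") {
  stopifnot(n_drop %in% c(1L, 2L))
  x <- table[[feature]]
  cls <- table[[class_field]]
  keep <- !is.na(x) & cls %in% .pharm_classes
  x <- x[keep]
  cls <- factor(cls[keep], levels = .pharm_classes)
  ids <- table$ligand_id[keep]
  n_all <- length(x)
  fit1 <- function(idx) {
    xi <- x[idx]
    ci <- cls[idx]
    cnt <- tabulate(ci, nbins = 3L)
    means <- vapply(1:3, function(k) mean(xi[as.integer(ci) == k]), 0)
    ssw <- sum(vapply(1:3, function(k)
      sum((xi[as.integer(ci) == k] - means[k])^2), 0))
    s <- sqrt(ssw / (length(xi) - 3L))
    coef <- 1 / s
    const <- -mean(xi) / s
    cen <- coef * means + const
    th_apa <- (cen[3] * cnt[3] + cen[2] * cnt[2]) / (cnt[3] + cnt[2])
    th_pa <- (cen[2] * cnt[2] + cen[1] * cnt[1]) / (cnt[2] + cnt[1])
    c(coef, const, th_apa, th_pa)
  }
  combos <- utils::combn(n_all, n_drop)
  best <- NULL
  best_dev <- Inf
  for (j in seq_len(ncol(combos))) {
    drop_idx <- combos[, j]
    r <- fit1(setdiff(seq_len(n_all), drop_idx))
    dev <- abs(r[3] - reference$theta_antago_pa) +
      abs(r[4] - reference$theta_pa_ago)
    if (dev < best_dev) {
      best_dev <- dev
      best <- list(drop_idx = drop_idx, fit = r)
    }
  }
  list(dropped = ids[best$drop_idx],
       coefficient = best$fit[1], constant = best$fit[2],
       theta_antago_pa = best$fit[3], theta_pa_ago = best$fit[4],
       deviation = best_dev)
}

#' Serialise a discriminant model (with optional cutoffs) to JSON
#'
#' @param model a `discriminant_model`.
#' @param cutoffs optional `cutoff_set` to embed.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
model_to_json <- function(model, cutoffs = NULL, path = NULL) {
  payload <- list(
    schema = "gpcrtriage/discriminant_model/1",
    features = model$features,
    coefficients = as.list(model$coefficients),
    constant = model$constant,
    class_centroids = as.list(model$class_centroids),
    class_counts = as.list(model$class_counts),
    training_n = model$training_n,
    n_excluded = model$n_excluded,
    grand_mean = as.list(model$grand_mean),
    class_field = model$class_field
  )
  if (!is.null(cutoffs)) payload$cutoffs <- unclass(cutoffs)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
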