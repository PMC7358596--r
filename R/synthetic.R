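## Class-conditional Gaussian generator for synthetic energy tables. The
## discriminant method assumes three pharmacological classes whose
## liganded-receptor / G-alpha-GDP binding energies separate on the mean
## (agonists most negative, antagonists least negative); this generator
## emulates exactly that structure, with per-class means/SDs estimated by
## default from the packaged training tables.

.spec_channels <- c("gdp", "ligand", "gtp")

#' Specify a class-conditional Gaussian energy-table generator
#'
#' Defines per-class Gaussian parameters for the G-alpha-GDP channel and
#' optionally the ligand and G-alpha-GTP channels, plus per-class sample
#' sizes. Defaults (means, SDs, counts) are estimated from the packaged
#' 80-record training set via [estimate_class_params()], so the default
#' generator emulates the training data's class structure. Means must be
#' ordered agonist < partial_agonist < antagonist and all SDs positive.
#'
#' @param n named integer vector of per-class sample sizes
#'   (agonist, partial_agonist, antagonist), each >= 0.
#' @param mean_gdp,sd_gdp named numeric vectors of per-class parameters
#'   for the G-alpha-GDP energy (kcal/mol).
#' @param mean_ligand,sd_ligand,mean_gtp,sd_gtp optional per-class
#'   parameters for the other two channels (both of a pair or neither).
#' @param truncation if `TRUE` (default), non-negative draws are
#'   resampled so every generated energy is strictly negative.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = NULL, mean_gdp = NULL, sd_gdp = NULL,
                           mean_ligand = NULL, sd_ligand = NULL,
                           mean_gtp = NULL, sd_gtp = NULL,
                           truncation = TRUE) {
  if (is.null(mean_gdp) || is.null(sd_gdp) || is.null(n)) {
    est <- estimate_class_params(load_fixture("training_all"))
    if (is.null(n)) n <- est$n
    if (is.null(mean_gdp)) mean_gdp <- est$mean_gdp
    if (is.null(sd_gdp)) sd_gdp <- est$sd_gdp
  }
  take <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (is.null(names(v))) {
      stopifnot(length(v) == 3L)
      names(v) <- .pharm_classes
    }
    if (!all(.pharm_classes %in% names(v))) {
      stop(what, " must name all three classes", call. = FALSE)
    }
    v[.pharm_classes]
  }
  n <- take(n, "n"); mean_gdp <- take(mean_gdp, "mean_gdp")
  sd_gdp <- take(sd_gdp, "sd_gdp")
  mean_ligand <- take(mean_ligand, "mean_ligand")
  sd_ligand <- take(sd_ligand, "sd_ligand")
  mean_gtp <- take(mean_gtp, "mean_gtp"); sd_gtp <- take(sd_gtp, "sd_gtp")
  stopifnot(all(n >= 0), all(sd_gdp > 0), all(mean_gdp < 0))
  if (xor(is.null(mean_ligand), is.null(sd_ligand)) ||
      xor(is.null(mean_gtp), is.null(sd_gtp))) {
    stop("optional channels need both a mean and an sd vector",
         call. = FALSE)
  }
  if (!is.null(sd_ligand)) stopifnot(all(sd_ligand > 0))
  if (!is.null(sd_gtp)) stopifnot(all(sd_gtp > 0))
  if (!(mean_gdp[["agonist"]] < mean_gdp[["partial_agonist"]] &&
        mean_gdp[["partial_agonist"]] < mean_gdp[["antagonist"]])) {
    stop("mean_gdp must be ordered agonist < partial_agonist < antagonist",
         call. = FALSE)
  }
  structure(list(n = stats::setNames(as.integer(n), .pharm_classes),
                 mean_gdp = mean_gdp, sd_gdp = sd_gdp,
                 mean_ligand = mean_ligand, sd_ligand = sd_ligand,
                 mean_gtp = mean_gtp, sd_gtp = sd_gtp,
                 truncation = isTRUE(truncation)),
            class = "synthetic_spec")
}

#' Estimate per-class Gaussian parameters from an energy table
#'
#' Per-class sample mean and standard deviation of the G-alpha-GDP energy
#' (and of the ligand and G-alpha-GTP channels when fully present), with
#' class counts, packaged as a [synthetic_spec()].
#'
#' @param table an [energy_table()] with at least 2 records per class
#'   (by `bib_class`).
#' @return A `synthetic_spec`.
#' @export
estimate_class_params <- function(table) {
  cls <- factor(table$bib_class, levels = .pharm_classes)
  keep <- !is.na(table$dg_gdp) & !is.na(cls)
  cls <- cls[keep, drop = FALSE]
  counts <- base::table(cls)
  if (any(counts < 2L)) {
    stop("each class needs at least 2 records with dg_gdp; counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
         call. = FALSE)
  }
  per_class <- function(v) {
    v <- v[keep]
    if (anyNA(v)) return(NULL)
    list(mean = vapply(.pharm_classes,
                       function(l) mean(v[cls == l]), 0),
         sd = vapply(.pharm_classes,
                     function(l) stats::sd(v[cls == l]), 0))
  }
  gdp <- per_class(table$dg_gdp)
  if (any(gdp$sd == 0)) {
    stop("degenerate class with zero dg_gdp standard deviation",
         call. = FALSE)
  }
  lig <- per_class(table$dg_ligand)
  gtp <- per_class(table$dg_gtp)
  synthetic_spec(
    n = stats::setNames(as.integer(counts), names(counts)),
    mean_gdp = gdp$mean, sd_gdp = gdp$sd,
    mean_ligand = lig$mean, sd_ligand = lig$sd,
    mean_gtp = gtp$mean, sd_gtp = gtp$sd
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic energy-table spec (class-conditional Gaussians)\n")
  for (lev in .pharm_classes) {
    cat(sprintf("  %-16s n = %5d, dG GDP ~ N(%8.1f, %6.1f)\n", lev,
                x$n[[lev]], x$mean_gdp[[lev]], x$sd_gdp[[lev]]))
  }
  extra <- c(if (!is.null(x$mean_ligand)) "ligand",
             if (!is.null(x$mean_gtp)) "GTP")
  if (length(extra) > 0L)
    cat("  extra channels:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

## Run `expr` under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Simulate an energy table from a synthetic spec
#'
#' Draws independent Gaussians per class and channel. Reproducible for a
#' fixed seed (the caller's RNG state is left untouched). With
#' `truncation` enabled (the default) any non-negative draw is resampled,
#' keeping every generated binding energy strictly negative. Synthetic
#' ligand ids are `syn_ago_001`, `syn_pa_001`, `syn_antago_001`, ...;
#' `bib_class` is set from the generating class and `model_class` is
#' `unknown`.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return An [energy_table()].
#' @export
#' @examples
#' tab <- simulate_energy_table(synthetic_spec(n = c(5, 5, 5)), seed = 1)
simulate_energy_table <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  draw <- function(n, mean, sd) {
    if (n == 0L) return(numeric())
    v <- stats::rnorm(n, mean, sd)
    if (spec$truncation) {
      while (any(v >= 0)) {
        bad <- v >= 0
        v[bad] <- stats::rnorm(sum(bad), mean, sd)
      }
    }
    v
  }
  short <- c(agonist = "ago", partial_agonist = "pa",
             antagonist = "antago")
  .with_seed(seed, {
    parts <- lapply(.pharm_classes, function(lev) {
      k <- spec$n[[lev]]
      if (k == 0L) return(NULL)
      data.frame(
        ligand_id = sprintf("syn_%s_%03d", short[[lev]], seq_len(k)),
        receptor_id = "synthetic",
        galpha_class = "unknown",
        dg_ligand = if (is.null(spec$mean_ligand)) NA_real_
          else draw(k, spec$mean_ligand[[lev]], spec$sd_ligand[[lev]]),
        dg_gdp = draw(k, spec$mean_gdp[[lev]], spec$sd_gdp[[lev]]),
        dg_gtp = if (is.null(spec$mean_gtp)) NA_real_
          else draw(k, spec$mean_gtp[[lev]], spec$sd_gtp[[lev]]),
        bib_class = lev,
        model_class = "unknown",
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, parts)
    if (is.null(df)) {
      return(energy_table(provenance = sprintf("synthetic(seed=%d)", seed)))
    }
    validate_energy_table(df)
    structure(df, class = c("energy_table", "data.frame"),
              provenance = sprintf("synthetic(seed=%d)", seed))
  })
}
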