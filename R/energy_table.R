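#' @keywords internal
"_PACKAGE"

## Controlled vocabularies used across the package. Class order is fixed
## (agonist, partial_agonist, antagonist) so confusion matrices and cutoff
## derivation are deterministic.
.pharm_classes <- c("agonist", "partial_agonist", "antagonist")
.model_classes <- c(.pharm_classes, "non_interactor", "unknown")
.bib_classes <- c(.pharm_classes, "unknown")
.galpha_classes <- c("Gs", "Gi", "Go", "Gq", "unknown")
.energy_features <- c("dg_ligand", "dg_gdp", "dg_gtp")

#' Construct a validated ligand-energy table
#'
#' An energy table holds one row per ligand-receptor pair with up to three
#' docking free-energy channels (all in kcal/mol): the ligand-receptor
#' binding energy (`dg_ligand`), the liganded-receptor to GDP-bound G-alpha
#' binding energy (`dg_gdp`), and the same for the GTP-bound G-alpha
#' (`dg_gtp`). Absent energies (`NA`) mean no docking solution was found for
#' that channel (a non-binder). Two class labels may accompany each pair: a
#' bibliographic pharmacological class (`bib_class`) and a model-predicted
#' class (`model_class`).
#'
#' Validation enforces: unique (ligand_id, receptor_id) pairs; every present
#' free energy strictly negative (binding energies); class labels drawn from
#' the controlled vocabularies; and rows lacking both G-alpha energies
#' carrying a `model_class` of `non_interactor` or `unknown`.
#'
#' @param ligand_id,receptor_id character identifiers.
#' @param galpha_class G-alpha family, one of Gs, Gi, Go, Gq, unknown.
#' @param dg_ligand,dg_gdp,dg_gtp numeric free energies in kcal/mol, `NA`
#'   for absent.
#' @param bib_class bibliographic class: agonist, partial_agonist,
#'   antagonist, unknown.
#' @param model_class model class: the three pharmacological classes plus
#'   non_interactor and unknown.
#' @param provenance character tag recording where the table came from.
#' @return A data frame of class `energy_table`.
#' @export
#' @examples
#' energy_table(ligand_id = "Naldemedine", receptor_id = "mu-opioid",
#'              galpha_class = "Gi", dg_ligand = -15.576, dg_gdp = -657.09,
#'              dg_gtp = -594.69, bib_class = "antagonist")
energy_table <- function(ligand_id = character(), receptor_id = character(),
                         galpha_class = "unknown",
                         dg_ligand = NA_real_, dg_gdp = NA_real_,
                         dg_gtp = NA_real_,
                         bib_class = "unknown", model_class = "unknown",
                         provenance = "constructed") {
  n <- length(ligand_id)
  df <- data.frame(
    ligand_id = as.character(ligand_id),
    receptor_id = as.character(receptor_id),
    galpha_class = rep_len(as.character(galpha_class), n),
    dg_ligand = rep_len(as.numeric(dg_ligand), n),
    dg_gdp = rep_len(as.numeric(dg_gdp), n),
    dg_gtp = rep_len(as.numeric(dg_gtp), n),
    bib_class = rep_len(as.character(bib_class), n),
    model_class = rep_len(as.character(model_class), n),
    stringsAsFactors = FALSE
  )
  validate_energy_table(df)
  structure(df, class = c("energy_table", "data.frame"),
            provenance = provenance)
}

#' Validate the energy-table invariants
#'
#' @param df a data frame with energy-table columns.
#' @return `df`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_energy_table <- function(df) {
  required <- c("ligand_id", "receptor_id", "galpha_class",
                .energy_features, "bib_class", "model_class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("energy table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$ligand_id, df$receptor_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (ligand_id, receptor_id) pair(s): ",
         paste(gsub("\r", " / ", dup), collapse = "; "), call. = FALSE)
  }
  for (f in .energy_features) {
    v <- df[[f]]
    if (any(!is.na(v) & v >= 0)) {
      stop("column ", f, " contains non-negative free energies; ",
           "binding free energies must be strictly negative", call. = FALSE)
    }
  }
  if (!all(df$galpha_class %in% .galpha_classes)) {
    stop("galpha_class values must be one of: ",
         paste(.galpha_classes, collapse = ", "), call. = FALSE)
  }
  if (!all(df$bib_class %in% .bib_classes)) {
    stop("bib_class values must be one of: ",
         paste(.bib_classes, collapse = ", "), call. = FALSE)
  }
  if (!all(df$model_class %in% .model_classes)) {
    stop("model_class values must be one of: ",
         paste(.model_classes, collapse = ", "), call. = FALSE)
  }
  nonbinder <- is.na(df$dg_gdp) & is.na(df$dg_gtp)
  bad <- nonbinder & !(df$model_class %in% c("non_interactor", "unknown"))
  if (any(bad)) {
    stop("row(s) without any G-alpha energy must have model_class ",
         "non_interactor or unknown: ",
         paste(df$ligand_id[bad], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("Energy table '%s': %d ligand-receptor pair(s)\n",
              attr(x, "provenance") %||% "?", nrow(x)))
  if (nrow(x) > 0L) {
    tb <- table(factor(x$bib_class, levels = .bib_classes))
    cat("  bibliographic classes:",
        paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
    nb <- sum(is.na(x$dg_gdp) & is.na(x$dg_gtp))
    if (nb > 0L) cat("  non-binders (no G-alpha energy):", nb, "\n")
  }
  NextMethod()
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
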