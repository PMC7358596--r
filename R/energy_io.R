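## Delimited-text I/O for energy tables, plus the packaged verification
## fixtures. The on-disk format is a headed CSV/TSV with columns
##   ligand_id, receptor_id, galpha_class,
##   dg_ligand_kcal, dg_gdp_kcal, dg_gtp_kcal, bib_class, model_class
## Absent free energies are written as the token "X" (no docking solution);
## class labels use a small controlled vocabulary, accepted
## case-insensitively ("Ago", "PA", "Antago" and full names).

.header_map <- c(
  dg_ligand_kcal = "dg_ligand",
  dg_gdp_kcal = "dg_gdp",
  dg_gtp_kcal = "dg_gtp"
)

.class_vocab <- c(
  "ago" = "agonist", "agonist" = "agonist",
  "pa" = "partial_agonist", "partial agonist" = "partial_agonist",
  "partial-agonist" = "partial_agonist",
  "partial_agonist" = "partial_agonist",
  "antago" = "antagonist", "antagonist" = "antagonist",
  "non_interactor" = "non_interactor",
  "non-interactor" = "non_interactor",
  "ni" = "non_interactor",
  "na" = "unknown", "unknown" = "unknown"
)

.normalize_class <- function(x, column) {
  x[is.na(x)] <- ""
  key <- tolower(trimws(x))
  key[key == ""] <- "unknown"
  out <- unname(.class_vocab[key])
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unrecognised ", column, " token(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

.normalize_galpha <- function(x) {
  x[is.na(x)] <- ""
  key <- tolower(trimws(x))
  key[key == "" | key == "na"] <- "unknown"
  lut <- stats::setNames(.galpha_classes, tolower(.galpha_classes))
  out <- unname(lut[key])
  if (anyNA(out)) {
    stop("unrecognised galpha_class token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

.parse_dg <- function(x, column) {
  x[is.na(x)] <- ""
  tok <- trimws(x)
  absent <- tok == "" | toupper(tok) == "X"
  out <- rep(NA_real_, length(tok))
  val <- suppressWarnings(as.numeric(tok[!absent]))
  if (anyNA(val)) {
    rows <- which(!absent)[is.na(val)]
    stop("non-numeric value in column ", column, " at data row ",
         paste(rows, collapse = ", "), " (use \"X\" for absent)",
         call. = FALSE)
  }
  out[!absent] <- val
  out
}

#' Read an energy table from delimited text
#'
#' Reads a headed CSV or TSV of docking free energies into a validated
#' [energy_table()]. The delimiter is auto-detected from the header line
#' (tab wins if present, else comma) unless given. The token `"X"`
#' (case-insensitive) or an empty cell in an energy column means the energy
#' is absent (no docking solution). Class tokens are normalised through a
#' controlled vocabulary (`"Ago"`, `"PA"`, `"Antago"`, full names, `"NA"`).
#'
#' @param path path to a delimited text file with a header row.
#' @param delim field delimiter; `NULL` (default) auto-detects.
#' @return An [energy_table()] with provenance set to `path`.
#' @export
read_energy_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, encoding = "UTF-8",
                           comment.char = "")
  names(raw) <- ifelse(names(raw) %in% names(.header_map),
                       .header_map[names(raw)], names(raw))
  for (col in c("ligand_id", "receptor_id")) {
    if (!col %in% names(raw)) {
      stop("missing required column: ", col, call. = FALSE)
    }
  }
  n <- nrow(raw)
  df <- data.frame(
    ligand_id = raw$ligand_id,
    receptor_id = raw$receptor_id,
    galpha_class = if ("galpha_class" %in% names(raw))
      .normalize_galpha(raw$galpha_class) else rep("unknown", n),
    stringsAsFactors = FALSE
  )
  for (f in .energy_features) {
    df[[f]] <- if (f %in% names(raw)) .parse_dg(raw[[f]], f)
               else rep(NA_real_, n)
  }
  df$bib_class <- if ("bib_class" %in% names(raw))
    .normalize_class(raw$bib_class, "bib_class") else rep("unknown", n)
  df$model_class <- if ("model_class" %in% names(raw))
    .normalize_class(raw$model_class, "model_class") else rep("unknown", n)
  validate_energy_table(df)
  structure(df, class = c("energy_table", "data.frame"), provenance = path)
}

#' Write an energy table to delimited text
#'
#' Inverse of [read_energy_table()]: absent energies are emitted as `"X"`,
#' so `read_energy_table(write_energy_table(t, path))` reproduces `t`
#' field for field.
#'
#' @param table an [energy_table()].
#' @param path output file path.
#' @param delim field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path, delim = ",") {
  validate_energy_table(table)
  fmt_dg <- function(v) ifelse(is.na(v), "X", vapply(v, format, "",
                                                     scientific = FALSE))
  out <- data.frame(
    ligand_id = table$ligand_id,
    receptor_id = table$receptor_id,
    galpha_class = table$galpha_class,
    dg_ligand_kcal = fmt_dg(table$dg_ligand),
    dg_gdp_kcal = fmt_dg(table$dg_gdp),
    dg_gtp_kcal = fmt_dg(table$dg_gtp),
    bib_class = table$bib_class,
    model_class = table$model_class,
    stringsAsFactors = FALSE
  )
  ## quote only the columns whose fields contain the delimiter
  qcols <- which(vapply(out, function(col)
    any(grepl(delim, col, fixed = TRUE)), TRUE))
  ok <- tryCatch({
    utils::write.table(out, path, sep = delim,
                       quote = if (length(qcols)) qcols else FALSE,
                       row.names = FALSE, col.names = TRUE, na = "X")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Load a packaged verification table
#'
#' The package ships transcriptions of the published docking free-energy
#' tables: three training tables (`table1`: beta2-adrenergic and
#' prostaglandin-DR2 / Gs; `table2`: dopamine-D3, mu-opioid, adenosine-A1
#' and rhodopsin / Gi; `table3`: serotonin / Go), the four FDA-drug
#' validation rows (`table4`, up to two receptor rows per drug, with `"X"`
#' marking receptors whose G-alpha did not associate), and the 13-ligand
#' OXER1 validation set (`table5`). `training_all` concatenates tables 1-3
#' into the 80-record training set, with both bibliographic and
#' model-predicted labels populated.
#'
#' @param name one of `"table1"` ... `"table5"`, `"training_all"`.
#' @return An [energy_table()].
#' @export
#' @examples
#' nrow(load_fixture("training_all"))   # 80
load_fixture <- function(name = c("table1", "table2", "table3", "table4",
                                  "table5", "training_all")) {
  name <- match.arg(name)
  one <- function(nm) {
    path <- system.file("extdata", paste0(nm, ".csv"),
                        package = "gpcrtriage", mustWork = TRUE)
    read_energy_table(path)
  }
  if (name == "training_all") {
    parts <- lapply(c("table1", "table2", "table3"), one)
    df <- do.call(rbind, lapply(parts, as.data.frame))
    validate_energy_table(df)
    return(structure(df, class = c("energy_table", "data.frame"),
                     provenance = "training_all"))
  }
  tab <- one(name)
  attr(tab, "provenance") <- name
  tab
}

#' Serialise an energy table to JSON
#'
#' @param table an [energy_table()].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
energy_table_json <- function(table, path = NULL) {
  validate_energy_table(table)
  payload <- list(
    schema = "gpcrtriage/energy_table/1",
    provenance = attr(table, "provenance") %||% "unknown",
    records = as.data.frame(table)
  )
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
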