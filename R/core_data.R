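#' Reference toxicity panel of 15 antibiotics
#'
#' Loads the packaged single-chemical toxicity table: for each antibiotic the
#' acute (15 min) and chronic (24 h) potency as \eqn{-\lg EC_{50}} (mol/L
#' basis), the linear dose-response slopes \eqn{K_a} and \eqn{K_c} (% inhibition
#' per log10 concentration decade), and three docking-based interaction
#' energies (kcal/mol): with luciferase (`e_luc`, the acute target), with the
#' class-specific chronic target protein (`e_target`; DHPS for sulfonamides,
#' DHFR for sulfonamide potentiators, the ribosomal 30S subunit for
#' tetracyclines) and with the quorum-sensing master regulator LitR
#' (`e_litr`).
#'
#' @return A data.frame of 15 rows with class `toxicity_dataset`, one row per
#'   antibiotic, keyed by `abbr`.
#' @examples
#' chems <- antibiotic_toxicity()
#' table(chems$chem_class)
#' @export
antibiotic_toxicity <- function() {
  path <- system.file("extdata", "antibiotic_toxicity.csv",
                      package = "qstracr", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged antibiotic toxicity table not found; installation is corrupt",
         call. = FALSE)
  }
  read_toxicity_data(path, schema = "chemicals")
}

#' Read a toxicity data table
#'
#' Reads one of the three delimited-text (CSV with header) interchange formats
#' used by the pipeline and validates it against the schema's invariants.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"chemicals"` (single-chemical records),
#'   `"dose_response"` (raw concentration/inhibition observations) or
#'   `"mixtures"` (binary-mixture records).
#' @return A validated data.frame; for `"chemicals"` it carries class
#'   `toxicity_dataset`. Row order is preserved. A header-only file yields an
#'   empty (0-row) table.
#' @seealso [write_toxicity_data()], [antibiotic_toxicity()]
#' @export
read_toxicity_data <- function(path, schema = c("chemicals", "dose_response",
                                                "mixtures")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  cols <- switch(schema,
    chemicals     = .chemical_cols,
    dose_response = .dose_response_cols,
    mixtures      = .mixture_cols
  )
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop(sprintf("%s file '%s' is missing column(s): %s", schema, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- x[cols]
  num_cols <- switch(schema,
    chemicals     = .chemical_cols[4:10],
    dose_response = c("concentration_mol_per_l", "inhibition_percent"),
    mixtures      = c("slope_K", "intercept_b", "neg_log_ec50_mix",
                      "conc_a_at_50", "conc_b_at_50", "tu")
  )
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric value in column '%s', row %d of '%s'",
                   cc, which(is.na(v))[1], path), call. = FALSE)
    }
    x[[cc]] <- v
  }
  out <- switch(schema,
    chemicals     = validate_chemicals(x),
    dose_response = validate_dose_response(x),
    mixtures      = validate_mixtures(x)
  )
  out
}

#' Write a toxicity data table
#'
#' Writes a table previously read (or built) in one of the pipeline schemas
#' back to CSV. Numeric fields are formatted with 15 significant digits so a
#' read/write round trip reproduces the values.
#'
#' @param x A data.frame in one of the three schemas.
#' @param path Destination file path.
#' @return Invisibly, `path`.
#' @export
write_toxicity_data <- function(x, path) {
  y <- as.data.frame(x)
  for (cc in names(y)) {
    if (is.numeric(y[[cc]])) {
      y[[cc]] <- vapply(y[[cc]], function(v) format(v, digits = 15, trim = TRUE),
                        character(1))
    }
  }
  status <- try(utils::write.csv(y, path, row.names = FALSE, quote = TRUE),
                silent = TRUE)
  if (inherits(status, "try-error")) {
    stop("failed to write '", path, "': ", attr(status, "condition")$message,
         call. = FALSE)
  }
  invisible(path)
}

#' Validate a single-chemical record table
#'
#' Checks the invariants every chemical record must satisfy: positive slopes
#' and potencies, strictly negative interaction energies (binding is
#' favourable), unique abbreviations, a known chemical class, and agreement of
#' the stated target protein with the class (SA to DHPS, SAP to DHFR, TC to
#' the ribosomal 30S subunit).
#'
#' @param x A data.frame with the `chemicals` schema columns.
#' @return `x`, with class `toxicity_dataset`, invisibly usable downstream.
#' @export
validate_chemicals <- function(x) {
  fail <- function(row, msg) {
    stop(sprintf("chemicals row %d (%s): %s", row,
                 if (is.na(x$abbr[row])) "?" else x$abbr[row], msg),
         call. = FALSE)
  }
  if (anyDuplicated(x$abbr)) {
    stop("duplicate abbr key(s): ",
         paste(unique(x$abbr[duplicated(x$abbr)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(x))) {
    if (!x$chem_class[i] %in% names(.class_targets))
      fail(i, paste0("unknown chem_class '", x$chem_class[i], "'"))
    if (!is.finite(x$slope_acute[i]) || x$slope_acute[i] <= 0)
      fail(i, "slope_acute (Ka) must be > 0")
    if (!is.finite(x$slope_chronic[i]) || x$slope_chronic[i] <= 0)
      fail(i, "slope_chronic (Kc) must be > 0")
    if (!is.finite(x$neg_log_ec50_acute[i]) || x$neg_log_ec50_acute[i] <= 0)
      fail(i, "neg_log_ec50_acute must be > 0 (EC50 below 1 mol/L)")
    if (!is.finite(x$neg_log_ec50_chronic[i]) || x$neg_log_ec50_chronic[i] <= 0)
      fail(i, "neg_log_ec50_chronic must be > 0 (EC50 below 1 mol/L)")
    for (ec in c("e_luc", "e_target", "e_litr")) {
      if (!is.finite(x[[ec]][i]) || x[[ec]][i] >= 0)
        fail(i, paste0(ec, " must be negative (favourable binding)"))
    }
    if (x$target_protein[i] != .class_targets[[x$chem_class[i]]])
      fail(i, sprintf("target_protein '%s' inconsistent with class %s (expected %s)",
                      x$target_protein[i], x$chem_class[i],
                      .class_targets[[x$chem_class[i]]]))
  }
  class(x) <- c("toxicity_dataset", "data.frame")
  x
}

validate_dose_response <- function(x) {
  if (nrow(x)) {
    bad_assay <- which(!x$assay %in% c("acute", "chronic"))
    if (length(bad_assay))
      stop(sprintf("dose_response row %d: assay must be 'acute' or 'chronic'",
                   bad_assay[1]), call. = FALSE)
    bad_c <- which(!is.finite(x$concentration_mol_per_l) |
                     x$concentration_mol_per_l <= 0)
    if (length(bad_c))
      stop(sprintf("dose_response row %d: concentration must be > 0 mol/L",
                   bad_c[1]), call. = FALSE)
    bad_i <- which(!is.finite(x$inhibition_percent) | x$inhibition_percent > 100)
    if (length(bad_i))
      stop(sprintf("dose_response row %d: inhibition cannot exceed 100%%",
                   bad_i[1]), call. = FALSE)
  }
  x
}

validate_mixtures <- function(x) {
  if (nrow(x)) {
    bad_assay <- which(!x$assay %in% c("acute", "chronic"))
    if (length(bad_assay))
      stop(sprintf("mixtures row %d: assay must be 'acute' or 'chronic'",
                   bad_assay[1]), call. = FALSE)
    for (cc in c("slope_K", "neg_log_ec50_mix", "conc_a_at_50",
                 "conc_b_at_50", "tu")) {
      bad <- which(!is.finite(x[[cc]]) | x[[cc]] <= 0)
      if (length(bad))
        stop(sprintf("mixtures row %d: %s must be > 0", bad[1], cc),
             call. = FALSE)
    }
    cls <- classify_joint_effect(x$tu)
    bad <- which(cls != x$joint_effect)
    if (length(bad))
      stop(sprintf(
        "mixtures row %d: joint_effect '%s' inconsistent with tu = %g (expected '%s')",
        bad[1], x$joint_effect[bad[1]], x$tu[bad[1]], cls[bad[1]]),
        call. = FALSE)
  }
  x
}

#' @export
print.toxicity_dataset <- function(x, ...) {
  cat(sprintf("Toxicity dataset: %d chemicals (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(x$chem_class)[unique(x$chem_class)],
                            unique(x$chem_class)), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}
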