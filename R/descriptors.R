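#' Canonical descriptor names
#'
#' The ten physico-chemical descriptors used throughout the package, in
#' canonical order: six continuous (molar mass in g/mol, percentage of
#' aromatic heavy atoms, polar surface area in square Angstrom, log D at
#' pH 7.4, log S, log P) and four discrete counts evaluated on the major
#' species at pH 7.4 (rotatable bonds, H-bond acceptors, H-bond donors,
#' net formal charge).
#'
#' @return Character vector of descriptor names.
#' @export
#' @examples
#' descriptor_names()
descriptor_names <- function() c(continuous_descriptors(), discrete_descriptors())

#' @rdname descriptor_names
#' @export
continuous_descriptors <- function() {
  c("molar_mass", "aromatic_pct", "psa", "logd74", "logs", "logp")
}

#' @rdname descriptor_names
#' @export
discrete_descriptors <- function() {
  c("rotatable_bonds", "hba74", "hbd74", "formal_charge74")
}

# counts that must be non-negative (formal charge may be negative)
.nonneg_counts <- function() c("rotatable_bonds", "hba74", "hbd74")

#' Validate a descriptor set
#'
#' Checks that a named list or one-row data frame carries all ten
#' descriptors with admissible values: positive molar mass, aromatic
#' percentage in [0, 100], non-negative PSA, integer counts
#' (non-negative except formal charge). Scoring refuses incomplete sets,
#' so this is the single gatekeeper.
#'
#' @param x Named list, named numeric vector, or one-row data frame.
#' @return A named list with the ten descriptors, counts stored as
#'   integers. Errors (class \code{hl_descriptor_error}) describe every
#'   violated constraint.
#' @export
#' @examples
#' as_descriptor_set(c(molar_mass = 317, aromatic_pct = 25, psa = 72,
#'   logd74 = 2.2, logs = -3.5, logp = 2.9, rotatable_bonds = 5,
#'   hba74 = 2, hbd74 = 0, formal_charge74 = 0))
as_descriptor_set <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single row of descriptors")
    x <- as.list(x)
  }
  x <- as.list(x)
  need <- descriptor_names()
  missing <- setdiff(need, names(x))
  present <- intersect(need, names(x))
  bad_na <- present[vapply(x[present], function(v) !is.numeric(v) || is.na(v), logical(1))]
  missing <- union(missing, bad_na)
  if (length(missing)) {
    stop(errorCondition(
      paste0("incomplete descriptor set; missing or non-numeric: ",
             paste(missing, collapse = ", ")),
      class = c("hl_descriptor_error", "hl_error")))
  }
  out <- lapply(x[need], as.numeric)
  probs <- character(0)
  if (out$molar_mass <= 0) probs <- c(probs, "molar_mass must be > 0")
  if (out$aromatic_pct < 0 || out$aromatic_pct > 100)
    probs <- c(probs, "aromatic_pct must lie in [0, 100]")
  if (out$psa < 0) probs <- c(probs, "psa must be >= 0")
  for (d in discrete_descriptors()) {
    v <- out[[d]]
    if (abs(v - round(v)) > 1e-9) {
      probs <- c(probs, paste0(d, " must be an integer (got ", v, ")"))
    } else if (d %in% .nonneg_counts() && round(v) < 0) {
      probs <- c(probs, paste0(d, " must be >= 0"))
    }
  }
  if (length(probs)) {
    stop(errorCondition(paste(probs, collapse = "; "),
                        class = c("hl_descriptor_error", "hl_error")))
  }
  for (d in discrete_descriptors()) out[[d]] <- as.integer(round(out[[d]]))
  out
}

# TRUE if row (named list) carries a full valid descriptor set
has_descriptors <- function(x) {
  !inherits(try(as_descriptor_set(x), silent = TRUE), "try-error")
}

#' Read a compound table
#'
#' Reads a CSV/TSV compound library (the "table" descriptor backend).
#' The canonical header is \code{compound_id}, optionally \code{smiles}
#' and \code{group}, plus the ten descriptor columns of
#' \code{\link{descriptor_names}}; \code{column_map} renames
#' dataset-specific headers onto the canonical ones. Rows that lack
#' required values, or carry non-integer counts, are diverted to a
#' rejects table with a reason; structurally broken input (duplicate
#' identifiers, non-numeric text in a numeric column) is an error with
#' row/column coordinates.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector mapping canonical
#'   names to the file's column names, e.g.
#'   \code{c(compound_id = "Name", logp = "cLogP")}.
#' @param sep Field separator; default guesses from the file extension
#'   (".tsv"/".txt" tab, otherwise comma).
#' @return List with \code{records} (data frame: compound_id, smiles,
#'   group and any descriptor columns present) and \code{rejects}
#'   (data frame: row, compound_id, reason).
#' @export
read_compound_table <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop(errorCondition(paste0("input file not found: ", path),
                        class = c("hl_io_error", "hl_error")))
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop(errorCondition(
          paste0("column_map refers to absent column: ", src),
          class = c("hl_io_error", "hl_error")))
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"compound_id" %in% names(raw)) {
    stop(errorCondition("no compound_id column (use column_map to name one)",
                        class = c("hl_io_error", "hl_error")))
  }
  has_structure <- "smiles" %in% names(raw)
  desc_cols <- intersect(descriptor_names(), names(raw))
  if (!has_structure && length(desc_cols) < length(descriptor_names())) {
    stop(errorCondition(
      paste0("columns must cover either smiles or the full descriptor set; ",
             "missing: ", paste(setdiff(descriptor_names(), desc_cols),
                                collapse = ", ")),
      class = c("hl_io_error", "hl_error")))
  }
  dup <- unique(raw$compound_id[duplicated(raw$compound_id)])
  if (length(dup)) {
    stop(errorCondition(
      paste0("duplicate compound_id: ", paste(dup, collapse = ", ")),
      class = c("hl_io_error", "hl_error")))
  }
  # parse numerics with a locale-independent decimal point
  for (col in desc_cols) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop(errorCondition(
        paste0("non-numeric value ", dQuote(v[bad[1]]), " in column ", col,
               ", row ", bad[1]),
        class = c("hl_io_error", "hl_error")))
    }
    raw[[col]] <- num
  }

  reject_row <- function(i, why) {
    data.frame(row = i, compound_id = raw$compound_id[i], reason = why,
               stringsAsFactors = FALSE)
  }
  rejects <- list()
  keep <- rep(TRUE, nrow(raw))
  full_desc <- length(desc_cols) == length(descriptor_names())
  for (i in seq_len(nrow(raw))) {
    if (is.na(raw$compound_id[i])) {
      rejects[[length(rejects) + 1L]] <- reject_row(i, "missing compound_id")
      keep[i] <- FALSE
      next
    }
    vals <- as.list(raw[i, desc_cols, drop = FALSE])
    n_missing <- sum(vapply(vals, is.na, logical(1)))
    row_has_smiles <- has_structure && !is.na(raw$smiles[i]) && nzchar(raw$smiles[i])
    if (length(desc_cols) && n_missing == 0L && full_desc) {
      bad_count <- discrete_descriptors()[vapply(
        discrete_descriptors(),
        function(d) abs(vals[[d]] - round(vals[[d]])) > 1e-9, logical(1))]
      if (length(bad_count)) {
        rejects[[length(rejects) + 1L]] <-
          reject_row(i, paste0("non-integer count: ",
                               paste(bad_count, collapse = ", ")))
        keep[i] <- FALSE
      }
    } else if (!row_has_smiles) {
      why <- if (length(desc_cols)) {
        paste0("missing required fields: ",
               paste(desc_cols[vapply(vals, is.na, logical(1))], collapse = ", "))
      } else "no structure and no descriptors"
      rejects[[length(rejects) + 1L]] <- reject_row(i, why)
      keep[i] <- FALSE
    }
  }
  records <- raw[keep, , drop = FALSE]
  rownames(records) <- NULL
  for (d in intersect(discrete_descriptors(), names(records))) {
    records[[d]] <- as.integer(round(records[[d]]))
  }
  rej <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(row = integer(0), compound_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(records = records, rejects = rej)
}

#' Write a normalized descriptor table
#'
#' Writes records with the canonical header; continuous descriptors are
#' formatted with two decimal places and counts as integers.
#'
#' @param records Data frame with \code{compound_id} and descriptor
#'   columns (as from \code{\link{read_compound_table}} or
#'   \code{\link{generate_library}}).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_descriptor_table <- function(records, path) {
  cols <- c("compound_id",
            intersect(c("smiles", "group"), names(records)),
            intersect(descriptor_names(), names(records)))
  out <- records[, cols, drop = FALSE]
  for (d in intersect(continuous_descriptors(), names(out))) {
    out[[d]] <- formatC(out[[d]], format = "f", digits = 2)
  }
  for (d in intersect(discrete_descriptors(), names(out))) {
    out[[d]] <- as.integer(out[[d]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
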