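#' Fit a herbicide-likeness reference model
#'
#' Fits per-descriptor reference statistics from a compound library with
#' complete descriptor sets: arithmetic mean and sample standard
#' deviation (n - 1 denominator) for the six continuous descriptors, and
#' the mode (most frequent value, smallest value winning ties) for the
#' four discrete ones. The returned object is the yardstick against
#' which candidate compounds are scored with \code{\link{predict.hl_reference}}.
#'
#' @param records Data frame of compounds: a \code{compound_id} column
#'   plus the ten descriptor columns (see \code{\link{descriptor_names}}).
#' @param provenance Free-text label recording where the model came
#'   from; defaults to \code{"fitted"}.
#' @return An object of class \code{hl_reference}: list with
#'   \code{continuous} (data frame of mean/sd, one row per continuous
#'   descriptor), \code{modes} (named integer vector), \code{n},
#'   \code{provenance}.
#' @seealso \code{\link{published_reference}} for the published
#'   commercial-herbicide parameters.
#' @export
#' @examples
#' lib <- generate_library(herbicide_like_spec(n = 100, seed = 1))
#' fit_reference(lib)
fit_reference <- function(records, provenance = "fitted") {
  if (!is.data.frame(records) || nrow(records) < 2L) {
    stop(errorCondition(
      "need at least 2 records to fit a reference model (sd undefined below that)",
      class = c("hl_fit_error", "hl_error")))
  }
  ids <- if ("compound_id" %in% names(records)) records$compound_id
         else as.character(seq_len(nrow(records)))
  missing_cols <- setdiff(descriptor_names(), names(records))
  if (length(missing_cols)) {
    stop(errorCondition(
      paste0("records lack descriptor columns: ",
             paste(missing_cols, collapse = ", ")),
      class = c("hl_fit_error", "hl_error")))
  }
  for (i in seq_len(nrow(records))) {
    if (!has_descriptors(as.list(records[i, descriptor_names()]))) {
      stop(errorCondition(
        paste0("record ", dQuote(ids[i]), " has an incomplete descriptor set"),
        class = c("hl_fit_error", "hl_error")))
    }
  }
  cont <- continuous_descriptors()
  continuous <- data.frame(
    mean = vapply(cont, function(d) mean(records[[d]]), numeric(1)),
    sd   = vapply(cont, function(d) stats::sd(records[[d]]), numeric(1)),
    row.names = cont)
  modes <- vapply(discrete_descriptors(), function(d) {
    tab <- table(records[[d]])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      message("mode tie for ", d, " among {",
              paste(top, collapse = ", "), "}; smallest value kept")
    }
    as.integer(min(as.integer(top)))
  }, integer(1))
  new_hl_reference(continuous, modes, nrow(records), provenance)
}

new_hl_reference <- function(continuous, modes, n, provenance) {
  stopifnot(identical(rownames(continuous), continuous_descriptors()),
            identical(names(modes), discrete_descriptors()),
            all(continuous$sd >= 0))
  structure(list(continuous = continuous, modes = modes,
                 n = as.integer(n), provenance = provenance),
            class = "hl_reference")
}

#' The published commercial-herbicide reference model
#'
#' The reference statistics of the 360-compound commercial-herbicide
#' database, transcribed at printed precision: molar mass 317 +/- 88
#' g/mol, aromatic atoms 25 +/- 12 %, PSA 72 +/- 39 A^2, log D 2.2 +/-
#' 2.4, log S -3.5 +/- 1, log P 2.9 +/- 1.5; modes rotatable bonds 5,
#' H-bond acceptors 2, H-bond donors 0, formal charge 0. Because these
#' are the printed constants (not a refit), scoring against this model
#' is reproducible without any dataset.
#'
#' @return An \code{hl_reference} object with provenance
#'   \code{"published-2021"} and \code{n = 360}.
#' @export
#' @examples
#' published_reference()
published_reference <- function() {
  continuous <- data.frame(
    mean = c(molar_mass = 317, aromatic_pct = 25, psa = 72,
             logd74 = 2.2, logs = -3.5, logp = 2.9),
    sd   = c(88, 12, 39, 2.4, 1, 1.5),
    row.names = continuous_descriptors())
  modes <- c(rotatable_bonds = 5L, hba74 = 2L, hbd74 = 0L,
             formal_charge74 = 0L)
  new_hl_reference(continuous, modes, 360L, "published-2021")
}

#' @export
print.hl_reference <- function(x, ...) {
  cat("Herbicide-likeness reference model (", x$provenance, ", n = ",
      x$n, ")\n\n", sep = "")
  cat("Continuous descriptors (mean +/- sd):\n")
  df <- x$continuous
  cat(paste0("  ", format(rownames(df), width = 16),
             formatC(df$mean, format = "g", width = 8), " +/- ",
             formatC(df$sd, format = "g"), collapse = "\n"), "\n")
  cat("Discrete descriptor modes:\n")
  cat(paste0("  ", format(names(x$modes), width = 16), x$modes,
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.hl_reference <- function(object, ...) {
  cat("Reference model fitted on", object$n, "compounds (",
      object$provenance, ")\n")
  print(coef(object))
  invisible(coef(object))
}

#' Reference parameters as a matrix
#'
#' @param object An \code{hl_reference} model.
#' @param ... Unused.
#' @return A 10 x 3 matrix with columns \code{mean}, \code{sd},
#'   \code{mode}; continuous rows carry NA modes, discrete rows carry NA
#'   mean/sd.
#' @export
coef.hl_reference <- function(object, ...) {
  m <- matrix(NA_real_, nrow = 10, ncol = 3,
              dimnames = list(descriptor_names(), c("mean", "sd", "mode")))
  m[continuous_descriptors(), "mean"] <- object$continuous$mean
  m[continuous_descriptors(), "sd"] <- object$continuous$sd
  m[discrete_descriptors(), "mode"] <- object$modes
  m
}

#' Serialise / restore a reference model
#'
#' Round-trips an \code{hl_reference} through a flat YAML file with a
#' \code{continuous} section (\code{name: [mean, sd]}) and a
#' \code{discrete} section (\code{name: mode}).
#'
#' @param model An \code{hl_reference} object.
#' @param path YAML file path.
#' @return \code{write_reference}: \code{path} invisibly;
#'   \code{read_reference}: the restored \code{hl_reference}.
#' @export
write_reference <- function(model, path) {
  stopifnot(inherits(model, "hl_reference"))
  obj <- list(
    continuous = stats::setNames(
      lapply(rownames(model$continuous), function(d)
        c(model$continuous[d, "mean"], model$continuous[d, "sd"])),
      rownames(model$continuous)),
    discrete = as.list(model$modes),
    n_reference = model$n,
    provenance = model$provenance)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  obj <- yaml::read_yaml(path)
  cont <- obj$continuous[continuous_descriptors()]
  if (any(vapply(cont, is.null, logical(1)))) {
    stop(errorCondition("reference file lacks a continuous descriptor",
                        class = c("hl_io_error", "hl_error")))
  }
  continuous <- data.frame(
    mean = vapply(cont, function(v) as.numeric(v[1]), numeric(1)),
    sd = vapply(cont, function(v) as.numeric(v[2]), numeric(1)),
    row.names = continuous_descriptors())
  modes <- vapply(discrete_descriptors(), function(d) {
    v <- obj$discrete[[d]]
    if (is.null(v)) stop(errorCondition(
      paste0("reference file lacks discrete descriptor ", d),
      class = c("hl_io_error", "hl_error")))
    as.integer(v)
  }, integer(1))
  new_hl_reference(continuous, modes,
                   if (is.null(obj$n_reference)) NA_integer_ else obj$n_reference,
                   if (is.null(obj$provenance)) paste0("file:", path) else obj$provenance)
}
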