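# Scoring rules: SD bands for continuous descriptors, mode offsets for
# discrete ones.  All scores are half-point multiples; totals are summed in
# integer half-points so no floating drift can enter.

.band_labels <- function() c("within_1sd", "within_2sd", "within_3sd", "beyond_3sd")
.offset_labels <- function() c("-2", "-1", "0", "+1", "+2", "other")

#' Default herbicide-likeness scoring rules
#'
#' The published weighted rule set. Continuous descriptors score 1.5 /
#' 1.0 / 0.5 / -1.0 for falling within 1, 2, 3 or beyond 3 standard
#' deviations of the reference mean, except log P which is weighted
#' double (3.0 / 2.0 / 1.0 / -1.0). Discrete descriptors score by offset
#' from the reference mode: rotatable bonds and H-bond donors
#' 0.5/1.0/1.5/1.0/0.5 for offsets -2..+2 with -1.0 beyond; formal
#' charge is weighted heavily and asymmetrically (offset +2 scores
#' -3.0, -2..+1 score 1.0/2.0/3.0/2.0, beyond -1.0). The published
#' H-bond acceptor row leaves offsets -1 and -2 unspecified:
#' \code{hba_na_policy = "mirrored"} (default) mirrors the +1/+2 scores,
#' \code{"strict"} gives those offsets the catch-all -1.0.
#'
#' The maximal total over the ten descriptors is 18 points.
#'
#' @param hba_na_policy How to score H-bond acceptor counts below the
#'   mode: \code{"mirrored"} or \code{"strict"}.
#' @return An object of class \code{hl_rules}: \code{continuous_bands}
#'   (6 x 4 matrix), \code{discrete_offsets} (4 x 6 matrix, columns
#'   offsets -2..+2 and "other"), \code{hba_na_policy}.
#' @export
#' @examples
#' default_rules()
#' max_score(default_rules())   # 18
default_rules <- function(hba_na_policy = c("mirrored", "strict")) {
  hba_na_policy <- match.arg(hba_na_policy)
  std <- c(1.5, 1.0, 0.5, -1.0)
  cb <- rbind(molar_mass = std, aromatic_pct = std, psa = std,
              logd74 = std, logs = std, logp = c(3.0, 2.0, 1.0, -1.0))
  colnames(cb) <- .band_labels()
  hba_low <- if (hba_na_policy == "mirrored") c(0.5, 1.0) else c(-1.0, -1.0)
  do <- rbind(
    rotatable_bonds = c(0.5, 1.0, 1.5, 1.0, 0.5, -1.0),
    hba74           = c(hba_low, 1.5, 1.0, 0.5, -1.0),
    hbd74           = c(0.5, 1.0, 1.5, 1.0, 0.5, -1.0),
    formal_charge74 = c(1.0, 2.0, 3.0, 2.0, -3.0, -1.0))
  colnames(do) <- .offset_labels()
  new_hl_rules(cb, do, hba_na_policy)
}

new_hl_rules <- function(continuous_bands, discrete_offsets,
                         hba_na_policy = "custom") {
  stopifnot(identical(rownames(continuous_bands), continuous_descriptors()),
            identical(colnames(continuous_bands), .band_labels()),
            identical(rownames(discrete_offsets), discrete_descriptors()),
            identical(colnames(discrete_offsets), .offset_labels()))
  if (any(abs(c(continuous_bands, discrete_offsets) * 2 -
              round(c(continuous_bands, discrete_offsets) * 2)) > 1e-9)) {
    stop(errorCondition("rule scores must be multiples of 0.5",
                        class = c("hl_rules_error", "hl_error")))
  }
  structure(list(continuous_bands = continuous_bands,
                 discrete_offsets = discrete_offsets,
                 hba_na_policy = hba_na_policy),
            class = "hl_rules")
}

#' @export
print.hl_rules <- function(x, ...) {
  cat("Herbicide-likeness scoring rules (max total ", max_score(x),
      ", HBA policy ", x$hba_na_policy, ")\n\nContinuous (SD bands):\n",
      sep = "")
  print(x$continuous_bands)
  cat("\nDiscrete (mode offsets):\n")
  print(x$discrete_offsets)
  invisible(x)
}

#' Maximal and minimal attainable totals of a rule set
#'
#' \code{max_score} sums, over the ten descriptors, the largest score
#' any band or offset can award; \code{min_score} sums the smallest.
#' Under the default rules these are 18 and -12 points.
#'
#' @param rules An \code{hl_rules} object.
#' @return A single score in points.
#' @export
max_score <- function(rules = default_rules()) {
  stopifnot(inherits(rules, "hl_rules"))
  half <- sum(round(2 * apply(rules$continuous_bands, 1, max))) +
    sum(round(2 * apply(rules$discrete_offsets, 1, max)))
  half / 2
}

#' @rdname max_score
#' @export
min_score <- function(rules = default_rules()) {
  stopifnot(inherits(rules, "hl_rules"))
  half <- sum(round(2 * apply(rules$continuous_bands, 1, min))) +
    sum(round(2 * apply(rules$discrete_offsets, 1, min)))
  half / 2
}

#' Serialise / restore scoring rules
#'
#' Round-trips an \code{hl_rules} object through YAML, mirroring the
#' reference-model format, so descriptors can be re-weighted without
#' code changes.
#'
#' @param rules An \code{hl_rules} object.
#' @param path YAML file path.
#' @return \code{write_rules}: \code{path} invisibly; \code{read_rules}:
#'   the restored \code{hl_rules}.
#' @export
write_rules <- function(rules, path) {
  stopifnot(inherits(rules, "hl_rules"))
  obj <- list(
    continuous = stats::setNames(
      lapply(continuous_descriptors(),
             function(d) as.numeric(rules$continuous_bands[d, ])),
      continuous_descriptors()),
    discrete = stats::setNames(
      lapply(discrete_descriptors(),
             function(d) as.numeric(rules$discrete_offsets[d, ])),
      discrete_descriptors()),
    hba_na_policy = rules$hba_na_policy)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  obj <- yaml::read_yaml(path)
  cb <- do.call(rbind, lapply(continuous_descriptors(), function(d) {
    v <- obj$continuous[[d]]
    if (is.null(v) || length(v) != 4L) {
      stop(errorCondition(
        paste0("rules file: bad or missing continuous entry for ", d),
        class = c("hl_io_error", "hl_error")))
    }
    as.numeric(v)
  }))
  dimnames(cb) <- list(continuous_descriptors(), .band_labels())
  do_ <- do.call(rbind, lapply(discrete_descriptors(), function(d) {
    v <- obj$discrete[[d]]
    if (is.null(v) || length(v) != 6L) {
      stop(errorCondition(
        paste0("rules file: bad or missing discrete entry for ", d),
        class = c("hl_io_error", "hl_error")))
    }
    as.numeric(v)
  }))
  dimnames(do_) <- list(discrete_descriptors(), .offset_labels())
  new_hl_rules(cb, do_, if (is.null(obj$hba_na_policy)) "custom"
                        else obj$hba_na_policy)
}
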