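# The weighted herbicide-likeness score.
#
# A continuous descriptor contributes by how many reference standard
# deviations it sits from the reference mean (closed upper band bounds:
# z <= 1, 1 < z <= 2, 2 < z <= 3, z > 3); a discrete one by its integer
# offset from the reference mode.  Totals are accumulated in integer
# half-points.

#' Score a continuous descriptor value by SD band
#'
#' Computes \code{z = |value - mean| / sd} and returns the band score:
#' band 1 for \code{z <= 1}, band 2 for \code{z <= 2}, band 3 for
#' \code{z <= 3}, otherwise the beyond-3SD score. A value exactly at a
#' band edge takes the better score ("within" is read inclusively).
#' With \code{sd = 0} the value is band 1 if it equals the mean and
#' beyond-3SD otherwise. Vectorised over \code{value}.
#'
#' @param value Observed descriptor value(s).
#' @param mean,sd Reference mean and standard deviation (\code{sd >= 0}).
#' @param band_scores Four scores, ordered within-1SD, within-2SD,
#'   within-3SD, beyond-3SD.
#' @return List with \code{score} and \code{band} (label), each the
#'   length of \code{value}.
#' @export
#' @examples
#' score_continuous(2.9, 2.9, 1.5, c(3, 2, 1, -1))   # at the mean: 3.0
score_continuous <- function(value, mean, sd, band_scores) {
  stopifnot(is.numeric(value), is.numeric(mean), is.numeric(sd),
            length(band_scores) == 4L)
  if (sd < 0) {
    stop(errorCondition("sd must be >= 0",
                        class = c("hl_score_error", "hl_error")))
  }
  z <- if (sd == 0) ifelse(value == mean, 0, Inf) else abs(value - mean) / sd
  idx <- ifelse(z <= 1, 1L, ifelse(z <= 2, 2L, ifelse(z <= 3, 3L, 4L)))
  list(score = as.numeric(band_scores[idx]), band = .band_labels()[idx])
}

#' Score a discrete descriptor value by mode offset
#'
#' Looks up \code{offset = value - mode} in the offset score table;
#' offsets beyond +/-2 take the catch-all score. Vectorised over
#' \code{value}.
#'
#' @param value Observed integer value(s).
#' @param mode Reference mode (integer).
#' @param offset_scores Six scores ordered offsets -2, -1, 0, +1, +2,
#'   catch-all (optionally named as in
#'   \code{default_rules()$discrete_offsets} rows).
#' @return List with \code{score} and \code{offset} (label), each the
#'   length of \code{value}.
#' @export
#' @examples
#' score_discrete(2, 0, default_rules()$discrete_offsets["formal_charge74", ])
score_discrete <- function(value, mode, offset_scores) {
  stopifnot(length(offset_scores) == 6L,
            all(abs(value - round(value)) < 1e-9),
            abs(mode - round(mode)) < 1e-9)
  offset <- as.integer(round(value)) - as.integer(round(mode))
  idx <- ifelse(abs(offset) <= 2L, offset + 3L, 6L)
  list(score = as.numeric(offset_scores[idx]),
       offset = .offset_labels()[idx])
}

#' Score one compound against a reference model
#'
#' Applies the band/offset rules to each of the ten descriptors and sums
#' the contributions in integer half-points (so the reported total is
#' exactly the sum of the per-descriptor scores). The breakdown records
#' every classification for audit.
#'
#' @param descriptors A complete descriptor set (named list, one-row
#'   data frame, or named vector; validated by
#'   \code{\link{as_descriptor_set}}).
#' @param model An \code{hl_reference}.
#' @param rules An \code{hl_rules}; defaults to the published rules.
#' @return Object of class \code{hl_score_breakdown}: data frame
#'   \code{per_descriptor} (descriptor, value, class, score) and
#'   \code{total}.
#' @export
#' @examples
#' at_ref <- c(molar_mass = 317, aromatic_pct = 25, psa = 72, logd74 = 2.2,
#'             logs = -3.5, logp = 2.9, rotatable_bonds = 5, hba74 = 2,
#'             hbd74 = 0, formal_charge74 = 0)
#' score_compound(at_ref, published_reference())$total   # 18
score_compound <- function(descriptors, model = published_reference(),
                           rules = default_rules()) {
  stopifnot(inherits(model, "hl_reference"), inherits(rules, "hl_rules"))
  d <- as_descriptor_set(descriptors)
  rows <- vector("list", 10L)
  i <- 0L
  for (name in continuous_descriptors()) {
    sc <- score_continuous(d[[name]], model$continuous[name, "mean"],
                           model$continuous[name, "sd"],
                           rules$continuous_bands[name, ])
    i <- i + 1L
    rows[[i]] <- data.frame(descriptor = name, value = d[[name]],
                            class = sc$band, score = sc$score,
                            stringsAsFactors = FALSE)
  }
  for (name in discrete_descriptors()) {
    sc <- score_discrete(d[[name]], model$modes[[name]],
                         rules$discrete_offsets[name, ])
    i <- i + 1L
    rows[[i]] <- data.frame(descriptor = name, value = as.numeric(d[[name]]),
                            class = sc$offset, score = sc$score,
                            stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  total <- sum(as.integer(round(per$score * 2))) / 2
  structure(list(per_descriptor = per, total = total),
            class = "hl_score_breakdown")
}

#' @export
print.hl_score_breakdown <- function(x, ...) {
  cat("Herbicide-likeness score:", format(x$total), "points\n")
  print(x$per_descriptor, row.names = FALSE)
  invisible(x)
}

#' Score every compound in a library
#'
#' @param records Data frame with \code{compound_id} and the descriptor
#'   columns.
#' @param model An \code{hl_reference}.
#' @param rules An \code{hl_rules}.
#' @return List with \code{scores} (data frame: compound_id, one score
#'   column per descriptor, one \code{<descriptor>_class} label column,
#'   \code{total}) and \code{rejects} (compound_id, reason) for records
#'   whose descriptor sets could not be scored.
#' @export
score_library <- function(records, model = published_reference(),
                          rules = default_rules()) {
  stopifnot(is.data.frame(records))
  ids <- if ("compound_id" %in% names(records)) as.character(records$compound_id)
         else as.character(seq_len(nrow(records)))
  out <- vector("list", nrow(records))
  rej <- list()
  for (i in seq_len(nrow(records))) {
    br <- try(score_compound(as.list(records[i, intersect(descriptor_names(),
                                                          names(records)),
                                             drop = FALSE]),
                             model, rules), silent = TRUE)
    if (inherits(br, "try-error")) {
      rej[[length(rej) + 1L]] <- data.frame(
        compound_id = ids[i],
        reason = conditionMessage(attr(br, "condition")),
        stringsAsFactors = FALSE)
      next
    }
    p <- br$per_descriptor
    row <- as.list(stats::setNames(p$score, p$descriptor))
    row <- c(list(compound_id = ids[i]), row,
             stats::setNames(as.list(p$class), paste0(p$descriptor, "_class")),
             list(total = br$total))
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  scores <- if (length(out)) do.call(rbind, out) else NULL
  rejects <- if (length(rej)) do.call(rbind, rej) else
    data.frame(compound_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(scores = scores, rejects = rejects)
}

#' Rank a compound library by herbicide-likeness
#'
#' Scores every record and sorts by total score, descending; equal
#' totals are ordered by \code{compound_id} (lexicographic). With a
#' \code{threshold}, also reports the shortlist of compounds scoring at
#' least that many points (comparison is \code{>=}, as in "scored 17 or
#' more"). Records that cannot be scored are collected into a rejects
#' report and ranking proceeds on the rest.
#'
#' @inheritParams score_library
#' @param threshold Optional score cut for the shortlist.
#' @return List with \code{ranked} (scores table plus a \code{rank}
#'   column), \code{rejects}, and if \code{threshold} was given
#'   \code{shortlist} (list: \code{threshold}, \code{count}, \code{ids}).
#' @export
rank_library <- function(records, model = published_reference(),
                         rules = default_rules(), threshold = NULL) {
  res <- score_library(records, model, rules)
  sc <- res$scores
  if (is.null(sc) || nrow(sc) == 0L) {
    stop(errorCondition("no scoreable records in the library",
                        class = c("hl_score_error", "hl_error")))
  }
  ord <- order(-sc$total, sc$compound_id, method = "radix")
  ranked <- sc[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL
  out <- list(ranked = ranked, rejects = res$rejects)
  if (!is.null(threshold)) {
    hit <- ranked$compound_id[ranked$total >= threshold]
    out$shortlist <- list(threshold = threshold, count = length(hit), ids = hit)
  }
  out
}

#' Score a library with a fitted reference model
#'
#' \code{predict} method for \code{hl_reference}: scores \code{newdata}
#' against the model, optionally thresholding (see
#' \code{\link{rank_library}}).
#'
#' @param object An \code{hl_reference}.
#' @param newdata Data frame of compounds with descriptor columns.
#' @param rules An \code{hl_rules}.
#' @param threshold Optional shortlist cut.
#' @param ... Unused.
#' @return As \code{\link{rank_library}}.
#' @export
predict.hl_reference <- function(object, newdata, rules = default_rules(),
                                 threshold = NULL, ...) {
  rank_library(newdata, object, rules, threshold)
}
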