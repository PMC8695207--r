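# Workflow driver behind the command-line front end (inst/cli/herblike).
# One command per invocation; every run writes its artifacts plus a
# provenance sidecar carrying the full configuration, model and rules, so an
# artifact is reproducible byte-for-byte from its sidecar alone.

#' Assemble a run configuration
#'
#' @param command One of \code{"score"}, \code{"rank"},
#'   \code{"refstats"}, \code{"compare"}, \code{"simulate"}.
#' @param input Primary input CSV/TSV path (compound table); for
#'   \code{compare}, group A.
#' @param input_b Group-B compound table (\code{compare} only).
#' @param model Model source: \code{"published"}, \code{"fitted:<path>"}
#'   (fit from a reference table) or \code{"file:<path>"} (serialised
#'   model).
#' @param rules Rules source: \code{"default"} or \code{"file:<path>"}.
#' @param backend \code{"table"} (descriptor columns are used as given)
#'   or \code{"computed"} (descriptors computed from a \code{smiles}
#'   column; never silently chosen when descriptor columns exist).
#' @param hba_na_policy Passed to \code{\link{default_rules}}.
#' @param ttest_variant Passed to \code{\link{compare_descriptors}}.
#' @param threshold Optional shortlist cut for \code{rank}.
#' @param n Library size for \code{simulate}.
#' @param generator \code{"herbicide_like"} or \code{"antimalarial_like"}
#'   (\code{simulate} only).
#' @param seed Optional integer seed (\code{simulate}).
#' @param outdir Output directory, created if absent.
#' @param column_map Optional named character vector for
#'   \code{\link{read_compound_table}}.
#' @return A validated list of class \code{hl_run_config}.
#' @export
hl_run_config <- function(command, input = NULL, input_b = NULL,
                          model = "published", rules = "default",
                          backend = c("table", "computed"),
                          hba_na_policy = c("mirrored", "strict"),
                          ttest_variant = c("pooled", "welch"),
                          threshold = NULL, n = 100,
                          generator = c("herbicide_like", "antimalarial_like"),
                          seed = NULL, outdir = ".", column_map = NULL) {
  command <- match.arg(command,
                       c("score", "rank", "refstats", "compare", "simulate"))
  backend <- match.arg(backend)
  hba_na_policy <- match.arg(hba_na_policy)
  ttest_variant <- match.arg(ttest_variant)
  generator <- match.arg(generator)
  needs_input <- command %in% c("score", "rank", "refstats", "compare")
  if (needs_input && (is.null(input) || !file.exists(input))) {
    stop(errorCondition(paste0("input file missing or not found: ",
                               if (is.null(input)) "<none>" else input),
                        class = c("hl_config_error", "hl_error")))
  }
  if (command == "compare" && (is.null(input_b) || !file.exists(input_b))) {
    stop(errorCondition("compare needs a second input (input_b)",
                        class = c("hl_config_error", "hl_error")))
  }
  for (src in list(model, rules)) {
    if (grepl("^(fitted|file):", src)) {
      p <- sub("^[a-z]+:", "", src)
      if (!file.exists(p)) {
        stop(errorCondition(paste0("referenced file not found: ", p),
                            class = c("hl_config_error", "hl_error")))
      }
    }
  }
  if (!model %in% "published" && !grepl("^(fitted|file):", model)) {
    stop(errorCondition(
      "model must be 'published', 'fitted:<path>' or 'file:<path>'",
      class = c("hl_config_error", "hl_error")))
  }
  if (!rules %in% "default" && !grepl("^file:", rules)) {
    stop(errorCondition("rules must be 'default' or 'file:<path>'",
                        class = c("hl_config_error", "hl_error")))
  }
  structure(list(command = command, input = input, input_b = input_b,
                 model = model, rules = rules, backend = backend,
                 hba_na_policy = hba_na_policy,
                 ttest_variant = ttest_variant, threshold = threshold,
                 n = as.integer(n), generator = generator,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 outdir = outdir, column_map = column_map),
            class = "hl_run_config")
}

.resolve_model <- function(config) {
  if (identical(config$model, "published")) return(published_reference())
  path <- sub("^[a-z]+:", "", config$model)
  if (grepl("^fitted:", config$model)) {
    tab <- read_compound_table(path, config$column_map)
    fit_reference(tab$records, provenance = paste0("fitted-from:", path))
  } else {
    read_reference(path)
  }
}

.resolve_rules <- function(config) {
  if (identical(config$rules, "default")) {
    default_rules(config$hba_na_policy)
  } else {
    read_rules(sub("^file:", "", config$rules))
  }
}

# load a compound table and, on the computed backend, fill descriptors from
# structures; the table backend never recomputes existing columns
.load_records <- function(path, config) {
  tab <- read_compound_table(path, config$column_map)
  rec <- tab$records
  if (identical(config$backend, "computed")) {
    if (!"smiles" %in% names(rec)) {
      stop(errorCondition("computed backend needs a smiles column",
                          class = c("hl_config_error", "hl_error")))
    }
    desc <- lapply(rec$smiles, compute_descriptors)
    for (d in descriptor_names()) {
      rec[[d]] <- vapply(desc, function(x) as.numeric(x[[d]]), numeric(1))
    }
    for (d in discrete_descriptors()) rec[[d]] <- as.integer(rec[[d]])
  }
  list(records = rec, rejects = tab$rejects)
}

.write_sidecar <- function(config, model, rules, outdir, files) {
  side <- list(
    tool = "herblike", version = as.character(utils::packageVersion("herblike")),
    config = config[!vapply(config, is.null, logical(1))],
    model = list(provenance = model$provenance, n_reference = model$n,
                 continuous = stats::setNames(
                   lapply(rownames(model$continuous), function(d)
                     as.numeric(model$continuous[d, ])),
                   rownames(model$continuous)),
                 modes = as.list(model$modes)),
    rules = list(hba_na_policy = rules$hba_na_policy,
                 continuous_bands = stats::setNames(
                   lapply(rownames(rules$continuous_bands), function(d)
                     as.numeric(rules$continuous_bands[d, ])),
                   rownames(rules$continuous_bands)),
                 discrete_offsets = stats::setNames(
                   lapply(rownames(rules$discrete_offsets), function(d)
                     as.numeric(rules$discrete_offsets[d, ])),
                   rownames(rules$discrete_offsets))),
    artifacts = files)
  class(side$config) <- NULL
  jsonlite::write_json(side, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Execute one workflow command
#'
#' Runs the configured command and writes its artifacts into
#' \code{config$outdir}: \code{score} writes \code{scores.csv} (+
#' \code{rejects.csv}); \code{rank} writes \code{ranked.csv},
#' \code{rejects.csv} and, with a threshold, \code{shortlist.csv};
#' \code{refstats} fits a reference model on the input and writes
#' \code{reference.yaml}; \code{compare} writes \code{comparison.csv}
#' and \code{fisher.csv}; \code{simulate} writes \code{library.csv}.
#' Every run writes \code{provenance.json} echoing the configuration,
#' the fully expanded model and rules, and the artifact list.
#'
#' @param config An \code{hl_run_config}.
#' @return Invisibly, the list of artifact paths written.
#' @export
hl_run <- function(config) {
  stopifnot(inherits(config, "hl_run_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  model <- .resolve_model(config)
  rules <- .resolve_rules(config)
  files <- character(0)
  emit <- function(df, name, digits = NULL) {
    p <- file.path(outdir, name)
    out <- df
    if (!is.null(digits)) {
      for (cl in names(out)) {
        if (is.double(out[[cl]])) {
          out[[cl]] <- formatC(out[[cl]], format = "f", digits = digits)
        }
      }
    }
    utils::write.csv(out, p, row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
    p
  }

  switch(config$command,
    score = ,
    rank = {
      loaded <- .load_records(config$input, config)
      res <- rank_library(loaded$records, model, rules, config$threshold)
      rejects <- rbind(loaded$rejects[, c("compound_id", "reason")],
                       res$rejects)
      if (config$command == "score") {
        emit(res$ranked[order(match(res$ranked$compound_id,
                                    loaded$records$compound_id)),
                        setdiff(names(res$ranked), "rank")], "scores.csv")
      } else {
        emit(res$ranked, "ranked.csv")
        if (!is.null(res$shortlist)) {
          emit(data.frame(compound_id = res$shortlist$ids,
                          threshold = res$shortlist$threshold), "shortlist.csv")
        }
      }
      emit(rejects, "rejects.csv")
    },
    refstats = {
      loaded <- .load_records(config$input, config)
      fit <- fit_reference(loaded$records,
                           provenance = paste0("fitted-from:", config$input))
      p <- file.path(outdir, "reference.yaml")
      write_reference(fit, p)
      files <- c(files, "reference.yaml")
      model <- fit
    },
    compare = {
      a <- .load_records(config$input, config)$records
      b <- .load_records(config$input_b, config)$records
      cmp <- compare_descriptors(a, b, variant = config$ttest_variant)
      cmp$variant <- attr(cmp, "variant")
      emit(cmp, "comparison.csv")
      fz <- fisher_charge_test(a, b)
      emit(data.frame(cell = c("positive_a", "non_positive_a",
                               "positive_b", "non_positive_b"),
                      count = as.integer(fz$table),
                      p_value = fz$p_value, odds_ratio = fz$odds_ratio),
           "fisher.csv")
    },
    simulate = {
      spec <- if (config$generator == "herbicide_like") {
        herbicide_like_spec(config$n, config$seed)
      } else {
        antimalarial_like_spec(config$n, config$seed)
      }
      lib <- generate_library(spec)
      p <- file.path(outdir, "library.csv")
      write_descriptor_table(lib, p)
      files <- c(files, "library.csv")
    })

  .write_sidecar(unclass(config), model, rules, outdir, files)
  invisible(file.path(outdir, c(files, "provenance.json")))
}
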