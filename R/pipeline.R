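## Workflow orchestration: config-driven runs of the logical
## steady-state, dependency-matrix and validation stages, each writing
## TSV/JSON artifacts plus a machine-readable manifest sufficient to
## re-run the deterministic stages bit-identically.

#' Read a run configuration
#'
#' YAML or JSON (decided by extension), returned as a named list.
#' Lists may also be passed directly to the `run_*` functions.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unrecognised config extension (want .yaml/.yml/.json): ", path)
  }
}

.as_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  stopifnot(is.list(config))
  config
}

.config_get <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) stop("config is missing required field '", key, "'")
  default
}

.load_network <- function(config) {
  path <- .config_get(config, "network", required = TRUE)
  if (!file.exists(path)) stop("network file not found: ", path)
  read_interactions(path, dialect = .config_get(config, "dialect", "sif"))
}

.write_manifest <- function(out_dir, stage, config, extra = list()) {
  manifest <- c(list(stage = stage,
                     package = "signalflow",
                     package_version = as.character(utils::packageVersion("signalflow")),
                     r_version = as.character(getRversion()),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     config = config),
                extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the logical steady-state stage
#'
#' Loads the network, computes the wild-type and knockout logical
#' steady states for the criterion node (clamped to `wt_value` and
#' `ko_value`), derives the per-node model predictions, and writes
#' `lss_states.tsv` (node, WT value, KO value, Emod) plus a manifest
#' to the output directory.
#'
#' Config fields: `network` (path), `dialect` (default `"sif"`),
#' `criterion` (node name), `wt_value` (default 1), `ko_value`
#' (default 0), `out_dir` (default `"."`).
#'
#' @param config named list or path to a YAML/JSON config.
#' @return invisibly, list with `state_wt`, `state_ko`, `emod`,
#'   `summary`.
#' @export
run_lss <- function(config) {
  config <- .as_config(config)
  net <- .load_network(config)
  criterion <- .config_get(config, "criterion", required = TRUE)
  if (!criterion %in% net$nodes) stop("criterion node not in network: ", criterion)
  out_dir <- .config_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt_value <- .config_get(config, "wt_value", 1)
  ko_value <- .config_get(config, "ko_value", 0)
  state_wt <- compute_lss(net, setNames(wt_value, criterion))
  state_ko <- compute_lss(net, setNames(ko_value, criterion))
  ev <- emod(state_wt, state_ko, criterion)
  fmt <- function(x) ifelse(is.nan(x), "NaN", format(x))
  tab <- data.frame(node = net$nodes,
                    lss_wt = fmt(state_wt$values[net$nodes]),
                    lss_ko = fmt(state_ko$values[net$nodes]),
                    emod = ifelse(net$nodes %in% attr(ev, "excluded"),
                                  NA_integer_, unname(ev[net$nodes])))
  write.table(tab, file.path(out_dir, "lss_states.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  s <- emod_summary(ev)
  .write_manifest(out_dir, "lss", config, list(emod_summary = as.list(s)))
  invisible(list(state_wt = state_wt, state_ko = state_ko, emod = ev,
                 summary = s))
}

#' Run the dependency-matrix / knockout stage
#'
#' Computes the full-model dependency matrix, then one structural
#' knockout scenario per listed node, and writes: the full matrix
#' (`depmat_full.tsv`), a class-count summary over all scenarios
#' (`depmat_counts.tsv`, one row per scenario plus the full model),
#' per-scenario 6 x 6 transition tables
#' (`depmat_transitions_<node>.tsv`) and the combined strong-change
#' list (`depmat_strong_changes.tsv`), plus a manifest.
#'
#' Config fields: `network`, `dialect`, `ko_nodes` (character vector;
#' may be empty for full-model counts only), `out_dir`.
#'
#' @param config named list or path to a YAML/JSON config.
#' @return invisibly, the [ko_scenario_report()] result.
#' @export
run_depmat <- function(config) {
  config <- .as_config(config)
  net <- .load_network(config)
  ko_nodes <- .config_get(config, "ko_nodes", character())
  out_dir <- .config_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- ko_scenario_report(net, ko_nodes)
  write_depmat(attr(report$full, "dm"), file.path(out_dir, "depmat_full.tsv"))
  counts <- rbind(`Full Model` = report$full,
                  do.call(rbind, lapply(report$scenarios, `[[`, "counts")))
  rownames(counts)[-1] <- paste0(names(report$scenarios), " KO")
  counts_df <- data.frame(scenario = rownames(counts), counts,
                          total = rowSums(counts), check.names = FALSE,
                          row.names = NULL)
  write.table(counts_df, file.path(out_dir, "depmat_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  strong_all <- list()
  for (v in names(report$scenarios)) {
    delta <- report$scenarios[[v]]$delta
    tr <- delta$transitions
    write.table(data.frame(before = rownames(tr), tr, check.names = FALSE),
                file.path(out_dir, paste0("depmat_transitions_", v, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(delta$strong_changes)) {
      strong_all[[v]] <- data.frame(node_deleted = v, delta$strong_changes)
    }
  }
  strong <- if (length(strong_all)) {
    do.call(rbind, c(strong_all, list(make.row.names = FALSE)))
  } else {
    data.frame(node_deleted = character(), source = character(),
               target = character(), before = character(), after = character())
  }
  write.table(strong, file.path(out_dir, "depmat_strong_changes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "depmat", config,
                  list(n_strong_changes = nrow(strong)))
  invisible(report)
}

#' Run the validation stage
#'
#' Scores the model's per-node predictions against observed expression
#' changes, sweeping the biological fold-change threshold. Two modes:
#'
#' * `mode = "cellline"`: reads a replicate expression matrix
#'   ([read_expression()]), derives per-group fold changes
#'   ([cellline_de()]) and observed calls, scores each group at each
#'   threshold, and (with 3+ groups) correlates the focal gene's fold
#'   change with the per-group correct rates at the first threshold.
#' * `mode = "clinical"`: reads a patient cohort ([read_cohort()]),
#'   stratifies it by the criterion gene at each configured statistic,
#'   runs the two-group test ([cohort_de()]), and scores at each
#'   threshold.
#'
#' Writes `validation_scores.tsv` (one row per group/split x
#' threshold), `validation_scores.json`, optionally
#' `validation_correlation.json`, and a manifest.
#'
#' Config fields: `network`, `dialect`, `criterion`, `mode`,
#' `expression` (prefix, cellline mode), `cohort` (path, clinical
#' mode), `groups` (optional subset), `split_statistics` (default
#' mean/median/upper_quartile/lower_quartile), `q_cut` (default 0.05),
#' `fc_thresholds` (default 1, 1.5, 2, 3), `out_dir`.
#'
#' @param config named list or path to a YAML/JSON config.
#' @return invisibly, list with `scores` (data.frame) and
#'   `correlation` (or `NULL`).
#' @export
run_validate <- function(config) {
  config <- .as_config(config)
  net <- .load_network(config)
  criterion <- .config_get(config, "criterion", required = TRUE)
  mode <- match.arg(.config_get(config, "mode", "cellline"),
                    c("cellline", "clinical"))
  q_cut <- .config_get(config, "q_cut", 0.05)
  thresholds <- unlist(.config_get(config, "fc_thresholds", c(1, 1.5, 2, 3)))
  out_dir <- .config_get(config, "out_dir", ".")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lss <- run_lss(c(config, list(out_dir = out_dir)))
  ev <- lss$emod
  rows <- list()
  correlation <- NULL
  add_row <- function(unit, thr, rep) {
    data.frame(unit = unit, fc_threshold = thr,
               n_evaluated = rep$n_evaluated,
               correct = rep$n_by_error[["correct"]],
               small_error = rep$n_by_error[["small_error"]],
               large_error = rep$n_by_error[["large_error"]],
               rate = rep$rate, p_value = rep$p_value)
  }
  if (mode == "cellline") {
    expr <- read_expression(.config_get(config, "expression", required = TRUE))
    groups <- .config_get(config, "groups", unique(expr$group))
    fc_focal <- numeric(0)
    first_rates <- numeric(0)
    for (g in groups) {
      de <- cellline_de(expr, g)
      for (thr in thresholds) {
        eexp <- eexp_from_de(de, q_cut = q_cut, fc_threshold = thr)
        rep <- score_predictions(ev, eexp, criterion,
                                 check_direction = identical(thr, thresholds[[1]]))
        rows[[paste(g, thr)]] <- add_row(g, thr, rep)
        if (identical(thr, thresholds[[1]])) first_rates[[g]] <- rep$rate
      }
      fc_focal[[g]] <- de$fc[de$gene == criterion]
    }
    if (length(groups) >= 3) {
      correlation <- knockdown_correlation(unname(fc_focal),
                                           unname(first_rates))
      jsonlite::write_json(correlation,
                           file.path(out_dir, "validation_correlation.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  } else {
    cohort <- read_cohort(.config_get(config, "cohort", required = TRUE))
    stats_list <- unlist(.config_get(config, "split_statistics",
                                     c("mean", "median", "upper_quartile",
                                       "lower_quartile")))
    for (st in stats_list) {
      split <- split_cohort(cohort, criterion, statistic = st)
      de <- cohort_de(cohort, split$high, split$low)
      for (thr in thresholds) {
        eexp <- eexp_from_de(de, q_cut = q_cut, fc_threshold = thr)
        rep <- score_predictions(ev, eexp, criterion,
                                 check_direction = identical(thr, thresholds[[1]]))
        rows[[paste(st, thr)]] <- add_row(st, thr, rep)
      }
    }
  }
  scores <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  write.table(scores, file.path(out_dir, "validation_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(scores, file.path(out_dir, "validation_scores.json"),
                       dataframe = "rows", digits = NA)
  .write_manifest(out_dir, "validate", config,
                  list(n_score_rows = nrow(scores)))
  invisible(list(scores = scores, correlation = correlation))
}
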