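#' Pipeline configuration
#'
#' One declarative object driving [run_pipeline()]: where the two groups'
#' CoNLL-U treebanks live, which mean-dependency-distance convention to use,
#' the screening and stepwise thresholds, and the network arc budget. All
#' values are echoed into the report for provenance.
#'
#' @param group_a_path,group_b_path CoNLL-U files or directories (group A is
#'   conventionally the clinical group).
#' @param group_a_label,group_b_label labels used in the report.
#' @param mdd_convention preset name for [mdd_convention()].
#' @param index_set index names (default: the full catalogue).
#' @param alpha,r_min correlation-screen thresholds.
#' @param vif_threshold collinearity exclusion threshold.
#' @param p_enter,p_remove stepwise thresholds.
#' @param top_k arc budget for rankings and the network cross difference.
#' @param seed integer seed recorded in the report.
#' @param output_dir where [run_pipeline()] writes its files; `NULL` for an
#'   in-memory run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(group_a_path, group_b_path,
                            group_a_label = "A", group_b_label = "B",
                            mdd_convention = "stated_rule",
                            index_set = index_catalogue(),
                            alpha = 0.05, r_min = 0.100, vif_threshold = 5,
                            p_enter = 0.05, p_remove = 0.10,
                            top_k = 200, seed = 1L, output_dir = NULL) {
  stopifnot(alpha > 0, r_min >= 0, vif_threshold > 0, p_enter > 0, p_remove > 0,
            top_k >= 1)
  structure(list(
    group_a_path = group_a_path, group_b_path = group_b_path,
    group_a_label = group_a_label, group_b_label = group_b_label,
    mdd_convention = mdd_convention, index_set = index_set,
    alpha = alpha, r_min = r_min, vif_threshold = vif_threshold,
    p_enter = p_enter, p_remove = p_remove, top_k = top_k,
    seed = as.integer(seed), output_dir = output_dir
  ), class = "pipeline_config")
}

group_model <- function(indices, mdd, config) {
  merged <- merge(indices, mdd[c("doc_id", "mdd")], by = "doc_id")
  merged <- merged[!is.na(merged$mdd), , drop = FALSE]
  X <- merged[intersect(config$index_set, names(merged))]
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  y <- merged$mdd[complete]
  n_dropped <- sum(!complete)
  if (nrow(X) < 8L) {
    return(list(screen = NULL, model = NULL, n_listwise_dropped = n_dropped))
  }
  screen <- suppressWarnings(correlation_screen(X, y, config$alpha, config$r_min))
  kept <- screen$retained
  vif_rep <- NULL
  if (length(kept) >= 2L) {
    vif_rep <- vif_screen(X[kept], config$vif_threshold)
    kept <- vif_rep$retained
  }
  model <- if (length(kept) >= 1L && nrow(X) >= length(kept) + 2L) {
    stepwise_regression(X[kept], y, config$p_enter, config$p_remove)
  } else {
    NULL
  }
  list(screen = screen, vif = vif_rep, model = model,
       n_listwise_dropped = n_dropped)
}

#' Run the full two-group analysis pipeline
#'
#' Loads both treebanks, computes per-transcript text MDD and the
#' fine-grained index table, compares group MDD, screens indices against
#' MDD (correlation, then VIF) and fits the per-group stepwise regression,
#' builds the two dependency networks with their Pajek-convention
#' summaries, top weighted vertices, per-vertex topology metrics and the
#' A-minus-B cross difference. When `config$output_dir` is set, writes
#' `report.json`, `mdd.csv`, `indices.csv`, `node_metrics_<label>.csv` and
#' `network_<label>.net`.
#'
#' @param config a [pipeline_config()]; alternatively `group_a`/`group_b`
#'   may be passed as in-memory `treebank` objects.
#' @param group_a,group_b optional treebanks overriding the config paths.
#' @return an `analysis_report` list (see details in the fields themselves).
#' @export
run_pipeline <- function(config, group_a = NULL, group_b = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  load_group <- function(tb, path, label) {
    if (is.null(tb)) tb <- read_conllu(path, group_label = label)
    if (nrow(tb) == 0L) stop("stage load: empty treebank for group ", label)
    tb
  }
  tb_a <- load_group(group_a, config$group_a_path, config$group_a_label)
  tb_b <- load_group(group_b, config$group_b_path, config$group_b_label)
  conv <- mdd_convention(config$mdd_convention)

  mdd_a <- mdd_by_transcript(tb_a, conv)
  mdd_b <- mdd_by_transcript(tb_b, conv)
  mdd_comparison <- compare_groups(mdd_a$mdd, mdd_b$mdd)

  idx_a <- compute_all_indices(tb_a)
  idx_b <- compute_all_indices(tb_b)

  model_a <- group_model(idx_a, mdd_a, config)
  model_b <- group_model(idx_b, mdd_b, config)

  net_a <- build_network(tb_a)
  net_b <- build_network(tb_b)
  metrics_a <- node_metrics(net_a)
  metrics_b <- node_metrics(net_b)
  diff_ab <- network_difference(net_a, net_b, top_k = config$top_k)

  report <- structure(list(
    config = config,
    groups = stats::setNames(list(
      list(label = config$group_a_label, n_transcripts = nrow(mdd_a),
           n_sentences = n_sentences(tb_a), n_tokens = nrow(tb_a),
           mdd = mdd_a, mdd_mean = mean(mdd_a$mdd, na.rm = TRUE),
           indices = idx_a, screening = model_a$screen, vif = model_a$vif,
           regression = model_a$model,
           n_listwise_dropped = model_a$n_listwise_dropped,
           network_summary = pajek_summary(net_a),
           top_weighted = weighted_degrees(net_a, config$top_k),
           node_metrics = metrics_a),
      list(label = config$group_b_label, n_transcripts = nrow(mdd_b),
           n_sentences = n_sentences(tb_b), n_tokens = nrow(tb_b),
           mdd = mdd_b, mdd_mean = mean(mdd_b$mdd, na.rm = TRUE),
           indices = idx_b, screening = model_b$screen, vif = model_b$vif,
           regression = model_b$model,
           n_listwise_dropped = model_b$n_listwise_dropped,
           network_summary = pajek_summary(net_b),
           top_weighted = weighted_degrees(net_b, config$top_k),
           node_metrics = metrics_b)
    ), c(config$group_a_label, config$group_b_label)),
    mdd_comparison = mdd_comparison,
    network_difference = diff_ab,
    networks = stats::setNames(list(net_a, net_b),
                               c(config$group_a_label, config$group_b_label))
  ), class = "analysis_report")

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  a <- x$groups[[1]]; b <- x$groups[[2]]
  cat("== two-group syntactic complexity report ==\n")
  cat(sprintf("group %s: %d transcripts, %d sentences, %d tokens; mean MDD %.4f\n",
              a$label, a$n_transcripts, a$n_sentences, a$n_tokens, a$mdd_mean))
  cat(sprintf("group %s: %d transcripts, %d sentences, %d tokens; mean MDD %.4f\n",
              b$label, b$n_transcripts, b$n_sentences, b$n_tokens, b$mdd_mean))
  cat("MDD comparison: ")
  print(x$mdd_comparison)
  for (g in x$groups) {
    s <- g$network_summary
    cat(sprintf("network %s: n = %d, m = %d, density = %.8f, average degree = %.8f\n",
                g$label, s$n, s$m, s$density_loops_allowed, s$average_degree))
    if (!is.null(g$regression)) {
      cat(sprintf("stepwise model %s: ", g$label)); print(g$regression)
    }
  }
  invisible(x)
}

write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labels <- names(report$groups)
  mdd_all <- do.call(rbind, lapply(labels, function(l) {
    cbind(group = l, report$groups[[l]]$mdd)
  }))
  utils::write.csv(mdd_all, file.path(dir, "mdd.csv"), row.names = FALSE)
  idx_all <- do.call(rbind, lapply(labels, function(l) {
    cbind(group = l, report$groups[[l]]$indices)
  }))
  utils::write.csv(idx_all, file.path(dir, "indices.csv"), row.names = FALSE)
  for (l in labels) {
    utils::write.csv(report$groups[[l]]$node_metrics,
                     file.path(dir, sprintf("node_metrics_%s.csv", l)),
                     row.names = FALSE)
    write_pajek_net(report$networks[[l]], file.path(dir, sprintf("network_%s.net", l)))
  }
  write_pajek_net(report$network_difference, file.path(dir, "network_difference.net"))
  json <- list(
    config = unclass(report$config),
    mdd_comparison = unclass(report$mdd_comparison),
    groups = lapply(report$groups, function(g) {
      list(label = g$label, n_transcripts = g$n_transcripts,
           n_sentences = g$n_sentences, n_tokens = g$n_tokens,
           mdd_mean = g$mdd_mean, network_summary = g$network_summary,
           selected_indices = if (!is.null(g$regression)) g$regression$selected else character(0),
           r_squared = if (!is.null(g$regression)) g$regression$r_squared else NA,
           adjusted_r_squared = if (!is.null(g$regression)) g$regression$adjusted_r_squared else NA,
           coefficients = if (!is.null(g$regression)) g$regression$coefficients else NULL)
    })
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}
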