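#' Assemble a pipeline configuration
#'
#' Collects every stage's tunables into one declarative list. A single
#' top-level seed is fanned out deterministically to per-stage seeds so that
#' partial reruns reproduce.
#'
#' @param table_path path to an input OTU TSV, or `NULL` to simulate a table.
#' @param metadata_path optional path to an environmental metadata TSV.
#' @param out_dir artifact directory.
#' @param min_days recurrence filter threshold (default 10).
#' @param wavelet mother wavelet (only `"sym2"` is implemented).
#' @param k,pos_threshold,neg_threshold scoring parameters.
#' @param inflation MCL inflation used for the reported partition
#'   (default 2.4).
#' @param inflations inflation sweep grid.
#' @param n_perm permutations for the significance stage (default 1000; 0
#'   skips the stage).
#' @param fdr_q FDR level (default 0.10).
#' @param max_lag_jsd largest beta-diversity lag (default 40).
#' @param sim_n_otus,sim_b,sim_p,sim_snr simulator settings used when
#'   `table_path` is `NULL`.
#' @param seed top-level seed.
#' @return a `waveclust_config` list.
#' @export
waveclust_config <- function(table_path = NULL, metadata_path = NULL,
                             out_dir = "waveclust_out", min_days = 10,
                             wavelet = "sym2", k = 0.25,
                             pos_threshold = 0.7, neg_threshold = -0.5,
                             inflation = 2.4,
                             inflations = c(1.6, 2.0, 2.4, 2.8, 3.2, 3.6, 4.2),
                             n_perm = 1000, fdr_q = 0.10, max_lag_jsd = 40,
                             sim_n_otus = 40, sim_b = 10, sim_p = 20,
                             sim_snr = 1, seed = 1L) {
  if (wavelet != "sym2") stop("only the sym2 mother wavelet is implemented")
  cfg <- as.list(environment())
  cfg$stage_seeds <- list(simulate = seed * 13L + 1L,
                          permtest = seed * 13L + 5L)
  structure(cfg, class = "waveclust_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages: prep (read or simulate, replicate-average, recurrence filter,
#' normalise), decompose/score (+/+ and -/+), permutation test + FDR
#' (optional), MCL clustering and inflation sweep, community profiles,
#' Granger causal network (when metadata are given), and the beta-diversity
#' lag curve. Every artifact is a TSV under `out_dir`; the resolved
#' configuration is written alongside them.
#'
#' @param config a [waveclust_config()].
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with the main in-memory results: `table`,
#'   `scores_pospos`, `scores_negpos`, `partition_pospos`,
#'   `partition_negpos`, `profiles`, `sweep`, `edges` (Granger, or `NULL`),
#'   `lag_curve`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "waveclust_config"))
  if (!is.null(config$table_path) && !file.exists(config$table_path))
    stop("input table not found: ", config$table_path)
  if (!is.null(config$metadata_path) && !file.exists(config$metadata_path))
    stop("metadata table not found: ", config$metadata_path)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[waveclust] ", ...)

  flat <- config[!vapply(config, is.list, logical(1L))]
  flat <- flat[!vapply(flat, is.null, logical(1L))]
  write_tsv(data.frame(key = names(flat),
                       value = vapply(flat, function(x)
                         paste(format(x), collapse = ","), character(1L))),
            file.path(config$out_dir, "config.tsv"))

  say("stage prep")
  tab <- if (is.null(config$table_path)) {
    simulate_otu_table(n_otus = config$sim_n_otus, b = config$sim_b,
                       p = config$sim_p, snr = config$sim_snr,
                       seed = config$stage_seeds$simulate)
  } else read_otu_table(config$table_path)
  tab <- average_replicates(tab)
  tab <- filter_recurrent(tab, config$min_days)
  if (nrow(tab$values) < 2L) stop("fewer than 2 OTUs survive the filter")
  rel <- to_relative_abundance(tab)
  write_otu_table(rel, file.path(config$out_dir, "prepped.tsv"))

  params <- score_params(config$pos_threshold, config$neg_threshold,
                         config$k)
  say("stage score")
  scores <- lapply(c(pospos = "pospos", negpos = "negpos"), function(m)
    score_table(rel, m, params))
  for (m in names(scores))
    write_tsv(score_edges(scores[[m]]),
              file.path(config$out_dir, paste0("scores_", m, ".tsv")))

  if (config$n_perm > 0) {
    say("stage permtest (", config$n_perm, " permutations)")
    for (m in names(scores)) {
      pr <- permutation_pvalues(rel, m, params, n_perm = config$n_perm,
                                seed = config$stage_seeds$permtest)
      ed <- score_edges(scores[[m]])
      ed$p.value <- pr$pvalues[cbind(ed$otu_a, ed$otu_b)]
      ed$q_pass <- if (nrow(ed)) bh_fdr(ed$p.value, config$fdr_q)
                   else logical(0)
      write_tsv(ed, file.path(config$out_dir, paste0("pvals_", m, ".tsv")))
    }
  }

  say("stage cluster")
  partitions <- list()
  for (m in names(scores)) {
    part <- mcl(scores[[m]], inflation = config$inflation)
    partitions[[m]] <- part
    write_tsv(data.frame(otu_id = names(part$membership),
                         community = part$membership),
              file.path(config$out_dir, paste0("partition_", m, ".tsv")))
    write_tsv(inflation_sweep(scores[[m]], config$inflations),
              file.path(config$out_dir, paste0("sweep_", m, ".tsv")))
  }
  sweep_tab <- inflation_sweep(scores$pospos, config$inflations)

  say("stage profiles")
  prof <- community_profiles(partitions$pospos, rel)
  write_tsv(data.frame(community = rownames(prof), prof, check.names = FALSE),
            file.path(config$out_dir, "profiles_pospos.tsv"))

  edges <- NULL
  if (!is.null(config$metadata_path)) {
    say("stage granger")
    md <- read_metadata(config$metadata_path)
    edges <- causal_network(prof, md, q = config$fdr_q)
    write_tsv(edges, file.path(config$out_dir, "causal_edges.tsv"))
  }

  say("stage jsd")
  lag_max <- min(config$max_lag_jsd,
                 max(rel$sample_days) - min(rel$sample_days) - 1L)
  curve <- lag_similarity_curve(rel, lag_max)
  write_tsv(curve, file.path(config$out_dir, "lag_similarity.tsv"))

  say("done: ", config$out_dir)
  invisible(list(table = rel, scores_pospos = scores$pospos,
                 scores_negpos = scores$negpos,
                 partition_pospos = partitions$pospos,
                 partition_negpos = partitions$negpos,
                 profiles = prof, sweep = sweep_tab, edges = edges,
                 lag_curve = curve))
}
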