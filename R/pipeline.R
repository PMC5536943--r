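#' Run the full analysis pipeline on a session
#'
#' Executes the analysis stages in order — behaviour (CR scoring),
#' single-unit selectivity, firing-rate stability, ensemble state-vector
#' analyses, population decoding — on either a loaded session (from
#' [read_session()] or [simulate_session()]) or a freshly generated
#' synthetic one. Every stage draws its randomness from a named sub-stream
#' of `config$rng_seed`, so rerunning with the same seed reproduces every
#' number. Results are returned as a named list and, when `out_dir` is
#' given, also written as CSV tables.
#'
#' @param session a session list, or `NULL` to simulate one.
#' @param config an [analysis_config()].
#' @param schedule,pop_config,cr_config generator settings used when
#'   `session` is `NULL`.
#' @param out_dir optional output directory for the CSV tables.
#' @param stages subset of
#'   `c("behavior", "selectivity", "stability", "ensemble", "decoding")`.
#' @param decoding_collapses collapse modes evaluated in the decoding stage.
#' @param decoding_spec_args named list of overrides passed to
#'   [decoding_spec()] (e.g. smaller `n_runs`).
#' @return a list of per-stage results (invisibly also written to disk).
#' @export
run_pipeline <- function(session = NULL, config = analysis_config(),
                         schedule = session_schedule(),
                         pop_config = population_config(),
                         cr_config = cr_behavior_config(),
                         out_dir = NULL,
                         stages = c("behavior", "selectivity", "stability",
                                    "ensemble", "decoding"),
                         decoding_collapses = c("none", "modality",
                                                "environment",
                                                "relationship"),
                         decoding_spec_args = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  run_stage <- function(name, expr) {
    message(sprintf("[lecensemble] stage '%s' (seed sub-stream %d)",
                    name, stage_seed(config$rng_seed, name)))
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(session)) {
    session <- run_stage("schedule",
                         simulate_session(schedule, pop_config, cr_config,
                                          seed = config$rng_seed,
                                          emg = "behavior" %in% stages))
  }
  out <- list(config = config)

  if ("behavior" %in% stages) {
    out$behavior <- run_stage("behavior", {
      stop_if_not(!is.null(session$emg), "behavior stage requires an EMG trace")
      sc <- score_session(session$emg, session$trials, session$schedule)
      list(scores = sc$scores, threshold = sc$threshold,
           block_stats = block_cr_stats(sc$scores))
    })
  }
  if ("selectivity" %in% stages) {
    out$selectivity <- run_stage("selectivity", {
      tab <- selectivity_table(session, config)
      res <- list(table = tab,
                  counts_trial = category_counts(tab, "trial",
                                                 responding = TRUE),
                  counts_iti = category_counts(tab, "iti"))
      if (!is.null(out$behavior))
        res$cr_correlation <- cr_correlation(session,
                                             out$behavior$scores$label,
                                             config)
      res
    })
  }
  if ("stability" %in% stages) {
    out$stability <- run_stage("stability", stability_table(session, config))
  }
  if ("ensemble" %in% stages) {
    out$ensemble <- run_stage("ensemble", {
      list(blockpair_trial = block_pair_comparison(session, "trial", config),
           blockpair_iti = block_pair_comparison(session, "iti", config),
           iti_matrix = iti_correlation_matrix(
             session, config$n_subsample_cells_ensemble, config,
             seed = stage_seed(config$rng_seed, "ensemble") + 55L),
           similarity = similarity_scores(session, config))
    })
  }
  if ("decoding" %in% stages) {
    out$decoding <- run_stage("decoding", {
      res <- list()
      for (p in c("trial", "iti")) for (cl in decoding_collapses) {
        args <- utils::modifyList(list(period = p, collapse = cl),
                                  decoding_spec_args)
        spec <- do.call(decoding_spec, args)
        res[[paste(p, cl, sep = "_")]] <- decode(session, spec, config)
      }
      res
    })
  }
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  invisible(out)
}

# CSV emission for every stage that ran
write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  if (!is.null(out$behavior)) {
    wr(out$behavior$scores, "cr_scores.csv")
    wr(out$behavior$block_stats, "cr_block_stats.csv")
  }
  if (!is.null(out$selectivity)) {
    wr(out$selectivity$table, "selectivity.csv")
    wr(out$selectivity$counts_trial, "category_counts_trial.csv")
    wr(out$selectivity$counts_iti, "category_counts_iti.csv")
    if (!is.null(out$selectivity$cr_correlation))
      wr(out$selectivity$cr_correlation, "cr_correlation.csv")
  }
  if (!is.null(out$stability)) wr(out$stability, "stability.csv")
  if (!is.null(out$ensemble)) {
    wr(rbind(cbind(period = "trial", out$ensemble$blockpair_trial),
             cbind(period = "iti", out$ensemble$blockpair_iti)),
       "ensemble_blockpair.csv")
    utils::write.csv(out$ensemble$iti_matrix,
                     file.path(out_dir, "iti_matrix.csv"))
    wr(out$ensemble$similarity, "similarity_scores.csv")
  }
  if (!is.null(out$decoding)) {
    wr(do.call(rbind, lapply(out$decoding, `[[`, "results")),
       "decoding_results.csv")
    conf <- do.call(rbind, lapply(names(out$decoding), function(nm) {
      m <- out$decoding[[nm]]$confusion
      data.frame(analysis = nm,
                 true = rep(rownames(m), ncol(m)),
                 predicted = rep(colnames(m), each = nrow(m)),
                 count = as.vector(m))
    }))
    wr(conf, "confusion_matrices.csv")
  }
  invisible(out_dir)
}
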