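# End-to-end orchestration: score -> correlate -> estimate -> centrality ->
# predictability -> stability -> flow -> layout -> export, with one master
# seed and a deterministic manifest. Stage timings go to a JSON-lines log,
# never into the manifest, so reruns are byte-identical.

#' Assemble a pipeline configuration
#'
#' Defaults follow the standard settings of this analysis family: EBIC
#' gamma 0.5, 2000 bootstrap resamples, alpha 0.05, 80th-percentile bridge
#' selection.
#'
#' @param data An `item_matrix`, a `synthetic_cohort`, or a path to a raw
#'   CSV response table (validated with `instruments`).
#' @param instruments List of [instrument] objects (default PHQ-9 + GAD-7);
#'   used for scoring and, when `data` is a path, validation.
#' @param gamma EBIC hyperparameter.
#' @param n_lambdas,lambda_min_ratio Penalty-path settings.
#' @param nboots Bootstrap resamples for edge CIs and difference tests.
#' @param cs_nboots Case-dropping resamples per proportion.
#' @param drop_proportions Case-dropping proportions.
#' @param cs_threshold,cs_confidence CS coefficient rule.
#' @param alpha Difference-test significance level.
#' @param bridge_percentile Bridge-selection percentile.
#' @param focal Optional focal node for the flow decomposition.
#' @param seed Master seed for every stochastic stage.
#' @param out_dir Output directory (created if needed).
#' @param run_stability Set FALSE to skip the bootstrap stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data, instruments = list(phq9(), gad7()),
                            gamma = 0.5, n_lambdas = 100L,
                            lambda_min_ratio = 0.01, nboots = 2000L,
                            cs_nboots = nboots,
                            drop_proportions = seq(0.05, 0.75, by = 0.05),
                            cs_threshold = 0.7, cs_confidence = 0.95,
                            alpha = 0.05, bridge_percentile = 80,
                            focal = NULL, seed = 1L, out_dir,
                            run_stability = TRUE) {
  structure(list(data = data, instruments = instruments, gamma = gamma,
                 n_lambdas = as.integer(n_lambdas),
                 lambda_min_ratio = lambda_min_ratio,
                 nboots = as.integer(nboots),
                 cs_nboots = as.integer(cs_nboots),
                 drop_proportions = drop_proportions,
                 cs_threshold = cs_threshold, cs_confidence = cs_confidence,
                 alpha = alpha, bridge_percentile = bridge_percentile,
                 focal = focal, seed = as.integer(seed), out_dir = out_dir,
                 run_stability = isTRUE(run_stability)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  fields <- config[setdiff(names(config), "out_dir")]
  # canonicalize: sorted names, instruments reduced to their definitions
  fields <- fields[order(names(fields))]
  rlang::hash(lapply(fields, function(f) {
    if (inherits(f, "item_matrix")) f[c("values", "communities")] else f
  }))
}

log_stage <- function(log_path, stage, status, elapsed = NULL,
                      message = NULL) {
  rec <- list(stage = stage, status = status)
  if (!is.null(elapsed)) rec$elapsed_s <- round(elapsed, 3)
  if (!is.null(message)) rec$message <- message
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the full symptom-network pipeline
#'
#' Executes every stage in order and writes each module's exports plus a
#' machine-readable manifest (`manifest.json`: package version, seed,
#' config hash, stage statuses) and a JSON-lines run log with timings. A
#' stage failure is recorded, a `FAILED` marker file is written, later
#' dependent stages are skipped, and earlier outputs are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the computed objects, per-stage statuses,
#'   and the output paths; `$failed` names the first failed stage (or NULL).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  res <- list(stages = list(), failed = NULL, out_dir = out)

  run_stage <- function(name, fun) {
    if (!is.null(res$failed) && name != "manifest") {
      res$stages[[name]] <<- "skipped"
      log_stage(log_path, name, "skipped")
      return(NULL)
    }
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(fun(), error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    if (inherits(val, "error")) {
      res$stages[[name]] <<- "failed"
      res$failed <<- name
      log_stage(log_path, name, "failed", el, conditionMessage(val))
      writeLines(paste0("stage ", name, ": ", conditionMessage(val)),
                 file.path(out, "FAILED"))
      NULL
    } else {
      res$stages[[name]] <<- "ok"
      log_stage(log_path, name, "ok", el)
      val
    }
  }

  responses <- run_stage("validate", function() {
    d <- config$data
    if (inherits(d, "synthetic_cohort")) d <- d$responses
    if (!inherits(d, "item_matrix")) {
      d <- validate_responses(read.csv(d, check.names = FALSE),
                              config$instruments)
    }
    vlog <- file.path(out, "validation.jsonl")
    if (file.exists(vlog)) unlink(vlog)
    cat(jsonlite::toJSON(list(record = "summary",
                              n_subjects = nrow(d$values),
                              n_rejected = nrow(d$rejected)),
                         auto_unbox = TRUE), "\n",
        file = vlog, append = TRUE, sep = "")
    for (i in seq_len(nrow(d$rejected))) {
      cat(jsonlite::toJSON(list(record = "rejected",
                                subject = d$rejected$subject[i],
                                reason = d$rejected$reason[i]),
                           auto_unbox = TRUE), "\n",
          file = vlog, append = TRUE, sep = "")
    }
    d
  })
  res$responses <- responses

  run_stage("score", function() {
    tab <- score_table(responses, config$instruments)
    write.csv(tab, file.path(out, "scores.csv"), row.names = FALSE)
    alphas <- vapply(config$instruments,
                     function(ins) cronbach_alpha(responses, ins), 0)
    names(alphas) <- vapply(config$instruments, `[[`, "", "name")
    jsonlite::write_json(
      list(n_subjects = nrow(responses$values),
           n_rejected = nrow(responses$rejected),
           cronbach_alpha = as.list(alphas)),
      file.path(out, "scoring_summary.json"), auto_unbox = TRUE, digits = NA)
    tab
  })

  cm <- run_stage("correlate", function() {
    cm <- nearest_psd(spearman_matrix(responses))
    write_correlation_csv(cm, file.path(out, "correlation.csv"))
    cm
  })
  res$correlation <- cm

  net <- run_stage("estimate", function() {
    net <- estimate_network(cm, gamma = config$gamma,
                            n_lambdas = config$n_lambdas,
                            lambda_min_ratio = config$lambda_min_ratio)
    write_edge_list(net, file.path(out, "network_edges.csv"), all = TRUE)
    write_graphml(net, file.path(out, "network.graphml"))
    write_network_json(net, file.path(out, "network.json"))
    net
  })
  res$network <- net

  pred <- run_stage("predictability", function() {
    node_predictability(responses, net)
  })
  res$predictability <- pred

  run_stage("centrality", function() {
    write_centrality_csv(net, file.path(out, "centrality.csv"),
                         predictability = pred,
                         percentile = config$bridge_percentile)
  })

  if (config$run_stability) {
    boot <- run_stage("bootstrap", function() {
      bootstrap_network(responses, nboots = config$nboots,
                        seed = config$seed, gamma = config$gamma,
                        n_lambdas = config$n_lambdas,
                        lambda_min_ratio = config$lambda_min_ratio)
    })
    res$boot <- boot
    run_stage("edge_ci", function() {
      write.csv(edge_ci(boot), file.path(out, "edge_cis.csv"),
                row.names = FALSE)
    })
    run_stage("difference_tests", function() {
      for (tgt in c("edges", "expected_influence",
                    "bridge_expected_influence")) {
        dt <- difference_tests(boot, target = tgt, alpha = config$alpha)
        n_sig <- sum(dt$significant[upper.tri(dt$significant)])
        jsonlite::write_json(
          list(target = tgt, alpha = config$alpha,
               n_pairs = ncol(dt$significant) *
                 (ncol(dt$significant) - 1) / 2,
               n_significant = n_sig,
               significant = dt$significant),
          file.path(out, paste0("difference_", tgt, ".json")),
          auto_unbox = TRUE, digits = NA)
      }
    })
    res$cs <- run_stage("cs", function() {
      cs <- lapply(c("expected_influence", "bridge_expected_influence"),
                   function(m)
                     cs_coefficient(responses, metric = m,
                                    drop_proportions = config$drop_proportions,
                                    nboots = config$cs_nboots,
                                    seed = config$seed,
                                    threshold = config$cs_threshold,
                                    confidence = config$cs_confidence,
                                    gamma = config$gamma,
                                    n_lambdas = config$n_lambdas,
                                    lambda_min_ratio = config$lambda_min_ratio))
      names(cs) <- c("expected_influence", "bridge_expected_influence")
      for (m in names(cs)) {
        write.csv(cs[[m]]$curve,
                  file.path(out, paste0("cs_curve_", m, ".csv")),
                  row.names = FALSE)
      }
      jsonlite::write_json(
        lapply(cs, function(r) list(cs = r$cs, threshold = r$threshold,
                                    confidence = r$confidence,
                                    nboots = r$nboots)),
        file.path(out, "cs_summary.json"), auto_unbox = TRUE, digits = NA)
      cs
    })
  }

  if (!is.null(config$focal)) {
    res$flow <- run_stage("flow", function() {
      fl <- flow_network(net, config$focal)
      write_flow_json(fl, file.path(out, "flow.json"))
      fl
    })
  }

  run_stage("layout", function() {
    xy <- layout_network(net, seed = config$seed)
    write.csv(data.frame(node = net$labels, x = xy[, 1], y = xy[, 2]),
              file.path(out, "layout.csv"), row.names = FALSE)
  })

  run_stage("manifest", function() {
    jsonlite::write_json(
      list(package = "symptomnet",
           version = as.character(utils::packageVersion("symptomnet")),
           seed = config$seed,
           config_hash = config_hash(config),
           settings = list(gamma = config$gamma,
                           n_lambdas = config$n_lambdas,
                           lambda_min_ratio = config$lambda_min_ratio,
                           nboots = config$nboots,
                           alpha = config$alpha,
                           bridge_percentile = config$bridge_percentile),
           stages = res$stages),
      file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  })
  invisible(res)
}

#' Force-directed node coordinates
#'
#' Fruchterman-Reingold layout with absolute edge weights as attraction, so
#' strongly connected nodes sit near the center. Purely presentational;
#' deterministic under the seed. A single node maps to the origin.
#'
#' @param net A `symptom_network`.
#' @param seed Layout seed.
#' @param niter Iterations (default 500).
#' @return Numeric matrix of coordinates (nodes x 2).
#' @export
layout_network <- function(net, seed = 1L, niter = 500L) {
  stopifnot(inherits(net, "symptom_network"))
  p <- length(net$labels)
  if (p == 1L) {
    return(matrix(0, 1, 2, dimnames = list(net$labels, c("x", "y"))))
  }
  A <- abs(net$W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, niter = niter,
                               weights = igraph::E(g)$weight)
  dimnames(xy) <- list(net$labels, c("x", "y"))
  xy
}
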