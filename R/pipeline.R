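#' Pipeline configuration
#'
#' Builds the nested configuration consumed by [run_pipeline()]. Either
#' supply `simulate` parameters (forwarded to [plant_spec()]) to generate
#' synthetic inputs, or an `inputs` block of file paths (`edgelists` as a
#' named class -> path list, `obo`, `annotations`, `expression`,
#' `complexes`, `pathways`). Defaults mirror the standard
#' parameterization: MCODE node score 0.2, haircut on, fluff off, max
#' depth 100, GO/correlation/frequency thresholds 0.5, maximum community
#' size 200, representative subset 5.
#'
#' @param seed global seed, propagated to every stochastic stage.
#' @param outdir report output directory (`NULL` keeps results in
#'   memory).
#' @param simulate list of [plant_spec()] overrides, or `NULL` when
#'   `inputs` is given.
#' @param inputs list of input file paths (see above), or `NULL`.
#' @param methods detectors to run, subset of
#'   `c("cpm", "mcode", "maxmod", "walktrap")`.
#' @param cpm_k clique size for CPM.
#' @param detect list of [detection_params()] overrides.
#' @param go_threshold,cor_threshold confidence thresholds.
#' @param freq_threshold matching-frequency threshold for class-level
#'   validation.
#' @param stages which stages to run, in order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL, simulate = list(),
                            inputs = NULL,
                            methods = c("cpm", "mcode", "maxmod",
                                        "walktrap"),
                            cpm_k = 4L, detect = list(),
                            go_threshold = 0.5, cor_threshold = 0.5,
                            freq_threshold = 0.5,
                            stages = c("simulate", "detect", "score",
                                       "validate", "report")) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 simulate = simulate, inputs = inputs, methods = methods,
                 cpm_k = as.integer(cpm_k),
                 detect = do.call(detection_params, detect),
                 thresholds = confidence_thresholds(go_threshold,
                                                    cor_threshold),
                 freq_threshold = freq_threshold, stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

stage_try <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> detect -> score -> validate -> report:
#' generates (or loads) the interactome classes, annotation layer,
#' expression compendium and catalogs; runs the configured detectors on
#' every class; computes annotation variables, confidence labels,
#' permanence and cross-talk per module; validates each (method, class)
#' module set against the complex catalog (class-level precision'/recall'
#' and protein-level precision/recall) and fits a power law to CPM module
#' sizes when enough modules exist; finally writes module, score and
#' validation tables plus a run manifest to `config$outdir`. Any stage
#' failure aborts with a stage-named error; outputs written by earlier
#' stages are retained. The run is deterministic given the config.
#'
#' @param config a [pipeline_config()], a YAML path, or a plain list of
#'   [pipeline_config()] arguments.
#' @return invisibly, a list with `inputs`, `modules`, `scores`,
#'   `validation`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  res <- list()

  if ("simulate" %in% config$stages || is.null(config$inputs)) {
    res$inputs <- stage_try("simulate", {
      if (is.null(config$inputs)) {
        spec <- do.call(plant_spec, c(config$simulate,
                                      list(seed = config$seed)))
        sim <- simulate_study(spec, outdir = config$outdir)
        message(sprintf("[simulate] %d classes, %d plants",
                        length(sim$classes), length(sim$truth$plants)))
        sim
      } else {
        inp <- config$inputs
        for (p in c(unlist(inp$edgelists), inp$obo, inp$annotations,
                    inp$expression, inp$complexes, inp$pathways)) {
          if (!file.exists(p)) stop("missing input file: ", p)
        }
        nets <- lapply(names(inp$edgelists), function(cl)
          load_edgelist(inp$edgelists[[cl]], cl))
        names(nets) <- names(inp$edgelists)
        if (!"INT" %in% names(nets)) {
          nets$INT <- integrate_networks(nets)
        }
        list(classes = nets, ontology = read_obo(inp$obo),
             annotations = read_annotations(inp$annotations),
             expression = read_expression(inp$expression),
             complexes = read_gmt(inp$complexes),
             pathways = read_gmt(inp$pathways))
      }
    })
  }
  if (!any(c("detect", "score", "validate", "report") %in%
           config$stages)) {
    return(invisible(res))
  }

  res$modules <- stage_try("detect", {
    out <- list()
    for (cl in names(res$inputs$classes)) {
      net <- res$inputs$classes[[cl]]
      if ("cpm" %in% config$methods) {
        out[[paste0("CPM.", cl)]] <- detect_cpm(net, config$cpm_k)
      }
      if ("mcode" %in% config$methods) {
        out[[paste0("MCODE.", cl)]] <- detect_mcode(net, config$detect)
      }
      if ("maxmod" %in% config$methods && nrow(net$edges)) {
        out[[paste0("MAXMOD.", cl)]] <- detect_greedy(net)$modules
      }
      if ("walktrap" %in% config$methods && nrow(net$edges)) {
        out[[paste0("WALKTRAP.", cl)]] <-
          detect_walktrap(net, config$detect$walktrap_steps)$modules
      }
    }
    message(sprintf("[detect] %d module set(s), %d modules total",
                    length(out), sum(vapply(out, nrow, 1L))))
    out
  })

  if (any(c("score", "validate", "report") %in% config$stages)) {
    res$scores <- stage_try("score", {
      out <- lapply(names(res$modules), function(key) {
        cl <- sub("^[A-Z]+\\.", "", key)
        score_modules(res$modules[[key]], res$inputs$ontology,
                      res$inputs$annotations, res$inputs$expression,
                      res$inputs$classes[[cl]],
                      gene_sets = res$inputs$pathways,
                      thresholds = config$thresholds)
      })
      names(out) <- names(res$modules)
      message(sprintf("[score] %d labeled module(s)",
                      sum(vapply(out, nrow, 1L))))
      out
    })
  }

  if (any(c("validate", "report") %in% config$stages)) {
    res$validation <- stage_try("validate", {
      out <- lapply(names(res$modules), function(key) {
        ms <- res$modules[[key]]
        if (nrow(ms) == 0L) return(NULL)
        cp <- class_pr(ms, res$inputs$complexes,
                       freq_threshold = config$freq_threshold)
        pp <- protein_pr(ms, res$inputs$complexes)
        pl <- if (nrow(ms) >= 10L &&
                  length(unique(lengths(ms$members))) > 1L) {
          tryCatch(fit_power_law(lengths(ms$members)),
                   error = function(e) NULL)
        }
        list(class_summary = cp, protein_counts = pp, power_law = pl)
      })
      names(out) <- names(res$modules)
      message(sprintf("[validate] %d module set(s) validated",
                      sum(!vapply(out, is.null, TRUE))))
      out
    })
  }

  res$manifest <- list(
    package = as.character(utils::packageVersion("ppimodules")),
    seed = config$seed, methods = config$methods,
    cpm_k = config$cpm_k,
    thresholds = unclass(config$thresholds),
    freq_threshold = config$freq_threshold,
    detect = unclass(config$detect),
    module_counts = vapply(res$modules, nrow, 1L))

  if ("report" %in% config$stages && !is.null(config$outdir)) {
    stage_try("report", {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      for (key in names(res$modules)) {
        write_modules(res$modules[[key]],
                      file.path(config$outdir,
                                sprintf("modules_%s.tsv", key)))
        utils::write.table(res$scores[[key]],
                           file.path(config$outdir,
                                     sprintf("scores_%s.tsv", key)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      vrows <- do.call(rbind, lapply(names(res$validation), function(k) {
        v <- res$validation[[k]]
        if (is.null(v)) return(NULL)
        data.frame(set = k, MM = v$class_summary$MM,
                   PM = v$class_summary$PM, MC = v$class_summary$MC,
                   KC = v$class_summary$KC,
                   precision_prime = v$class_summary$precision_prime,
                   recall_prime = v$class_summary$recall_prime,
                   protein_precision = v$protein_counts$precision,
                   protein_recall = v$protein_counts$recall,
                   alpha = if (is.null(v$power_law)) NA_real_ else
                     v$power_law$alpha,
                   stringsAsFactors = FALSE)
      }))
      if (!is.null(vrows)) {
        utils::write.table(vrows,
                           file.path(config$outdir, "validation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      jsonlite::write_json(res$manifest,
                           file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      message("[report] bundle written to ", config$outdir)
    })
  }
  invisible(res)
}
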