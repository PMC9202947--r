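#' Run the full validation pipeline from a configuration
#'
#' Wires the stages together: simulate (or load) a Ct table, QC-collapse
#' technical replicates, calibrate amplification efficiencies, rank
#' reference-gene stability by the five estimators, compute the geNorm
#' pairwise-variation curve, quantify a gene of interest by 2^-ddCt, and
#' screen an FPKM table. Stages are run in dependency order; each stage
#' writes plain CSV/JSON into `out_dir` and a combined Markdown report is
#' emitted at the end, so the whole bundle is diff-able.
#'
#' @param config A named list, or path to a YAML file with the same
#'   structure. Recognized entries:
#'   \describe{
#'     \item{seed}{integer; seeds all randomness.}
#'     \item{template}{template kind to analyze (default `"total"`).}
#'     \item{simulate}{`list(preset = "sea-urchin-7gene")` or any
#'       arguments accepted by [sim_config()]; mutually exclusive with
#'       `input`.}
#'     \item{input}{`list(path =, layout =)` for [read_ct_table()].}
#'     \item{qc}{`list(max_spread = 0.5)`.}
#'     \item{stability}{`list(methods = "all", v_threshold = 0.15)`.}
#'     \item{efficiency}{`list(input = path)` of dilution-series CSV.}
#'     \item{ddct}{`list(goi =, refs =, calibrator =)`.}
#'     \item{screen}{`list(input = path, min_fpkm =, max_fold =,
#'       goi_min_fpkm =, goi_min_fold =)`.}
#'   }
#' @param out_dir Output directory (created if missing). Omit to skip all
#'   file output and only return results.
#' @param dry_run Validate the configuration and input paths without
#'   computing anything.
#' @return Invisibly, a list of stage results (`table`, `qc`, `summary`,
#'   `stability`, `rank`, `pairwise_variation`, `efficiency`, `ddct`,
#'   `screen`) plus the validated `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, dry_run = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- validate_pipeline_config(config)
  if (dry_run) return(invisible(list(config = cfg)))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir,
                                                                   name)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- list(config = cfg)

  # --- input ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- simulate_ct_experiment(cfg$sim_config)
    res$table <- sim$table
    res$truth <- sim$truth
    if (!is.null(out_dir)) {
      write_ct_table(sim$table, emit("ct_table.csv"))
      jsonlite::write_json(sim$truth[c("fold", "most_stable", "goi")],
                           emit("truth.json"), auto_unbox = TRUE, digits = NA)
    }
  } else {
    res$table <- read_ct_table(cfg$input$path,
                               layout = cfg$input$layout %||% "long")
  }

  # --- qc ------------------------------------------------------------
  collapsed <- collapse_replicates(res$table,
                                   max_spread = cfg$qc$max_spread %||% 0.5)
  res$qc <- qc_report(collapsed)
  res$summary <- summarize_ct(collapsed)
  if (!is.null(out_dir)) {
    write_qc_report(res$qc, csv = emit("qc_cells.csv"),
                    json = emit("qc.json"))
    utils::write.csv(res$summary, emit("ct_summary.csv"), row.names = FALSE)
  }

  # --- efficiency ----------------------------------------------------
  if (!is.null(cfg$efficiency)) {
    series <- read_dilution_series(cfg$efficiency$input)
    res$efficiency <- fit_standard_curves(series,
                                          window = cfg$efficiency$window %||%
                                            c(90, 110))
    if (!is.null(out_dir)) {
      write_efficiency_fits(res$efficiency, csv = emit("efficiency.csv"),
                            json = emit("efficiency.json"))
    }
  }

  # --- stability + ranking -------------------------------------------
  template <- cfg$template %||% unique(collapsed$template)[1]
  panel <- collapsed
  goi <- cfg$ddct$goi
  if (!is.null(goi) && goi %in% panel$gene) {
    panel_df <- as.data.frame(panel)[panel$gene != goi, ]
    panel <- ct_table(panel_df)
  }
  methods <- cfg$stability$methods %||% "all"
  if (identical(methods, "all") || "all" %in% methods) {
    methods <- c("bestkeeper", "cv", "delta_ct", "genorm", "normfinder")
  }
  res$stability <- stability_all(panel, template = template,
                                 methods = methods)
  if (length(res$stability) >= 1) {
    res$rank <- aggregate_rankings(res$stability)
  }
  if ("genorm" %in% names(res$stability)) {
    res$pairwise_variation <- genorm_pairwise_variation(
      panel, ranking = res$stability$genorm$ranking,
      threshold = cfg$stability$v_threshold %||% 0.15, template = template)
  }
  if (!is.null(out_dir)) {
    for (m in names(res$stability)) {
      utils::write.csv(as.data.frame(res$stability[[m]]),
                       emit(paste0("stability_", m, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(res$rank)) {
      write_rank_table(res$rank, csv = emit("rank_table.csv"),
                       json = emit("rank_table.json"))
    }
    if (!is.null(res$pairwise_variation)) {
      pv <- res$pairwise_variation
      utils::write.csv(data.frame(pair = names(pv$v), v = unname(pv$v)),
                       emit("pairwise_variation.csv"), row.names = FALSE)
    }
  }

  # --- ddct ----------------------------------------------------------
  if (!is.null(cfg$ddct)) {
    res$ddct <- ddct(collapsed, goi = cfg$ddct$goi,
                     refs = unlist(cfg$ddct$refs),
                     calibrator = cfg$ddct$calibrator,
                     template = template)
    if (!is.null(out_dir)) {
      write_rel_expr(res$ddct, csv = emit("ddct_samples.csv"),
                     json = emit("ddct.json"))
    }
  }

  # --- screen --------------------------------------------------------
  if (!is.null(cfg$screen)) {
    ft <- read_fpkm_table(cfg$screen$input)
    res$screen <- list(
      reference = screen_reference_candidates(
        ft, min_fpkm = cfg$screen$min_fpkm %||% 1000,
        max_fold = cfg$screen$max_fold %||% 1.5),
      goi = screen_goi_candidates(
        ft, min_fpkm = cfg$screen$goi_min_fpkm %||% 0.5,
        min_fold = cfg$screen$goi_min_fold %||% 2))
    if (!is.null(out_dir)) {
      utils::write.csv(res$screen$reference, emit("screen_reference.csv"),
                       row.names = FALSE)
      utils::write.csv(res$screen$goi, emit("screen_goi.csv"),
                       row.names = FALSE)
    }
  }

  if (!is.null(out_dir)) {
    writeLines(pipeline_report(res), file.path(out_dir, "report.md"))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$simulate) && !is.null(cfg$input)) {
    stop("config has both `simulate` and `input`; choose one", call. = FALSE)
  }
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stop("config needs either `simulate` or `input`", call. = FALSE)
  }
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$path)) stop("`input$path` is required",
                                      call. = FALSE)
    if (!file.exists(cfg$input$path)) {
      stop("input Ct table not found: ", cfg$input$path, call. = FALSE)
    }
  }
  if (!is.null(cfg$simulate)) {
    cfg$sim_config <- if (identical(cfg$simulate$preset, "sea-urchin-7gene")) {
      preset_sea_urchin()
    } else if (inherits(cfg$simulate, "sim_config")) {
      cfg$simulate
    } else if (!is.null(cfg$simulate$genes)) {
      do.call(sim_config, cfg$simulate)
    } else {
      stop("`simulate` needs a `preset` or a `genes` table", call. = FALSE)
    }
  }
  for (f in c(cfg$efficiency$input, cfg$screen$input)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  thresholds <- c(cfg$qc$max_spread, cfg$stability$v_threshold,
                  cfg$screen$min_fpkm, cfg$screen$max_fold,
                  cfg$screen$goi_min_fpkm, cfg$screen$goi_min_fold)
  if (any(unlist(thresholds) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  if (!is.null(cfg$ddct)) {
    need <- setdiff(c("goi", "refs", "calibrator"), names(cfg$ddct))
    if (length(need)) {
      stop("`ddct` config is missing: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (cfg$ddct$goi %in% unlist(cfg$ddct$refs)) {
      stop("gene of interest '", cfg$ddct$goi,
           "' cannot be one of the reference genes", call. = FALSE)
    }
  }
  cfg
}

pipeline_report <- function(res) {
  lines <- c("# RT-qPCR reference-gene validation report", "")
  lines <- c(lines, sprintf("- genes: %d, samples: %d",
                            length(unique(res$table$gene)),
                            length(unique(res$table$sample))))
  lines <- c(lines, sprintf("- QC: %d cells, %d flagged (spread >= %.2f)",
                            nrow(res$qc$cells), res$qc$n_flagged,
                            res$qc$max_spread), "")
  if (!is.null(res$rank)) {
    lines <- c(lines, "## Stability ranking", "",
               format_rank_table(res$rank, "markdown"), "")
    cons <- res$rank$consensus
    lines <- c(lines, sprintf(
      "Consensus (geometric mean of ranks): %s",
      paste(cons$gene, collapse = " > ")), "")
  }
  if (!is.null(res$pairwise_variation)) {
    pv <- res$pairwise_variation
    lines <- c(lines, "## Pairwise variation", "",
               sprintf("- %s = %.4f", names(pv$v), pv$v),
               sprintf("- recommended number of reference genes: %d",
                       pv$recommended), "")
  }
  if (!is.null(res$ddct)) {
    g <- res$ddct$groups
    lines <- c(lines, "## Relative expression", "",
               sprintf("- %s vs %s (calibrator %s): %s",
                       res$ddct$goi, paste(res$ddct$refs, collapse = "/"),
                       res$ddct$calibrator,
                       paste(sprintf("%s fold = %.3f", g$group, g$fold),
                             collapse = ", ")),
               sprintf("- t = %.3f, df = %.3g, p = %.4g",
                       res$ddct$test$statistic, res$ddct$test$df,
                       res$ddct$test$p_value), "")
  }
  if (!is.null(res$screen)) {
    lines <- c(lines, "## Candidate screen", "",
               sprintf("- reference candidates: %s",
                       paste(res$screen$reference$transcript,
                             collapse = ", ")),
               sprintf("- enriched candidates: %s",
                       paste(res$screen$goi$transcript, collapse = ", ")), "")
  }
  lines
}
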