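# End-to-end pipeline: simulate (or read) -> QC -> single-step GREML ->
# weighted iterations -> window scan -> annotate, with a reproducible
# run manifest.

#' Run the full analysis pipeline
#'
#' Stages run in order: `simulate` (skipped when real input files are
#' given under `io$inputs`), `qc`, the single-step GREML / weighted
#' GBLUP iterations, the window scan, and BED annotation when an
#' interval file is configured. Outputs (window TSVs, components JSON,
#' Manhattan-ready table, log, manifest with input/output md5 hashes)
#' are written under the output directory.
#'
#' @param config path to a YAML configuration, or an equivalent named
#'   list with sections `simulate`, `qc`, `model`, `wssgwas`, `io`.
#' @param out_dir output directory (overrides `io$out_dir`).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  io <- cfg$io %||% list()
  out_dir <- out_dir %||% io$out_dir %||% "wssgblup_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- "setup"
  on_fail <- function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  tryCatch({
    manifest <- list(config = cfg, started = format(Sys.time()),
                     version = as.character(utils::packageVersion("wssgblup")))
    inputs <- io$inputs

    stage <- "simulate"
    if (is.null(inputs)) {
      sc <- do.call(sim_config, cfg$simulate %||% list())
      logf("simulate: trait %s, seed %d", sc$trait_profile, sc$seed)
      herd <- simulate_herd(sc)
      fx <- write_fixtures(herd, file.path(out_dir, "sim"))
      manifest$seed <- sc$seed
      manifest$inputs <- as.list(fx)
      ped <- herd$ped
      phen <- herd$phenotypes
      g_all <- subset_genotypes(herd$genotypes,
                                attr(herd$genotypes, "genotyped_ids"))
      trait <- sc$trait_profile
    } else {
      logf("reading inputs")
      ped <- compute_inbreeding(read_pedigree(inputs$pedigree))
      phen <- read_phenotypes(inputs$phenotypes)
      g_all <- read_plink_text(inputs$ped, inputs$map)
      manifest$inputs <- inputs
      trait <- cfg$model$trait %||% "custom"
    }

    stage <- "qc"
    qc_args <- cfg$qc %||% list()
    qc <- do.call(qc_filter, c(list(g_all), qc_args))
    logf("qc: dropped %s; %d SNPs, %d animals remain",
         paste(sprintf("%d %s", qc$report$removed, qc$report$stage),
               collapse = ", "),
         utils::tail(qc$report$snps_remaining, 1),
         utils::tail(qc$report$animals_remaining, 1))
    write_tsv0(qc$report, file.path(out_dir, "qc_report.tsv"))

    stage <- "wssgblup"
    model <- cfg$model %||% list()
    ws <- cfg$wssgwas %||% list()
    spec <- trait_model_spec(model$trait %||% trait)
    vc_fixed <- if (!is.null(model$vc))
      variance_components(model$vc$sigma2_a, model$vc$sigma2_hys,
                          model$vc$sigma2_e) else NULL
    run <- run_wssgblup(spec, phen, ped, qc$genotypes,
                        n_iterations = ws$n_iterations %||% 2L,
                        vc = vc_fixed,
                        blend_alpha = ws$blend_alpha %||% 0.05,
                        tol = model$reml_tol %||% 1e-8)
    for (itr in run$iterations) {
      d <- as.numeric(itr$weights)
      logf("iteration %d: h2 = %.4f, weights mean/max = %.3f/%.3f",
           itr$iteration, itr$vc$h2, mean(d), max(d))
    }
    write_vc_json(run$vc, file.path(out_dir, "components.json"))

    stage <- "scan"
    scan <- scan_windows(run, span_bp = ws$window_bp %||% 1e6,
                         threshold_pct = ws$threshold_pct %||% 1)
    write_tsv0(scan$windows, file.path(out_dir, "windows.tsv"))
    write_tsv0(scan$selected, file.path(out_dir, "selected_windows.tsv"))
    write_tsv0(manhattan_table(scan$windows),
               file.path(out_dir, "manhattan.tsv"))
    logf("scan: %d windows, %d selected above %.2f%%",
         nrow(scan$windows), nrow(scan$selected), ws$threshold_pct %||% 1)
    top <- utils::head(scan$selected, 10)

    stage <- "annotate"
    if (!is.null(io$bed)) {
      ann <- annotate_windows(scan$selected, io$bed)
      write_tsv0(ann, file.path(out_dir, "annotated_windows.tsv"))
      logf("annotate: %d window-feature overlaps", nrow(ann))
    }

    stage <- "manifest"
    manifest$components <- list(sigma2_a = run$vc$sigma2_a,
                                sigma2_hys = run$vc$sigma2_hys,
                                sigma2_e = run$vc$sigma2_e, h2 = run$vc$h2)
    manifest$top_windows <- top
    outs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    outs <- outs[!grepl("manifest\\.json$|run\\.log$", outs)]
    manifest$file_md5 <- as.list(stats::setNames(
      as.character(tools::md5sum(outs)),
      sub(paste0("^", out_dir, "/?"), "", outs)))
    manifest$finished <- format(Sys.time())
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(manifest)
  }, error = on_fail)
}
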