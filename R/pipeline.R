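# Command-line-style orchestration: build targets, simulate a time course,
# annotate, assemble KMD plot data, subtract spectra and compute aging
# trends, writing TSV artifacts plus a provenance file to an output
# directory.

#' Pipeline run configuration
#'
#' @param target_config A \code{target_config} (see [target_list_config()]).
#' @param aging An \code{aging_params} for the simulator.
#' @param tol_ppm Annotation and matching tolerance in ppm (default 2).
#' @param sn_threshold KMD plot S/N threshold (default 30).
#' @param kmd_range Lipid KMD window (default \code{c(0.05, 0.35)}).
#' @param ages,replicates Simulated time-course design.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(target_config = target_list_config(),
                            aging = aging_params(), tol_ppm = 2,
                            sn_threshold = 30, kmd_range = c(0.05, 0.35),
                            ages = c(0, 1, 3, 5, 7), replicates = 4L) {
  stopifnot(inherits(target_config, "target_config"),
            inherits(aging, "aging_params"), tol_ppm > 0, sn_threshold >= 0)
  if (length(kmd_range) != 2 || kmd_range[1] >= kmd_range[2])
    stop("kmd_range must be an increasing window", call. = FALSE)
  structure(list(target_config = target_config, aging = aging,
                 tol_ppm = tol_ppm, sn_threshold = sn_threshold,
                 kmd_range = kmd_range, ages = ages,
                 replicates = as.integer(replicates)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys (all optional, defaults as in [pipeline_config()]):
#' \code{tol_ppm}, \code{sn_threshold}, \code{kmd_range} (2 numbers),
#' \code{ages}, \code{replicates}, and any argument of [aging_params()] or
#' [target_list_config()] under the maps \code{aging:} and \code{targets:}.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  aging <- do.call(aging_params, as.list(y$aging))
  targets <- do.call(target_list_config, as.list(y$targets))
  args <- y[setdiff(names(y), c("aging", "targets"))]
  args$aging <- aging
  args$target_config <- targets
  do.call(pipeline_config, args)
}

.log_line <- function(out_dir, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
  message(line)
  cat(line, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

.write_provenance <- function(config, seed, out_dir) {
  prov <- list(
    package = "kmdaging",
    version = as.character(utils::packageVersion("kmdaging")),
    seed = seed,
    tol_ppm = config$tol_ppm, sn_threshold = config$sn_threshold,
    kmd_range = config$kmd_range, ages = config$ages,
    replicates = config$replicates,
    aging = unclass(config$aging),
    targets = list(ranges = config$target_config$ranges,
                   mz_range = config$target_config$mz_range))
  writeLines(yaml::as.yaml(prov), file.path(out_dir, "provenance.yml"))
}

.pipeline_timecourse <- function(config, seed, out_dir) {
  tc <- generate_timecourse(config$ages, config$replicates,
                            params = config$aging, seed = seed)
  spectra_dir <- file.path(out_dir, "spectra")
  truth_dir <- file.path(out_dir, "truth")
  dir.create(spectra_dir, showWarnings = FALSE)
  dir.create(truth_dir, showWarnings = FALSE)
  for (s in tc$samples) {
    sid <- s$peaks$meta$sample_id
    write_peaklist(s$peaks, file.path(spectra_dir, paste0(sid, ".tsv")))
    utils::write.table(s$truth,
                       file.path(truth_dir, paste0(sid, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  }
  tc
}

.read_spectra_dir <- function(out_dir) {
  spectra_dir <- file.path(out_dir, "spectra")
  files <- sort(list.files(spectra_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (!length(files))
    stop("no spectra found under ", spectra_dir,
         "; run the simulate stage (or place peak-list TSVs there) first",
         call. = FALSE)
  lapply(files, read_peaklist)
}

#' Run the analysis pipeline
#'
#' Stages (\code{command}): \describe{
#'   \item{build-targets}{write the in silico target list
#'     (\code{targets.tsv}).}
#'   \item{simulate}{generate the synthetic time course; write
#'     \code{spectra/*.tsv} and \code{truth/*.tsv}.}
#'   \item{annotate}{annotate every spectrum under \code{spectra/} at
#'     \code{tol_ppm}; write \code{annotations/*.tsv}.}
#'   \item{kmdplot}{write KMD plot tables (\code{kmd/*.tsv}) and, when
#'     ggplot2 is installed, a fresh-vs-oldest overlay figure
#'     (\code{kmd/kmd_overlay.png}).}
#'   \item{subtract}{normalize the first fresh and oldest replicate-1
#'     spectra and write their subtracted spectrum
#'     (\code{subtracted.tsv}).}
#'   \item{trends}{write the epoxide ratio series, FA profiles and FA 10:0
#'     marker (\code{trends/*.tsv}).}
#'   \item{all}{run every stage in order.}
#' }
#' Every run writes \code{provenance.yml} (package version, seed, full
#' configuration) and appends to \code{pipeline.log}; with a fixed seed the
#' artifact set is byte-identical across runs.
#'
#' @param command One of the stage names above.
#' @param config A \code{pipeline_config}.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed controlling all simulator randomness.
#' @return Invisibly, a character vector of artifact paths.
#' @export
run_pipeline <- function(command = c("all", "build-targets", "simulate",
                                     "annotate", "kmdplot", "subtract",
                                     "trends"),
                         config = pipeline_config(), out_dir, seed = 1L) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_provenance(config, seed, out_dir)
  artifacts <- character(0)
  stages <- if (command == "all")
    c("build-targets", "simulate", "annotate", "kmdplot", "subtract",
      "trends")
  else command

  targets <- NULL
  need_targets <- function() {
    if (is.null(targets))
      targets <<- build_target_list(config$target_config)
    targets
  }

  for (stage in stages) {
    .log_line(out_dir, "stage %s: start", stage)
    if (stage == "build-targets") {
      tl <- need_targets()
      p <- file.path(out_dir, "targets.tsv")
      write_target_list(tl, p)
      artifacts <- c(artifacts, p)
      .log_line(out_dir, "stage %s: %d target entries", stage, nrow(tl))
    } else if (stage == "simulate") {
      tc <- .pipeline_timecourse(config, seed, out_dir)
      artifacts <- c(artifacts,
                     list.files(file.path(out_dir, "spectra"),
                                full.names = TRUE))
      .log_line(out_dir, "stage %s: %d spectra", stage, length(tc$samples))
    } else if (stage == "annotate") {
      pls <- .read_spectra_dir(out_dir)
      ann_dir <- file.path(out_dir, "annotations")
      dir.create(ann_dir, showWarnings = FALSE)
      tl <- need_targets()
      n_assigned <- 0L
      for (pl in pls) {
        ann <- annotate_peaks(pl, tl, config$tol_ppm)
        ann <- flag_type2_interference(ann, pl, tol_ppm = config$tol_ppm)
        p <- file.path(ann_dir, paste0(pl$meta$sample_id, "_annotation.tsv"))
        write_annotation(ann, p)
        artifacts <- c(artifacts, p)
        n_assigned <- n_assigned + sum(!is.na(ann$label))
      }
      .log_line(out_dir, "stage %s: %d peaks assigned over %d spectra",
                stage, n_assigned, length(pls))
    } else if (stage == "kmdplot") {
      pls <- .read_spectra_dir(out_dir)
      kmd_dir <- file.path(out_dir, "kmd")
      dir.create(kmd_dir, showWarnings = FALSE)
      tabs <- list()
      for (pl in pls) {
        tab <- kmd_plot_data(pl, config$kmd_range,
                             sn_threshold = config$sn_threshold)
        p <- file.path(kmd_dir, paste0(pl$meta$sample_id, "_kmd.tsv"))
        utils::write.table(tab, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        artifacts <- c(artifacts, p)
        tabs[[length(tabs) + 1L]] <- tab
      }
      ages <- vapply(pls, function(pl) pl$meta$age_days, numeric(1))
      if (requireNamespace("ggplot2", quietly = TRUE) &&
          length(unique(ages[!is.na(ages)])) >= 2) {
        sel <- c(which(ages == min(ages, na.rm = TRUE))[1],
                 which(ages == max(ages, na.rm = TRUE))[1])
        overlay <- do.call(rbind, tabs[sel])
        fig <- file.path(kmd_dir, "kmd_overlay.png")
        grDevices::png(fig, width = 1400, height = 900, res = 150)
        print(plot_kmd(overlay))
        grDevices::dev.off()
        artifacts <- c(artifacts, fig)
      }
      .log_line(out_dir, "stage %s: %d plot tables", stage, length(tabs))
    } else if (stage == "subtract") {
      pls <- .read_spectra_dir(out_dir)
      ages <- vapply(pls, function(pl) pl$meta$age_days, numeric(1))
      fresh <- pls[[which(ages == min(ages, na.rm = TRUE))[1]]]
      aged <- pls[[which(ages == max(ages, na.rm = TRUE))[1]]]
      tl <- need_targets()
      fresh <- normalize_to_saturated_tg(fresh,
                                         annotate_peaks(fresh, tl,
                                                        config$tol_ppm))
      aged <- normalize_to_saturated_tg(aged,
                                        annotate_peaks(aged, tl,
                                                       config$tol_ppm))
      sub <- subtract_spectra(fresh, aged, config$tol_ppm)
      p <- file.path(out_dir, "subtracted.tsv")
      write_subtracted(sub, p)
      artifacts <- c(artifacts, p)
      .log_line(out_dir, "stage %s: %d bins (%s d minus %s d)", stage,
                nrow(sub), aged$meta$age_days, fresh$meta$age_days)
    } else if (stage == "trends") {
      pls <- .read_spectra_dir(out_dir)
      tl <- need_targets()
      atc <- annotate_timecourse(pls, tl, config$tol_ppm)
      trends_dir <- file.path(out_dir, "trends")
      dir.create(trends_dir, showWarnings = FALSE)
      outs <- list(
        epoxide_ratio_r0 = epoxide_ratio_series(atc, residual_db = 0L),
        epoxide_ratio_r1 = epoxide_ratio_series(atc, residual_db = 1L),
        fa_profile_sat = fa_profile_series(atc, db = 0L),
        fa_profile_mono = fa_profile_series(atc, db = 1L),
        fa10_marker = fa10_marker(atc))
      for (nm in names(outs)) {
        p <- file.path(trends_dir, paste0(nm, ".tsv"))
        write_marker_series(outs[[nm]], p)
        artifacts <- c(artifacts, p)
      }
      .log_line(out_dir, "stage %s: %d marker tables", stage, length(outs))
    }
    .log_line(out_dir, "stage %s: done", stage)
  }
  invisible(artifacts)
}
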