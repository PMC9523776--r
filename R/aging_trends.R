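# Time-course aging markers: TG epoxide ratios normalized to the
# corresponding saturated TG, FA chain-length profiles, and the FA 10:0
# medium-chain fatty-acid marker.

#' Annotate every sample of a time course
#'
#' Runs [annotate_peaks()] (and optionally saturated-TG normalization) on
#' each sample of a synthetic or assembled time course.
#'
#' @param tc An \code{fp_timecourse} from [generate_timecourse()], or a
#'   list of \code{peaklist}s carrying \code{age_days}/\code{replicate}
#'   metadata.
#' @param targets A \code{target_list}.
#' @param tol_ppm Annotation tolerance in ppm.
#' @param normalize Normalize each sample to its summed saturated-TG signal
#'   before storing intensities (default TRUE). The markers themselves are
#'   ratios and scale-invariant either way.
#' @return Object of class \code{fp_timecourse_annotated}: list of samples,
#'   each with \code{age_days}, \code{replicate} and \code{annotation}.
#' @export
annotate_timecourse <- function(tc, targets, tol_ppm = 2, normalize = TRUE) {
  pls <- if (inherits(tc, "fp_timecourse"))
    lapply(tc$samples, `[[`, "peaks") else tc
  samples <- lapply(pls, function(pl) {
    stopifnot(inherits(pl, "peaklist"))
    ann <- annotate_peaks(pl, targets, tol_ppm)
    if (normalize) {
      pl <- normalize_to_saturated_tg(pl, ann)
      ann$intensity <- pl$peaks$intensity
    }
    ann <- flag_type2_interference(ann, pl, tol_ppm = tol_ppm)
    list(age_days = pl$meta$age_days, replicate = pl$meta$replicate,
         annotation = ann)
  })
  structure(list(samples = samples), class = "fp_timecourse_annotated")
}

# mean/sd/n aggregation of one marker value per sample into a per-age series
.aggregate_marker <- function(df, marker_name) {
  ages <- sort(unique(df$age_days))
  out <- data.frame(
    marker = marker_name, age_days = ages,
    mean = vapply(ages, function(a) mean(df$value[df$age_days == a],
                                         na.rm = TRUE), numeric(1)),
    sd = vapply(ages, function(a) {
      v <- df$value[df$age_days == a]
      if (sum(!is.na(v)) >= 2) stats::sd(v, na.rm = TRUE) else NA_real_
    }, numeric(1)),
    n = vapply(ages, function(a) sum(df$age_days == a & !is.na(df$value)),
               integer(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("marker_series", "data.frame")
  out
}

.samples_of <- function(tc) {
  stopifnot(inherits(tc, "fp_timecourse_annotated"))
  tc$samples
}

# intensity of the best Na-adduct match for a given (substrate, tag, c, DBE)
.series_intensity <- function(ann, substrate, tag, species_c, dbe_value,
                              adduct = "[M+Na]+") {
  sel <- !is.na(ann$label) &
    vapply(strsplit(ann$substrate, "|", fixed = TRUE),
           function(s) substrate %in% s, logical(1)) &
    vapply(strsplit(ann$product_tag, "|", fixed = TRUE),
           function(s) tag %in% s, logical(1)) &
    ann$species_c == species_c & ann$DBE == dbe_value &
    ann$adduct == adduct
  sum(ann$intensity[sel])
}

#' TG epoxide ratio time series
#'
#' For each monitored carbon number the epoxide is normalized to the
#' corresponding saturated TG, e.g. TG(E) 44:1 / TG 44:0; ratios are
#' averaged over the monitored carbons per sample and then aggregated as
#' mean and one standard deviation over replicates per age. Because the
#' TG(A) aldehyde series shares the epoxide heteroatom class at lower mass,
#' the monitored carbon window defaults to the high-mass mode of the class
#' profile, determined by [split_bimodal_profile()] on the replicate-pooled
#' profile (all carbons when the profile is unimodal).
#'
#' @param tc An \code{fp_timecourse_annotated}.
#' @param residual_db Residual unsaturation of the epoxide (0 for TG(E)
#'   X:0, the epoxides of monounsaturated TGs).
#' @param carbon_numbers Acyl carbon numbers to monitor, or NULL for the
#'   automatic epoxide-mode window.
#' @return A \code{marker_series} data frame (age_days, mean, sd, n).
#' @export
epoxide_ratio_series <- function(tc, residual_db = 0L,
                                 carbon_numbers = NULL) {
  samples <- .samples_of(tc)
  dbe_e <- 4L + residual_db   # epoxide: 3 esters + ring + residual C=C
  if (is.null(carbon_numbers)) {
    pooled <- NULL
    for (s in samples) {
      pr <- class_intensity_profile(s$annotation, n_O = 7L,
                                    dbe_value = dbe_e)
      pooled <- if (is.null(pooled)) pr else {
        m <- merge(as.data.frame(pooled)[, c("c", "intensity")],
                   as.data.frame(pr)[, c("c", "intensity")],
                   by = "c", all = TRUE)
        m[is.na(m)] <- 0
        data.frame(c = m$c, intensity = m$intensity.x + m$intensity.y)
      }
    }
    if (is.null(pooled) || !nrow(pooled)) {
      warning("no epoxide-class signal found", call. = FALSE)
      return(.aggregate_marker(
        data.frame(age_days = numeric(0), value = numeric(0)),
        sprintf("TG(E) X:%d / TG X:0", residual_db)))
    }
    split <- split_bimodal_profile(pooled)
    cs <- if (split$n_modes == 2L) split$high$c else pooled$c
    carbon_numbers <- cs - 3L  # formula carbons -> acyl carbons
  }
  vals <- lapply(samples, function(s) {
    ann <- s$annotation
    ratios <- vapply(carbon_numbers, function(ci) {
      den <- .series_intensity(ann, "TG", "substrate", ci, 3L)
      if (!isTRUE(den > 0)) return(NA_real_)
      num <- .series_intensity(ann, "TG", "E", ci, dbe_e)
      num / den
    }, numeric(1))
    if (all(is.na(ratios)))
      warning("no saturated-TG denominator for monitored carbons in ",
              "sample aged ", s$age_days, " d", call. = FALSE)
    data.frame(age_days = s$age_days, value = mean(ratios, na.rm = TRUE))
  })
  df <- do.call(rbind, vals)
  df$value[is.nan(df$value)] <- NA_real_
  .aggregate_marker(df, sprintf("TG(E) X:%d / TG X:0", residual_db))
}

#' FA chain-length intensity profiles over aging
#'
#' Per-age mean (and sd) intensity of the disodiated fatty-acid ions over
#' chain length, for saturated (\code{db = 0}) or monounsaturated
#' (\code{db = 1}) FAs.
#'
#' @param tc An \code{fp_timecourse_annotated}.
#' @param db Number of double bonds of the profiled FAs (0 or 1).
#' @param chains Chain lengths to profile (default 8--20).
#' @return Data frame with columns \code{age_days}, \code{chain},
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
fa_profile_series <- function(tc, db = 0L, chains = 8:20) {
  samples <- .samples_of(tc)
  rows <- list()
  for (ch in chains) {
    per_sample <- data.frame(
      age_days = vapply(samples, `[[`, numeric(1), "age_days"),
      value = vapply(samples, function(s)
        .series_intensity(s$annotation, "FA", "substrate", ch, 1L + db,
                          adduct = "[M-H+2Na]+"), numeric(1)))
    agg <- .aggregate_marker(per_sample, sprintf("FA %d:%d", ch, db))
    agg$chain <- ch
    rows[[length(rows) + 1L]] <- agg
  }
  out <- do.call(rbind, rows)
  out[, c("age_days", "chain", "mean", "sd", "n", "marker")]
}

#' FA 10:0 aging marker
#'
#' Intensity of the disodiated FA 10:0 ion (m/z 217.117), the accumulating
#' omega-10 ozonolysis tail acid, normalized to an endogenous long-chain FA
#' that is constant over aging. FA 15:0 is the default normalizer (odd
#' chain, little contamination risk).
#'
#' @param tc An \code{fp_timecourse_annotated}.
#' @param norm_chain Chain length of the saturated normalizing FA
#'   (default 15).
#' @return A \code{marker_series} data frame.
#' @export
fa10_marker <- function(tc, norm_chain = 15L) {
  samples <- .samples_of(tc)
  vals <- lapply(samples, function(s) {
    num <- .series_intensity(s$annotation, "FA", "substrate", 10L, 1L,
                             adduct = "[M-H+2Na]+")
    den <- .series_intensity(s$annotation, "FA", "substrate", norm_chain,
                             1L, adduct = "[M-H+2Na]+")
    if (!isTRUE(den > 0))
      stop("normalizing FA ", norm_chain, ":0 absent in sample aged ",
           s$age_days, " d", call. = FALSE)
    data.frame(age_days = s$age_days, value = num / den)
  })
  .aggregate_marker(do.call(rbind, vals),
                    sprintf("FA 10:0 / FA %d:0", norm_chain))
}

#' Write a marker series as TSV
#'
#' @param x A \code{marker_series} (or the [fa_profile_series()] table).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_marker_series <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
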