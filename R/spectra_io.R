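# Centroid peak-list container, TSV round-trip, saturated-TG normalization
# and spectrum subtraction.

#' Create a centroid peak list
#'
#' Carrier for one sample's centroided spectrum: strictly increasing m/z
#' with non-negative intensities, plus sample metadata. Duplicate m/z rows
#' are merged by intensity sum with a warning.
#'
#' @param mz Numeric m/z values in (0, 10000).
#' @param intensity Non-negative intensities, same length.
#' @param sample_id Sample identifier.
#' @param age_days Fingerprint age in days (>= 0, or NA when unknown).
#' @param replicate Replicate number.
#' @param noise_level Optional additive noise level used for S/N.
#' @return An object of class \code{peaklist}: a list with elements
#'   \code{peaks} (data frame \code{mz}, \code{intensity}) and \code{meta}.
#' @export
peaklist <- function(mz, intensity, sample_id = "sample", age_days = NA_real_,
                     replicate = 1L, noise_level = NULL) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length", call. = FALSE)
  if (length(mz) && (any(!is.finite(mz)) || any(mz <= 0) || any(mz >= 1e4)))
    stop("mz values must lie in (0, 10000)", call. = FALSE)
  if (length(intensity) && (any(!is.finite(intensity)) || any(intensity < 0)))
    stop("intensities must be finite and >= 0", call. = FALSE)
  if (!is.na(age_days) && age_days < 0)
    stop("age_days must be >= 0", call. = FALSE)
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    warning("duplicate m/z values merged by intensity sum", call. = FALSE)
    intensity <- as.vector(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(
    peaks = data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity)),
    meta = list(sample_id = sample_id, age_days = as.numeric(age_days),
                replicate = as.integer(replicate),
                noise_level = if (is.null(noise_level)) NULL
                              else as.numeric(noise_level),
                normalized = FALSE)),
    class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> %s: %d peaks", x$meta$sample_id, nrow(x$peaks)))
  if (!is.na(x$meta$age_days))
    cat(sprintf(", age %g d, replicate %d", x$meta$age_days,
                x$meta$replicate))
  if (isTRUE(x$meta$normalized)) cat(" (normalized)")
  cat("\n")
  invisible(x)
}

#' Read a centroid peak list from TSV
#'
#' Native dialect: optional '#'-prefixed \code{key: value} metadata header
#' lines (\code{sample_id}, \code{age_days}, \code{replicate},
#' \code{noise_level}, \code{normalized}) followed by a tab-separated table
#' with header columns \code{mz} and \code{intensity}. m/z is sorted
#' ascending on read; duplicate m/z rows merge with a warning.
#'
#' @param path File path.
#' @return A \code{peaklist}.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  meta <- list(sample_id = "sample", age_days = NA_real_, replicate = 1L,
               noise_level = NULL, normalized = FALSE)
  for (ml in meta_lines) {
    kv <- regmatches(ml, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(kv) == 3)
      meta[[kv[2]]] <- utils::type.convert(kv[3], as.is = TRUE)
  }
  if (!length(body))
    stop("no table in ", path, call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("mz", "intensity") %in% header))
    stop("header must name columns mz and intensity", call. = FALSE)
  i_mz <- match("mz", header); i_int <- match("intensity", header)
  rows <- body[-1]
  rows <- rows[nzchar(rows)]
  mz <- numeric(length(rows)); intensity <- numeric(length(rows))
  for (i in seq_along(rows)) {
    f <- strsplit(rows[i], "\t", fixed = TRUE)[[1]]
    v_mz <- suppressWarnings(as.numeric(f[i_mz]))
    v_in <- suppressWarnings(as.numeric(f[i_int]))
    if (length(f) < max(i_mz, i_int) || is.na(v_mz) || is.na(v_in))
      stop("malformed row at line ", length(meta_lines) + 1L + i, " of ",
           path, call. = FALSE)
    mz[i] <- v_mz; intensity[i] <- v_in
  }
  pl <- peaklist(mz, intensity, sample_id = meta$sample_id,
                 age_days = as.numeric(meta$age_days),
                 replicate = meta$replicate,
                 noise_level = meta$noise_level)
  pl$meta$normalized <- isTRUE(as.logical(meta$normalized))
  pl
}

#' Write a centroid peak list as TSV
#'
#' Values are written with six decimals; a write/read cycle reproduces them
#' bit-exactly at that precision.
#'
#' @param x A \code{peaklist}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_peaklist <- function(x, path) {
  stopifnot(inherits(x, "peaklist"))
  con <- file(path, "w")
  on.exit(close(con))
  m <- x$meta
  cat(sprintf("# sample_id: %s\n", m$sample_id), file = con)
  if (!is.na(m$age_days))
    cat(sprintf("# age_days: %g\n", m$age_days), file = con)
  cat(sprintf("# replicate: %d\n", m$replicate), file = con)
  if (!is.null(m$noise_level))
    cat(sprintf("# noise_level: %.6g\n", m$noise_level), file = con)
  cat(sprintf("# normalized: %s\n", m$normalized), file = con)
  cat("mz\tintensity\n", file = con)
  if (nrow(x$peaks))
    writeLines(sprintf("%.6f\t%.6f", x$peaks$mz, x$peaks$intensity), con)
  invisible(path)
}

#' Normalize a spectrum to the summed saturated-TG signal
#'
#' Divides every intensity by the summed intensity of peaks annotated as
#' unreacted saturated TGs (substrate tag, DBE 3), so that spectra of
#' different deposition amounts become comparable; after normalization that
#' sum equals 1.
#'
#' @param x A \code{peaklist}.
#' @param annotations Annotation table for this peak list (see
#'   [annotate_peaks()]) identifying at least one saturated-TG substrate
#'   peak.
#' @return The normalized \code{peaklist} (idempotent: normalizing twice
#'   equals normalizing once).
#' @export
normalize_to_saturated_tg <- function(x, annotations) {
  stopifnot(inherits(x, "peaklist"), is.data.frame(annotations))
  sel <- !is.na(annotations$label) &
    annotations$product_tag == "substrate" &
    annotations$substrate == "TG" & annotations$DBE == 3L
  total <- sum(annotations$intensity[sel])
  if (!isTRUE(total > 0))
    stop("no saturated-TG substrate signal: normalization undefined",
         call. = FALSE)
  # annotations may carry intensities on a different (already normalized)
  # scale; recompute the factor on this peak list's own intensities
  tg_mz <- annotations$mz[sel]
  idx <- vapply(tg_mz, function(m) which.min(abs(x$peaks$mz - m)), integer(1))
  factor <- sum(x$peaks$intensity[unique(idx)])
  if (!isTRUE(factor > 0))
    stop("no saturated-TG substrate signal: normalization undefined",
         call. = FALSE)
  x$peaks$intensity <- x$peaks$intensity / factor
  if (!is.null(x$meta$noise_level))
    x$meta$noise_level <- x$meta$noise_level / factor
  x$meta$normalized <- TRUE
  x$meta$norm_factor <- factor
  x
}

#' Subtract a fresh spectrum from an aged spectrum
#'
#' Peaks of the two (normalized) spectra are paired by mutual nearest
#' neighbour within a ppm tolerance; unmatched peaks are kept with the
#' absent side at zero. The result is \code{delta = aged - fresh} per bin,
#' so signal lost on aging (e.g. squalene) appears negative.
#'
#' @param fresh,aged Normalized \code{peaklist}s (see
#'   [normalize_to_saturated_tg()]).
#' @param match_tol_ppm Pairing tolerance in ppm (default 2, the annotation
#'   tolerance).
#' @return Data frame of class \code{subtracted_spectrum} with columns
#'   \code{mz}, \code{delta}, \code{intensity_fresh}, \code{intensity_aged};
#'   the tolerance is recorded as attribute \code{match_tol_ppm}.
#' @export
subtract_spectra <- function(fresh, aged, match_tol_ppm = 2) {
  stopifnot(inherits(fresh, "peaklist"), inherits(aged, "peaklist"))
  if (!isTRUE(fresh$meta$normalized) || !isTRUE(aged$meta$normalized))
    stop("both spectra must be normalized before subtraction", call. = FALSE)
  f <- fresh$peaks; a <- aged$peaks
  nf <- nrow(f); na_ <- nrow(a)
  near <- function(from, to) {
    # index of nearest 'to' peak per 'from' peak, NA outside tolerance
    if (!nrow(to)) return(rep(NA_integer_, nrow(from)))
    i <- findInterval(from$mz, to$mz)
    cand_lo <- pmax(i, 1L); cand_hi <- pmin(i + 1L, nrow(to))
    d_lo <- abs(from$mz - to$mz[cand_lo])
    d_hi <- abs(from$mz - to$mz[cand_hi])
    best <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
    d <- abs(from$mz - to$mz[best])
    best[d > match_tol_ppm * 1e-6 * from$mz] <- NA_integer_
    best
  }
  a2f <- if (na_) near(a, f) else integer(0)
  f2a <- if (nf) near(f, a) else integer(0)
  mutual <- which(!is.na(a2f) & f2a[a2f] == seq_len(na_))
  rows <- list()
  if (length(mutual))
    rows[[1]] <- data.frame(
      mz = (a$mz[mutual] + f$mz[a2f[mutual]]) / 2,
      delta = a$intensity[mutual] - f$intensity[a2f[mutual]],
      intensity_fresh = f$intensity[a2f[mutual]],
      intensity_aged = a$intensity[mutual])
  lone_a <- setdiff(seq_len(na_), mutual)
  if (length(lone_a))
    rows[[length(rows) + 1L]] <- data.frame(
      mz = a$mz[lone_a], delta = a$intensity[lone_a],
      intensity_fresh = 0, intensity_aged = a$intensity[lone_a])
  lone_f <- setdiff(seq_len(nf), a2f[mutual])
  if (length(lone_f))
    rows[[length(rows) + 1L]] <- data.frame(
      mz = f$mz[lone_f], delta = -f$intensity[lone_f],
      intensity_fresh = f$intensity[lone_f], intensity_aged = 0)
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(mz = numeric(0), delta = numeric(0),
                         intensity_fresh = numeric(0),
                         intensity_aged = numeric(0))
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  attr(out, "match_tol_ppm") <- match_tol_ppm
  class(out) <- c("subtracted_spectrum", "data.frame")
  out
}

#' Write a subtracted spectrum as TSV
#'
#' @param x A \code{subtracted_spectrum}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_subtracted <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
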