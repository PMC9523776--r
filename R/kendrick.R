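# Kendrick mass / Kendrick mass defect computation and homologous-series
# grouping. The Kendrick base is the CH2 alkyl unit: m/z values are rescaled
# by 14/14.01565 so that CH2 homologs differ by exactly 14 and share a KMD.

.CH2_MASS <- 12 + 2 * 1.00782503207  # from the pinned atomic-mass table

.round_half_up <- function(x) floor(x + 0.5)

#' Kendrick mass
#'
#' \code{KM = m/z * 14 / 14.01565}, with the CH2 base mass taken from the
#' package atomic-mass table.
#'
#' @param mz Numeric vector of positive m/z values.
#' @return Kendrick masses.
#' @examples
#' kendrick_mass(14.01565006414) # exactly 14
#' @export
kendrick_mass <- function(mz) {
  if (any(!is.finite(mz)) || any(mz <= 0))
    stop("mz must be positive and finite", call. = FALSE)
  mz * (14 / .CH2_MASS)
}

#' Kendrick mass defect
#'
#' \code{KMD = round(KM) - KM}, rounding half up to the nearest integer.
#' With this sign convention sebum lipids fall in the positive 0.05--0.35
#' window. Members of a CH2 homologous series share a KMD; series differing
#' by one degree of unsaturation are offset by 0.0134.
#'
#' @inheritParams kendrick_mass
#' @return KMD values in (-0.5, 0.5].
#' @export
kendrick_mass_defect <- function(mz) {
  km <- kendrick_mass(mz)
  .round_half_up(km) - km
}

#' Group peaks into CH2 homologous series
#'
#' Two peaks belong to the same series when their KMDs agree within
#' \code{kmd_tol} and their m/z difference is an integer multiple of the
#' CH2 mass within a ppm tolerance; membership is closed transitively
#' (union-find over the sorted KMD axis).
#'
#' @param x Data frame with at least an \code{mz} column (a \code{kmd}
#'   column is computed if absent), or a \code{peaklist}.
#' @param kmd_tol KMD agreement tolerance (default 0.0005, about 2 ppm in
#'   KMD units at m/z 250).
#' @param ppm_tol ppm tolerance on the CH2 spacing (default 2, matching the
#'   annotation tolerance).
#' @return The input rows with \code{kmd}, \code{series} (integer id,
#'   numbered by ascending minimum m/z) and \code{series_size} columns,
#'   sorted by series then m/z.
#' @export
group_homologous_series <- function(x, kmd_tol = 5e-4, ppm_tol = 2) {
  if (inherits(x, "peaklist"))
    x <- x$peaks
  stopifnot(is.data.frame(x), "mz" %in% names(x))
  n <- nrow(x)
  if (n == 0L) {
    x$kmd <- numeric(0)
    x$series <- integer(0)
    x$series_size <- integer(0)
    return(x)
  }
  x$kmd <- kendrick_mass_defect(x$mz)
  ord <- order(x$kmd)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    b <- a + 1L
    while (b <= n && x$kmd[ord[b]] - x$kmd[i] <= kmd_tol) {
      j <- ord[b]
      d <- abs(x$mz[j] - x$mz[i])
      k <- round(d / .CH2_MASS)
      tol_da <- ppm_tol * 1e-6 * max(x$mz[i], x$mz[j])
      if (abs(d - k * .CH2_MASS) <= tol_da) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      b <- b + 1L
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # stable ids: series numbered by their minimum m/z
  min_mz <- tapply(x$mz, root, min)
  id_of_root <- stats::setNames(rank(min_mz, ties.method = "first"),
                                names(min_mz))
  x$series <- as.integer(id_of_root[as.character(root)])
  sizes <- table(x$series)
  x$series_size <- as.integer(sizes[as.character(x$series)])
  x <- x[order(x$series, x$mz), ]
  rownames(x) <- NULL
  x
}

#' Assemble KMD plot data
#'
#' Computes KM/KMD for a peak list, applies the signal-to-noise and plot
#' window filters, and returns an overlay-ready table. The defaults are the
#' lipid KMD window 0.05--0.35 and S/N > 30. S/N is taken as intensity over
#' the peak list's \code{noise_level} metadata when present, otherwise over
#' the median peak intensity.
#'
#' @param x A \code{peaklist} or data frame with \code{mz} and
#'   \code{intensity} columns.
#' @param kmd_range Length-2 increasing KMD window (default
#'   \code{c(0.05, 0.35)}).
#' @param mz_range Length-2 increasing m/z window (default
#'   \code{c(100, 1200)}).
#' @param sn_threshold Minimum S/N retained (default 30).
#' @return Data frame with columns \code{mz}, \code{km}, \code{kmd},
#'   \code{intensity}, \code{sn}, \code{sample_id}.
#' @export
kmd_plot_data <- function(x, kmd_range = c(0.05, 0.35),
                          mz_range = c(100, 1200), sn_threshold = 30) {
  sample_id <- "sample"
  noise <- NULL
  if (inherits(x, "peaklist")) {
    sample_id <- x$meta$sample_id
    noise <- x$meta$noise_level
    x <- x$peaks
  }
  stopifnot(is.data.frame(x), all(c("mz", "intensity") %in% names(x)))
  if (length(kmd_range) != 2 || kmd_range[1] >= kmd_range[2] ||
      length(mz_range) != 2 || mz_range[1] >= mz_range[2])
    stop("kmd_range and mz_range must be increasing windows", call. = FALSE)
  if (nrow(x) == 0L)
    return(data.frame(mz = numeric(0), km = numeric(0), kmd = numeric(0),
                      intensity = numeric(0), sn = numeric(0),
                      sample_id = character(0)))
  if (is.null(noise) || !is.finite(noise) || noise <= 0)
    noise <- stats::median(x$intensity[x$intensity > 0])
  out <- data.frame(mz = x$mz, km = kendrick_mass(x$mz),
                    kmd = kendrick_mass_defect(x$mz),
                    intensity = x$intensity, sn = x$intensity / noise,
                    sample_id = sample_id, stringsAsFactors = FALSE)
  out <- out[out$sn > sn_threshold &
               out$kmd >= kmd_range[1] & out$kmd <= kmd_range[2] &
               out$mz >= mz_range[1] & out$mz <= mz_range[2], ]
  rownames(out) <- NULL
  out
}

#' Plot KMD data
#'
#' Scatter (or bubble, intensity-scaled size) KMD plot of one or more
#' samples assembled with [kmd_plot_data()]. Requires ggplot2.
#'
#' @param data Output of [kmd_plot_data()] (rows of several samples may be
#'   concatenated for an overlay).
#' @param bubble Scale point size by intensity.
#' @return A ggplot object.
#' @export
plot_kmd <- function(data, bubble = FALSE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_kmd requires the ggplot2 package", call. = FALSE)
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$mz, y = .data$kmd, colour = .data$sample_id))
  p <- if (bubble)
    p + ggplot2::geom_point(ggplot2::aes(size = .data$intensity),
                            alpha = 0.6) +
      ggplot2::scale_size_area(max_size = 8)
  else
    p + ggplot2::geom_point(alpha = 0.6, size = 1)
  p + ggplot2::labs(x = "m/z", y = "Kendrick mass defect",
                    colour = "sample") +
    ggplot2::theme_bw()
}
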