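# Peak annotation against the in silico target list at +-2 ppm, Type-II
# isotopic interference flagging, and heteroatom-class intensity profiles.

.C13_DELTA <- 13.0033548378 - 12

#' Annotate peaks against a target list
#'
#' Each peak is assigned to the minimum-|ppm| target within the tolerance
#' (binary search over the sorted target m/z), or left unassigned. Ties at
#' equal |ppm| prefer Na over K adducts, substrate over product tags, then
#' lower oxygen count -- potassium adducts are treated as minor species that
#' must never outcompete a sodium assignment.
#'
#' @param x A \code{peaklist} or data frame with \code{mz} and
#'   \code{intensity}.
#' @param targets A \code{target_list} (see [build_target_list()]).
#' @param tol_ppm Mass tolerance in ppm (default 2).
#' @return Data frame of class \code{annotation}, one row per peak, with
#'   the peak columns plus target columns (\code{label}, \code{formula},
#'   \code{target_mz}, \code{ppm_error}, \code{c}, \code{species_c},
#'   \code{DBE}, \code{O}, \code{Na}, \code{K}, \code{product_tag},
#'   \code{substrate}, \code{adduct}, \code{class_id}), interference flags
#'   and an \code{alternates} column (other in-tolerance targets, sorted by
#'   |ppm|, semicolon-joined). Unassigned peaks carry NA target fields.
#' @export
annotate_peaks <- function(x, targets, tol_ppm = 2) {
  meta <- list(sample_id = "sample", age_days = NA_real_, replicate = 1L)
  if (inherits(x, "peaklist")) {
    meta <- x$meta
    x <- x$peaks
  }
  stopifnot(is.data.frame(x), all(c("mz", "intensity") %in% names(x)))
  stopifnot(is.data.frame(targets))
  tgt <- as.data.frame(targets)
  if (is.unsorted(tgt$mz)) tgt <- tgt[order(tgt$mz), ]
  n <- nrow(x)
  tcols <- c("label", "formula", "target_mz", "ppm_error", "c", "species_c",
             "DBE", "O", "Na", "K", "product_tag", "substrate", "adduct",
             "class_id")
  out <- data.frame(mz = x$mz, intensity = x$intensity,
                    label = rep(NA_character_, n),
                    formula = rep(NA_character_, n),
                    target_mz = rep(NA_real_, n),
                    ppm_error = rep(NA_real_, n),
                    c = rep(NA_integer_, n), species_c = rep(NA_integer_, n),
                    DBE = rep(NA_integer_, n), O = rep(NA_integer_, n),
                    Na = rep(NA_integer_, n), K = rep(NA_integer_, n),
                    product_tag = rep(NA_character_, n),
                    substrate = rep(NA_character_, n),
                    adduct = rep(NA_character_, n),
                    class_id = rep(NA_character_, n),
                    type2_isotope_risk = rep(FALSE, n),
                    multi_class_ambiguous = rep(FALSE, n),
                    potassium_adduct = rep(FALSE, n),
                    alternates = rep("", n), stringsAsFactors = FALSE)
  if (n == 0L || nrow(tgt) == 0L) {
    attr(out, "known_classes") <- unique(tgt$class_id)
    attr(out, "tol_ppm") <- tol_ppm
    attr(out, "sample_meta") <- meta
    class(out) <- c("annotation", "data.frame")
    return(out)
  }
  tag_is_product <- tgt$product_tag != "substrate" &
    !grepl("(^|\\|)substrate(\\||$)", tgt$product_tag)
  lo_all <- findInterval(x$mz * (1 - tol_ppm * 1e-6), tgt$mz) + 1L
  hi_all <- findInterval(x$mz * (1 + tol_ppm * 1e-6), tgt$mz)
  for (i in seq_len(n)) {
    lo <- lo_all[i]; hi <- hi_all[i]
    if (lo > hi) next
    cand <- lo:hi
    ppm <- (x$mz[i] - tgt$mz[cand]) / tgt$mz[cand] * 1e6
    keep <- abs(ppm) <= tol_ppm
    cand <- cand[keep]; ppm <- ppm[keep]
    if (!length(cand)) next
    ord <- order(abs(ppm), tgt$K[cand], tag_is_product[cand], tgt$O[cand])
    cand <- cand[ord]; ppm <- ppm[ord]
    b <- cand[1]
    out$label[i] <- tgt$label[b]
    out$formula[i] <- tgt$formula[b]
    out$target_mz[i] <- tgt$mz[b]
    out$ppm_error[i] <- ppm[1]
    out$c[i] <- tgt$c[b]
    out$species_c[i] <- tgt$species_c[b]
    out$DBE[i] <- tgt$DBE[b]
    out$O[i] <- tgt$O[b]
    out$Na[i] <- tgt$Na[b]
    out$K[i] <- tgt$K[b]
    out$product_tag[i] <- tgt$product_tag[b]
    out$substrate[i] <- tgt$substrate[b]
    out$adduct[i] <- tgt$adduct[b]
    out$class_id[i] <- tgt$class_id[b]
    out$potassium_adduct[i] <- tgt$K[b] > 0L
    if (length(cand) > 1L) {
      alt <- cand[-1]
      out$multi_class_ambiguous[i] <-
        any(tgt$class_id[alt] != tgt$class_id[b])
      out$alternates[i] <- paste(sprintf("%s@%.2fppm", tgt$label[alt],
                                         ppm[-1]), collapse = ";")
    }
  }
  attr(out, "known_classes") <- unique(tgt$class_id)
  attr(out, "tol_ppm") <- tol_ppm
  attr(out, "sample_meta") <- meta
  class(out) <- c("annotation", "data.frame")
  out
}

#' Flag Type-II isotopic interference
#'
#' A lipid with one more double bond sits 2.0157 Da (2 H) below its
#' homolog; its second \eqn{^{13}}C isotopologue therefore lands only
#' 0.0089 Da below the heavier homolog's monoisotopic peak. An assigned
#' peak is flagged when a peak exists at \code{mz - 2 * (m13C - m12C)}
#' within tolerance whose expected M+2 isotopologue contribution (binomial
#' \eqn{^{13}}C abundance at that peak's carbon count) reaches
#' \code{min_fraction} of the assigned peak's intensity.
#'
#' @param annotated An \code{annotation} table.
#' @param x The \code{peaklist} (or peak data frame) the annotation was
#'   computed from.
#' @param min_fraction Flagging threshold as a fraction of the assigned
#'   peak intensity (default 0.2).
#' @param tol_ppm Tolerance for locating the lighter peak (default 2).
#' @param p13 Isotopic abundance of \eqn{^{13}}C (default 0.0107).
#' @return The annotation with \code{type2_isotope_risk} updated.
#' @export
flag_type2_interference <- function(annotated, x, min_fraction = 0.2,
                                    tol_ppm = 2, p13 = 0.0107) {
  stopifnot(inherits(annotated, "annotation"))
  if (inherits(x, "peaklist")) x <- x$peaks
  gap <- 2 * .C13_DELTA
  assigned <- which(!is.na(annotated$label))
  for (i in assigned) {
    m_lo <- annotated$mz[i] - gap
    j <- which.min(abs(x$mz - m_lo))
    if (!length(j) || abs(x$mz[j] - m_lo) > tol_ppm * 1e-6 * m_lo) next
    # carbon count of the interfering (lighter) species: its annotation if
    # that peak was assigned, else the alkyl-chain estimate m/z / 14
    k <- which(abs(annotated$mz - x$mz[j]) < 1e-9)
    nc <- if (length(k) && !is.na(annotated$c[k[1]])) annotated$c[k[1]]
          else round(x$mz[j] / 14)
    m2_ratio <- choose(nc, 2) * p13^2 / (1 - p13)^2
    if (x$intensity[j] * m2_ratio >= min_fraction * annotated$intensity[i])
      annotated$type2_isotope_risk[i] <- TRUE
  }
  annotated
}

#' Intensity profile of one heteroatom class
#'
#' Collects the annotated intensities of one heteroatom class (fixed O, Na,
#' K and DBE, i.e. one horizontal KMD line) as a series over the carbon
#' number c, zero-filled over the observed carbon range so that valleys
#' between modes are explicit.
#'
#' @param annotated An \code{annotation} table.
#' @param n_O,n_Na,n_K Heteroatom counts of the class ion.
#' @param dbe_value Class DBE (neutral-parent convention).
#' @return Data frame of class \code{class_profile} with columns \code{c},
#'   \code{mz} (mean observed m/z, NA where zero-filled) and
#'   \code{intensity}. An unknown class (absent from the target list used
#'   for annotation) is an error; a known class with no assigned peaks
#'   yields an empty profile.
#' @export
class_intensity_profile <- function(annotated, n_O, dbe_value, n_Na = 1L,
                                    n_K = 0L) {
  stopifnot(inherits(annotated, "annotation"))
  cid <- sprintf("O%dNa%dK%d/DBE%d", n_O, n_Na, n_K, dbe_value)
  known <- attr(annotated, "known_classes")
  if (!is.null(known) && !cid %in% known)
    stop("unknown heteroatom class: ", cid, call. = FALSE)
  sel <- !is.na(annotated$label) & annotated$class_id == cid
  if (!any(sel)) {
    out <- data.frame(c = integer(0), mz = numeric(0), intensity = numeric(0))
  } else {
    sub <- annotated[sel, ]
    cs <- sort(unique(sub$c))
    grid <- seq(min(cs), max(cs))
    intensity <- vapply(grid, function(ci) sum(sub$intensity[sub$c == ci]),
                        numeric(1))
    mzv <- vapply(grid, function(ci) {
      v <- sub$mz[sub$c == ci]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    out <- data.frame(c = grid, mz = mzv, intensity = intensity)
  }
  attr(out, "class_id") <- cid
  attr(out, "sample_meta") <- attr(annotated, "sample_meta")
  class(out) <- c("class_profile", "data.frame")
  out
}

#' Split a bimodal class profile into its two modes
#'
#' The A and E products of one substrate share a heteroatom class but sit
#' in different mass regions (chain-cleaved aldehydes low, intact epoxides
#' at the substrate mass range), producing a bimodal intensity profile
#' along the carbon number. The profile is smoothed with a 3-point moving
#' average; if two local maxima exist, it is split at the interior minimum
#' between the two largest. Mode labels "A" (low) and "E" (high) are
#' attached when the mode means differ by at least 8 carbons, matching the
#' roughly 10-carbon offset of omega-10 cleavage.
#'
#' @param profile A \code{class_profile} (or data frame with \code{c} and
#'   \code{intensity}), at least 5 members for a split to be attempted.
#' @param min_rel_height Minimum height of the secondary mode relative to
#'   the main one for the profile to count as bimodal (default 0.05);
#'   smaller bumps are treated as baseline structure.
#' @return List with \code{n_modes}, \code{valley_c} (NA when unimodal),
#'   \code{low} and \code{high} sub-profiles and \code{mode_labels}.
#' @export
split_bimodal_profile <- function(profile, min_rel_height = 0.05) {
  stopifnot(is.data.frame(profile), all(c("c", "intensity") %in%
                                          names(profile)))
  y <- profile$intensity
  n <- length(y)
  single <- list(n_modes = 1L, valley_c = NA_integer_, low = profile,
                 high = NULL, mode_labels = NULL)
  if (n < 5L) return(single)
  ypad <- c(y[1], y, y[n])
  sm <- (ypad[1:n] + ypad[2:(n + 1)] + ypad[3:(n + 2)]) / 3
  is_max <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) sm[i - 1] else -Inf
    r <- if (i < n) sm[i + 1] else -Inf
    sm[i] > 0 && sm[i] >= l && sm[i] > r
  }, logical(1))
  peaks <- which(is_max)
  peaks <- peaks[sm[peaks] >= min_rel_height * max(sm[peaks])]
  if (length(peaks) < 2L) return(single)
  top2 <- peaks[order(sm[peaks], decreasing = TRUE)][1:2]
  top2 <- sort(top2)
  interior <- (top2[1] + 1L):(top2[2] - 1L)
  if (!length(interior) || top2[2] - top2[1] < 2L) return(single)
  valley <- interior[which.min(sm[interior])]
  low <- profile[seq_len(valley), ]
  high <- profile[(valley + 1L):n, ]
  wmean <- function(p) if (sum(p$intensity) > 0)
    sum(p$c * p$intensity) / sum(p$intensity) else mean(p$c)
  labels <- if (wmean(high) - wmean(low) >= 8)
    c(low = "A", high = "E") else NULL
  list(n_modes = 2L, valley_c = profile$c[valley], low = low, high = high,
       mode_labels = labels)
}

#' Write an annotation table as TSV
#'
#' @param annotated An \code{annotation} table.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(annotated, path) {
  utils::write.table(as.data.frame(annotated), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
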