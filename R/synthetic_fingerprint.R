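# Ground-truthed synthetic fingerprint spectra: a TG-dominated sebum
# profile, deterministic expectation-based oxidation kinetics (ozonolysis +
# capped monolayer epoxidation), and a forward model of the MALDI
# measurement (adduction, in-source ozonide fragmentation, 13C
# isotopologues, ppm jitter, noise).

#' Simulator kinetics and measurement parameters
#'
#' @param k_ozonolysis First-order ambient ozonolysis rate per C=C per day.
#'   The value sets relative trends only; no absolute rate is implied.
#' @param epoxide_cap Fraction of each unsaturated species converted to the
#'   epoxide in the rapid initial (top-monolayer) epoxidation, after which
#'   epoxidation stops.
#' @param branching Detection branching of an accumulated secondary
#'   ozonide: named probabilities \code{soz} (intact secondary ozonide
#'   ion), \code{A} (in-source head aldehyde) and \code{bc} (in-source
#'   Criegee products: head B/C ion plus the complementary tail acid).
#'   Must sum to 1. These are free parameters of the simulator.
#' @param acid_disodiated_fraction Fraction of head Criegee signal detected
#'   as the disodiated acid (C) rather than the monosodiated B/C ion.
#' @param c13_abundance Isotopic abundance of 13C.
#' @param mz_jitter_ppm Gaussian m/z jitter standard deviation in ppm
#'   (clipped at 2 ppm, the annotation tolerance).
#' @param noise_peaks Number of additive random noise peaks per spectrum.
#' @param noise_level Scale of the additive noise (also stored as the peak
#'   list's S/N noise level).
#' @param k_adduct_fraction Relative intensity of the one-K-substituted
#'   adduct twin of every Na-bearing ion.
#' @param intensity_noise_sdlog Log-sd of the multiplicative per-peak
#'   intensity noise (MALDI shot-to-shot variability).
#' @param deposition_sdlog Log-sd of the per-replicate deposition factor.
#' @return An object of class \code{aging_params}.
#' @export
aging_params <- function(k_ozonolysis = 0.3, epoxide_cap = 0.05,
                         branching = c(soz = 0.60, A = 0.25, bc = 0.15),
                         acid_disodiated_fraction = 0.5,
                         c13_abundance = 0.0107, mz_jitter_ppm = 0.5,
                         noise_peaks = 300L, noise_level = 0.002,
                         k_adduct_fraction = 0.05,
                         intensity_noise_sdlog = 0.1,
                         deposition_sdlog = 0.25) {
  if (k_ozonolysis < 0) stop("k_ozonolysis must be >= 0", call. = FALSE)
  if (epoxide_cap < 0 || epoxide_cap > 1)
    stop("epoxide_cap must be in [0, 1]", call. = FALSE)
  if (!all(c("soz", "A", "bc") %in% names(branching)) ||
      abs(sum(branching) - 1) > 1e-9 || any(branching < 0))
    stop("branching must be probabilities soz/A/bc summing to 1",
         call. = FALSE)
  if (mz_jitter_ppm < 0 || mz_jitter_ppm > 2)
    stop("mz_jitter_ppm must be in [0, 2]", call. = FALSE)
  structure(list(k_ozonolysis = k_ozonolysis, epoxide_cap = epoxide_cap,
                 branching = branching[c("soz", "A", "bc")],
                 acid_disodiated_fraction = acid_disodiated_fraction,
                 c13_abundance = c13_abundance,
                 mz_jitter_ppm = mz_jitter_ppm,
                 noise_peaks = as.integer(noise_peaks),
                 noise_level = noise_level,
                 k_adduct_fraction = k_adduct_fraction,
                 intensity_noise_sdlog = intensity_noise_sdlog,
                 deposition_sdlog = deposition_sdlog),
            class = "aging_params")
}

#' Sparse-ozone (climate chamber) parameter preset
#'
#' Mimics aging with about five-fold less ozone but sustained singlet
#' oxygen: ozonolysis slowed five-fold, the epoxide monolayer cap doubled.
#' Under this preset the summed TG epoxide signal exceeds the TG Criegee
#' (C) signal, the reverse of the ambient preset.
#'
#' @param base Parameters to modify (default [aging_params()]).
#' @return An \code{aging_params} object.
#' @export
sparse_ozone_params <- function(base = aging_params()) {
  base$k_ozonolysis <- base$k_ozonolysis / 5
  base$epoxide_cap <- min(1, base$epoxide_cap * 2)
  base
}

#' Default sebum lipid profile
#'
#' TG-dominated composition with WE, DG, endogenous long-chain FAs and
#' squalene; double-bond omega positions biased to omega-10 (weight 0.65,
#' omega-8/9/11 sharing the remainder), reflecting the prevalence of
#' omega-10 acyl chains (sapienic-acid-type) in sebum. Medium-chain FAs
#' (including FA 10:0) start at zero abundance: they are rare in nature and
#' arise only as oxidation fragments.
#'
#' @param seed Integer seed for the reproducible per-species abundance
#'   jitter.
#' @return An object of class \code{sebum_profile}: a list with
#'   \code{species} (data frame \code{class}, \code{species_c}, \code{db},
#'   \code{abundance}) and \code{omega_weights}.
#' @export
default_sebum_profile <- function(seed = 1L) {
  set.seed(seed)
  gauss <- function(c, mu, sd) exp(-(c - mu)^2 / (2 * sd^2))
  rows <- list()
  add <- function(class, cs, dbs, db_w, total, mu, sd) {
    g <- expand.grid(species_c = cs, db = dbs)
    w <- gauss(g$species_c, mu, sd) * db_w[g$db + 1L]
    g$abundance <- total * w / sum(w)
    g$class <- class
    rows[[length(rows) + 1L]] <<- g[, c("class", "species_c", "db",
                                        "abundance")]
  }
  add("TG", 42:56, 0:3, c(0.30, 0.40, 0.20, 0.10), total = 100, mu = 48,
      sd = 3)
  add("WE", 30:44, 0:2, c(0.50, 0.35, 0.15), total = 15, mu = 37, sd = 4)
  add("DG", 28:36, 0:2, c(0.40, 0.40, 0.20), total = 8, mu = 32, sd = 3)
  fa <- data.frame(
    class = "FA",
    species_c = c(13:18, 14:18),
    db = c(rep(0L, 6), rep(1L, 5)),
    abundance = c(0.8, 1.5, 1.0, 3.0, 0.7, 1.2,   # endogenous saturated
                  0.4, 0.3, 2.5, 0.3, 1.5))       # 16:1 = sapienic acid
  rows[[length(rows) + 1L]] <- fa
  rows[[length(rows) + 1L]] <- data.frame(class = "SQ", species_c = 30L,
                                          db = 6L, abundance = 20)
  species <- do.call(rbind, rows)
  species$abundance <- species$abundance *
    stats::rlnorm(nrow(species), 0, 0.05)
  rownames(species) <- NULL
  structure(list(species = species,
                 omega_weights = c(`8` = 0.35 / 3, `9` = 0.35 / 3,
                                   `10` = 0.65, `11` = 0.35 / 3)),
            class = "sebum_profile")
}

#' Evolve a sebum profile under ambient oxidation
#'
#' Deterministic expectation kinetics. At day 0+ a monolayer fraction
#' (\code{epoxide_cap}) of each unsaturated species converts to its epoxide
#' and epoxidation then stops. Each remaining C=C reacts with ozone
#' first-order at rate \code{k_ozonolysis}; species with one reacted bond
#' accumulate in a (relatively stable) secondary-ozonide pool, species with
#' two or more in a double-ozonide pool (DG/WE/TG only). Epoxides with
#' residual unsaturation continue to ozonolyze. Cleavage omega positions
#' follow the profile's omega-weight distribution in expectation. Reacted
#' squalene is treated as lost to volatile products.
#'
#' @param profile A \code{sebum_profile}.
#' @param days Age in days (>= 0).
#' @param params An \code{aging_params}.
#' @return Data frame of pools with columns \code{class}, \code{species_c},
#'   \code{db} (original), \code{pool} (one of substrate, E, OZ1, OZ2,
#'   E_OZ, LOST, OZBOND), \code{residual_db}, \code{omega}, \code{omega2},
#'   \code{abundance}. OZBOND rows count expected cleaved bonds per omega
#'   (the source of in-source tail products) and are excluded from species
#'   mass balance.
#' @export
age_profile <- function(profile, days, params = aging_params()) {
  stopifnot(inherits(profile, "sebum_profile"),
            inherits(params, "aging_params"))
  if (days < 0) stop("days must be >= 0", call. = FALSE)
  w <- profile$omega_weights
  omegas <- as.integer(names(w))
  q <- 1 - exp(-params$k_ozonolysis * days)
  cap <- params$epoxide_cap
  rows <- list()
  emit <- function(class, sc, db, pool, residual, abundance, omega = NA,
                   omega2 = NA) {
    if (abundance <= 0) return(invisible())
    rows[[length(rows) + 1L]] <<- data.frame(
      class = class, species_c = sc, db = db, pool = pool,
      residual_db = residual, omega = omega, omega2 = omega2,
      abundance = abundance, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(profile$species))) {
    s <- profile$species[i, ]
    a0 <- s$abundance; d <- s$db
    if (d == 0L) {
      emit(s$class, s$species_c, d, "substrate", 0L, a0)
      next
    }
    e0 <- cap * a0
    s0 <- a0 - e0
    p0 <- (1 - q)^d
    emit(s$class, s$species_c, d, "substrate", d, s0 * p0)
    # epoxide pool: stable when fully saturated, ozonolyzes otherwise
    r <- d - 1L
    e_left <- if (r == 0L) e0 else e0 * (1 - q)^r
    emit(s$class, s$species_c, d, "E", r, e_left)
    e_oz <- e0 - e_left
    if (s$class == "SQ") {
      # ozonolysis products of squalene are volatile: signal simply lost
      emit(s$class, s$species_c, d, "LOST", NA_integer_,
           s0 * (1 - p0) + e_oz)
      next
    }
    if (e_oz > 0)
      for (k in seq_along(omegas))
        emit(s$class, s$species_c, d, "E_OZ", r - 1L, e_oz * w[k],
             omega = omegas[k])
    if (d == 1L || s$class == "FA") {
      oz1 <- s0 * (1 - p0)
      oz2 <- 0
    } else {
      p1 <- d * q * (1 - q)^(d - 1)
      oz1 <- s0 * p1
      oz2 <- s0 * (1 - p0 - p1)
    }
    if (oz1 > 0)
      for (k in seq_along(omegas))
        emit(s$class, s$species_c, d, "OZ1", d - 1L, oz1 * w[k],
             omega = omegas[k])
    if (oz2 > 0)
      for (k1 in seq_along(omegas)) for (k2 in seq_along(omegas))
        emit(s$class, s$species_c, d, "OZ2", d - 2L,
             oz2 * w[k1] * w[k2], omega = omegas[k1], omega2 = omegas[k2])
    # expected cleaved-bond count feeding in-source tail products
    cleaved <- s0 * d * q + e0 * r * q
    if (cleaved > 0)
      for (k in seq_along(omegas))
        emit(s$class, s$species_c, d, "OZBOND", NA_integer_,
             cleaved * w[k], omega = omegas[k])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "days") <- days
  attr(out, "params") <- params
  out
}

# Neutral composition helpers for rendered product ions. sc/db are the
# original species numbers; omega the cleavage position.
.pool_ion_rows <- function(p, params) {
  br <- params$branching
  acid_f <- params$acid_disodiated_fraction
  rows <- list()
  push <- function(comp_neutral, label, tag, weight, disodiated = FALSE) {
    if (weight <= 0) return(invisible())
    na2 <- elemental_composition(Na = 2)
    na1 <- elemental_composition(Na = 1)
    h1 <- elemental_composition(H = 1)
    ion <- if (disodiated) comp_neutral - h1 + na2 else comp_neutral + na1
    rows[[length(rows) + 1L]] <<- data.frame(
      formula = format_formula(ion), mz = ion_mz(ion), label = label,
      product_tag = tag, substrate = p$class, species_c = p$species_c,
      residual_db = p$residual_db, omega = p$omega,
      adduct = if (disodiated) "[M-H+2Na]+" else "[M+Na]+",
      intensity = weight, stringsAsFactors = FALSE)
  }
  sc <- p$species_c; db <- p$db; rd <- p$residual_db
  h2 <- elemental_composition(H = 2)
  o1 <- elemental_composition(O = 1)
  lab <- function(tag, c_, r_) {
    tl <- if (tag == "substrate") "" else paste0("(", tag, ")")
    sprintf("%s%s %d:%d", p$class, tl, c_, r_)
  }
  switch(p$pool,
    substrate = {
      comp <- compose_lipid(p$class, sc, db)
      push(comp, lab("substrate", sc, db), "substrate", p$abundance,
           disodiated = p$class == "FA")
    },
    E = {
      comp <- compose_lipid(p$class, sc, rd + 1L) + o1
      push(comp, lab("E", sc, rd), "E", p$abundance,
           disodiated = p$class == "FA")
    },
    OZ1 = {
      w <- p$omega
      soz <- compose_lipid(p$class, sc, db) +
        elemental_composition(O = 3)
      push(soz, lab("SOZ", sc, rd), "SOZ", p$abundance * br[["soz"]])
      head_c <- sc - w
      if (head_c >= 2) {
        headA <- compose_lipid(p$class, head_c, rd) - h2 + o1
        push(headA, lab("A", head_c, rd), "A", p$abundance * br[["A"]],
             disodiated = p$class == "FA")
        headBC <- headA + o1
        wt_bc <- p$abundance * br[["bc"]]
        if (p$class == "FA") {
          push(headBC, lab("B/C", head_c, rd), "B/C", wt_bc,
               disodiated = TRUE)
        } else {
          push(headBC, lab("B/C", head_c, rd), "B/C", wt_bc * (1 - acid_f))
          push(headBC, lab("C", head_c, rd), "C", wt_bc * acid_f,
               disodiated = TRUE)
        }
      }
    },
    OZ2 = {
      head_c <- sc - p$omega - p$omega2
      if (head_c >= 2) {
        comp <- compose_lipid(p$class, head_c, rd) - h2 - h2 + o1 + o1
        push(comp, lab("AA", head_c, rd), "AA", p$abundance * br[["A"]])
      }
    },
    E_OZ = {
      head_c <- sc - p$omega
      if (head_c >= 2 && rd >= 0) {
        comp <- compose_lipid(p$class, head_c, rd) - h2 + o1 + o1
        push(comp, lab("E+A", head_c, rd), "E+A",
             p$abundance * br[["A"]])
      }
    },
    OZBOND = {
      w <- p$omega
      tail_acid <- elemental_composition(C = w, H = 2 * w, O = 2)
      rows_before <- length(rows)
      push(tail_acid, sprintf("FA %d:0", w), "substrate",
           p$abundance * br[["bc"]], disodiated = TRUE)
      # tag the tail acid as what it is for the ground truth
      if (length(rows) > rows_before)
        rows[[length(rows)]]$product_tag <- "tail_C"
    },
    LOST = NULL
  )
  rows
}

#' Render a synthetic MALDI spectrum from oxidation pools
#'
#' Forward model of the measurement: every pool is converted to its
#' sodiated (carboxylic acids: disodiated) ion at the theoretical m/z;
#' accumulated ozonides emit the intact secondary-ozonide ion, the head
#' aldehyde and the Criegee head/tail products according to the in-source
#' branching; isobaric contributions are summed per ion formula; M+1 and
#' M+2 \eqn{^{13}}C isotopologues are added at binomial abundance; every
#' Na-bearing ion gets a small one-K-substituted twin; Gaussian ppm jitter
#' (one draw per distinct ion formula, clipped at 2 ppm) and additive
#' uniform-m/z noise peaks complete the spectrum.
#'
#' @param pools Output of [age_profile()].
#' @param params An \code{aging_params}.
#' @param seed Integer seed; identical seeds give identical spectra.
#' @param sample_id Sample identifier for the peak list.
#' @param deposition_factor Multiplier on all signal (not noise)
#'   intensities, emulating deposition amount.
#' @return List with \code{peaks} (a \code{peaklist}) and \code{truth}
#'   (data frame mapping every signal peak to its source: formula, labels,
#'   tags, isotopologue, adduct).
#' @export
render_spectrum <- function(pools, params = aging_params(), seed = 1L,
                            sample_id = "synthetic",
                            deposition_factor = 1) {
  stopifnot(inherits(params, "aging_params"))
  set.seed(seed)
  days <- attr(pools, "days")
  ions <- list()
  for (i in seq_len(nrow(pools)))
    ions <- c(ions, .pool_ion_rows(pools[i, ], params))
  ions <- do.call(rbind, ions)
  if (is.null(ions) || !nrow(ions))
    stop("no ions to render", call. = FALSE)
  # merge isobaric sources: one centroid per distinct ion formula
  agg <- function(x, f) as.vector(tapply(x, f, function(v)
    paste(unique(v), collapse = "|")))
  key <- ions$formula
  o <- order(key, ions$mz)
  ions <- ions[o, ]
  key <- ions$formula
  first <- !duplicated(key)
  base <- ions[first, c("formula", "mz", "label", "product_tag",
                        "substrate", "adduct")]
  base$intensity <- as.vector(tapply(ions$intensity, key, sum)[base$formula])
  base$label <- agg(ions$label, key)[match(base$formula, sort(unique(key)))]
  base$product_tag <- agg(ions$product_tag, key)[
    match(base$formula, sort(unique(key)))]

  # one-K-substituted adduct twins
  na1 <- elemental_composition(Na = 1)
  k1 <- elemental_composition(K = 1)
  kt <- base[base$intensity > 0, ]
  kt <- kt[grepl("Na", kt$formula), ]
  if (nrow(kt)) {
    comps <- lapply(kt$formula, parse_formula)
    kt$formula <- vapply(comps, function(cc)
      format_formula(cc - na1 + k1), character(1))
    kt$mz <- vapply(comps, function(cc) ion_mz(cc - na1 + k1), numeric(1))
    kt$adduct <- sub("2Na", "Na+K", sub("\\+Na\\]", "+K]", kt$adduct))
    kt$intensity <- kt$intensity * params$k_adduct_fraction
    base <- rbind(base, kt)
  }

  # 13C isotopologues at binomial abundance (M, M+1, M+2)
  comps <- lapply(base$formula, parse_formula)
  ncarb <- vapply(comps, function(cc) cc[["C"]], integer(1))
  p13 <- params$c13_abundance
  iso_rows <- list()
  for (iso in 0:2) {
    b <- base
    b$isotopologue <- iso
    b$intensity <- base$intensity * stats::dbinom(iso, ncarb, p13)
    if (iso > 0) {
      b$formula <- vapply(comps, function(cc)
        format_formula(cc - elemental_composition(C = iso) +
                         elemental_composition(C13 = iso)), character(1))
      b$mz <- b$mz + iso * .C13_DELTA
    }
    iso_rows[[iso + 1L]] <- b
  }
  sig <- do.call(rbind, iso_rows)
  sig <- sig[sig$intensity > 1e-9, ]

  # ppm jitter: one draw per distinct observed formula
  jit <- stats::rnorm(nrow(sig), 0, params$mz_jitter_ppm)
  jit <- pmax(pmin(jit, 2), -2)
  sig$mz_observed <- sig$mz * (1 + jit * 1e-6)
  sig$intensity <- sig$intensity * deposition_factor *
    stats::rlnorm(nrow(sig), 0, params$intensity_noise_sdlog)
  sig$source <- "signal"

  nn <- params$noise_peaks
  noise <- data.frame(
    formula = rep(NA_character_, nn), mz = rep(NA_real_, nn),
    label = rep(NA_character_, nn), product_tag = rep(NA_character_, nn),
    substrate = rep(NA_character_, nn), adduct = rep(NA_character_, nn),
    intensity = stats::rexp(nn, 1 / params$noise_level),
    isotopologue = rep(NA_integer_, nn),
    mz_observed = stats::runif(nn, 100, 1200),
    source = rep("noise", nn), stringsAsFactors = FALSE)
  truth <- rbind(sig, noise)
  truth <- truth[order(truth$mz_observed), ]
  rownames(truth) <- NULL

  pl <- suppressWarnings(peaklist(
    truth$mz_observed, truth$intensity, sample_id = sample_id,
    age_days = if (is.null(days)) NA_real_ else days,
    noise_level = params$noise_level))
  list(peaks = pl, truth = truth)
}

#' Generate a full synthetic aging time course
#'
#' One spectrum per (age, replicate) with a replicate-specific lognormal
#' deposition factor, mirroring an ambient aging experiment over 0--7 days
#' with quadruplicate measurement.
#'
#' @param ages Numeric vector of ages in days (default
#'   \code{c(0, 1, 3, 5, 7)}).
#' @param replicates Replicates per age (default 4).
#' @param profile A \code{sebum_profile} (default
#'   \code{default_sebum_profile(seed)}).
#' @param params An \code{aging_params}.
#' @param seed Integer master seed; per-sample seeds and deposition factors
#'   derive from it, so a fixed seed reproduces the output set exactly.
#' @return Object of class \code{fp_timecourse}: list with \code{samples}
#'   (each: \code{age_days}, \code{replicate}, \code{deposition_factor},
#'   \code{peaks}, \code{truth}), \code{profile}, \code{params},
#'   \code{seed}.
#' @export
generate_timecourse <- function(ages = c(0, 1, 3, 5, 7), replicates = 4L,
                                profile = NULL, params = aging_params(),
                                seed = 1L) {
  set.seed(seed)
  if (is.null(profile)) profile <- default_sebum_profile(seed)
  grid <- expand.grid(replicate = seq_len(replicates), age_days = ages)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  depo <- stats::rlnorm(nrow(grid), 0, params$deposition_sdlog)
  samples <- vector("list", nrow(grid))
  pools_by_age <- lapply(stats::setNames(ages, ages), function(a)
    age_profile(profile, a, params))
  for (i in seq_len(nrow(grid))) {
    a <- grid$age_days[i]; r <- grid$replicate[i]
    sid <- sprintf("d%02g_r%d", a, r)
    rs <- render_spectrum(pools_by_age[[as.character(a)]], params,
                          seed = sub_seeds[i], sample_id = sid,
                          deposition_factor = depo[i])
    rs$peaks$meta$replicate <- as.integer(r)
    samples[[i]] <- list(age_days = a, replicate = as.integer(r),
                         deposition_factor = depo[i], peaks = rs$peaks,
                         truth = rs$truth)
  }
  structure(list(samples = samples, profile = profile, params = params,
                 seed = seed, ages = ages, replicates = replicates),
            class = "fp_timecourse")
}

#' @export
print.fp_timecourse <- function(x, ...) {
  cat(sprintf("<fp_timecourse> %d samples (ages %s; %d replicates)\n",
              length(x$samples), paste(x$ages, collapse = ", "),
              x$replicates))
  invisible(x)
}
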