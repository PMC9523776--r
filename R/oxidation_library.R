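# Enumeration of sebum lipid substrates and their ambient oxidation
# products: ozonolysis of C=C bonds (head aldehyde A, head Criegee-derived
# B/C and its acid form C, tail acid / tail aldehyde, double ozonolysis AA)
# and singlet-oxygen epoxidation (E, one O added without chain loss).

.LIPID_CLASSES <- c("FA", "DG", "TG", "WE", "SQ")
# ester groups contributing to DBE, and backbone (glycerol) carbons
.ESTER_COUNT <- c(FA = 1L, DG = 2L, TG = 3L, WE = 1L, SQ = 0L)
.BACKBONE_C  <- c(FA = 0L, DG = 3L, TG = 3L, WE = 0L, SQ = 0L)

#' Define a lipid species
#'
#' A species is a lipid class plus its total acyl/chain carbon count and
#' total number of C=C double bonds, optionally with the omega positions
#' (carbons from the methyl terminus) of those bonds. Squalene is a single
#' molecule: \code{acyl_c} and \code{n_db} are fixed at 30 and 6.
#'
#' @param class One of \code{"FA"}, \code{"DG"}, \code{"TG"}, \code{"WE"},
#'   \code{"SQ"}.
#' @param acyl_c Total acyl/chain carbons (the first number of the shorthand
#'   nomenclature, e.g. 48 in "TG 48:0"; excludes glycerol carbons).
#' @param n_db Total number of C=C double bonds (>= 0).
#' @param db_positions Optional integer vector of omega positions, one per
#'   double bond, each >= 2.
#' @return An object of class \code{lipid_species}.
#' @examples
#' lipid_species("TG", 47, 1, db_positions = 10)
#' @export
lipid_species <- function(class, acyl_c = NULL, n_db = 0L, db_positions = NULL) {
  class <- match.arg(class, .LIPID_CLASSES)
  if (class == "SQ") {
    acyl_c <- 30L
    n_db <- 6L
  }
  if (is.null(acyl_c) || acyl_c < 1 || n_db < 0)
    stop("acyl_c must be >= 1 and n_db >= 0", call. = FALSE)
  if (!is.null(db_positions)) {
    if (length(db_positions) != n_db)
      stop("db_positions must have one entry per double bond", call. = FALSE)
    if (any(db_positions < 2))
      stop("omega positions must be >= 2", call. = FALSE)
  }
  structure(list(class = class, acyl_c = as.integer(acyl_c),
                 n_db = as.integer(n_db),
                 db_positions = if (is.null(db_positions)) NULL
                                else as.integer(db_positions)),
            class = "lipid_species")
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid> %s %d:%d", x$class, x$acyl_c, x$n_db))
  if (!is.null(x$db_positions))
    cat(" (omega ", paste(x$db_positions, collapse = ","), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Neutral elemental composition of a lipid species
#'
#' Standard stoichiometry: FA n:d = C_nH_{2n-2d}O2; WE n:d is isomeric with
#' the FA of the same n:d; DG = glycerol + 2 acyls - 2 H2O; TG = glycerol +
#' 3 acyls - 3 H2O; SQ = C30H50. The resulting DBE equals
#' \code{n_db + ester count} (FA/WE 1, DG 2, TG 3; SQ has its 6 C=C).
#'
#' @param species A \code{lipid_species}, or a class string (then supply
#'   \code{acyl_c} and \code{n_db}).
#' @param acyl_c,n_db Used only when \code{species} is a class string.
#' @return Neutral \code{elemcomp}.
#' @examples
#' format_formula(compose_lipid("TG", 48, 0)) # "C51H98O6"
#' @export
compose_lipid <- function(species, acyl_c = NULL, n_db = 0L) {
  if (is.character(species))
    species <- lipid_species(species, acyl_c, n_db)
  stopifnot(inherits(species, "lipid_species"))
  n <- species$acyl_c
  d <- species$n_db
  comp <- switch(species$class,
    FA = elemental_composition(C = n, H = 2 * n - 2 * d, O = 2),
    WE = elemental_composition(C = n, H = 2 * n - 2 * d, O = 2),
    DG = elemental_composition(C = n + 3, H = 2 * n - 2 * d + 4, O = 5),
    TG = elemental_composition(C = n + 3, H = 2 * n - 2 * d + 2, O = 6),
    SQ = elemental_composition(C = 30, H = 50)
  )
  comp
}

#' Ozonolysis products of one C=C cleavage
#'
#' Ozone adds across a C=C to give a primary then secondary ozonide; the
#' (relatively stable) secondary ozonide fragments, mostly in-source during
#' MALDI, into a head aldehyde (product A) plus tail aldehyde, or a head
#' Criegee-derived carbonyl oxide/acid (products B/C) plus tail aldehyde,
#' with the complementary tail acid (product C of the tail side) produced
#' when the Criegee chemistry lands on the tail. Cleavage at omega-n leaves
#' n carbons on the tail.
#'
#' @param species Unsaturated \code{lipid_species} (n_db >= 1).
#' @param omega Omega position of the cleaved bond, \code{2 <= omega <=
#'   acyl_c - 2}.
#' @return Named list of neutral \code{elemcomp}s: \code{head_aldehyde_A}
#'   (substrate - C_wH_2w + O), \code{head_criegee_BC} (substrate -
#'   C_wH_2w + 2O), \code{tail_acid_C} (C_wH_2wO2, an FA w:0) and
#'   \code{tail_aldehyde} (C_wH_2wO).
#' @examples
#' p <- ozonolysis_products(lipid_species("TG", 47, 1), omega = 10)
#' format_formula(p$head_aldehyde_A) # "C40H74O7", i.e. TG(A) 37:0
#' @export
ozonolysis_products <- function(species, omega) {
  stopifnot(inherits(species, "lipid_species"))
  if (species$n_db < 1)
    stop("ozonolysis requires at least one C=C", call. = FALSE)
  if (omega < 2 || omega > species$acyl_c - 2)
    stop("omega must satisfy 2 <= omega <= acyl_c - 2", call. = FALSE)
  sub <- compose_lipid(species)
  cut <- elemental_composition(C = omega, H = 2 * omega)
  oxo <- elemental_composition(O = 1)
  list(
    head_aldehyde_A = sub - cut + oxo,
    head_criegee_BC = sub - cut + oxo + oxo,
    tail_acid_C     = elemental_composition(C = omega, H = 2 * omega, O = 2),
    tail_aldehyde   = elemental_composition(C = omega, H = 2 * omega, O = 1)
  )
}

#' Double-ozonolysis (AA) product
#'
#' Sequential head-aldehyde cleavage at two C=C sites on distinct acyl
#' chains; only DG, WE and TG carry cleavable bonds on more than one chain.
#'
#' @param species \code{lipid_species} of class DG/WE/TG with n_db >= 2.
#' @param omegas Integer pair of omega positions for the two cleavages.
#' @return Neutral \code{elemcomp} of the di-aldehyde (AA) product.
#' @export
double_ozonolysis_products <- function(species, omegas) {
  stopifnot(inherits(species, "lipid_species"))
  if (!species$class %in% c("DG", "WE", "TG"))
    stop("double ozonolysis is enumerated only for DG, WE and TG",
         call. = FALSE)
  if (species$n_db < 2)
    stop("double ozonolysis requires at least two C=C", call. = FALSE)
  if (length(omegas) != 2)
    stop("omegas must be a pair", call. = FALSE)
  sub <- compose_lipid(species)
  cut <- elemental_composition(C = sum(omegas), H = 2 * sum(omegas))
  sub - cut + elemental_composition(O = 2)
}

#' Epoxidation (E) product
#'
#' Ambient singlet-oxygen epoxidation adds one O across a C=C, forming an
#' oxirane: C and H are unchanged, one C=C is consumed by the ring, and DBE
#' is conserved. In the shorthand nomenclature "TG X:1 becomes TG(E) X:0".
#'
#' @param species Unsaturated \code{lipid_species}.
#' @return Neutral \code{elemcomp} of the epoxide.
#' @examples
#' format_formula(epoxidation_product(lipid_species("TG", 50, 1))) # C53H100O7
#' @export
epoxidation_product <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (species$n_db < 1)
    stop("epoxidation requires at least one C=C", call. = FALSE)
  compose_lipid(species) + elemental_composition(O = 1)
}

# ---------------------------------------------------------------------------
# Target list construction

#' Configuration for the in silico heteroatom-class target list
#'
#' Carbon-number ranges are in formula carbons (the c of C_cH_{2c-Z}...),
#' i.e. including glycerol backbone carbons for DG/TG. DBE ranges are those
#' of the substrate class (saturated FA/WE = 1, DG = 2, TG = 3). Defaults
#' span the m/z 100--1200 spectral range of the instrument.
#'
#' @param fa_c,dg_c,tg_c,we_c Length-2 formula-carbon ranges per substrate.
#' @param fa_dbe,dg_dbe,tg_dbe,we_dbe Length-2 substrate DBE ranges.
#' @param include_sq Emit squalene substrate/epoxide entries (squalene is a
#'   single species, not a homologous class).
#' @param include_double_ozonolysis Emit AA entries for DG/WE/TG.
#' @param include_tail_aldehyde Emit tail-aldehyde entries. Off by default:
#'   short aldehydes (e.g. decanal) are volatile and seen by GC-MS, not
#'   MALDI.
#' @param allow_one_K_substitution Duplicate every Na-bearing entry with one
#'   Na replaced by K.
#' @param product_c_reach How far below the substrate carbon range product
#'   entries extend (covers cleavage at large omega), in carbons.
#' @param mz_range Retained m/z window; must lie within the instrument range
#'   100--1200.
#' @return An object of class \code{target_config}.
#' @export
target_list_config <- function(fa_c = c(8L, 26L), fa_dbe = c(1L, 4L),
                               dg_c = c(26L, 44L), dg_dbe = c(2L, 6L),
                               tg_c = c(40L, 60L), tg_dbe = c(3L, 6L),
                               we_c = c(26L, 46L), we_dbe = c(1L, 5L),
                               include_sq = TRUE,
                               include_double_ozonolysis = TRUE,
                               include_tail_aldehyde = FALSE,
                               allow_one_K_substitution = TRUE,
                               product_c_reach = 16L,
                               mz_range = c(100, 1200)) {
  rng <- list(FA = list(c = fa_c, dbe = fa_dbe),
              DG = list(c = dg_c, dbe = dg_dbe),
              TG = list(c = tg_c, dbe = tg_dbe),
              WE = list(c = we_c, dbe = we_dbe))
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r$c) != 2 || r$c[1] > r$c[2] || length(r$dbe) != 2 ||
        r$dbe[1] > r$dbe[2])
      stop("empty or inverted range for ", nm, call. = FALSE)
  }
  if (length(mz_range) != 2 || mz_range[1] >= mz_range[2] ||
      mz_range[1] < 100 || mz_range[2] > 1200)
    stop("mz_range must be an increasing window within 100-1200",
         call. = FALSE)
  structure(list(ranges = rng, include_sq = include_sq,
                 include_double_ozonolysis = include_double_ozonolysis,
                 include_tail_aldehyde = include_tail_aldehyde,
                 allow_one_K_substitution = allow_one_K_substitution,
                 product_c_reach = as.integer(product_c_reach),
                 mz_range = mz_range),
            class = "target_config")
}

# Neutral composition of a (substrate class, tag) member at formula carbons
# cf and substrate-convention DBE value B. Returns NULL when the combination
# is not chemically realizable (negative counts).
.tag_composition <- function(class, tag, cf, B) {
  base <- .ESTER_COUNT[[class]]
  acyl <- cf - .BACKBONE_C[[class]]
  mk <- function(d, dH2, dO) {
    if (d < 0 || acyl < 2) return(NULL)
    tryCatch({
      comp <- compose_lipid(class, acyl, d)
      if (dH2 > 0)
        comp <- comp - elemental_composition(H = 2 * dH2)
      if (dO > 0)
        comp <- comp + elemental_composition(O = dO)
      comp
    }, error = function(e) NULL)
  }
  switch(tag,
    substrate = mk(B - base, 0, 0),
    A         = mk(B - base - 1L, 1, 1),
    E         = mk(B - base - 1L, 1, 1),
    `B/C`     = mk(B - base - 1L, 1, 2),
    AA        = mk(B - base - 2L, 2, 2),
    stop("unknown product tag ", tag)
  )
}

# Nomenclature number pair (species carbons : residual double bonds)
.tag_species_numbers <- function(class, tag, cf, B) {
  base <- .ESTER_COUNT[[class]]
  acyl <- cf - .BACKBONE_C[[class]]
  r <- switch(tag, substrate = B - base, AA = B - base - 2L, B - base - 1L)
  c(acyl = acyl, r = r)
}

#' Build the in silico heteroatom-class target list
#'
#' Enumerates, for every substrate class and product tag (substrate, A,
#' B/C, AA, E), the theoretical sodiated ions over the configured carbon and
#' DBE ranges. Carboxylic-acid analytes -- FA-class entries and the acid
#' form of the Criegee products (tag C) -- are additionally emitted as
#' disodiated ions, the sodium adduct of the sodium carboxylate. With
#' \code{allow_one_K_substitution}, every entry is duplicated with one Na
#' replaced by K. Entries whose ion formulas coincide (e.g. the A and E
#' products of one class, which share one extra O and the same Z) are
#' collapsed into a single multi-label entry.
#'
#' @param config A \code{target_config}; see [target_list_config()].
#' @return A data frame of class \code{target_list}, sorted by m/z, with
#'   columns \code{label}, \code{formula}, \code{mz}, \code{kmd}, \code{c},
#'   \code{species_c}, \code{DBE}, \code{Z}, \code{O}, \code{Na}, \code{K},
#'   \code{product_tag}, \code{substrate}, \code{adduct}, \code{class_id}.
#' @examples
#' tl <- build_target_list(target_list_config())
#' tl[tl$label == "FA 10:0" & tl$adduct == "[M-H+2Na]+", c("formula", "mz")]
#' @export
build_target_list <- function(config = target_list_config()) {
  stopifnot(inherits(config, "target_config"))
  rows <- list()
  add <- function(label, comp, species_c, tag, class, adduct) {
    neutral <- neutralize_ion(comp)
    B <- dbe(neutral)
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, formula = format_formula(comp), mz = ion_mz(comp),
      c = comp[["C"]] + comp[["C13"]], species_c = species_c,
      DBE = B, Z = 2L * (B - 1L),
      O = comp[["O"]], Na = comp[["Na"]], K = comp[["K"]],
      product_tag = tag, substrate = class, adduct = adduct,
      stringsAsFactors = FALSE)
  }
  sodium <- elemental_composition(Na = 1)
  hydrogen <- elemental_composition(H = 1)

  for (class in names(config$ranges)) {
    rng <- config$ranges[[class]]
    c1 <- rng$c[1]; c2 <- rng$c[2]
    b1 <- rng$dbe[1]; b2 <- rng$dbe[2]
    base <- .ESTER_COUNT[[class]]
    tags <- c("substrate", "A", "E", "B/C")
    if (config$include_double_ozonolysis && class != "FA")
      tags <- c(tags, "AA")
    for (tag in tags) {
      cr <- if (tag == "substrate") c1:c2
            else max(6L, c1 - config$product_c_reach):c2
      br <- switch(tag,
        substrate = max(b1, base):b2,
        A = ,
        E = ,
        `B/C` = max(b1, base + 1L):b2,
        AA = if (b2 >= base + 2L) (base + 2L):b2 else integer(0))
      for (cf in cr) for (B in br) {
        comp <- .tag_composition(class, tag, cf, B)
        if (is.null(comp)) next
        num <- .tag_species_numbers(class, tag, cf, B)
        tag_lab <- if (tag == "substrate") "" else paste0("(", tag, ")")
        label <- sprintf("%s%s %d:%d", class, tag_lab, num[["acyl"]],
                         num[["r"]])
        add(label, comp + sodium, num[["acyl"]], tag, class, "[M+Na]+")
        # acid-bearing analytes: FA class (COOH retained in every product)
        # and the acid form (C) of any Criegee B/C series
        if (class == "FA" && tag != "B/C")
          add(label, comp - hydrogen + sodium + sodium, num[["acyl"]],
              tag, class, "[M-H+2Na]+")
        if (tag == "B/C") {
          lab_c <- sprintf("%s(C) %d:%d", class, num[["acyl"]], num[["r"]])
          add(lab_c, comp - hydrogen + sodium + sodium, num[["acyl"]],
              "C", class, "[M-H+2Na]+")
        }
      }
    }
  }
  if (config$include_sq) {
    sq <- compose_lipid("SQ")
    add("SQ 30:6", sq + sodium, 30L, "substrate", "SQ", "[M+Na]+")
    add("SQ(E) 30:5", sq + elemental_composition(O = 1) + sodium, 30L, "E",
        "SQ", "[M+Na]+")
  }
  if (config$include_tail_aldehyde) {
    # volatile tail aldehydes (C_wH_2wO); off by default
    for (w in 6:14)
      add(sprintf("aldehyde %d:0", w),
          elemental_composition(C = w, H = 2 * w, O = 1) + sodium,
          w, "tail_aldehyde", "FA", "[M+Na]+")
  }
  out <- do.call(rbind, rows)

  if (config$allow_one_K_substitution) {
    ktwin <- out[out$Na > 0, ]
    if (nrow(ktwin)) {
      dm <- .ATOMIC_MASS[["K"]] - .ATOMIC_MASS[["Na"]]
      ktwin$mz <- ktwin$mz + dm
      ktwin$Na <- ktwin$Na - 1L
      ktwin$K <- ktwin$K + 1L
      ktwin$adduct <- sub("2Na", "Na+K", sub("\\+Na\\]", "+K]", ktwin$adduct))
      ktwin$formula <- vapply(seq_len(nrow(ktwin)), function(i) {
        comp <- parse_formula(out$formula[out$Na > 0][i])
        format_formula(comp - elemental_composition(Na = 1) +
                         elemental_composition(K = 1))
      }, character(1))
      out <- rbind(out, ktwin)
    }
  }

  out <- out[out$mz >= config$mz_range[1] & out$mz <= config$mz_range[2], ]

  # collapse exact-isobar duplicates (identical ion formula) to one entry
  out <- out[order(out$formula, out$product_tag), ]
  agg_lab <- function(x) paste(unique(x), collapse = "|")
  key <- out$formula
  first <- !duplicated(key)
  merged <- out[first, ]
  merged$label <- as.vector(tapply(out$label, key, agg_lab)[merged$formula])
  merged$product_tag <- as.vector(
    tapply(out$product_tag, key, agg_lab)[merged$formula])
  merged$substrate <- as.vector(
    tapply(out$substrate, key, agg_lab)[merged$formula])
  out <- merged

  out$class_id <- sprintf("O%dNa%dK%d/DBE%d", out$O, out$Na, out$K, out$DBE)
  out$kmd <- kendrick_mass_defect(out$mz)
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  structure(out, class = c("target_list", "data.frame"), config = config)
}

#' Write a target list as TSV
#'
#' @param targets A \code{target_list}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_target_list <- function(targets, path) {
  stopifnot(inherits(targets, "target_list"))
  out <- as.data.frame(targets)
  out$mz_theoretical <- sprintf("%.6f", out$mz)
  cols <- c("label", "formula", "mz_theoretical", "c", "species_c", "DBE",
            "Z", "O", "Na", "K", "product_tag", "substrate", "adduct",
            "class_id")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
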