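#' Per-insecticide fitness parameters
#'
#' Bundles the parameters that calibrate the fitness of the three
#' single-locus genotypes with respect to one insecticide:
#'
#' * `effectiveness` (phi): proportion of fully susceptible (SS) mosquitoes
#'   killed on contact with the insecticide, so the SS fitness in an
#'   exposed niche is `1 - phi`.
#' * `dominance` (h): position of the heterozygote between the SS and RR
#'   fitnesses in the presence of the insecticide (0 = resistance
#'   recessive, 1 = dominant).
#' * `rr_restoration`: the fraction of the insecticide-induced fitness loss
#'   that the RR genotype recovers. The selection coefficient is derived as
#'   `s = rr_restoration * effectiveness`, which guarantees the RR fitness
#'   `1 - phi + s` never exceeds one. Alternatively `selection` may be
#'   given directly (subject to `1 - phi + s <= 1`).
#' * `cost` (z) and `cost_dominance`: fitness cost of carrying resistance
#'   alleles in the insecticide-free niche, and its dominance.
#'
#' Low-concentration niches are fully parameterised (`low = list(...)` with
#' the same fields) but default to the high-concentration calibration.
#'
#' @param effectiveness,dominance Numbers in `[0, 1]`.
#' @param rr_restoration Number in `[0, 1]`, or `NULL` if `selection` is
#'   supplied directly.
#' @param selection Selection coefficient `s >= 0` favouring resistance in
#'   exposed niches; ignored when `rr_restoration` is given.
#' @param cost,cost_dominance Numbers in `[0, 1]`; default 0.
#' @param low Optional list overriding `effectiveness`, `dominance`,
#'   `rr_restoration`/`selection` for the low-concentration niches.
#' @return An object of class `insecticide_params` with elements `high`,
#'   `low` (each `list(phi, h, s)`), `cost` and `cost_dominance`.
#' @examples
#' insecticide_params(effectiveness = 1, dominance = 1, rr_restoration = 1)
#' @export
insecticide_params <- function(effectiveness, dominance,
                               rr_restoration = NULL, selection = NULL,
                               cost = 0, cost_dominance = 0,
                               low = NULL) {
  level <- function(phi, h, restoration, s, label) {
    chk01 <- function(x, name) {
      if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
        stop(sprintf("%s (%s concentration) must be a number in [0, 1]",
                     name, label))
      }
      x
    }
    phi <- chk01(phi, "effectiveness")
    h <- chk01(h, "dominance")
    if (!is.null(restoration)) {
      s <- selection_from_restoration(chk01(restoration, "rr_restoration"), phi)
    } else if (is.null(s)) {
      stop("either rr_restoration or selection must be supplied")
    }
    if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0) {
      stop("selection coefficient must be a non-negative number")
    }
    if (1 - phi + s > 1 + 1e-12) {
      stop(sprintf(
        "selection coefficient %g with effectiveness %g gives RR fitness %g > 1 (%s concentration)",
        s, phi, 1 - phi + s, label
      ))
    }
    list(phi = phi, h = h, s = s)
  }
  high <- level(effectiveness, dominance, rr_restoration, selection, "high")
  low <- if (is.null(low)) {
    high
  } else {
    level(
      phi = if (is.null(low$effectiveness)) effectiveness else low$effectiveness,
      h = if (is.null(low$dominance)) dominance else low$dominance,
      restoration = low$rr_restoration,
      s = if (is.null(low$rr_restoration)) {
        if (is.null(low$selection)) high$s else low$selection
      } else {
        NULL
      },
      "low"
    )
  }
  for (nm in c("cost", "cost_dominance")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("%s must be a number in [0, 1]", nm))
    }
  }
  structure(
    list(high = high, low = low, cost = cost, cost_dominance = cost_dominance),
    class = "insecticide_params"
  )
}

#' Selection coefficient from a restoration coefficient
#'
#' The RR selection coefficient cannot be specified freely because large
#' values would push the RR fitness `1 - phi + s` above the reference
#' fitness of 1. The restoration coefficient expresses the RR genotype's
#' ability to recover the fitness removed by the insecticide:
#' `s = restoration * phi`. A restoration of 1 means RR mosquitoes are
#' completely unaffected by the insecticide (fitness 1); a restoration of 0
#' means the resistance allele is ineffective (RR fitness equals SS
#' fitness).
#'
#' @param restoration,phi Numbers in `[0, 1]`.
#' @return The selection coefficient `s`.
#' @export
selection_from_restoration <- function(restoration, phi) {
  stopifnot(
    is.numeric(restoration), restoration >= 0, restoration <= 1,
    is.numeric(phi), phi >= 0, phi <= 1
  )
  restoration * phi
}

#' Single-locus fitness by niche
#'
#' Builds the fitness `w` of each single-locus genotype (SS, RS, RR) at
#' each locus in each of the nine niches. In a niche where the locus's own
#' insecticide is present at concentration level c:
#' `w(SS) = 1 - phi_c`, `w(RS) = w(SS) + h_c * s_c`, `w(RR) = w(SS) + s_c`.
#' Where it is absent: `w(SS) = 1`, `w(RS) = 1 - cost_dominance * cost`,
#' `w(RR) = 1 - cost`. A computed fitness outside `[0, 1]` indicates a
#' mis-calibration and raises an error naming the offending cell rather
#' than being clamped.
#'
#' @param params1,params2 [insecticide_params] for insecticide 1 (locus 1)
#'   and insecticide 2 (locus 2).
#' @return A `2 x 3 x 9` array with dimensions locus, genotype
#'   (`LOCUS_GENOTYPES`) and niche (`NICHES`).
#' @export
single_locus_fitness_table <- function(params1, params2) {
  params <- list(params1, params2)
  conc <- rbind(NICHE_CONC1, NICHE_CONC2)
  w <- array(NA_real_, dim = c(2L, 3L, 9L),
             dimnames = list(c("locus1", "locus2"), LOCUS_GENOTYPES, NICHES))
  for (l in 1:2) {
    p <- params[[l]]
    for (n in seq_len(9L)) {
      lev <- conc[l, n]
      if (lev == 1L) {
        trio <- c(1, 1 - p$cost_dominance * p$cost, 1 - p$cost)
      } else {
        lv <- if (lev == 2L) p$low else p$high
        ss <- 1 - lv$phi
        trio <- c(ss, ss + lv$h * lv$s, ss + lv$s)
      }
      bad <- which(trio < -1e-12 | trio > 1 + 1e-12)
      if (length(bad)) {
        stop(sprintf(
          "calibration error: fitness of %s at locus %d in niche '%s' is %g (outside [0, 1])",
          LOCUS_GENOTYPES[bad[1]], l, NICHES[n], trio[bad[1]]
        ))
      }
      w[l, , n] <- pmin(pmax(trio, 0), 1)
    }
  }
  w
}

#' Interaction factors for dual-insecticide niches
#'
#' Mixture effects are multiplicative by default; the four niches where
#' both insecticides are present can be scaled by a factor Lambda to encode
#' synergy (`< 1`) or antagonism / cross-resistance (`> 1`).
#'
#' @param ab,Ab,aB,AB Positive scaling factors, default 1.
#' @return A named numeric vector over the dual niches.
#' @export
interaction_factors <- function(ab = 1, Ab = 1, aB = 1, AB = 1) {
  lam <- c(ab = ab, Ab = Ab, aB = aB, AB = AB)
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("interaction factors must be positive")
  }
  lam
}

#' Two-locus genotype fitness by niche
#'
#' The fitness of a two-locus genotype in a niche is the product of its two
#' single-locus fitnesses in that niche, times the interaction factor
#' Lambda in the four niches where both insecticides are present (Lambda is
#' identically 1 in single-insecticide and insecticide-free niches).
#' Coupling and repulsion double heterozygotes are assigned equal fitness.
#'
#' @param w Array from [single_locus_fitness_table()].
#' @param lam Interaction factors from [interaction_factors()].
#' @return A 10 x 9 matrix (genotype x niche).
#' @export
two_locus_fitness_tables <- function(w, lam = interaction_factors()) {
  if (!setequal(names(lam), DUAL_NICHES)) {
    stop("interaction factors must be named ", paste(DUAL_NICHES, collapse = ", "))
  }
  Wn <- w[1L, GENO_L1, , drop = TRUE] * w[2L, GENO_L2, , drop = TRUE]
  dimnames(Wn) <- list(GENOTYPES, NICHES)
  for (n in DUAL_NICHES) Wn[, n] <- Wn[, n] * lam[[n]]
  Wn
}

#' Exposure profile over the nine niches
#'
#' @param alpha A 2 x 9 numeric matrix (rows `m`, `f`; columns `NICHES`) of
#'   the proportion of each sex encountering each niche; rows must sum to
#'   one within `tol`.
#' @param tol Tolerance on row sums.
#' @return An object of class `exposure_profile`.
#' @seealso [build_exposure_profile()] to construct profiles from
#'   operational deployment parameters.
#' @export
exposure_profile <- function(alpha, tol = 1e-9) {
  stopifnot(all(dim(alpha) == c(2L, 9L)))
  if (!is.null(colnames(alpha))) {
    if (!setequal(colnames(alpha), NICHES)) {
      stop("unknown niche labels: ",
           paste(setdiff(colnames(alpha), NICHES), collapse = ", "))
    }
    alpha <- alpha[, NICHES, drop = FALSE]
  }
  dimnames(alpha) <- list(SEXES, NICHES)
  if (any(alpha < 0)) stop("exposure proportions must be non-negative")
  s <- rowSums(alpha)
  if (any(abs(s - 1) > tol)) {
    stop(sprintf("per-sex exposures must sum to 1 (sums %.12g, %.12g)",
                 s[[1]], s[[2]]))
  }
  structure(alpha / s, class = c("exposure_profile", "matrix", "array"))
}

#' Niche-weighted marginal fitness
#'
#' The marginal fitness of a genotype in each sex is the average of its
#' niche fitnesses weighted by that sex's exposure to each niche. Fitnesses
#' are frequency-independent, so this is computed once per deployment phase
#' and reused every generation of that phase.
#'
#' @param Wn 10 x 9 genotype-by-niche fitness matrix from
#'   [two_locus_fitness_tables()].
#' @param exp An [exposure_profile].
#' @return A 2 x 10 matrix (sex x genotype) of marginal fitnesses.
#' @export
marginal_fitness <- function(Wn, exp) {
  W <- unclass(exp) %*% t(Wn)
  dimnames(W) <- list(SEXES, GENOTYPES)
  W
}
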