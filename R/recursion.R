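#' Gamete frequencies after selection
#'
#' Applies one round of viability selection and Mendelian gamete production.
#' For each sex, the contribution of each parental genotype to each
#' haplotype is the product of the genotype's frequency, its marginal
#' fitness under the current deployment, and its Mendelian transmission
#' probability (with recombination between the loci); haplotype frequencies
#' are the column sums, normalised to one within each sex. The normalising
#' constants (the fitness-weighted parental mass G_m and G_f) are retained
#' on the result.
#'
#' @param F A [genotype_freq] state.
#' @param W 2 x 10 marginal-fitness matrix from [marginal_fitness()].
#' @param r Recombination rate in `[0, 0.5]`.
#' @return A [gamete_freq] object.
#' @export
gamete_frequencies <- function(F, W, r = 0.5) {
  m <- segregation_matrix(r)
  raw <- (unclass(F) * W) %*% m
  norm <- rowSums(raw)
  if (any(norm <= 0) || any(!is.finite(norm))) {
    stop("population extinct: total fitness-weighted parental mass is zero")
  }
  gamete_freq(raw / norm, normaliser = norm)
}

#' Random union of gametes
#'
#' Forms the next generation's genotype frequencies by random mating:
#' every ordered female x male gamete pair contributes its product of
#' frequencies to the genotype it produces. Double heterozygotes formed
#' from `(SS, RR)` gamete pairs are coupling; from `(SR, RS)` pairs,
#' repulsion. Both loci are autosomal so male and female offspring
#' frequencies are identical.
#'
#' @param G A [gamete_freq] object.
#' @return A [genotype_freq] object.
#' @export
next_generation <- function(G) {
  g <- unclass(G)
  off <- drop(UNION_MATRIX %*% as.vector(outer(g["f", ], g["m", ])))
  genotype_freq(rbind(m = off, f = off), tol = 1e-9)
}

#' One generation of the recursion
#'
#' Composition of [gamete_frequencies()] and [next_generation()]: one call
#' advances the population by one non-overlapping mosquito generation under
#' the supplied marginal fitnesses.
#'
#' @inheritParams gamete_frequencies
#' @return A [genotype_freq] object.
#' @export
step <- function(F, W, r = 0.5) {
  next_generation(gamete_frequencies(F, W, r))
}

#' Gametic linkage disequilibrium
#'
#' The LD metric is `D = f(RR) - f(R1) f(R2)` computed on the selected
#' gamete pool: the frequency of the double-resistant haplotype minus the
#' product of the marginal R-allele frequencies. Because selection may
#' differ between the sexes the male and female values are averaged (both
#' sexes contribute equal numbers of gametes to the next generation).
#'
#' @param G A [gamete_freq] object.
#' @return A single number in `[-0.25, 0.25]`.
#' @export
linkage_disequilibrium <- function(G) {
  g <- unclass(G)
  d <- g[, "RR"] - (g[, "RS"] + g[, "RR"]) * (g[, "SR"] + g[, "RR"])
  mean(d)
}

#' Mean population fitness
#'
#' The frequency-weighted mean fitness of the female population,
#' `sum_i F_f(i) W_f(i)` over the ten genotypes. Females are used because
#' mean fitness proxies the reduction in egg lay of the controlled
#' population relative to a fully susceptible, unexposed one; enough males
#' are assumed to survive to fertilise all eggs.
#'
#' @inheritParams gamete_frequencies
#' @return A single non-negative number.
#' @export
mean_population_fitness <- function(F, W) {
  sum(unclass(F)["f", ] * W["f", ])
}

# Internal workhorse: iterate the recursion under a fixed marginal-fitness
# matrix, tracking per-locus sex-averaged R frequencies and recording the
# first generation (counted from `gen0 + 1`) at which each watched locus
# strictly exceeds `threshold`. Stops when all watched loci have crossed or
# `max_gen` generations have been run. Kept free of S3 dispatch and
# validation in the loop: the per-generation state is renormalised once per
# update and the drift guard is enforced at the end.
#
# Returns list(F, gens, cross = c(g1, g2) (NA if not crossed),
#              freq_at = 2-col matrix of sex-averaged freqs per generation
#              (NULL unless record), ld, meanw, other_at_first)
run_phase <- function(F, W, r, threshold, max_gen,
                      watch = c(TRUE, TRUE), gen0 = 0L, record = FALSE) {
  m <- segregation_matrix(r)
  u <- UNION_MATRIX
  f <- unclass(F)
  Wm <- W["m", ]; Wf <- W["f", ]
  d1 <- GENO_DOSE1 / 2; d2 <- GENO_DOSE2 / 2
  cross <- c(NA_integer_, NA_integer_)
  freq <- c(
    mean(c(sum(f[1L, ] * d1), sum(f[2L, ] * d1))),
    mean(c(sum(f[1L, ] * d2), sum(f[2L, ] * d2)))
  )
  # a locus already above threshold at entry has crossing time gen0
  cross[watch & freq > threshold] <- gen0
  if (record) {
    traj <- matrix(NA_real_, nrow = max_gen, ncol = 8L)
    colnames(traj) <- c("freq_R1_m", "freq_R1_f", "freq_R2_m", "freq_R2_f",
                        "LD", "mean_fitness", "avg1", "avg2")
  }
  gens <- 0L
  done <- function() any(watch) && all(!watch | !is.na(cross))
  while (gens < max_gen && !done()) {
    raw_m <- (f[1L, ] * Wm) %*% m
    raw_f <- (f[2L, ] * Wf) %*% m
    nm <- sum(raw_m); nf <- sum(raw_f)
    if (nm <= 0 || nf <= 0 || !is.finite(nm) || !is.finite(nf)) {
      stop("population extinct: total fitness-weighted parental mass is zero")
    }
    gm <- raw_m / nm; gf <- raw_f / nf
    off <- drop(u %*% as.vector(t(gf) %*% gm))
    off <- off / sum(off)
    f <- rbind(off, off)
    gens <- gens + 1L
    p1 <- sum(off * d1); p2 <- sum(off * d2)
    freq <- c(p1, p2)
    for (l in 1:2) {
      if (watch[l] && is.na(cross[l]) && freq[l] > threshold) {
        cross[l] <- gen0 + gens
      }
    }
    if (record) {
      ld <- mean(c(
        gm[4L] - (gm[3L] + gm[4L]) * (gm[2L] + gm[4L]),
        gf[4L] - (gf[3L] + gf[4L]) * (gf[2L] + gf[4L])
      ))
      traj[gens, ] <- c(p1, p1, p2, p2, ld, sum(off * Wf), p1, p2)
    }
  }
  dimnames(f) <- list(SEXES, GENOTYPES)
  list(
    F = genotype_freq(f),
    gens = gens,
    cross = cross,
    freq = freq,
    traj = if (record) traj[seq_len(gens), , drop = FALSE] else NULL
  )
}
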