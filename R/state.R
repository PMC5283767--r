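#' Genotype-frequency state
#'
#' The simulator's state is a 2 x 10 matrix of relative genotype
#' frequencies, one row per sex (`"m"`, `"f"`), one column per two-locus
#' genotype. Each row sums to one. Constructors validate and renormalise;
#' the renormalisation only absorbs floating-point drift — inputs whose row
#' sums deviate from one by more than `tol` are rejected.
#'
#' @param freq A 2 x 10 (or 10 x 2, or length-10 for both sexes) numeric
#'   object of genotype frequencies. Columns may be named with `GENOTYPES`
#'   in any order; unnamed input is taken in the canonical order.
#' @param tol Maximum tolerated deviation of each row sum from one before
#'   renormalisation.
#' @return An object of class `genotype_freq`: a 2 x 10 matrix with rows
#'   `c("m", "f")` and columns `GENOTYPES`, each row summing to one.
#' @seealso [init_from_allele_freqs()] for the Hardy-Weinberg /
#'   linkage-equilibrium constructor.
#' @export
genotype_freq <- function(freq, tol = 1e-9) {
  if (is.data.frame(freq)) freq <- as.matrix(freq)
  if (is.null(dim(freq)) && length(freq) == 10L) {
    freq <- rbind(m = freq, f = freq)
  }
  if (nrow(freq) == 10L && ncol(freq) == 2L) freq <- t(freq)
  if (!all(dim(freq) == c(2L, 10L))) {
    stop("genotype frequencies must be a 2 x 10 (sex x genotype) matrix")
  }
  if (!is.null(colnames(freq))) {
    if (!setequal(colnames(freq), GENOTYPES)) {
      stop("unknown genotype labels: ",
           paste(setdiff(colnames(freq), GENOTYPES), collapse = ", "))
    }
    freq <- freq[, GENOTYPES, drop = FALSE]
  }
  dimnames(freq) <- list(SEXES, GENOTYPES)
  if (any(freq < 0)) {
    stop("genotype frequencies must be non-negative")
  }
  s <- rowSums(freq)
  if (any(abs(s - 1) > tol)) {
    stop(sprintf(
      "per-sex genotype frequencies must sum to 1 (sums %.12g, %.12g)",
      s[[1]], s[[2]]
    ))
  }
  freq <- freq / s
  structure(freq, class = c("genotype_freq", "matrix", "array"))
}

#' Initialise genotype frequencies from allele frequencies
#'
#' Builds the population state from the R-allele frequency at each locus
#' assuming Hardy-Weinberg equilibrium within loci and linkage equilibrium
#' between them, identically in the two sexes. Haplotype frequencies are
#' the products of allele frequencies and genotypes are formed by random
#' union of those haplotypes, so the double-heterozygote mass
#' `4 p1 (1-p1) p2 (1-p2)` is split equally between the coupling and
#' repulsion phases (the two phases have equal frequency under linkage
#' equilibrium).
#'
#' @param p1,p2 R-allele frequency at locus 1 and locus 2, each in `[0, 1]`.
#' @return A [genotype_freq] object.
#' @examples
#' F0 <- init_from_allele_freqs(0.01, 0.001)
#' allele_frequencies(F0)$avg
#' @export
init_from_allele_freqs <- function(p1, p2) {
  for (p in c(p1, p2)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop("allele frequencies must be single numbers in [0, 1]")
    }
  }
  hap <- c(
    SS = (1 - p1) * (1 - p2),
    SR = (1 - p1) * p2,
    RS = p1 * (1 - p2),
    RR = p1 * p2
  )
  g <- gamete_freq(rbind(m = hap, f = hap))
  next_generation(g)
}

#' Initialise genotype frequencies from an explicit genotype table
#'
#' Accepts a per-sex table of the ten two-locus genotype frequencies, for
#' populations that are not in Hardy-Weinberg or linkage equilibrium (for
#' example a population carried over from a previous deployment phase).
#' Frequencies are renormalised to sum exactly to one; sums further than
#' `1e-9` from one, or negative entries, are rejected.
#'
#' @inheritParams genotype_freq
#' @return A [genotype_freq] object.
#' @export
init_from_genotype_freqs <- function(freq, tol = 1e-9) {
  genotype_freq(freq, tol = tol)
}

#' Allele frequencies of a genotype-frequency state
#'
#' The R-allele frequency at each locus is the dose-weighted sum of
#' genotype frequencies divided by two (ploidy). Reported per sex and as
#' the unweighted male/female average, which is the quantity compared
#' against resistance-management thresholds (both sexes contribute equal
#' numbers of gametes to the next generation).
#'
#' @param F A [genotype_freq] object.
#' @return A list with components `m`, `f` (each a named length-2 vector of
#'   locus-1 and locus-2 R frequencies) and `avg`, their mean.
#' @export
allele_frequencies <- function(F) {
  d <- cbind(locus1 = GENO_DOSE1, locus2 = GENO_DOSE2) / 2
  per_sex <- unclass(F) %*% d
  list(
    m = per_sex["m", ],
    f = per_sex["f", ],
    avg = colMeans(per_sex)
  )
}

#' Gamete-frequency state
#'
#' A 2 x 4 matrix of haplotype frequencies in the selected gamete pool, one
#' row per sex, columns in the fixed order `SS, SR, RS, RR` (locus-1 allele
#' first). Rows sum to one; the per-sex normalising constants (the total
#' fitness-weighted parental mass, often written G_m and G_f) are kept in
#' the `"normaliser"` attribute.
#'
#' @param freq A 2 x 4 numeric matrix (rows m, f).
#' @param normaliser Optional length-2 numeric of per-sex normalising
#'   constants.
#' @return An object of class `gamete_freq`.
#' @export
gamete_freq <- function(freq, normaliser = c(m = 1, f = 1)) {
  stopifnot(all(dim(freq) == c(2L, 4L)))
  if (any(freq < 0)) stop("gamete frequencies must be non-negative")
  s <- rowSums(freq)
  if (any(s <= 0)) stop("per-sex gamete frequencies must have positive sum")
  freq <- freq / s
  dimnames(freq) <- list(SEXES, HAPLOTYPES)
  structure(freq,
    normaliser = stats::setNames(as.numeric(normaliser), SEXES),
    class = c("gamete_freq", "matrix", "array")
  )
}

#' @export
print.genotype_freq <- function(x, ...) {
  cat("Two-locus genotype frequencies (per sex):\n")
  print(round(unclass(x), 6), ...)
  invisible(x)
}

#' @export
print.gamete_freq <- function(x, ...) {
  cat("Gamete (haplotype) frequencies (per sex):\n")
  print(round(unclass(x), 6), ...)
  cat("normalisers:",
      paste(sprintf("%s = %.6g", SEXES, attr(x, "normaliser")), collapse = ", "),
      "\n")
  invisible(x)
}
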