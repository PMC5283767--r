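#' Genotype, haplotype and niche labels
#'
#' The model tracks ten two-locus genotypes: three single-locus genotypes
#' (SS, RS, RR) at each of two loci give nine combinations, and the double
#' heterozygote is split into its two phases, coupling (one chromosome
#' carries both R alleles, the other both S alleles) and repulsion (each
#' chromosome carries one R and one S). The two phases are assumed to have
#' identical fitness but differ in the gametes they produce when the loci
#' are linked, so both are tracked.
#'
#' Haplotype names give the locus-1 allele first, so `"SR"` is sensitive at
#' locus 1 and resistant at locus 2.
#'
#' Niches are the nine insecticide-exposure environments formed by each
#' insecticide being absent (`0`), present at low concentration (`a`/`b`) or
#' present at high concentration (`A`/`B`).
#'
#' @format Character vectors of labels.
#' @name model_labels
#' @keywords internal
NULL

# locus-1 genotype index 1..3 = SS, RS, RR
LOCUS_GENOTYPES <- c("SS", "RS", "RR")

GENOTYPES <- c(
  "SS1SS2", "SS1RS2", "SS1RR2",
  "RS1SS2", "RS1RS2_cis", "RS1RS2_trans",
  "RS1RR2",
  "RR1SS2", "RR1RS2", "RR1RR2"
)

# per-genotype single-locus genotype indices (into LOCUS_GENOTYPES)
GENO_L1 <- c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L)
GENO_L2 <- c(1L, 2L, 3L, 1L, 2L, 2L, 3L, 1L, 2L, 3L)

# "cis" is the coupling phase (RR / SS chromosomes), "trans" the repulsion
# phase (RS / SR chromosomes)
COUPLING <- 5L
REPULSION <- 6L

HAPLOTYPES <- c("SS", "SR", "RS", "RR")

# R-allele dose carried by each haplotype at each locus
HAP_R1 <- c(0, 0, 1, 1)
HAP_R2 <- c(0, 1, 0, 1)

# niche order follows the exposure table: insecticide 1 level crossed with
# insecticide 2 level (0 = absent, lower case = low, upper case = high)
NICHES <- c("00", "a0", "A0", "0b", "0B", "ab", "Ab", "aB", "AB")

# concentration level (1 = absent, 2 = low, 3 = high) of each insecticide
# in each niche
NICHE_CONC1 <- c(1L, 2L, 3L, 1L, 1L, 2L, 3L, 2L, 3L)
NICHE_CONC2 <- c(1L, 1L, 1L, 2L, 3L, 2L, 2L, 3L, 3L)

# the four niches where both insecticides are present
DUAL_NICHES <- c("ab", "Ab", "aB", "AB")

SEXES <- c("m", "f")

#' Mendelian gamete-production matrix
#'
#' Returns the 10 x 4 matrix `m` whose entry `m[g, h]` is the probability
#' that a parent of two-locus genotype `g` transmits haplotype `h`.
#' Homozygous loci transmit their allele with certainty, single-locus
#' heterozygotes transmit each allele with probability 1/2, and the double
#' heterozygotes depend on phase and the recombination rate `r`: the
#' coupling parent emits the parental `SS`/`RR` haplotypes at `(1-r)/2`
#' each and the recombinant `SR`/`RS` at `r/2` each, the repulsion parent
#' the reverse.
#'
#' @param r Recombination rate between the loci, in `[0, 0.5]`; `0.5` means
#'   unlinked loci.
#' @return A 10 x 4 numeric matrix with rows `GENOTYPES` and columns
#'   `HAPLOTYPES`; each row sums to 1.
#' @examples
#' segregation_matrix(0.5)["RS1RS2_cis", ]
#' @export
segregation_matrix <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, r >= 0, r <= 0.5)
  # per-locus transmission of the R allele
  p_r <- c(SS = 0, RS = 0.5, RR = 1)
  m <- matrix(0, nrow = 10L, ncol = 4L, dimnames = list(GENOTYPES, HAPLOTYPES))
  for (g in seq_len(10L)) {
    if (g == COUPLING) {
      m[g, ] <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
    } else if (g == REPULSION) {
      m[g, ] <- c(r / 2, (1 - r) / 2, (1 - r) / 2, r / 2)
    } else {
      p1 <- p_r[GENO_L1[g]]
      p2 <- p_r[GENO_L2[g]]
      m[g, ] <- c((1 - p1) * (1 - p2), (1 - p1) * p2, p1 * (1 - p2), p1 * p2)
    }
  }
  m
}

# 10 x 16 matrix mapping the vectorised outer product of female x male
# gamete frequencies, outer(G_f, G_m) with female haplotypes as rows, onto
# offspring genotype frequencies. Double heterozygotes formed from an
# (SS, RR) or (RR, SS) gamete pair are coupling; from (SR, RS) or (RS, SR)
# pairs, repulsion.
union_matrix <- function() {
  u <- matrix(0, nrow = 10L, ncol = 16L)
  rownames(u) <- GENOTYPES
  k <- 0L
  for (hm in seq_len(4L)) {       # column-major: male haplotype varies slowest
    for (hf in seq_len(4L)) {
      k <- k + 1L
      g1 <- 1L + HAP_R1[hf] + HAP_R1[hm]   # 1=SS, 2=RS, 3=RR
      g2 <- 1L + HAP_R2[hf] + HAP_R2[hm]
      if (g1 == 2L && g2 == 2L) {
        # both loci heterozygous: phase set by the parental haplotypes
        idx <- if ((hf == 1L && hm == 4L) || (hf == 4L && hm == 1L)) {
          COUPLING
        } else {
          REPULSION
        }
      } else {
        idx <- which(GENO_L1 == g1 & GENO_L2 == g2)
      }
      u[idx, k] <- u[idx, k] + 1
    }
  }
  u
}

UNION_MATRIX <- union_matrix()

# genotype R-allele dose at each locus (0, 1 or 2)
GENO_DOSE1 <- c(0, 0, 0, 1, 1, 1, 1, 2, 2, 2)
GENO_DOSE2 <- c(0, 1, 2, 0, 1, 1, 2, 0, 1, 2)
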