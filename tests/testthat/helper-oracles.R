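# Independent oracles and small builders shared across the test files.
# The oracles deliberately avoid the package's vectorised machinery: they
# work from first principles with strings and loops so that agreement with
# the package is a genuine cross-check.

geno_labels <- resistmix:::GENOTYPES
hap_labels <- resistmix:::HAPLOTYPES
niche_labels <- resistmix:::NICHES

# per-locus genotype of each two-locus genotype label, as strings
oracle_locus_geno <- function(g) {
  l1 <- substr(g, 1, 2)
  l2 <- substr(g, 4, 5)
  phase <- if (grepl("_cis$", g)) "cis" else if (grepl("_trans$", g)) "trans" else "none"
  list(l1 = l1, l2 = l2, phase = phase)
}

# Mendelian gamete distribution of one parent genotype, from first
# principles: enumerate the parent's two chromosomes, recombine with
# probability r, pick one chromosome at random.
oracle_gametes <- function(g, r) {
  info <- oracle_locus_geno(g)
  chrom <- function(a1, a2) paste0(a1, a2)
  # the two chromosomes of this parent
  if (info$phase == "cis") {
    chroms <- c("RR", "SS")
  } else if (info$phase == "trans") {
    chroms <- c("RS", "SR")
  } else {
    a1 <- strsplit(info$l1, "")[[1]]  # alleles at locus 1
    a2 <- strsplit(info$l2, "")[[1]]
    # for single-locus heterozygotes the assignment of alleles to
    # chromosomes is immaterial
    chroms <- c(chrom(a1[1], a2[1]), chrom(a1[2], a2[2]))
  }
  out <- setNames(numeric(4), hap_labels)
  c1 <- strsplit(chroms[1], "")[[1]]
  c2 <- strsplit(chroms[2], "")[[1]]
  parental <- c(chroms[1], chroms[2])
  recombinant <- c(paste0(c1[1], c2[2]), paste0(c2[1], c1[2]))
  for (h in parental) out[h] <- out[h] + (1 - r) / 2
  for (h in recombinant) out[h] <- out[h] + r / 2
  out
}

# genotype label formed by an ordered (female, male) pair of haplotypes
oracle_offspring <- function(hf, hm) {
  af <- strsplit(hf, "")[[1]]
  am <- strsplit(hm, "")[[1]]
  lg <- function(x, y) paste(sort(c(x, y), decreasing = TRUE), collapse = "")
  # sort "S" < "R" decreasing gives RS ordering used in the labels
  l1 <- lg(af[1], am[1])
  l2 <- lg(af[2], am[2])
  if (l1 == "SR") l1 <- "RS"
  if (l2 == "SR") l2 <- "RS"
  if (l1 == "RS" && l2 == "RS") {
    if ((hf == "RR" && hm == "SS") || (hf == "SS" && hm == "RR")) {
      return("RS1RS2_cis")
    }
    return("RS1RS2_trans")
  }
  paste0(l1, "1", l2, "2")
}

# Brute-force one-generation update: enumerate all 10 x 10 ordered
# (female, male) parental crosses, weight by fitness-scaled frequencies,
# and accumulate the Mendelian offspring distribution of each cross.
oracle_next_generation <- function(F, W, r) {
  Fm <- unclass(F)["m", ]
  Ff <- unclass(F)["f", ]
  wm <- Fm * W["m", ]
  wf <- Ff * W["f", ]
  wm <- wm / sum(wm)
  wf <- wf / sum(wf)
  off <- setNames(numeric(10), geno_labels)
  for (gf in geno_labels) {
    gam_f <- oracle_gametes(gf, r)
    for (gm in geno_labels) {
      cross_w <- wf[gf] * wm[gm]
      if (cross_w == 0) next
      gam_m <- oracle_gametes(gm, r)
      for (hf in hap_labels) {
        for (hm in hap_labels) {
          p <- gam_f[hf] * gam_m[hm]
          if (p == 0) next
          off[oracle_offspring(hf, hm)] <- off[oracle_offspring(hf, hm)] +
            cross_w * p
        }
      }
    }
  }
  off / sum(off)
}

# scalar single-locus recursion: one generation of selection + random
# mating at one locus with per-sex fitnesses w = c(SS, RS, RR). Takes and
# returns the genotype-frequency vector (identical in both sexes after
# random union, but not generally in Hardy-Weinberg proportions when the
# sexes' gamete pools differ).
oracle_single_locus_step <- function(geno, w_m, w_f) {
  gam <- function(w) {
    sel <- unname(geno * w)
    (sel[2] * 0.5 + sel[3]) / sum(sel)
  }
  qm <- gam(w_m)
  qf <- gam(w_f)
  c(
    SS = (1 - qf) * (1 - qm),
    RS = qf * (1 - qm) + qm * (1 - qf),
    RR = qf * qm
  )
}

# partial correlation on ranks via the inverse correlation matrix: an
# independent route to PRCC
oracle_prcc <- function(X, y) {
  R <- cbind(apply(as.matrix(X), 2, rank), .y = rank(y))
  C <- stats::cor(R)
  P <- solve(C)
  k <- ncol(R)
  sapply(seq_len(k - 1L), function(j) -P[j, k] / sqrt(P[j, j] * P[k, k]))
}

# marginal fitness matrix for the idealised calibration with a given niche
# receiving all the exposure
idealised_fitness <- function(niche, exposure = 0.9) {
  p <- insecticide_params(1, 1, rr_restoration = 1)
  Wn <- two_locus_fitness_tables(single_locus_fitness_table(p, p))
  al <- matrix(0, 2, 9, dimnames = list(c("m", "f"), niche_labels))
  al[, niche] <- exposure
  al[, "00"] <- al[, "00"] + 1 - exposure
  marginal_fitness(Wn, exposure_profile(al))
}

curtis_idealised_calibration <- function(p1 = 0.01, p2 = 0.001, ...) {
  resistance_calibration(
    insecticide_params(1, 1, rr_restoration = 1),
    insecticide_params(1, 1, rr_restoration = 1),
    start_freq = c(p1, p2),
    exposure = 0.9,
    ...
  )
}

# random valid genotype-frequency state (possibly sex-asymmetric)
random_state <- function() {
  f <- matrix(stats::runif(20), 2, 10)
  genotype_freq(f / rowSums(f))
}

# random marginal-fitness matrix bounded away from total extinction
random_fitness <- function() {
  W <- matrix(stats::runif(20, 0.05, 1), 2, 10,
              dimnames = list(c("m", "f"), geno_labels))
  W
}
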