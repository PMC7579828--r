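#' Gene-drop genotypes down a simulated pedigree
#'
#' Founder haplotypes are drawn from per-SNP allele frequencies sampled
#' uniformly from `maf_range`; descendants inherit one allele per parent
#' per SNP, independently across SNPs (unlinked markers, no LD). SNPs are
#' spread across 29 autosomes with arbitrary but reproducible positions.
#'
#' @param ped pedigree from [simulate_pedigree()] (parents precede
#'   offspring).
#' @param config a [sim_config()] object.
#' @return A list of class `sim_genotypes` with `geno` (allele-count
#'   matrix, animals x SNPs), `map` (`snp`, `chr`, `pos`, `a1`, `a2`) and
#'   `founder_freq`.
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- nrow(ped)
  m <- config$n_snps
  freq <- runif(m, config$maf_range[1], config$maf_range[2])
  si <- match(normalize_parent(ped$sire), ped$animal)
  di <- match(normalize_parent(ped$dam), ped$animal)
  # haplotype pair per animal, simulated in pedigree order
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  draw_founder <- function() rbinom(m, 1L, freq)
  for (i in seq_len(n)) {
    h1[i, ] <- if (is.na(si[i])) draw_founder() else
      ifelse(runif(m) < 0.5, h1[si[i], ], h2[si[i], ])
    h2[i, ] <- if (is.na(di[i])) draw_founder() else
      ifelse(runif(m) < 0.5, h1[di[i], ], h2[di[i], ])
  }
  geno <- h1 + h2
  snp_ids <- sprintf("SNP%05d", seq_len(m))
  dimnames(geno) <- list(ped$animal, snp_ids)
  chr <- sort(rep_len(1:29, m))
  pos <- integer(m)
  for (c_ in unique(chr)) {
    k <- sum(chr == c_)
    pos[chr == c_] <- sort(sample.int(1e8, k))
  }
  map <- data.frame(snp = snp_ids, chr = chr, pos = pos,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  structure(list(geno = geno, map = map, founder_freq = freq),
            class = "sim_genotypes")
}
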