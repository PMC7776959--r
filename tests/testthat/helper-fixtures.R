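# Shared fixtures, all generated in code (no binary data).

# Minimal VCF with one triallelic record, one half-missing genotype and one
# phased genotype, for the reader contract tests.
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("chr1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", sep = "\t"),
    paste("chr1", "200", "v2", "C", "T,G", ".", "PASS", ".", "GT",
          "1/2", "0/0", sep = "\t"),
    paste("chr1", "300", "v3", "G", "A", ".", "PASS", ".", "GT",
          "./.", "1|1", sep = "\t"),
    paste("chr1", "400", "v4", "T", "C", ".", "PASS", ".", "GT",
          "./1", "0/0", sep = "\t")
  ), path)
  path
}

# Tiny genotype matrix + sample frame with reference panels on both ends.
make_ref_fixture <- function(n_ref = 2, n_loci = 3, seed = 1) {
  set.seed(seed)
  ids <- c(paste0("p1_", seq_len(n_ref)), paste0("p2_", seq_len(n_ref)), "q1")
  dos <- rbind(matrix(2L, n_ref, n_loci), matrix(0L, n_ref, n_loci),
               matrix(1L, 1, n_loci))
  rownames(dos) <- ids
  G <- genotype_matrix(dos, locus_ids = paste0("l", seq_len(n_loci)))
  S <- sample_frame(ids,
                    position = c(rep(-100, n_ref), rep(100, n_ref), 0),
                    habitat = c(rep("desert", n_ref), rep("dune", n_ref),
                                "ecotone"),
                    role = c(rep("reference_P1", n_ref),
                             rep("reference_P2", n_ref), "query"))
  list(G = G, S = S)
}

# Random 3-way count table for log-linear property tests.
rand_table3 <- function(dims = c(3, 3, 2), lambda = 20) {
  array(stats::rpois(prod(dims), lambda), dim = dims,
        dimnames = list(h = paste0("h", seq_len(dims[1])),
                        p = paste0("p", seq_len(dims[2])),
                        o = paste0("o", seq_len(dims[3]))))
}

# Small transplant table with fully controlled cell composites.
make_transplant_fixture <- function() {
  rows <- expand.grid(habitat = c("desert", "dune"),
                      phenotype = c("P1", "P2"), rep = 1:5,
                      stringsAsFactors = FALSE)
  biomass <- ifelse(rows$habitat == "desert" & rows$phenotype == "P1", 6,
             ifelse(rows$habitat == "desert", 0.6487212707,  # exp(0.5)-... arbitrary
             ifelse(rows$phenotype == "P2", 6, 1)))
  transplant_table(data.frame(
    plant_id = sprintf("pl%02d", seq_len(nrow(rows))),
    phenotype = rows$phenotype, habitat = rows$habitat, water = "ambient",
    survived = 1, biomass = biomass, death_cause = "alive",
    stringsAsFactors = FALSE))
}

# Independent brute-force six-class likelihood oracle: a literal transcription
# of the category genotype-frequency model, written without vectorisation so
# it shares no code path with the package implementation.
oracle_class_loglik <- function(g, f1, f2) {
  w <- list(P1 = c(1, 0, 0), P2 = c(0, 0, 1), F1 = c(0, 1, 0),
            F2 = c(1 / 4, 1 / 2, 1 / 4), BC1 = c(1 / 2, 1 / 2, 0),
            BC2 = c(0, 1 / 2, 1 / 2))
  pg <- function(g1, a, b) {  # P(g | origin state) by direct enumeration
    c(both1 = choose(2, g1) * a^g1 * (1 - a)^(2 - g1),
      one = if (g1 == 2) a * b else if (g1 == 1) a * (1 - b) + (1 - a) * b
            else (1 - a) * (1 - b),
      both2 = choose(2, g1) * b^g1 * (1 - b)^(2 - g1))
  }
  sapply(names(w), function(cl) {
    tot <- 0
    for (l in seq_along(g)) {
      p <- sum(w[[cl]] * pg(g[l], f1[l], f2[l]))
      tot <- tot + log(p)
    }
    tot
  })
}

# Grid-search oracle for the supervised admixture likelihood.
oracle_grid_q <- function(g, f1, f2, step = 1e-4) {
  qs <- seq(0, 1, by = step)
  ll <- vapply(qs, function(q) {
    pi <- q * f1 + (1 - q) * f2
    pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
    sum(g * log(pi) + (2 - g) * log(1 - pi))
  }, numeric(1))
  qs[which.max(ll)]
}
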