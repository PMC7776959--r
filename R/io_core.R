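#' Construct a genotype matrix
#'
#' A `genotype_matrix` stores biallelic SNP genotypes as allele dosages
#' (count of the "pool-1" / ALT allele), one row per individual and one
#' column per locus. Missing genotypes are `NA`.
#'
#' @param dosage integer matrix (individuals x loci) with entries in
#'   `{0, 1, 2}` or `NA`.
#' @param sample_ids character vector of unique individual identifiers;
#'   defaults to `rownames(dosage)`.
#' @param locus_ids character vector of unique locus identifiers; defaults
#'   to `colnames(dosage)`.
#' @return An integer matrix of class `genotype_matrix` with `sample_ids`
#'   as rownames and `locus_ids` as colnames.
#' @examples
#' g <- genotype_matrix(rbind(s1 = c(0, 1, 2)), locus_ids = c("l1", "l2", "l3"))
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            locus_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(dosage)))
  if (is.null(locus_ids)) locus_ids <- paste0("l", seq_len(ncol(dosage)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(dosage))
    stop("length(sample_ids) does not match nrow(dosage)")
  if (length(locus_ids) != ncol(dosage))
    stop("length(locus_ids) does not match ncol(dosage)")
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  mode(dosage) <- "integer"
  bad <- which(!is.na(dosage) & !(dosage %in% 0:2))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(dosage))
    stop(sprintf("invalid dosage %s at sample '%s', locus '%s' (must be 0/1/2 or NA)",
                 dosage[bad[1]], sample_ids[i[1]], locus_ids[i[2]]))
  }
  dimnames(dosage) <- list(sample_ids, locus_ids)
  class(dosage) <- c("genotype_matrix", class(dosage))
  dosage
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

.habitats <- c("desert", "ecotone", "dune")
.roles <- c("reference_P1", "reference_P2", "query")

#' Per-individual transect metadata
#'
#' Positions are signed meters from the ecotone midline: negative on the
#' desert side, positive on the dune side, 0 at the midline.
#'
#' @param sample_id character identifiers.
#' @param position numeric, signed meters from the ecotone midline.
#' @param habitat one of `"desert"`, `"ecotone"`, `"dune"` per sample.
#' @param role one of `"reference_P1"`, `"reference_P2"`, `"query"`.
#' @return A `data.frame` of class `sample_frame`.
#' @export
sample_frame <- function(sample_id, position, habitat, role) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  habitat <- as.character(habitat)
  role <- as.character(role)
  if (!all(habitat %in% .habitats))
    stop("habitat must be one of: ", paste(.habitats, collapse = ", "))
  if (!all(role %in% .roles))
    stop("role must be one of: ", paste(.roles, collapse = ", "))
  if (!is.numeric(position) || length(position) != length(sample_id))
    stop("position must be numeric, one value per sample")
  out <- data.frame(sample_id = sample_id, position = as.numeric(position),
                    habitat = habitat, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_frame", "data.frame")
  out
}

#' Check that a sample frame matches a genotype matrix
#' @param S a [sample_frame()].
#' @param G a [genotype_matrix()].
#' @return `S` invisibly; errors if any sample is absent from `G`.
#' @export
validate_samples <- function(S, G) {
  missing <- setdiff(S$sample_id, rownames(G))
  if (length(missing))
    stop("samples absent from genotype matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(S)
}

#' Read a genotype matrix from VCF or a 0/1/2 TSV
#'
#' The TSV dialect is tab-separated with a header row: first column
#' `sample_id`, remaining columns one locus each, entries `0`, `1`, `2`
#' or `NA` (empty also accepted). The VCF path keeps only biallelic SNVs
#' (others are skipped and counted); dosage is the ALT-allele count and
#' half-missing genotypes (e.g. `./1`) are treated as missing.
#'
#' @param path file path.
#' @param format `"tsv012"` or `"vcf"`.
#' @return A [genotype_matrix()]. For VCF input the number of skipped
#'   non-biallelic/non-SNV records is attached as attribute `"skipped"`
#'   and reported via `message()`.
#' @export
read_genotypes <- function(path, format = c("tsv012", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv012") .read_genotypes_tsv(path) else .read_genotypes_vcf(path)
}

.read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop("malformed header: first column must be 'sample_id'")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(m, 2, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(m), dimnames = dimnames(m))
  bad <- which((!is.na(m) & is.na(num)) | (!is.na(num) & !(num %in% 0:2)))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf("non-{0,1,2} value '%s' at row %d (sample '%s'), column '%s'",
                 m[bad[1]], i[1], ids[i[1]], colnames(m)[i[2]]))
  }
  genotype_matrix(num, sample_ids = ids, locus_ids = colnames(m))
}

.read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the 'VariantAnnotation' package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  altc <- rep(NA_character_, length(n_alt))
  altc[n_alt == 1L] <- as.character(unlist(alt[n_alt == 1L]))
  refc <- as.character(VariantAnnotation::ref(vcf))
  keep <- n_alt == 1L & nchar(refc) == 1L & !is.na(altc) &
    grepl("^[ACGT]$", altc) & grepl("^[ACGT]$", refc)
  skipped <- sum(!keep)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("malformed VCF: no GT field")
  gt <- gt[keep, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  conv <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
            "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  for (j in seq_len(nrow(gt))) {
    v <- conv[gt[j, ]]
    dos[, j] <- unname(v)
  }
  if (skipped) message(skipped, " non-biallelic/non-SNV record(s) skipped")
  out <- genotype_matrix(dos)
  attr(out, "skipped") <- skipped
  out
}

#' Write a genotype matrix as a 0/1/2 TSV
#' @param G a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  df <- data.frame(sample_id = rownames(G), as.data.frame(unclass(G)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate parental allele frequencies from reference panels
#'
#' Counted-allele frequencies in the two parental reference pools, with
#' Agresti-style shrinkage (default 0.5 pseudo-allele of each type per
#' pool) so downstream class likelihoods are never degenerate. Loci with
#' fewer than `min_alleles` non-missing alleles in either pool are dropped
#' and reported.
#'
#' @param G a [genotype_matrix()].
#' @param S a [sample_frame()] with at least one `reference_P1` and one
#'   `reference_P2` sample.
#' @param shrinkage pseudo-alleles of each type added per pool (default 0.5).
#' @param min_alleles minimum non-missing allele count per pool per locus.
#' @return A `data.frame` of class `parental_frequencies` with columns
#'   `locus_id`, `f1`, `f2`, `n1`, `n2` (allele-count denominators).
#'   Dropped locus ids are attached as attribute `"dropped"`.
#' @export
parental_frequencies <- function(G, S, shrinkage = 0.5, min_alleles = 2) {
  validate_samples(S, G)
  p1 <- S$sample_id[S$role == "reference_P1"]
  p2 <- S$sample_id[S$role == "reference_P2"]
  if (!length(p1) || !length(p2))
    stop("both reference pools must be non-empty (reference_P1, reference_P2)")
  pool <- function(ids) {
    g <- G[ids, , drop = FALSE]
    cnt <- colSums(g, na.rm = TRUE)
    den <- 2 * colSums(!is.na(g))
    list(cnt = cnt, den = den)
  }
  a <- pool(p1); b <- pool(p2)
  keep <- a$den >= min_alleles & b$den >= min_alleles
  dropped <- colnames(G)[!keep]
  if (length(dropped))
    message(length(dropped), " locus/loci dropped (insufficient reference alleles)")
  f1 <- (a$cnt[keep] + shrinkage) / (a$den[keep] + 2 * shrinkage)
  f2 <- (b$cnt[keep] + shrinkage) / (b$den[keep] + 2 * shrinkage)
  out <- data.frame(locus_id = colnames(G)[keep],
                    f1 = unname(f1), f2 = unname(f2),
                    n1 = unname(a$den[keep]), n2 = unname(b$den[keep]),
                    stringsAsFactors = FALSE)
  class(out) <- c("parental_frequencies", "data.frame")
  attr(out, "dropped") <- dropped
  out
}

.phenotypes <- c("P1", "P2", "HYB")
.waters <- c("ambient", "supplemented")
.causes <- c("alive", "burial", "herbivory", "other")

#' Validate a reciprocal-transplant outcome table
#'
#' One row per transplanted plant. `survived == 1` if and only if
#' `death_cause == "alive"`; `biomass` (grams, total above- plus
#' belowground at harvest or at death) must be non-negative.
#'
#' @param df a data.frame with columns `plant_id`, `phenotype`
#'   (`P1`/`P2`/`HYB`), `habitat` (`desert`/`ecotone`/`dune`), `water`
#'   (`ambient`/`supplemented`), `survived` (0/1), `biomass` (grams),
#'   `death_cause` (`alive`/`burial`/`herbivory`/`other`).
#' @return The validated data.frame with class `transplant_table`.
#' @export
transplant_table <- function(df) {
  need <- c("plant_id", "phenotype", "habitat", "water", "survived",
            "biomass", "death_cause")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$plant_id)) stop("plant ids must be unique")
  if (!all(df$phenotype %in% .phenotypes)) stop("invalid phenotype value")
  if (!all(df$habitat %in% .habitats)) stop("invalid habitat value")
  if (!all(df$water %in% .waters)) stop("invalid water value")
  if (!all(df$survived %in% c(0, 1))) stop("survived must be 0/1")
  if (!all(df$death_cause %in% .causes)) stop("invalid death_cause value")
  if (any(df$biomass < 0 | is.na(df$biomass))) stop("biomass must be >= 0")
  if (any((df$survived == 1) != (df$death_cause == "alive")))
    stop("survived == 1 must coincide exactly with death_cause == 'alive'")
  class(df) <- c("transplant_table", "data.frame")
  df
}

#' Read a transplant table from TSV
#' @param path TSV file with the columns documented in [transplant_table()].
#' @return A `transplant_table`.
#' @export
read_transplant <- function(path) {
  transplant_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Validate a leaf morphometry table
#'
#' One row per measured leaf: identifier columns `sample_id` and `leaf_id`
#' followed by numeric measurement columns (area in mm^2 plus dimensionless
#' shape descriptors). The first measurement column is taken to be area and
#' must be non-negative.
#'
#' @param df data.frame as described above.
#' @param samples optional [sample_frame()]; if given, every leaf row must
#'   map to a known sample.
#' @return The validated data.frame with class `morph_table`.
#' @export
morph_table <- function(df, samples = NULL) {
  if (!all(c("sample_id", "leaf_id") %in% names(df)))
    stop("morph table needs 'sample_id' and 'leaf_id' columns")
  meas <- setdiff(names(df), c("sample_id", "leaf_id"))
  if (!length(meas)) stop("morph table has no measurement columns")
  if (!all(vapply(df[meas], is.numeric, logical(1))))
    stop("all measurement columns must be numeric")
  if (any(df[[meas[1]]] < 0, na.rm = TRUE))
    stop("negative leaf area")
  if (!is.null(samples)) {
    unknown <- setdiff(df$sample_id, samples$sample_id)
    if (length(unknown))
      stop("leaves for unknown sample(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  class(df) <- c("morph_table", "data.frame")
  df
}
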