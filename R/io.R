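#' Read genotypes from TSV or PLINK .raw files
#'
#' Two plain-text dialects are supported: a genotype TSV (header row of
#' locus labels, one row per individual, allele counts 0/1/2) and the
#' PLINK `.raw` additive-coding export (whitespace-separated, six
#' leading pedigree columns `FID IID PAT MAT SEX PHENOTYPE` followed by
#' one column per SNP).  Missing values are rejected: the analysis model
#' has no missingness concept, so any `NA` is a hard error naming the
#' offending cell, as is any entry outside {0, 1, 2}.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.raw` selects the PLINK
#'   dialect), `"tsv"` or `"plink_raw"`.
#' @return A raw [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.raw$", path, ignore.case = TRUE))
      "plink_raw" else "tsv"
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = "character")
    codes <- df
  } else {
    df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                            colClasses = "character")
    if (ncol(df) < 7)
      stop("PLINK .raw file needs 6 pedigree columns plus SNP columns",
           call. = FALSE)
    codes <- df[, -(1:6), drop = FALSE]
  }
  m <- as.matrix(codes)
  bad_l <- is.na(m) | !(m == "0" | m == "1" | m == "2")
  if (any(bad_l)) {
    bad <- which(bad_l, arr.ind = TRUE)
    stop(sprintf("invalid genotype value '%s' at row %d, column '%s'",
                 ifelse(is.na(m[bad[1, 1], bad[1, 2]]), "NA",
                        m[bad[1, 1], bad[1, 2]]),
                 bad[1, 1], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  genotype_matrix(m, locus_labels = colnames(m))
}

#' Write genotypes as TSV or PLINK .raw
#'
#' @param G a raw [genotype_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"plink_raw"`; default chosen from the
#'   extension.  The `.raw` writer fills the pedigree columns with
#'   sequential IDs and missing (`-9`) phenotype.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("auto", "tsv", "plink_raw")) {
  stopifnot(inherits(G, "geno_matrix"))
  if (is_centered(G))
    stop("write raw (uncentered) genotypes only", call. = FALSE)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.raw$", path, ignore.case = TRUE))
      "plink_raw" else "tsv"
  m <- unclass(G)
  if (format == "tsv") {
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    ped <- data.frame(FID = seq_len(nrow(m)), IID = seq_len(nrow(m)),
                      PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9)
    out <- cbind(ped, as.data.frame(m))
    utils::write.table(out, path, sep = " ", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read / write a phenotype TSV (columns IID, value)
#'
#' @param path file path.
#' @return `read_phenotypes` returns a numeric vector named by IID.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("IID", "value") %in% names(df)))
    stop("phenotype TSV needs columns IID and value", call. = FALSE)
  stats::setNames(as.numeric(df$value), df$IID)
}

#' @rdname read_phenotypes
#' @param y numeric phenotype vector (names used as IIDs if present).
#' @export
write_phenotypes <- function(y, path) {
  df <- data.frame(IID = names(y) %||% seq_along(y), value = as.numeric(y))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a covariate TSV (one column per covariate, header required)
#'
#' @param path file path.
#' @return A numeric matrix.
#' @export
read_covariates <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as.matrix(df)
}

#' Build a scenario from a YAML configuration
#'
#' The configuration mirrors the arguments of [scenario()]:
#' `model`, `sample_size`, `qtl_variance_fraction`, `alpha`,
#' `replicates`, `master_seed`, plus an `ld_spec` block with either
#' `allele_freqs`/`pairwise_D`/`three_locus_D` (closed-form three-locus
#' law) or `maf`/`positions`/`decay_lambda` (Markov chromosome law) and
#' optional `qtl_index`/`marker_indices`.  See
#' `system.file("extdata", "scenario_example.yaml", package =
#' "phantomepi")` for a complete example.
#'
#' @param path YAML file path.
#' @return A [scenario()] object.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  ld <- cfg$ld_spec
  if (!is.null(ld$allele_freqs)) {
    dist <- make_haplotype_distribution(
      as.numeric(ld$allele_freqs),
      pairwise_D = as.numeric(ld$pairwise_D %||% 0),
      three_locus_D = as.numeric(ld$three_locus_D %||% 0))
  } else if (!is.null(ld$maf)) {
    pos <- as.numeric(ld$positions)
    dist <- markov_haplotype_distribution(
      rep_len(as.numeric(ld$maf), length(pos)),
      rho = exp(-diff(pos) / as.numeric(ld$decay_lambda %||% 3e5)),
      positions = pos)
  } else stop("ld_spec must give allele_freqs or maf/positions",
              call. = FALSE)
  n <- cfg$sample_size %||% cfg[["n"]]
  if (is.null(n))
    stop("configuration needs a `sample_size` field", call. = FALSE)
  scenario(dist,
           model = cfg$model %||% "additive",
           n = n,
           qtl_index = cfg$qtl_index %||% 1,
           marker_indices = as.numeric(cfg$marker_indices %||% c(2, 3)),
           qtl_variance_fraction = cfg$qtl_variance_fraction %||% 0.01,
           a = cfg$a %||% 1, d = cfg$d %||% 0,
           error_variance = cfg$error_variance %||% 1,
           polygenic_fraction = cfg$polygenic_fraction %||% 0,
           alpha = cfg$alpha %||% 0.05,
           replicates = cfg$replicates %||% 1000,
           master_seed = cfg$master_seed %||% 1,
           id = cfg$id)
}
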