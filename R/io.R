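# Plain-text interchange: long-format phenotype tables, dosage matrices
# (TSV or VCF), labeled variance-component matrices and summary statistics.

#' Read a long-format phenotype table
#'
#' Tab-separated with header columns `individual_id, trait_id, time, value`
#' plus covariates; the missing-value token is `NA` (rows with missing
#' `value` are dropped as missing records).
#'
#' @param file path.
#' @param covariates covariate columns (default: all extra columns).
#' @export
read_phenotypes <- function(file, covariates = NULL) {
  d <- as.data.frame(data.table::fread(file, sep = "\t", na.strings = "NA"))
  d <- d[!is.na(d$value), , drop = FALSE]
  pheno_long(d, covariates = covariates)
}

#' Write a long-format phenotype table
#' @param pheno a [pheno_long()] table.
#' @param file path.
#' @export
write_phenotypes <- function(pheno, file) {
  data.table::fwrite(as.data.frame(pheno), file, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(file)
}

#' Read a dosage matrix
#'
#' Tab-separated, variants in rows: leading columns `variant_id, chrom, pos,
#' ref, alt`, then one dosage column per individual.
#'
#' @param file path.
#' @export
read_dosage <- function(file) {
  d <- data.table::fread(file, sep = "\t")
  meta <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(meta, names(d))
  if (length(miss)) stop("dosage file lacks column(s): ", paste(miss, collapse = ", "))
  ids <- setdiff(names(d), meta)
  G <- t(as.matrix(d[, ids, with = FALSE]))
  colnames(G) <- d$variant_id
  if (any(!is.finite(G)) || any(G < 0 | G > 2))
    stop("dosages must lie in [0, 2]")
  info <- as.data.frame(d[, meta, with = FALSE])
  info$chrom <- as.character(info$chrom)
  genotype_dosage(G, info)
}

#' Write a dosage matrix
#' @param geno a [genotype_dosage()].
#' @param file path.
#' @export
write_dosage <- function(geno, file) {
  stopifnot(inherits(geno, "genotype_dosage"))
  out <- data.table::data.table(geno$info)
  dt <- data.table::as.data.table(t(geno$dosage))
  data.table::setnames(dt, rownames(geno$dosage))
  data.table::fwrite(cbind(out, dt), file, sep = "\t", quote = FALSE)
  invisible(file)
}

#' Read dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise converts `GT` to an
#' alternate-allele count. Requires the `vcfR` package.
#'
#' @param file VCF path (plain or gzipped).
#' @export
read_vcf_dosage <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the 'vcfR' package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if ("DS" %in% fmt) {
    M <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    M <- matrix(vapply(gt, function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(gsub("\\|", "/", g), "/")[[1]]) > 0)
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  } else stop("VCF has neither DS nor GT FORMAT fields")
  fix <- vcfR::getFIX(v)
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(vid) | vid == "."]
  info <- data.frame(variant_id = vid, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                     alt = fix[, "ALT"], stringsAsFactors = FALSE)
  G <- t(M)
  colnames(G) <- vid
  genotype_dosage(G, info)
}

#' Write variance components to a labeled TSV file
#'
#' Two sections: the 2K x 2K genetic matrix with `trait:CS` / `trait:LT`
#' labels, then the K x K residual matrix. Values carry 17 significant
#' digits so that a read/write round trip is bit-stable.
#'
#' @param vc a [variance_components()] object.
#' @param file path.
#' @export
write_variance_components <- function(vc, file) {
  stopifnot(inherits(vc, "variance_components"))
  fmt <- function(m) {
    rows <- apply(m, 1L, function(r)
      paste(format(r, digits = 17, scientific = TRUE, trim = TRUE),
            collapse = "\t"))
    paste(rownames(m), rows, sep = "\t")
  }
  lines <- c(paste0("#genetic\t", paste(colnames(vc$C), collapse = "\t")),
             fmt(vc$C),
             paste0("#residual\t", paste(colnames(vc$E), collapse = "\t")),
             fmt(vc$E))
  writeLines(lines, file)
  invisible(file)
}

#' Read variance components written by [write_variance_components()]
#' @param file path.
#' @export
read_variance_components <- function(file) {
  lines <- readLines(file)
  gi <- grep("^#genetic\t", lines)
  ri <- grep("^#residual\t", lines)
  if (length(gi) != 1L || length(ri) != 1L)
    stop("not a variance-components file (missing section headers)")
  parse_block <- function(header, body) {
    labs <- strsplit(lines[header], "\t")[[1]][-1L]
    rows <- strsplit(body, "\t")
    m <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(labs))))
    dimnames(m) <- list(vapply(rows, `[`, character(1), 1L), labs)
    m
  }
  C <- parse_block(gi, lines[(gi + 1L):(ri - 1L)])
  E <- parse_block(ri, lines[(ri + 1L):length(lines)])
  traits <- rownames(E)
  variance_components(C, E, traits)
}

#' Write tidy summary statistics
#' @param results data.frame of per-variant results.
#' @param file path.
#' @export
write_results <- function(results, file) {
  data.table::fwrite(results, file, sep = "\t", na = "NA", quote = FALSE)
  invisible(file)
}
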