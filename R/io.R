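#' Read / write genotype matrices as TSV
#'
#' Rows are individuals (first column `id`), columns are marker ids, cells
#' are alternate-allele dosages 0/1/2 with `NA` for missing. Malformed cells
#' raise an error naming the line.
#'
#' @param path File path.
#' @return `read_genotypes()` returns an integer genotype matrix with
#'   individual rownames and marker colnames.
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if (names(df)[1L] != "id") abort("Genotype TSV must start with an 'id' column.")
  ids <- df$id
  cells <- as.matrix(df[, -1L, drop = FALSE])
  ok <- is.na(cells) | cells %in% c("0", "1", "2") | cells == "NA"
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    abort(paste0("Invalid genotype '", cells[bad[1L], bad[2L]], "' at line ",
                 bad[1L] + 1L, ", marker ", colnames(cells)[bad[2L]], "."))
  }
  G <- matrix(suppressWarnings(as.integer(cells)), nrow = nrow(cells),
              dimnames = list(ids, colnames(cells)))
  G
}

#' @rdname read_genotypes
#' @param G Genotype matrix to write.
#' @export
write_genotypes <- function(G, path) {
  df <- tibble::as_tibble(G, rownames = "id")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' Read genotype dosages from a VCF file
#'
#' Converts diploid GT fields (phased or unphased) to alternate-allele
#' dosages 0/1/2; `./.` becomes missing. Biallelic records only. Returns the
#' matrix in the package's individuals-by-markers orientation.
#'
#' @param path VCF file path (plain or gzipped).
#' @return Integer genotype matrix, individuals x markers.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF requires the 'vcfR' package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(x) {
    x <- sub("\\|", "/", x)
    ifelse(is.na(x) | x %in% c("./.", "."), NA_integer_,
           vapply(strsplit(x, "/", fixed = TRUE),
                  function(a) sum(as.integer(a)), integer(1)))
  }
  M <- apply(gt, 2L, dosage)
  if (is.null(dim(M))) M <- matrix(M, nrow = 1L, dimnames = list(rownames(gt), colnames(gt)))
  out <- t(M)
  ids <- rownames(gt) %||% paste0("var", seq_len(ncol(out)))
  colnames(out) <- ids
  out
}

#' Read / write phenotype CSV
#'
#' Dialect: `clone,site,rep,set,block,trait,value`; `value` numeric, other
#' columns character.
#'
#' @param path File path.
#' @return `read_phenotypes()` returns a tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    clone = readr::col_character(), site = readr::col_character(),
    rep = readr::col_character(), set = readr::col_character(),
    block = readr::col_character(), trait = readr::col_character(),
    value = readr::col_double()
  ))
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble to write.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_csv(pheno, path, na = "NA")
  invisible(path)
}

#' Read / write a labelled dense matrix TSV (A or G)
#'
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ))
  M <- as.matrix(df[, -1L, drop = FALSE])
  rownames(M) <- df$id
  M
}

#' @rdname read_matrix_tsv
#' @param M Matrix with dimnames to write.
#' @export
write_matrix_tsv <- function(M, path) {
  readr::write_tsv(tibble::as_tibble(M, rownames = "id"), path)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report A list (e.g. from [run_pipeline()]); tibbles are serialized
#'   as data-frame arrays.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}
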