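# Tab-separated serialization of cohorts, panels and association tables,
# plus optional VCF genotype import. Truth tuples travel in JSON side-cars.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- NA
    out
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
}

.read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = "",
             stringsAsFactors = FALSE, check.names = FALSE)
}

.truth_path <- function(path) paste0(path, ".truth.json")

#' Write / read a cohort as a tab-separated table
#'
#' Columns are `subject_id`, `y0`, `y1`, `treatment`, `age`, `g_1`. If the
#' cohort carries generating parameters they are written to a
#' `<path>.truth.json` side-car and restored on read.
#'
#' @param x A `cfb_cohort`.
#' @param path Output/input TSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `cfb_cohort`.
#' @export
write_cohort <- function(x, path) {
  if (!inherits(x, "cfb_cohort")) stopf("x must be a cfb_cohort")
  df <- data.frame(subject_id = x$subject_id, y0 = x$y0, y1 = x$y1,
                   treatment = x$treatment, age = x$age, g_1 = x$genotype)
  .write_tsv(df, path)
  truth <- attr(x, "truth")
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth), .truth_path(path),
                         auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- .read_tsv(path)
  gcol <- if ("genotype" %in% names(df)) "genotype" else {
    gc <- grep("^g_", names(df), value = TRUE)
    if (length(gc) != 1L)
      stopf("expected exactly one genotype column (g_* or genotype)")
    gc
  }
  truth <- NULL
  if (file.exists(.truth_path(path))) {
    tl <- jsonlite::read_json(.truth_path(path), simplifyVector = TRUE)
    tl$seed <- tl$seed %||% NULL
    truth <- do.call(sim_params, tl[setdiff(names(tl), character(0))])
  }
  cohort(df$y0, df$y1, df$treatment, df$age, df[[gcol]], truth = truth)
}

#' Write / read a variant panel
#'
#' The main table `<path>` holds `subject_id`, shared phenotypes (for the
#' additive rule), `treatment`, `age` and one `g_<variant_id>` column per
#' variant. Per-variant truth tuples and the composition rule go to
#' `<path>.truth.json`. Panels built under the single-causal rule carry
#' per-variant phenotypes, written as wide tables `<path>.y0.tsv` and
#' `<path>.y1.tsv`.
#'
#' @param x A `cfb_panel`.
#' @param path Output/input path of the main TSV.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` a
#'   `cfb_panel`.
#' @export
write_panel <- function(x, path) {
  if (!inherits(x, "cfb_panel")) stopf("x must be a cfb_panel")
  n <- nrow(x$genotypes)
  df <- data.frame(subject_id = seq_len(n))
  single <- is.matrix(x$y0)
  if (!single) {
    df$y0 <- x$y0
    df$y1 <- x$y1
  }
  df$treatment <- x$treatment
  df$age <- x$age
  g <- as.data.frame(x$genotypes)
  names(g) <- paste0("g_", colnames(x$genotypes))
  .write_tsv(cbind(df, g), path)
  if (single) {
    for (ph in c("y0", "y1")) {
      w <- as.data.frame(x[[ph]])
      names(w) <- colnames(x$genotypes)
      .write_tsv(cbind(data.frame(subject_id = seq_len(n)), w),
                 paste0(path, ".", ph, ".tsv"))
    }
  }
  jsonlite::write_json(list(rule = x$rule, truth = x$truth),
                       .truth_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- .read_tsv(path)
  side <- jsonlite::read_json(.truth_path(path), simplifyVector = TRUE)
  gcols <- grep("^g_", names(df), value = TRUE)
  g <- as.matrix(df[gcols])
  colnames(g) <- sub("^g_", "", gcols)
  rownames(g) <- df$subject_id
  single <- identical(side$rule, "single_causal")
  if (single) {
    y0 <- as.matrix(.read_tsv(paste0(path, ".y0.tsv"))[, -1, drop = FALSE])
    y1 <- as.matrix(.read_tsv(paste0(path, ".y1.tsv"))[, -1, drop = FALSE])
    colnames(y0) <- colnames(y1) <- colnames(g)
  } else {
    y0 <- df$y0
    y1 <- df$y1
  }
  structure(list(genotypes = g, y0 = y0, y1 = y1, treatment = df$treatment,
                 age = df$age, truth = side$truth, rule = side$rule),
            class = "cfb_panel")
}

#' Write / read an association table
#'
#' Tab-separated with empty fields where a statistic does not apply,
#' mirroring a per-variant GWAS summary table.
#'
#' @param x Association data frame (e.g. `run_gwas()$assoc` or a
#'   `cfb_assoc` row).
#' @param path Output/input TSV path.
#' @export
write_assoc <- function(x, path) {
  .write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_assoc
#' @export
read_assoc <- function(path) .read_tsv(path)

#' Import genotype dosages from a VCF file
#'
#' Reads a biallelic, autosomal, unphased (or phased) diploid VCF and counts
#' alternate alleles per genotype call, giving a subjects-by-variants dosage
#' matrix of 0/1/2 (NA for missing calls). Requires the `vcfR` package.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return Numeric matrix, subjects in rows (named by sample), variants in
#'   columns (named by ID or CHROM:POS).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(s) {
    if (is.na(s)) return(NA_real_)
    sum(strsplit(s, "[/|]")[[1]] == "1")
  })
  t(dos)
}
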