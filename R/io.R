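# CSV dialect: comma-separated, UTF-8; missing values are empty cells ("."
# is never used as a missing marker in numeric columns). Genotype calls are
# exported in {0, 1, 2} dosage coding (parent A hom = 0, het = 1, parent B
# hom = 2, missing = empty).

#' Write / read a genotype matrix as CSV
#'
#' Lines x markers table with calls in \{0, 1, 2\} dosage coding and empty
#' cells for missing. The marker map travels in a separate CSV
#' ([write_marker_map_csv()]).
#'
#' @param geno a [geno_matrix()].
#' @param path file path.
#' @param map_path map CSV path (for the reader).
#' @return `read_genotypes_csv` returns a [geno_matrix()].
#' @export
write_genotypes_csv <- function(geno, path) {
  m <- geno$calls + 1L  # -1/0/1 -> 0/1/2
  df <- data.frame(line = geno$line_ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path, map_path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- read_marker_map_csv(map_path)
  calls <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(calls) <- "integer"
  bad <- calls[!is.na(calls)]
  if (!all(bad %in% 0:2)) stop("genotype CSV must contain calls in {0,1,2}")
  if (!identical(colnames(calls), map$marker))
    stop("genotype columns do not match marker map")
  geno_matrix(calls - 1L, df[[1L]], map)
}

#' Write / read the marker map as CSV
#'
#' Columns `marker`, `chrom`, `pos_cM` (genetic positions as floating-point
#' cM), ordered by (chrom, pos_cM).
#'
#' @param map data.frame or a `pgebv_geno`'s `$map`.
#' @param path file path.
#' @return `read_marker_map_csv` returns the map data.frame.
#' @export
write_marker_map_csv <- function(map, path) {
  if (inherits(map, "pgebv_geno")) map <- map$map
  write.csv(map[, c("marker", "chrom", "pos_cM")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_map_csv
#' @export
read_marker_map_csv <- function(path) {
  map <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("marker", "chrom", "pos_cM") %in% names(map)))
    stop("map CSV needs columns marker, chrom, pos_cM")
  if (is.unsorted(order(map$chrom, map$pos_cM)))
    map <- map[order(map$chrom, map$pos_cM), ]
  map
}

#' Write / read the plot table as CSV
#'
#' @param plots plot table (with or without reflectance columns).
#' @param path file path.
#' @return `read_plot_table_csv` returns the data.frame.
#' @export
write_plot_table_csv <- function(plots, path) {
  write.csv(as.data.frame(plots), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_plot_table_csv
#' @export
read_plot_table_csv <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write / read the BLUE table as CSV
#' @param blues a [build_blue_table()] result.
#' @param path file path.
#' @return `read_blue_table_csv` returns the data.frame.
#' @export
write_blue_table_csv <- function(blues, path) {
  write.csv(as.data.frame(blues), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_blue_table_csv
#' @export
read_blue_table_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  class(d) <- c("pgebv_blues", "data.frame")
  d
}

#' Write bin-map definition and bin calls as CSV
#'
#' @param binmap a `pgebv_binmap`.
#' @param bins_path,calls_path output paths.
#' @return invisibly, the paths.
#' @export
write_binmap_csv <- function(binmap, bins_path, calls_path) {
  write.csv(binmap$bins, bins_path, row.names = FALSE, na = "")
  calls <- binmap$bin_calls + 1L
  df <- data.frame(line = binmap$line_ids, calls, check.names = FALSE)
  write.csv(df, calls_path, row.names = FALSE, na = "")
  invisible(c(bins_path, calls_path))
}

#' Read a bin map from its two CSVs
#' @param bins_path,calls_path paths written by [write_binmap_csv()].
#' @return a `pgebv_binmap`.
#' @export
read_binmap_csv <- function(bins_path, calls_path) {
  bins <- read.csv(bins_path, stringsAsFactors = FALSE)
  df <- read.csv(calls_path, check.names = FALSE, stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(calls) <- "integer"
  calls <- calls - 1L
  rownames(calls) <- df[[1L]]
  structure(list(bins = bins, bin_calls = calls, line_ids = df[[1L]]),
            class = "pgebv_binmap")
}

#' Write the truth bundle as JSON
#' @param truth a `pgebv_truth`.
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(line_ids = truth$line_ids,
              genetic_values = as.list(truth$genetic_values),
              qtl = truth$qtl,
              genetic_variance = truth$genetic_variance)
  if (!is.null(truth$env_effects)) obj$env_effects <- as.list(truth$env_effects)
  if (!is.null(truth$gxe)) {
    obj$gxe <- as.data.frame(truth$gxe)
    obj$gxe$line <- rownames(truth$gxe)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- minimal VCF (GT-only, unphased) ---------------------------------------

#' Write a genotype matrix as a minimal VCF (GT-only)
#'
#' Biallelic sites, unphased GT field only (`0/0`, `1/1`, `0/1`, `./.`).
#' Positions are the cM map positions scaled to integer base pairs
#' (1 cM = 1e6 bp) purely to satisfy the coordinate column.
#'
#' @param geno a [geno_matrix()].
#' @param path output path (plain text).
#' @export
write_vcf_min <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$line_ids), collapse = "\t")),
             con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$calls))) {
    calls <- geno$calls[, j]
    tok <- ifelse(is.na(calls), "./.", gt[calls + 2L])
    writeLines(paste(c(geno$map$chrom[j],
                       max(1L, round(geno$map$pos_cM[j] * 1e6)),
                       geno$map$marker[j], "A", "T", ".", "PASS", ".", "GT",
                       tok), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a GT-only VCF
#'
#' Maps `0/0` to parent A, `1/1` to parent B, `0/1` (and `1/0`) to
#' heterozygous and `./.` to missing. Multi-allelic sites and malformed GT
#' tokens are rejected with the offending line and marker named. Requires
#' the vcfR package.
#'
#' @param path VCF path.
#' @return a [geno_matrix()].
#' @export
read_vcf_min <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi))
    stop(sum(multi), " multi-allelic site(s) rejected, e.g. ",
         fix[which(multi)[1L], "ID"])
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(tok, marker, line) {
    switch(tok,
           "0/0" = -1L, "0|0" = -1L,
           "1/1" = 1L, "1|1" = 1L,
           "0/1" = 0L, "1/0" = 0L, "0|1" = 0L, "1|0" = 0L,
           "./." = NA_integer_, "." = NA_integer_,
           stop("malformed GT token \"", tok, "\" at marker ", marker,
                ", line ", line))
  }
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt))
  for (j in seq_len(nrow(gt))) for (i in seq_len(ncol(gt))) {
    tok <- gt[j, i]
    calls[i, j] <- if (is.na(tok)) NA_integer_
                   else code(tok, fix[j, "ID"], colnames(gt)[i])
  }
  map <- data.frame(marker = fix[, "ID"],
                    chrom = as.integer(fix[, "CHROM"]),
                    pos_cM = as.numeric(fix[, "POS"]) / 1e6,
                    stringsAsFactors = FALSE)
  geno_matrix(calls, colnames(gt), map)
}

# ---- run configuration ------------------------------------------------------

#' Read a run configuration from YAML
#'
#' The YAML maps 1:1 onto [sim_config()] (block `sim`), learner
#' hyperparameter overrides (block `hyper`), and the CV block (`cv`:
#' `schemes`, `reps` — a count or `"paper"` —, `n_boot`, `seed`).
#'
#' @param path YAML path; `NULL` returns the default configuration.
#' @return list of class `pgebv_run_config` with elements `sim`
#'   (a `pgebv_config`), `hyper`, `cv`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  sim <- do.call(sim_config, raw$sim %||% list())
  cv <- raw$cv %||% list()
  cv$schemes <- cv$schemes %||% c("within_2fold", "across_LOEO")
  cv$reps <- cv$reps %||% 50L
  cv$n_boot <- cv$n_boot %||% 1000L
  cv$seed <- cv$seed %||% sim$seed
  structure(list(sim = sim, hyper = raw$hyper %||% list(), cv = cv),
            class = "pgebv_run_config")
}
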