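## Shared data model + readers/writers for the plain-text exchange formats.
## Conventions: region coordinates are stored 0-based half-open (BED); every
## user-facing region string is 1-based inclusive "chr:start-end" (en dash),
## matching how CGIs are conventionally printed.

GENE_CONTEXTS <- c("exon1", "gene_body", "upstream")

#' Render region labels in 1-based inclusive notation
#'
#' Converts internally stored 0-based half-open coordinates to the
#' conventional display form \code{"chr1:248020330–248021252"}
#' (1-based inclusive, en dash).
#'
#' @param regions A region table as returned by [read_regions_bed()].
#' @return Character vector of display labels, one per region.
#' @export
region_label <- function(regions) {
  sprintf("%s:%d–%d", regions$chrom, regions$start + 1L, regions$end)
}

validate_beta_values <- function(values, what = "beta matrix") {
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "%s: value %g outside [0, 1] at probe '%s', sample '%s'",
      what, values[bad[1, 1], bad[1, 2]],
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
    ), call. = FALSE)
  }
  invisible(values)
}

#' Read a probe-level beta-value matrix
#'
#' Expects a TSV with a header row of sample ids and a first column
#' \code{probe_id}; cells are beta-values in \[0, 1\], with empty cells or
#' \code{NA} marking missing measurements.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (probes x samples) with probe ids as row names.
#' @export
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = c("NA", ""))
  if (ncol(df) < 2) stop("beta matrix needs a probe_id column plus >= 1 sample column")
  probe_ids <- df[[1]]
  if (anyDuplicated(probe_ids)) {
    stop(sprintf("duplicate probe id(s): %s",
                 paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  rownames(mat) <- probe_ids
  validate_beta_values(mat)
  mat
}

#' Write a beta-value matrix
#'
#' Inverse of [read_beta_matrix()]; missing values are written as \code{NA}.
#'
#' @param beta Numeric probe x sample matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_values(beta)
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest
#'
#' TSV with columns \code{probe_id}, \code{chrom}, \code{pos} (1-based
#' coordinate of the interrogated CpG site).
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns probe_id, chrom, pos.
#' @export
read_probe_manifest <- function(path) {
  df <- read.delim(path, colClasses = c("character", "character", "integer"))
  validate_probe_manifest(df)
}

validate_probe_manifest <- function(df) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(df)))
  if (anyDuplicated(df$probe_id)) stop("probe manifest: duplicate probe ids", call. = FALSE)
  if (any(df$pos < 1)) stop("probe manifest: pos must be >= 1", call. = FALSE)
  if (any(!nzchar(df$chrom))) stop("probe manifest: empty chrom", call. = FALSE)
  df
}

#' @rdname read_probe_manifest
#' @param manifest Probe manifest data.frame.
#' @export
write_probe_manifest <- function(manifest, path) {
  write.table(manifest[, c("probe_id", "chrom", "pos")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

normalize_context <- function(x) {
  key <- gsub("[ _]", "", tolower(x))
  out <- c(exon1 = "exon1", genebody = "gene_body", upstream = "upstream")[key]
  if (anyNA(out[!is.na(x)])) {
    stop(sprintf("unknown gene_context token(s): %s",
                 paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", ")),
         call. = FALSE)
  }
  unname(out)
}

#' Read CGI region definitions from BED
#'
#' BED coordinates (0-based half-open) are kept internally; [region_label()]
#' renders the 1-based inclusive display form. Optional columns: 4 = region
#' name (defaults to the display label), 5 = associated gene symbol, 6 = gene
#' context, one of \code{exon1}, \code{gene_body}, \code{upstream}
#' (case/space insensitive).
#'
#' @param path Path to the BED file.
#' @return data.frame with columns region_id, chrom, start, end, gene,
#'   gene_context.
#' @export
read_regions_bed <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   na.strings = c("NA", "", "."))
  if (ncol(df) < 3) stop("BED needs at least chrom/start/end columns")
  regions <- data.frame(
    chrom = df[[1]],
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    stringsAsFactors = FALSE
  )
  if (any(regions$start >= regions$end)) {
    stop("region with start >= end (empty or inverted interval)", call. = FALSE)
  }
  regions$region_id <- if (ncol(df) >= 4) df[[4]] else region_label(regions)
  regions$region_id[is.na(regions$region_id)] <- region_label(regions)[is.na(regions$region_id)]
  regions$gene <- if (ncol(df) >= 5) df[[5]] else NA_character_
  regions$gene_context <- if (ncol(df) >= 6) normalize_context(df[[6]]) else NA_character_
  if (anyDuplicated(regions$region_id)) {
    stop(sprintf("duplicate region id(s): %s",
                 paste(unique(regions$region_id[duplicated(regions$region_id)]), collapse = ", ")),
         call. = FALSE)
  }
  regions[, c("region_id", "chrom", "start", "end", "gene", "gene_context")]
}

#' @rdname read_regions_bed
#' @param regions Region table.
#' @export
write_regions_bed <- function(regions, path) {
  out <- data.frame(regions$chrom, regions$start, regions$end, regions$region_id,
                    ifelse(is.na(regions$gene), ".", regions$gene),
                    ifelse(is.na(regions$gene_context), ".", regions$gene_context))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a paired tumor/normal sample sheet
#'
#' TSV with columns \code{patient_id}, \code{tumor_sample},
#' \code{normal_sample}, \code{smoking_status} (\code{S} smoker /
#' \code{NS} never-smoker).
#'
#' @param path Path to the TSV file.
#' @return data.frame of patient-matched pairs.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, colClasses = "character")
  validate_design(df)
}

validate_design <- function(design) {
  stopifnot(all(c("patient_id", "tumor_sample", "normal_sample", "smoking_status") %in% names(design)))
  if (any(design$tumor_sample == design$normal_sample)) {
    stop("pair with identical tumor and normal sample id", call. = FALSE)
  }
  all_samples <- c(design$tumor_sample, design$normal_sample)
  if (anyDuplicated(all_samples)) {
    stop(sprintf("sample(s) appearing in more than one pair: %s",
                 paste(unique(all_samples[duplicated(all_samples)]), collapse = ", ")),
         call. = FALSE)
  }
  if (!all(design$smoking_status %in% c("S", "NS"))) {
    stop("smoking_status must be 'S' or 'NS'", call. = FALSE)
  }
  design
}

## Error early if a design references samples absent from a data matrix/table.
check_design_samples <- function(design, sample_ids) {
  orphans <- setdiff(c(design$tumor_sample, design$normal_sample), sample_ids)
  if (length(orphans) > 0) {
    stop(sprintf("design references sample(s) absent from the data: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  invisible(design)
}

#' @rdname read_sample_sheet
#' @param design Paired design data.frame.
#' @export
write_sample_sheet <- function(design, path) {
  write.table(design[, c("patient_id", "tumor_sample", "normal_sample", "smoking_status")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

EXPR_CONTEXTS <- c("tumor", "normal_pair", "cell_line", "normal_reference",
                   "treated", "vehicle")

#' Read a gene-level relative-expression table
#'
#' TSV with columns \code{gene}, \code{sample}, \code{context} (one of
#' \code{tumor}, \code{normal_pair}, \code{cell_line},
#' \code{normal_reference}, \code{treated}, \code{vehicle}) and
#' \code{rel_expr} (non-negative, expression normalized to a reference gene,
#' e.g. GAPDH).
#'
#' @param path Path to the TSV file.
#' @return data.frame of expression records.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, colClasses = c("character", "character", "character", "numeric"))
  validate_expression(df)
}

validate_expression <- function(expr) {
  stopifnot(all(c("gene", "sample", "context", "rel_expr") %in% names(expr)))
  if (!all(expr$context %in% EXPR_CONTEXTS)) {
    stop(sprintf("unknown expression context(s): %s",
                 paste(setdiff(unique(expr$context), EXPR_CONTEXTS), collapse = ", ")),
         call. = FALSE)
  }
  if (any(expr$rel_expr < 0, na.rm = TRUE)) stop("rel_expr must be >= 0", call. = FALSE)
  key <- paste(expr$gene, expr$sample, expr$context)
  if (anyDuplicated(key)) stop("duplicate (gene, sample, context) record", call. = FALSE)
  expr
}

#' @rdname read_expression
#' @param expr Expression table.
#' @export
write_expression <- function(expr, path) {
  write.table(expr[, c("gene", "sample", "context", "rel_expr")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site-level percent-methylation table
#'
#' Pyrosequencing-style readout: TSV with columns \code{site_id},
#' \code{sample}, \code{percent_meth} in \[0, 100\].
#'
#' @param path Path to the TSV file.
#' @return data.frame of site-level records.
#' @export
read_site_methylation <- function(path) {
  df <- read.delim(path, colClasses = c("character", "character", "numeric"))
  validate_site_methylation(df)
}

validate_site_methylation <- function(sites) {
  stopifnot(all(c("site_id", "sample", "percent_meth") %in% names(sites)))
  if (any(sites$percent_meth < 0 | sites$percent_meth > 100, na.rm = TRUE)) {
    stop("percent_meth must lie in [0, 100]", call. = FALSE)
  }
  sites
}

#' @rdname read_site_methylation
#' @param sites Site methylation table.
#' @export
write_site_methylation <- function(sites, path) {
  write.table(sites[, c("site_id", "sample", "percent_meth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a printed gene-evidence matrix
#'
#' Reads the funnel evidence format used for published candidate tables: one
#' row per gene with columns \code{gene}, \code{gene_context},
#' \code{normal_expression} (\code{expressed} / \code{very_low}) and fraction
#' columns \code{tumor_fraction}, \code{cell_fraction},
#' \code{restore_fraction} holding strings like \code{"8/11"}, \code{"-"}
#' (not evaluated), optionally with an extended-panel annotation such as
#' \code{"10/11 (36/37)"} that is retained as metadata only.
#'
#' @param path Path to the TSV file.
#' @return data.frame with parsed integer columns \code{tumor_k},
#'   \code{tumor_n}, \code{cell_k}, \code{cell_n}, \code{restore_k},
#'   \code{restore_n} plus \code{extended_annotation}.
#' @export
read_evidence <- function(path) {
  df <- read.delim(path, colClasses = "character")
  stopifnot(all(c("gene", "normal_expression", "tumor_fraction",
                  "cell_fraction", "restore_fraction") %in% names(df)))
  if (!all(df$normal_expression %in% c("expressed", "very_low"))) {
    stop("normal_expression must be 'expressed' or 'very_low'", call. = FALSE)
  }
  parse_fraction <- function(x) {
    core <- sub("\\s*\\(.*\\)\\s*$", "", trimws(x))
    k <- n <- rep(NA_integer_, length(x))
    ok <- grepl("^\\d+/\\d+$", core)
    k[ok] <- as.integer(sub("/.*", "", core[ok]))
    n[ok] <- as.integer(sub(".*/", "", core[ok]))
    bad <- !ok & core != "-"
    if (any(bad)) stop(sprintf("unparseable fraction: %s", x[bad][1]), call. = FALSE)
    if (any(k[ok] > n[ok])) stop("fraction with k > n", call. = FALSE)
    list(k = k, n = n)
  }
  tf <- parse_fraction(df$tumor_fraction)
  cf <- parse_fraction(df$cell_fraction)
  rf <- parse_fraction(df$restore_fraction)
  ext <- regmatches(df$tumor_fraction, regexpr("\\(.*\\)", df$tumor_fraction))
  extended <- rep(NA_character_, nrow(df))
  extended[grepl("\\(", df$tumor_fraction)] <- gsub("[()]", "", ext)
  data.frame(
    gene = df$gene,
    gene_context = if ("gene_context" %in% names(df)) df$gene_context else NA_character_,
    normal_expression = df$normal_expression,
    tumor_k = tf$k, tumor_n = tf$n,
    cell_k = cf$k, cell_n = cf$n,
    restore_k = rf$k, restore_n = rf$n,
    extended_annotation = extended,
    stringsAsFactors = FALSE
  )
}
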