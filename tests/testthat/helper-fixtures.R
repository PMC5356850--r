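# Small in-code fixtures shared across test files.

tiny_beta <- function() {
  m <- matrix(c(0.10, 0.50,
                0.20, 0.60,
                0.90, 0.30), nrow = 3, byrow = TRUE,
              dimnames = list(c("cg000001", "cg000002", "cg000003"),
                              c("T01", "N01")))
  m
}

tiny_design <- function(n = 2) {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    tumor_sample = sprintf("T%02d", seq_len(n)),
    normal_sample = sprintf("N%02d", seq_len(n)),
    smoking_status = rep(c("S", "NS"), length.out = n),
    stringsAsFactors = FALSE
  )
}

# Minimal expression table for one gene with configurable panel values.
gene_expr <- function(gene = "G1",
                      tumor = NULL, normal = NULL,
                      cell = NULL, reference = 1,
                      treated = NULL, vehicle = NULL) {
  rows <- list()
  if (!is.null(tumor)) {
    rows <- c(rows, list(
      data.frame(gene = gene, sample = sprintf("P%02d", seq_along(tumor)),
                 context = "tumor", rel_expr = tumor),
      data.frame(gene = gene, sample = sprintf("P%02d", seq_along(normal)),
                 context = "normal_pair", rel_expr = normal)))
  }
  if (!is.null(cell)) {
    rows <- c(rows, list(
      data.frame(gene = gene, sample = sprintf("CL%02d", seq_along(cell)),
                 context = "cell_line", rel_expr = cell)))
  }
  if (!is.null(reference)) {
    rows <- c(rows, list(
      data.frame(gene = gene, sample = "NormalLung",
                 context = "normal_reference", rel_expr = reference)))
  }
  if (!is.null(treated)) {
    rows <- c(rows, list(
      data.frame(gene = gene, sample = sprintf("CL%02d", seq_along(treated)),
                 context = "treated", rel_expr = treated),
      data.frame(gene = gene, sample = sprintf("CL%02d", seq_along(vehicle)),
                 context = "vehicle", rel_expr = vehicle)))
  }
  do.call(rbind, rows)
}

evidence_fixture_path <- function() {
  system.file("extdata", "published_candidate_evidence.tsv", package = "cgiscreen")
}
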