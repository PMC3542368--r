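#' Read a MAF-dialect somatic mutation file into a binary matrix
#'
#' Reads a tab-separated per-mutation table with (at least) the columns
#' `Hugo_Symbol`, `Tumor_Sample_Barcode` and `Variant_Classification`, and
#' builds the patients x genes binary incidence matrix: a cell is 1 when the
#' patient carries at least one somatic mutation in the gene, so multiple
#' mutation rows for the same (sample, gene) collapse to a single 1.
#'
#' TCGA-style sample barcodes are truncated to patient identifiers by keeping
#' the first `patient_id_tokens` dash-delimited tokens (e.g.
#' `TCGA-04-1331-01A` -> `TCGA-04-1331`).
#'
#' @param path Path to the tab-separated mutation file.
#' @param patient_id_tokens Number of leading dash-delimited barcode tokens
#'   that form the patient identifier (default 3, the TCGA convention).
#' @param exclude_silent Drop rows whose `Variant_Classification` is
#'   `"Silent"` before building the matrix (default `FALSE`: the incidence
#'   matrix counts every reported somatic mutation).
#' @return Integer patients x genes matrix with 0/1 entries; rows and columns
#'   sorted by identifier.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
#'              "TP53\tTCGA-01-0001-01A\tMissense_Mutation",
#'              "BRCA2\tTCGA-01-0002-01A\tNonsense_Mutation"), f)
#' read_maf(f)
#' @export
read_maf <- function(path, patient_id_tokens = 3L, exclude_silent = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  maf <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  required <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing_cols <- setdiff(required, names(maf))
  if (length(missing_cols)) {
    stop(sprintf("mutation file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(maf) == 0L) stop("mutation file contains no mutation rows", call. = FALSE)
  if (isTRUE(exclude_silent)) {
    maf <- maf[maf$Variant_Classification != "Silent", , drop = FALSE]
    if (nrow(maf) == 0L) stop("no mutation rows left after excluding silent variants",
                              call. = FALSE)
  }
  pid <- vapply(strsplit(maf$Tumor_Sample_Barcode, "-", fixed = TRUE),
                function(tok) paste(tok[seq_len(min(length(tok), patient_id_tokens))],
                                    collapse = "-"),
                character(1))
  patients <- sort(unique(pid))
  genes <- sort(unique(maf$Hugo_Symbol))
  X <- matrix(0L, nrow = length(patients), ncol = length(genes),
              dimnames = list(patients, genes))
  X[cbind(match(pid, patients), match(maf$Hugo_Symbol, genes))] <- 1L
  X
}

#' Read a clinical tab-separated table
#'
#' Expects one row per patient with columns `patient_id`, `os_months`,
#' `os_event`, `pfs_months`, `pfs_event`, `age_gt60`, `grade`, `stage`,
#' `residual`, `platinum`. Missing values may be empty or `NA`. Categorical
#' columns are checked against their admissible levels (grade 2/3, stage
#' 2/3/4, residual microscopic/macroscopic, platinum sensitive/resistant).
#'
#' @param path Path to the tab-separated clinical file.
#' @return data.frame with one row per patient.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cl <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   na.strings = c("NA", ""))
  required <- c("patient_id", "os_months", "os_event", "pfs_months", "pfs_event",
                "age_gt60", "grade", "stage", "residual", "platinum")
  missing_cols <- setdiff(required, names(cl))
  if (length(missing_cols)) {
    stop(sprintf("clinical file is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(cl$patient_id)) {
    stop("clinical file has duplicate patient IDs", call. = FALSE)
  }
  check_levels <- function(col, levels) {
    bad <- !is.na(cl[[col]]) & !(cl[[col]] %in% levels)
    if (any(bad)) {
      stop(sprintf("clinical column `%s` has values outside {%s}", col,
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
  }
  check_levels("age_gt60", c(0L, 1L))
  check_levels("grade", c(2L, 3L))
  check_levels("stage", c(2L, 3L, 4L))
  check_levels("residual", c("microscopic", "macroscopic"))
  check_levels("platinum", c("sensitive", "resistant"))
  cl
}

#' Drop rarely mutated genes
#'
#' Retains exactly the genes mutated in at least `min_mutated_patients`
#' distinct patients; the patient set is unchanged. The default threshold of
#' 5 removes "very rarely mutated" genes before model building. "Frequency"
#' is the number of distinct mutated patients, not the raw mutation count:
#' the incidence matrix is binary.
#'
#' @param matrix Patients x genes binary matrix (see [read_maf()]).
#' @param min_mutated_patients Minimum number of mutated patients (>= 1).
#' @return The filtered matrix (possibly with zero gene columns, with a
#'   warning).
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 1, 0), nrow = 3,
#'             dimnames = list(paste0("P", 1:3), c("A", "B")))
#' filter_rare_genes(m, min_mutated_patients = 2)
#' @export
filter_rare_genes <- function(matrix, min_mutated_patients = 5L) {
  check_mutation_matrix(matrix)
  if (min_mutated_patients < 1) {
    stop("`min_mutated_patients` must be at least 1", call. = FALSE)
  }
  keep <- colSums(matrix) >= min_mutated_patients
  if (!any(keep)) {
    warning("no genes pass the rare-gene filter; returning a zero-column matrix")
  }
  matrix[, keep, drop = FALSE]
}

#' Align the mutation matrix with clinical outcomes for one endpoint
#'
#' Drops patients missing the chosen endpoint's follow-up time or event
#' indicator, restricts all tables to the common patient set in a single
#' canonical order (the clinical table's order), and assembles the
#' [surv_outcome] for that endpoint. Patients present in the clinical table
#' but absent from the mutation file (i.e. carrying no reported mutation) are
#' retained with an all-zero mutation row when `zero_fill = TRUE` (default).
#'
#' @param matrix Patients x genes binary matrix.
#' @param clinical Clinical data.frame from [read_clinical()] (or the
#'   `clinical` element of a synthetic cohort).
#' @param endpoint `"OS"` (overall survival) or `"PFS"` (progression-free
#'   survival).
#' @param zero_fill Keep clinical patients missing from the mutation matrix
#'   as all-zero rows (default `TRUE`); when `FALSE`, such patients are
#'   dropped.
#' @return List with elements `mutations` (matrix), `outcome`
#'   ([surv_outcome]) and `clinical` (data.frame), all in one patient order.
#' @export
align_cohort <- function(matrix, clinical, endpoint = c("OS", "PFS"),
                         zero_fill = TRUE) {
  endpoint <- match.arg(endpoint)
  check_mutation_matrix(matrix)
  tcol <- if (endpoint == "OS") "os_months" else "pfs_months"
  ecol <- if (endpoint == "OS") "os_event" else "pfs_event"
  keep <- !is.na(clinical[[tcol]]) & !is.na(clinical[[ecol]])
  cl <- clinical[keep, , drop = FALSE]
  if (!zero_fill) cl <- cl[cl$patient_id %in% rownames(matrix), , drop = FALSE]
  if (nrow(cl) == 0L) {
    stop("no patients with both mutation data and the chosen endpoint", call. = FALSE)
  }
  X <- matrix(0L, nrow = nrow(cl), ncol = ncol(matrix),
                  dimnames = list(cl$patient_id, colnames(matrix)))
  present <- cl$patient_id %in% rownames(matrix)
  if (!any(present)) {
    stop("no overlap between mutation and clinical patient IDs", call. = FALSE)
  }
  X[present, ] <- matrix[cl$patient_id[present], , drop = FALSE]
  rownames(cl) <- NULL
  list(mutations = X,
       outcome = surv_outcome(cl[[tcol]], cl[[ecol]], cl$patient_id),
       clinical = cl)
}
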