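#' Construct a two-channel protein quantification table
#'
#' Holds per-replicate linear intensities for the experiment (medium label)
#' and control (light label) channels plus unique-peptide counts, the input
#' to the enrichment filter. Missing intensities are NA.
#'
#' @param accession character vector of protein accessions
#' @param intensities_exp,intensities_ctl numeric matrices
#'   (proteins x replicates), non-negative or NA
#' @param unique_peptides integer matrix (proteins x replicates)
#' @return object of class `quant_table`
#' @export
quant_table <- function(accession, intensities_exp, intensities_ctl,
                        unique_peptides) {
  intensities_exp <- as.matrix(intensities_exp)
  intensities_ctl <- as.matrix(intensities_ctl)
  unique_peptides <- as.matrix(unique_peptides)
  stopifnot(length(accession) == nrow(intensities_exp),
            nrow(intensities_exp) == nrow(intensities_ctl),
            nrow(intensities_exp) == nrow(unique_peptides),
            ncol(intensities_exp) == ncol(intensities_ctl))
  if (any(intensities_exp < 0, na.rm = TRUE) ||
      any(intensities_ctl < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(accession = as.character(accession),
                 intensities_exp = intensities_exp,
                 intensities_ctl = intensities_ctl,
                 unique_peptides = unique_peptides),
            class = "quant_table")
}

#' Enrichment filter criteria
#'
#' Defaults implement the compound call used for proximity-labeling hits:
#' fold change greater than 5, p below 0.01, and at least 2 unique peptides
#' in at least 2 replicates.
#'
#' @param min_fold_change fold-change threshold (exceeded strictly)
#' @param max_p p-value threshold (strict)
#' @param min_unique_peptides peptides needed for a replicate to count
#' @param min_replicates_with_peptides replicates that must reach it
#' @return object of class `filter_criteria`
#' @export
filter_criteria <- function(min_fold_change = 5, max_p = 0.01,
                            min_unique_peptides = 2L,
                            min_replicates_with_peptides = 2L) {
  stopifnot(min_fold_change > 0, max_p > 0,
            min_unique_peptides > 0, min_replicates_with_peptides > 0)
  structure(list(min_fold_change = min_fold_change, max_p = max_p,
                 min_unique_peptides = as.integer(min_unique_peptides),
                 min_replicates_with_peptides = as.integer(min_replicates_with_peptides)),
            class = "filter_criteria")
}

.impute_min_matrix <- function(m, what) {
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(is.na(col))) {
      stop(sprintf("%s replicate column %d is fully missing; minimum imputation undefined",
                   what, j), call. = FALSE)
    }
    col[is.na(col)] <- min(col, na.rm = TRUE)
    m[, j] <- col
  }
  m
}

#' Deterministic minimum imputation of missing intensities
#'
#' Replaces each missing value by the minimum observed value of its
#' replicate column (scope = "column", the default reading of per-dataset
#' minimum imputation) or of its protein row (scope = "row"). Idempotent.
#'
#' @param table a `quant_table`
#' @param scope "column" or "row"
#' @return an imputed `quant_table`
#' @export
impute_min <- function(table, scope = c("column", "row")) {
  scope <- match.arg(scope)
  stopifnot(inherits(table, "quant_table"))
  if (scope == "column") {
    table$intensities_exp <- .impute_min_matrix(table$intensities_exp, "experiment")
    table$intensities_ctl <- .impute_min_matrix(table$intensities_ctl, "control")
  } else {
    both <- cbind(table$intensities_exp, table$intensities_ctl)
    ne <- ncol(table$intensities_exp)
    for (i in seq_len(nrow(both))) {
      row <- both[i, ]
      if (all(is.na(row))) {
        stop(sprintf("protein %s has no observed intensity; minimum imputation undefined",
                     table$accession[i]), call. = FALSE)
      }
      row[is.na(row)] <- min(row, na.rm = TRUE)
      both[i, ] <- row
    }
    table$intensities_exp <- both[, seq_len(ne), drop = FALSE]
    table$intensities_ctl <- both[, -seq_len(ne), drop = FALSE]
  }
  table
}

#' Per-protein fold change and t-test
#'
#' Fold change is the ratio of channel means on linear intensities; the
#' p-value comes from an unpaired two-tailed equal-variance Student's
#' t-test on log2 intensities. Zero-variance (degenerate) comparisons with
#' unequal means are reported as p = 0 with `degenerate = TRUE` rather than
#' a silent infinity.
#'
#' @param table an imputed `quant_table` (no NAs; call [impute_min()] first)
#' @return data.frame: accession, fold_change, log2_fc, p_value, degenerate
#' @export
protein_stats <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (anyNA(table$intensities_exp) || anyNA(table$intensities_ctl)) {
    stop("table contains missing values; run impute_min() first", call. = FALSE)
  }
  if (ncol(table$intensities_exp) < 2L || ncol(table$intensities_ctl) < 2L) {
    stop("at least 2 replicates per channel are required", call. = FALSE)
  }
  n <- length(table$accession)
  fc <- p <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    e <- table$intensities_exp[i, ]
    c0 <- table$intensities_ctl[i, ]
    if (mean(c0) == 0) {
      stop(sprintf("protein %s: zero control mean, fold change undefined",
                   table$accession[i]), call. = FALSE)
    }
    fc[i] <- mean(e) / mean(c0)
    le <- log2(e); lc <- log2(c0)
    if (stats::sd(le) == 0 && stats::sd(lc) == 0) {
      degen[i] <- TRUE
      p[i] <- if (isTRUE(all.equal(mean(le), mean(lc)))) 1 else 0
    } else {
      p[i] <- stats::t.test(le, lc, var.equal = TRUE)$p.value
    }
  }
  data.frame(accession = table$accession, fold_change = fc,
             log2_fc = log2(fc), p_value = p, degenerate = degen,
             stringsAsFactors = FALSE)
}

#' Apply the compound enrichment filter
#'
#' A protein is called enriched iff its fold change strictly exceeds
#' `min_fold_change`, its p-value is strictly below `max_p`, and at least
#' `min_replicates_with_peptides` replicates identified at least
#' `min_unique_peptides` unique peptides. Benjamini-Hochberg FDR is
#' computed and reported; with `strict_fdr = TRUE` it replaces the raw
#' p-value in the call (FDR < `max_p`).
#'
#' @param stats data.frame from [protein_stats()]
#' @param table the matching `quant_table` (for peptide counts)
#' @param criteria a [filter_criteria()] object
#' @param strict_fdr gate on BH FDR instead of raw p
#' @return object of class `enrichment_result`: `records` data.frame
#'   (accession, fold_change, log2_fc, p_value, bh_fdr, passes) and
#'   `enriched_set` (character vector)
#' @export
apply_filters <- function(stats, table, criteria = filter_criteria(),
                          strict_fdr = FALSE) {
  stopifnot(identical(stats$accession, table$accession))
  bh <- stats::p.adjust(stats$p_value, method = "BH")
  pep_ok <- rowSums(table$unique_peptides >= criteria$min_unique_peptides) >=
    criteria$min_replicates_with_peptides
  p_used <- if (strict_fdr) bh else stats$p_value
  passes <- stats$fold_change > criteria$min_fold_change &
    p_used < criteria$max_p & pep_ok
  records <- data.frame(
    accession = stats$accession,
    fold_change = stats$fold_change,
    log2_fc = stats$log2_fc,
    p_value = stats$p_value,
    bh_fdr = bh,
    peptide_support = pep_ok,
    passes = passes,
    stringsAsFactors = FALSE
  )
  structure(list(records = records,
                 enriched_set = stats$accession[passes],
                 criteria = criteria),
            class = "enrichment_result")
}

#' Read a quantification CSV
#'
#' Expects columns `accession`, `exp_rep1..n`, `ctl_rep1..n`,
#' `pep_rep1..n`; empty cells are missing intensities.
#'
#' @param path CSV path
#' @return a `quant_table`
#' @export
read_quant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  exp_cols <- grep("^exp_rep", names(df), value = TRUE)
  ctl_cols <- grep("^ctl_rep", names(df), value = TRUE)
  pep_cols <- grep("^pep_rep", names(df), value = TRUE)
  if (length(exp_cols) == 0L || length(ctl_cols) == 0L) {
    stop("quant CSV must contain exp_rep*/ctl_rep* columns", call. = FALSE)
  }
  quant_table(df$accession,
              as.matrix(df[exp_cols]),
              as.matrix(df[ctl_cols]),
              as.matrix(df[pep_cols]))
}

#' Write a quantification table as CSV
#'
#' @param table a `quant_table`
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_quant_table <- function(table, path) {
  ne <- ncol(table$intensities_exp)
  np <- ncol(table$unique_peptides)
  df <- data.frame(accession = table$accession, stringsAsFactors = FALSE)
  for (j in seq_len(ne)) df[[paste0("exp_rep", j)]] <- table$intensities_exp[, j]
  for (j in seq_len(ne)) df[[paste0("ctl_rep", j)]] <- table$intensities_ctl[, j]
  for (j in seq_len(np)) df[[paste0("pep_rep", j)]] <- table$unique_peptides[, j]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the volcano table and enriched list
#'
#' @param result an `enrichment_result`
#' @param csv_path volcano CSV path (accession, log2_fc, minus_log10_p,
#'   bh_fdr, passes)
#' @param txt_path enriched-accession list path (one per line)
#' @return invisibly, a list of the two paths
#' @export
export_enrichment <- function(result, csv_path, txt_path = NULL) {
  r <- result$records
  out <- data.frame(accession = r$accession, log2_fc = r$log2_fc,
                    minus_log10_p = -log10(pmax(r$p_value, .Machine$double.xmin)),
                    bh_fdr = r$bh_fdr, passes = r$passes,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) writeLines(result$enriched_set, txt_path)
  invisible(list(csv = csv_path, txt = txt_path))
}
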