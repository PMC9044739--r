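#' Roll up one precursor from its transition areas
#'
#' Peptide-precursor quantity is the summed area of the four most prominent
#' transitions; when fewer than four are observed, all observed transitions
#' are summed. Ties at the fourth-largest area are broken by lexicographic
#' `transition_id` so the roll-up is deterministic.
#'
#' @param areas numeric vector of transition areas (NA = missing).
#' @param transition_ids optional ids used only to break ties.
#' @param n_top number of transitions summed (default 4).
#' @return the precursor quantity, or `NA` if every area is missing.
#' @export
rollup_precursor <- function(areas, transition_ids = NULL, n_top = 4L) {
  if (is.null(transition_ids)) transition_ids <- as.character(seq_along(areas))
  stopifnot(length(areas) == length(transition_ids))
  ok <- !is.na(areas)
  if (!any(ok)) return(NA_real_)
  if (any(areas[ok] < 0)) stopf("transition areas must be non-negative")
  a <- areas[ok]
  id <- transition_ids[ok]
  ord <- order(-a, id)
  sum(a[ord[seq_len(min(n_top, length(a)))]])
}

#' Roll up one protein from its precursor quantities
#'
#' Protein quantity is the sum of all available peptide-precursor
#' quantities; missing precursors are skipped and a protein with no
#' observed precursor stays missing (never zero).
#'
#' @param precursor_quantities numeric vector (NA = missing).
#' @return the protein quantity or `NA`.
#' @export
rollup_protein <- function(precursor_quantities) {
  ok <- !is.na(precursor_quantities)
  if (!any(ok)) return(NA_real_)
  sum(precursor_quantities[ok])
}

#' Build a samples-by-proteins quantity table from a transition report
#'
#' Applies the two-stage roll-up to a transition-level report: transitions
#' are summed to precursor quantities (top four per precursor, per sample),
#' then precursor quantities are summed to protein quantities. Distinct
#' charge states of the same peptide are distinct precursors. The result
#' carries a per-cell state flag (`raw`, `normalized`, `imputed`) and the
#' id of the spike-in normalizer.
#'
#' @param transitions data.frame with columns `sample_id`, `protein`,
#'   `peptide`, `precursor_charge`, `transition_id`, `area` (or the names
#'   given in `col_map`).
#' @param col_map named character vector mapping the canonical column names
#'   to the ones present in `transitions`, so transition-report exports
#'   with other headers can be ingested directly.
#' @param reference_proteins protein ids treated as spike-in/QC references.
#' @param n_top transitions summed per precursor.
#' @return a `quant_table` object.
#' @export
quantify_proteins <- function(transitions,
                              col_map = c(sample_id = "sample_id",
                                          protein = "protein",
                                          peptide = "peptide",
                                          precursor_charge = "precursor_charge",
                                          transition_id = "transition_id",
                                          area = "area"),
                              reference_proteins = "A1AG_BOVIN",
                              n_top = 4L) {
  need <- c("sample_id", "protein", "peptide", "precursor_charge",
            "transition_id", "area")
  miss <- setdiff(need, names(col_map))
  if (length(miss)) stopf("col_map lacks: %s", paste(miss, collapse = ", "))
  absent <- setdiff(unname(col_map[need]), names(transitions))
  if (length(absent))
    stopf("transition report lacks column(s): %s",
          paste(absent, collapse = ", "))

  dt <- data.table::as.data.table(transitions)
  data.table::setnames(dt, unname(col_map[need]), need)
  if (anyDuplicated(dt, by = c("sample_id", "protein", "peptide",
                               "precursor_charge", "transition_id")))
    stopf("duplicate (sample, protein, peptide, charge, transition) rows")
  if (any(dt$area < 0, na.rm = TRUE))
    stopf("transition areas must be non-negative")

  area <- transition_id <- protein <- NULL # appease R CMD check
  prec <- dt[, .(q = rollup_precursor(area, transition_id, n_top)),
             by = .(sample_id, protein, peptide, precursor_charge)]
  protq <- prec[, .(q = rollup_protein(q)), by = .(sample_id, protein)]

  samples <- sort(unique(dt$sample_id))
  proteins <- sort(unique(dt$protein))
  mat <- matrix(NA_real_, length(samples), length(proteins),
                dimnames = list(samples, proteins))
  mat[cbind(match(protq$sample_id, samples),
            match(protq$protein, proteins))] <- protq$q
  new_quant_table(mat, state = "raw",
                  reference_proteins = intersect(reference_proteins,
                                                 proteins))
}

new_quant_table <- function(mat, state, reference_proteins = character(),
                            normalizer_id = NA_character_,
                            state_matrix = NULL) {
  if (is.null(state_matrix)) {
    state_matrix <- matrix(state, nrow(mat), ncol(mat),
                           dimnames = dimnames(mat))
    state_matrix[is.na(mat)] <- NA_character_
  }
  structure(list(mat = mat, state = state_matrix,
                 reference_proteins = reference_proteins,
                 normalizer_id = normalizer_id),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d samples x %d proteins (%s)\n",
              nrow(x$mat), ncol(x$mat),
              if (is.na(x$normalizer_id)) "raw"
              else paste0("normalized to ", x$normalizer_id)))
  nm <- sum(is.na(x$mat))
  cat(sprintf("  missing cells: %d (%.1f%%); reference/QC columns: %s\n",
              nm, 100 * nm / length(x$mat),
              if (length(x$reference_proteins))
                paste(x$reference_proteins, collapse = ", ") else "none"))
  invisible(x)
}

#' Samples and proteins of a quantity table
#' @param x a `quant_table`.
#' @return character vector of ids.
#' @export
quant_samples <- function(x) rownames(x$mat)

#' @rdname quant_samples
#' @export
quant_proteins <- function(x) colnames(x$mat)

#' Candidate (non-reference) proteins of a quantity table
#' @param x a `quant_table`.
#' @export
candidate_proteins <- function(x)
  setdiff(colnames(x$mat), x$reference_proteins)

#' Normalize protein quantities to a spike-in reference
#'
#' Divides every protein quantity by the sample's quantity of the spike-in
#' normalizer, removing per-sample processing variation. The normalizer
#' column becomes identically 1. Fails loudly, naming the sample, if the
#' normalizer is missing or non-positive anywhere. Normalizing an
#' already-normalized table with the same reference is a no-op.
#'
#' @param x a `quant_table`.
#' @param normalizer_id protein id of the spike-in reference.
#' @return the normalized `quant_table`.
#' @export
normalize_to_reference <- function(x, normalizer_id = "A1AG_BOVIN") {
  stopifnot(inherits(x, "quant_table"))
  if (!normalizer_id %in% colnames(x$mat))
    stopf("normalizer '%s' not in table", normalizer_id)
  ref <- x$mat[, normalizer_id]
  bad <- which(is.na(ref) | ref <= 0)
  if (length(bad))
    stopf("normalizer '%s' missing or non-positive in sample(s): %s",
          normalizer_id, paste(rownames(x$mat)[bad], collapse = ", "))
  mat <- sweep(x$mat, 1, ref, "/")
  state <- x$state
  state[!is.na(mat)] <- "normalized"
  new_quant_table(mat, reference_proteins = x$reference_proteins,
                  normalizer_id = normalizer_id, state_matrix = state)
}

#' Write / read a protein quantity matrix as delimited text
#'
#' Samples are rows; the first column is `sample_id`. Missing quantities
#' are written as `NA`.
#'
#' @param x a `quant_table`.
#' @param path file path.
#' @return `path`, invisibly (writer); a `quant_table` (reader).
#' @export
write_quant_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x$mat), x$mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_table
#' @param reference_proteins spike-in/QC columns of the stored matrix.
#' @param normalizer_id normalizer id if the stored matrix is normalized.
#' @export
read_quant_table <- function(path, reference_proteins = "A1AG_BOVIN",
                             normalizer_id = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$sample_id
  state <- if (is.na(normalizer_id)) "raw" else "normalized"
  new_quant_table(mat, state = state,
                  reference_proteins = intersect(reference_proteins,
                                                 colnames(mat)),
                  normalizer_id = normalizer_id)
}
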