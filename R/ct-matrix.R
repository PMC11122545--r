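#' Ct matrix container
#'
#' Holds raw qPCR threshold-cycle (Ct) values for a cohort: one row per
#' sample, one column per gene (targets plus housekeeping), a response
#' label per sample, and a mask flagging wells that never amplified
#' ("Undetermined"); masked wells carry a configurable ceiling Ct.
#'
#' @param ct numeric matrix (samples x genes) with rownames = sample ids
#'   and colnames = gene symbols.
#' @param group character/factor of per-sample labels, `"responder"` or
#'   `"non-responder"`.
#' @param panel optional [gene_panel()]; when given, all housekeeping genes
#'   must be present among the columns.
#' @param undetermined logical matrix of the same shape marking
#'   no-amplification wells (default: none).
#' @param undetermined_ct Ct ceiling stored in masked cells (default 35).
#' @return An object of class `ct_matrix`.
#' @export
ct_matrix <- function(ct, group, panel = NULL, undetermined = NULL,
                      undetermined_ct = 35) {
  if (!is.matrix(ct) || !is.numeric(ct)) {
    stop("ct must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop("ct must have sample ids as rownames and gene symbols as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(ct))) {
    stop("duplicate sample id: ",
         paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(ct))) {
    stop("duplicate gene column", call. = FALSE)
  }
  group <- as.character(group)
  if (length(group) != nrow(ct)) {
    stop("one group label per sample required", call. = FALSE)
  }
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown group label: ", paste(bad, collapse = ", "),
         " (expected 'responder' or 'non-responder')", call. = FALSE)
  }
  if (any(table(factor(group, levels = GROUP_LEVELS)) < 2L)) {
    stop("each response group needs at least 2 samples", call. = FALSE)
  }
  if (is.null(undetermined)) {
    undetermined <- matrix(FALSE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  }
  if (!identical(dim(undetermined), dim(ct))) {
    stop("undetermined mask must match ct dimensions", call. = FALSE)
  }
  if (any(!is.finite(ct[!undetermined]))) {
    stop("non-finite Ct value in an unmasked well", call. = FALSE)
  }
  if (!is.null(panel)) {
    missing_hk <- setdiff(panel$housekeeping, colnames(ct))
    if (length(missing_hk) > 0L) {
      stop("missing housekeeping gene: ", paste(missing_hk, collapse = ", "),
           call. = FALSE)
    }
  }
  names(group) <- rownames(ct)
  structure(
    list(ct = ct, group = group, undetermined = undetermined,
         undetermined_ct = undetermined_ct),
    class = "ct_matrix"
  )
}

#' Read a Ct matrix from CSV
#'
#' Expected dialect: comma-separated, dot decimal, one header row; first
#' column the sample id, second column the response group label, remaining
#' columns one gene each. Numeric cells are Ct values; the token
#' `"Undetermined"` marks a well with no amplification and is replaced by
#' the ceiling Ct while being flagged in the mask.
#'
#' @param path CSV file path.
#' @param panel [gene_panel()] used to validate housekeeping coverage.
#' @param undetermined_ct Ct assigned to masked wells (default 35).
#' @return A validated [ct_matrix()].
#' @export
read_ct_matrix <- function(path, panel, undetermined_ct = 35) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 3L) {
    stop("Ct CSV needs sample id, group and at least one gene column",
         call. = FALSE)
  }
  sample_ids <- raw[[1L]]
  group <- raw[[2L]]
  cells <- as.matrix(raw[, -(1:2), drop = FALSE])
  mask <- cells == "Undetermined"
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  if (any(is.na(vals) & !mask)) {
    stop("non-numeric Ct cell that is not 'Undetermined'", call. = FALSE)
  }
  vals[mask] <- undetermined_ct
  dimnames(vals) <- list(sample_ids, colnames(cells))
  dimnames(mask) <- dimnames(vals)
  ct_matrix(vals, group, panel = panel, undetermined = mask,
            undetermined_ct = undetermined_ct)
}

#' Write a Ct matrix to CSV
#'
#' Inverse of [read_ct_matrix()]: masked wells are written back as
#' `"Undetermined"`.
#'
#' @param x a [ct_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_matrix <- function(x, path) {
  stopifnot(inherits(x, "ct_matrix"))
  cells <- matrix(format(x$ct, trim = TRUE, digits = 15),
                  nrow(x$ct), ncol(x$ct), dimnames = dimnames(x$ct))
  cells[x$undetermined] <- "Undetermined"
  out <- data.frame(sample_id = rownames(x$ct), group = unname(x$group),
                    cells, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ct_matrix <- function(x, ...) {
  tab <- table(factor(x$group, levels = GROUP_LEVELS))
  cat(sprintf(
    "Ct matrix: %d samples (%d responders, %d non-responders) x %d genes; %d undetermined wells (ceiling Ct %.1f)\n",
    nrow(x$ct), tab[[RESPONDER]], tab[[NON_RESPONDER]], ncol(x$ct),
    sum(x$undetermined), x$undetermined_ct))
  invisible(x)
}
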