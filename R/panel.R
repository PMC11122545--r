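#' Gene panel definition
#'
#' A gene panel pairs an ordered list of target genes with the housekeeping
#' (reference) genes used for within-sample normalization. The bundled
#' default mirrors an 84-target inflammatory-response qPCR array with five
#' housekeeping genes (ACTB, B2M, GAPDH, HPRT1, RPLP0).
#'
#' @param targets character vector of target gene symbols.
#' @param housekeeping character vector of housekeeping gene symbols;
#'   must be non-empty and disjoint from `targets`.
#' @param name free-text panel name.
#' @return An object of class `gene_panel` with elements `targets`,
#'   `housekeeping` and `name`.
#' @export
gene_panel <- function(targets, housekeeping, name = "custom") {
  targets <- as.character(targets)
  housekeeping <- as.character(housekeeping)
  if (length(housekeeping) == 0L) {
    stop("panel must define at least one housekeeping gene", call. = FALSE)
  }
  if (anyDuplicated(targets)) {
    stop("duplicate target gene symbols: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(housekeeping)) {
    stop("duplicate housekeeping gene symbols", call. = FALSE)
  }
  overlap <- intersect(targets, housekeeping)
  if (length(overlap) > 0L) {
    stop("genes listed as both target and housekeeping: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  structure(
    list(targets = targets, housekeeping = housekeeping, name = name),
    class = "gene_panel"
  )
}

# Genes of the inflammatory-response array that carry study-calibrated
# effects or network roles; the remainder of the 84 targets are synthetic
# placeholder symbols (IRG*), since the full commercial array membership is
# user-replaceable via read_panel().
named_panel_genes <- function() {
  c(
    # +/-2-fold dysregulated set
    "CXCL2", "CXCL3", "BCL6", "CXCL5", "FASLG", "CRP", "CCL21", "CXCR1",
    "CD40", "IL22", "CCL11", "CXCL1", "CCL2", "CCL16", "IL17A", "IL1B",
    "IL23A", "CCR2", "IL23R", "CCL24", "CCL22", "ITGB2", "CXCL9", "CCR1",
    "C3AR1", "CXCL10", "NOS2", "CD40LG", "LY96",
    # significant but below the fold cutoff
    "TNFSF14",
    # additional network / classifier genes
    "CCR7", "CSF1", "CCL13", "IL1RN", "CCL19", "CEBPB", "IL1A",
    "LTA", "TLR5", "CCL5", "CCL23"
  )
}

#' Bundled default gene panel
#'
#' 84 target genes (41 named inflammation/chemokine genes plus synthetic
#' `IRG` placeholders padding the panel to its nominal size) and the five
#' standard housekeeping genes.
#'
#' @return A [gene_panel()].
#' @export
default_panel <- function() {
  named <- named_panel_genes()
  n_pad <- 84L - length(named)
  pad <- sprintf("IRG%02d", seq_len(n_pad))
  gene_panel(
    targets = c(named, pad),
    housekeeping = c("ACTB", "B2M", "GAPDH", "HPRT1", "RPLP0"),
    name = "inflammatory-response-84"
  )
}

#' Read a gene panel from YAML or CSV
#'
#' YAML files carry keys `name`, `targets` and `housekeeping`. CSV files
#' carry columns `gene` and `role` (role is `target` or `housekeeping`).
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` vs
#'   `.csv`).
#' @return A validated [gene_panel()].
#' @export
read_panel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    spec <- yaml::read_yaml(path)
    gene_panel(
      targets = spec$targets,
      housekeeping = spec$housekeeping,
      name = spec$name %||% basename(path)
    )
  } else if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("gene", "role") %in% names(tab))) {
      stop("panel CSV needs columns 'gene' and 'role'", call. = FALSE)
    }
    gene_panel(
      targets = tab$gene[tab$role == "target"],
      housekeeping = tab$gene[tab$role == "housekeeping"],
      name = basename(path)
    )
  } else {
    stop("unsupported panel format: ", ext, call. = FALSE)
  }
}

#' Write a gene panel to YAML
#'
#' @param panel a [gene_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  yaml::write_yaml(
    list(name = panel$name, targets = panel$targets,
         housekeeping = panel$housekeeping),
    path
  )
  invisible(path)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel '%s': %d targets, %d housekeeping (%s)\n",
              x$name, length(x$targets), length(x$housekeeping),
              paste(x$housekeeping, collapse = ", ")))
  invisible(x)
}
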