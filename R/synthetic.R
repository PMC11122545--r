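#' Synthetic cohort specification
#'
#' Describes a Ct-level cohort generator: group sizes, per-gene baseline Ct
#' in responders, planted signed fold regulations for non-responders versus
#' responders, Gaussian well noise on the Ct scale, and latent-factor
#' co-expression modules that induce correlated blocks within one response
#' group (or both).
#'
#' Fold regulation uses the display sign convention of qPCR array reports:
#' values >= 1 are the fold change itself, values <= -1 the negative
#' reciprocal of a fold change below one (so -24.3 plants a 24.3-fold
#' down-regulation in non-responders); 1 means no effect.
#'
#' @param panel a [gene_panel()].
#' @param n_responders,n_non_responders group sizes (each >= 2).
#' @param fold_regulation named numeric vector over (a subset of) panel
#'   targets; unnamed genes default to 1. All entries must satisfy
#'   `abs(x) >= 1`.
#' @param baseline_ct per-gene mean Ct in responders; a scalar is recycled
#'   (default 25 cycles).
#' @param hk_baseline_ct mean Ct of the housekeeping genes (default 20).
#' @param noise_sd Gaussian well-noise standard deviation in cycles
#'   (default 0.5; 0 gives the exact noiseless limit).
#' @param modules list of co-expression modules, each a list with elements
#'   `genes` (subset of panel targets), `scope` (`"responder"`,
#'   `"non-responder"` or `"both"`) and `loading` (factor loading in
#'   cycles).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(panel, n_responders, n_non_responders,
                        fold_regulation = numeric(), baseline_ct = 25,
                        hk_baseline_ct = 20, noise_sd = 0.5,
                        modules = list()) {
  stopifnot(inherits(panel, "gene_panel"))
  if (n_responders < 2L || n_non_responders < 2L) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  fr <- stats::setNames(rep(1, length(panel$targets)), panel$targets)
  if (length(fold_regulation) > 0L) {
    unknown <- setdiff(names(fold_regulation), panel$targets)
    if (length(unknown) > 0L) {
      stop("fold regulation for genes absent from panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    fr[names(fold_regulation)] <- fold_regulation
  }
  if (any(abs(fr) < 1)) {
    stop("|fold regulation| must be >= 1 (1 = no effect)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  baseline <- rep_len(baseline_ct, length(panel$targets))
  names(baseline) <- panel$targets
  for (m in modules) {
    if (!all(c("genes", "scope", "loading") %in% names(m))) {
      stop("each module needs 'genes', 'scope' and 'loading'", call. = FALSE)
    }
    if (!all(m$genes %in% panel$targets)) {
      stop("module genes must be panel targets", call. = FALSE)
    }
    if (!m$scope %in% c(GROUP_LEVELS, "both")) {
      stop("module scope must be 'responder', 'non-responder' or 'both'",
           call. = FALSE)
    }
  }
  structure(
    list(panel = panel, n_responders = as.integer(n_responders),
         n_non_responders = as.integer(n_non_responders),
         fold_regulation = fr, baseline_ct = baseline,
         hk_baseline_ct = hk_baseline_ct, noise_sd = noise_sd,
         modules = modules),
    class = "cohort_spec"
  )
}

# Fold regulations of the 29 genes beyond the +/-2-fold cutoff in
# non-responders, plus the modestly up-regulated TNFSF14.
study_fold_regulations <- function() {
  c(
    CXCL2 = 6.95, CXCL3 = 6.66, BCL6 = 5.68, CXCL5 = 5.67, FASLG = 3.93,
    CRP = 3.04, CCL21 = 3.03, CXCR1 = 2.86, CD40 = 2.68, IL22 = 2.61,
    CCL11 = 2.55, CXCL1 = 2.34, CCL2 = 2.2, CCL16 = 2.19, IL17A = 2.19,
    IL1B = 2.14,
    IL23A = -24.3, CCR2 = -16.86, IL23R = -13.59, CCL24 = -12.61,
    CCL22 = -9.44, ITGB2 = -2.73, CXCL9 = -2.68, CCR1 = -2.63,
    C3AR1 = -2.25, CXCL10 = -2.17, NOS2 = -2.13, CD40LG = -2.08,
    LY96 = -2.07,
    TNFSF14 = 1.38
  )
}

#' Study-calibrated synthetic cohort specification
#'
#' The default generator conditions: 22 responders and 14 non-responders,
#' planted fold regulations equal to the study's reported dysregulated set
#' (e.g. CXCL2 +6.95, IL23A -24.3, TNFSF14 +1.38; all other genes null),
#' Gaussian Ct noise of 0.5 cycles, and two latent-factor co-expression
#' modules mirroring the group-specific hub structure: a responder-scoped
#' module on BCL6/CRP/CCR1/CCL16 and a non-responder-scoped module on
#' CCL11/CCL22/IL23R. The default module loading of 3 cycles dominates the
#' well noise so that module gene pairs survive a rank-correlation 0.9
#' edge cutoff at these sample sizes.
#'
#' @param panel a [gene_panel()] containing all named study genes
#'   (default: [default_panel()]).
#' @param noise_sd Ct noise standard deviation in cycles (default 0.5).
#' @param module_loading latent-factor loading in cycles (default 3).
#' @param modules include the co-expression modules (default TRUE).
#' @return A [cohort_spec()].
#' @export
study_cohort_spec <- function(panel = default_panel(), noise_sd = 0.5,
                              module_loading = 3, modules = TRUE) {
  fr <- study_fold_regulations()
  mods <- if (modules) {
    list(
      list(genes = c("BCL6", "CRP", "CCR1", "CCL16"),
           scope = RESPONDER, loading = module_loading),
      list(genes = c("CCL11", "CCL22", "IL23R"),
           scope = NON_RESPONDER, loading = module_loading)
    )
  } else {
    list()
  }
  cohort_spec(panel, n_responders = 22L, n_non_responders = 14L,
              fold_regulation = fr, noise_sd = noise_sd, modules = mods)
}

#' Generate a synthetic Ct cohort
#'
#' Draws `Ct(s, g) = baseline[g] - I(s non-responder) * log2(FC_g) +
#' sum_modules loading * L_m(s) + noise`, where `FC_g` is the fold change
#' implied by the planted fold regulation (`FR` for `FR >= 1`, `1/|FR|`
#' otherwise), `L_m(s)` is a standard-normal per-sample module factor
#' applied to module genes within the module's scope, and the noise is
#' i.i.d. Gaussian with the spec's standard deviation. Housekeeping genes
#' receive their baseline plus noise only. Deterministic for a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A [ct_matrix()] over the spec's panel.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  panel <- spec$panel
  n_r <- spec$n_responders
  n_n <- spec$n_non_responders
  n <- n_r + n_n
  group <- c(rep(RESPONDER, n_r), rep(NON_RESPONDER, n_n))
  sample_ids <- sprintf("%s_%02d", ifelse(group == RESPONDER, "R", "NR"),
                        c(seq_len(n_r), seq_len(n_n)))
  genes <- c(panel$targets, panel$housekeeping)
  fr <- spec$fold_regulation
  fc <- ifelse(fr >= 1, fr, 1 / abs(fr))
  shift <- -log2(fc)  # Ct shift in non-responders (down-regulation -> +Ct)

  ct <- with_local_seed(substream_seed(seed, "cohort"), {
    m <- matrix(0, n, length(genes), dimnames = list(sample_ids, genes))
    m[, panel$targets] <- rep(spec$baseline_ct, each = n)
    m[group == NON_RESPONDER, panel$targets] <-
      m[group == NON_RESPONDER, panel$targets, drop = FALSE] +
      rep(shift, each = n_n)
    m[, panel$housekeeping] <- spec$hk_baseline_ct
    for (mod in spec$modules) {
      in_scope <- if (mod$scope == "both") rep(TRUE, n) else group == mod$scope
      L <- stats::rnorm(n)
      m[in_scope, mod$genes] <- m[in_scope, mod$genes, drop = FALSE] +
        mod$loading * L[in_scope]
    }
    if (spec$noise_sd > 0) {
      m <- m + matrix(stats::rnorm(n * length(genes), 0, spec$noise_sd),
                      n, length(genes))
    }
    m
  })
  ct_matrix(ct, group, panel = panel)
}

#' @export
print.cohort_spec <- function(x, ...) {
  n_eff <- sum(abs(x$fold_regulation) > 1)
  cat(sprintf(
    "Synthetic cohort spec: %d responders / %d non-responders, %d target genes (%d with planted effects), noise sd %.2f cycles, %d co-expression module(s)\n",
    x$n_responders, x$n_non_responders, length(x$fold_regulation), n_eff,
    x$noise_sd, length(x$modules)))
  invisible(x)
}
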