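#' Mean pure-component profiles on the linear scale
#'
#' Averages the replicate columns of each pure component on the linear
#' (normalized) scale, yielding the per-miRNA mean signals that drive the
#' mixing model and the tissue-selectivity classification.
#'
#' @param table Normalized linear-scale expression tibble containing the
#'   pure samples.
#' @param manifest Manifest tibble mapping columns to roles.
#' @param design A `mixqc_design`.
#' @return A tibble with column `mirna` and one mean-signal column per
#'   design component.
#' @export
pure_profile <- function(table, manifest, design) {
  validate_manifest(manifest, design)
  cols <- lapply(design$components, function(comp) {
    ids <- manifest_pure_ids(manifest, comp)
    if (!length(ids))
      stop("no pure samples for component '", comp, "' in the manifest", call. = FALSE)
    rowMeans(as.matrix(table[ids]))
  })
  names(cols) <- design$components
  tibble::as_tibble(c(list(mirna = table$mirna), cols))
}

profile_matrix <- function(profile) {
  m <- as.matrix(profile[setdiff(names(profile), "mirna")])
  rownames(m) <- profile$mirna
  m
}

#' Variable and invariable components of a two-mixture design
#'
#' A component is *invariable* when its fraction is the same in both
#' mixtures (liver in the default design): miRNAs selective for it show no
#' Mix1/Mix2 difference and join the 1-to-1 class. The remaining components
#' are *variable* and provide the designed true-positive ratios.
#'
#' @param design A `mixqc_design` with 2 mixtures.
#' @return List with character vectors `variable` and `invariable`.
#' @export
design_component_roles <- function(design) {
  stopifnot(inherits(design, "mixqc_design"), ncol(design$phi) == 2L)
  invar <- abs(design$phi[, 1L] - design$phi[, 2L]) < 1e-9
  list(variable = design$components[!invar],
       invariable = design$components[invar])
}

#' Classify miRNAs by tissue selectivity
#'
#' A miRNA is selective for a tissue when its mean signal there is at least
#' `fold` times its mean in *each* other tissue ("at least" — the exact
#' threshold counts as selective). For `fold > 1` at most one tissue can
#' satisfy the rule. Selectivity for the invariable component (liver) is
#' assigned to the 1-to-1 class with subtype `liver_selective`; non-selective
#' miRNAs whose two variable-component signals are both positive and within
#' `equality_tol_log2` of each other are 1-to-1 with subtype
#' `brain_equals_placenta`. Everything else (including all-zero rows) is
#' `non_selective`. Classes are the truth labels for all downstream metrics:
#' variable-selective miRNAs are designed true positives, 1-to-1 miRNAs
#' designed true negatives.
#'
#' @param profile Pure-profile tibble from [pure_profile()] (linear-scale
#'   means).
#' @param design A `mixqc_design`.
#' @param fold Selectivity fold threshold (> 1; default 10).
#' @param equality_tol_log2 Half-width of the "approximately equal"
#'   brain/placenta band, in log2 units (default 0.5, about 1.41-fold).
#' @return A tibble `mirna`, `class`
#'   (`<tissue>_selective` / `one_to_one` / `non_selective`) and `subtype`
#'   (`liver_selective` / `brain_equals_placenta` / `none`).
#' @export
classify_selectivity <- function(profile, design = default_mix_design(),
                                 fold = 10, equality_tol_log2 = 0.5) {
  stopifnot(fold > 1, equality_tol_log2 > 0)
  m <- profile_matrix(profile)
  if (!setequal(colnames(m), design$components))
    stop("profile columns must match the design components", call. = FALSE)
  m <- m[, design$components, drop = FALSE]
  roles <- design_component_roles(design)

  selective_for <- function(i) {
    v <- m[i, ]
    for (comp in design$components) {
      others <- v[setdiff(design$components, comp)]
      if (v[[comp]] > 0 && all(v[[comp]] >= fold * others)) return(comp)
    }
    NA_character_
  }
  sel <- vapply(seq_len(nrow(m)), selective_for, character(1))

  class <- rep("non_selective", nrow(m))
  subtype <- rep("none", nrow(m))
  is_var_sel <- !is.na(sel) & sel %in% roles$variable
  class[is_var_sel] <- paste0(sel[is_var_sel], "_selective")
  is_invar_sel <- !is.na(sel) & sel %in% roles$invariable
  class[is_invar_sel] <- "one_to_one"
  subtype[is_invar_sel] <- paste0(sel[is_invar_sel], "_selective")

  if (length(roles$variable) == 2L) {
    a <- m[, roles$variable[1L]]
    b <- m[, roles$variable[2L]]
    eq <- is.na(sel) & a > 0 & b > 0 & abs(log2(a / b)) <= equality_tol_log2
    class[eq] <- "one_to_one"
    subtype[eq] <- paste0(roles$variable[1L], "_equals_", roles$variable[2L])
  }

  tibble::tibble(mirna = profile$mirna, class = class, subtype = subtype)
}

#' Tally detected miRNAs per selectivity class
#'
#' @param classification Tibble from [classify_selectivity()].
#' @param design A `mixqc_design` (fixes the class column order).
#' @return A one-row tibble with counts `non_selective`, `one_to_one`, and
#'   one `<tissue>_selective` column per variable component; the counts sum
#'   to the number of classified miRNAs.
#' @export
class_counts <- function(classification, design = default_mix_design()) {
  roles <- design_component_roles(design)
  lvls <- c("non_selective", "one_to_one", paste0(roles$variable, "_selective"))
  counts <- table(factor(classification$class, levels = lvls))
  tibble::as_tibble(as.list(counts))
}

#' Write / read a selectivity classification as TSV
#' @param classification Tibble from [classify_selectivity()].
#' @param path File path.
#' @return The path (writer, invisibly) or the classification tibble (reader).
#' @export
write_classification <- function(classification, path) {
  readr::write_tsv(classification, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_classification
#' @export
read_classification <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), show_col_types = FALSE,
                  progress = FALSE)
}
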