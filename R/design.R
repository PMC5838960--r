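#' Construct a reciprocal mixture design
#'
#' A mixture design records which pure total-RNA components enter each
#' composite sample and in what fraction. Fractions are stored normalized:
#' by-volume proportions such as 1:1:2 are converted to fractions of total
#' RNA (0.25, 0.25, 0.5) at construction, because the linear mixing model
#' operates on fractions.
#'
#' @param components Character vector of component labels, e.g.
#'   `c("liver", "brain", "placenta")`. Order is fixed and used consistently
#'   for all downstream vectors.
#' @param proportions Numeric matrix with one row per component and one
#'   column per mixture; entries are nonnegative mixing proportions (volumes
#'   or fractions — each column is normalized to sum to 1). Column names are
#'   the mixture labels (defaults `mix1`, `mix2`, ...).
#' @return An object of class `mixqc_design` with elements `components`,
#'   `mixtures` and `phi` (the fraction matrix, components x mixtures).
#' @examples
#' mix_design(c("liver", "brain", "placenta"),
#'            cbind(mix1 = c(1, 1, 2), mix2 = c(1, 2, 1)))
#' @export
mix_design <- function(components, proportions) {
  components <- as.character(components)
  phi <- as.matrix(proportions)
  if (length(components) < 2L)
    stop("a mixture design needs at least 2 components", call. = FALSE)
  if (ncol(phi) < 2L)
    stop("a mixture design needs at least 2 mixtures", call. = FALSE)
  if (nrow(phi) != length(components))
    stop("`proportions` must have one row per component", call. = FALSE)
  if (any(!is.finite(phi)) || any(phi < 0))
    stop("mixing proportions must be finite and nonnegative", call. = FALSE)
  totals <- colSums(phi)
  if (any(totals == 0))
    stop("each mixture must receive a positive total amount", call. = FALSE)
  phi <- sweep(phi, 2L, totals, "/")
  if (is.null(colnames(phi))) colnames(phi) <- paste0("mix", seq_len(ncol(phi)))
  rownames(phi) <- components
  stopifnot(all(abs(colSums(phi) - 1) < 1e-12))
  structure(
    list(components = components, mixtures = colnames(phi), phi = phi),
    class = "mixqc_design"
  )
}

#' The default liver/brain/placenta reciprocal design
#'
#' Three components mixed 1:1:2 (Mix1) and 1:2:1 (Mix2) in liver, brain,
#' placenta order, i.e. fraction columns (0.25, 0.25, 0.5) and
#' (0.25, 0.5, 0.25). Liver is the invariable component (equal fraction in
#' both mixtures); brain and placenta are the reciprocal 2:1 components.
#'
#' @return A `mixqc_design`.
#' @export
default_mix_design <- function() {
  mix_design(c("liver", "brain", "placenta"),
             cbind(mix1 = c(1, 1, 2), mix2 = c(1, 2, 1)))
}

#' @export
print.mixqc_design <- function(x, ...) {
  cat("<mixqc_design> ", length(x$components), " components, ",
      length(x$mixtures), " mixtures\n", sep = "")
  print(round(x$phi, 4))
  invisible(x)
}

#' Largest achievable |log2 ratio| under a two-mixture design
#'
#' Under the linear mixing model the signal ratio between the two mixtures
#' for any miRNA is a ratio of convex combinations of its pure-component
#' signals, so its extreme values are attained at the vertices: the bound is
#' `max over components c of |log2(phi[c,1] / phi[c,2])|`. For the default
#' design this is 1 (a 2-fold difference), attained by miRNAs specific to
#' either reciprocal component.
#'
#' @param design A `mixqc_design` with exactly 2 mixtures.
#' @return A nonnegative number; `Inf` if some component has a zero fraction
#'   in one mixture but not the other (the ratio is then unbounded).
#' @export
design_log2_bound <- function(design) {
  stopifnot(inherits(design, "mixqc_design"))
  if (ncol(design$phi) != 2L)
    stop("log2 bound is defined for designs with exactly 2 mixtures", call. = FALSE)
  p1 <- design$phi[, 1L]
  p2 <- design$phi[, 2L]
  if (any(xor(p1 == 0, p2 == 0))) return(Inf)
  keep <- p1 > 0 & p2 > 0
  if (!any(keep)) return(0)
  max(abs(log2(p1[keep] / p2[keep])))
}

#' Build a sample manifest for a measurement round
#'
#' Enumerates the samples a participating lab processes in one round: every
#' pure component and every mixture (`mode = "full"`, the 15-sample set at 3
#' replicates for the default design) or the mixtures alone
#' (`mode = "mixtures_only"`, the reduced 6-sample set used once a pure-tissue
#' baseline has been established).
#'
#' @param design A `mixqc_design`.
#' @param n_replicates Positive integer, replicates per sample.
#' @param mode `"full"` or `"mixtures_only"`.
#' @param round_id Label for the measurement round.
#' @return A tibble with columns `sample_id`, `role` (`pure:<component>` or
#'   `mix:<mixture>`), `replicate` and `round`.
#' @export
build_manifest <- function(design, n_replicates = 3L,
                           mode = c("full", "mixtures_only"),
                           round_id = "round1") {
  stopifnot(inherits(design, "mixqc_design"))
  mode <- match.arg(mode)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("`n_replicates` must be a positive integer", call. = FALSE)
  roles <- paste0("mix:", design$mixtures)
  if (mode == "full") roles <- c(paste0("pure:", design$components), roles)
  tidyr::expand_grid(role = roles, replicate = seq_len(n_replicates)) |>
    dplyr::mutate(
      sample_id = paste0(sub("^(pure|mix):", "", .data$role), "_r", .data$replicate),
      round = round_id
    ) |>
    dplyr::select("sample_id", "role", "replicate", "round")
}

#' Role helpers for manifests
#'
#' `manifest_pure_ids()` returns the sample ids measuring a given pure
#' component; `manifest_mix_ids()` those measuring a given mixture.
#'
#' @param manifest A manifest tibble from [build_manifest()] or
#'   [read_manifest()].
#' @param component,mixture Label to look up.
#' @return Character vector of sample ids.
#' @export
manifest_pure_ids <- function(manifest, component) {
  manifest$sample_id[manifest$role == paste0("pure:", component)]
}

#' @rdname manifest_pure_ids
#' @export
manifest_mix_ids <- function(manifest, mixture) {
  manifest$sample_id[manifest$role == paste0("mix:", mixture)]
}

validate_manifest <- function(manifest, design) {
  if (anyDuplicated(manifest$sample_id))
    stop("manifest sample ids must be unique", call. = FALSE)
  known <- c(paste0("pure:", design$components), paste0("mix:", design$mixtures))
  bad <- setdiff(unique(manifest$role), known)
  if (length(bad))
    stop("manifest roles not present in the design: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(manifest)
}

#' Read and write designs and manifests as YAML
#'
#' The design file records the component labels and the per-mixture
#' proportion columns; the manifest file records the sample-to-role map with
#' replicate indices and the round label.
#'
#' @param design A `mixqc_design`.
#' @param manifest A manifest tibble.
#' @param path File path.
#' @return `read_design()` returns a `mixqc_design`; `read_manifest()` a
#'   manifest tibble. The writers return `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "mixqc_design"))
  cols <- lapply(seq_along(design$mixtures), function(j) unname(design$phi[, j]))
  names(cols) <- design$mixtures
  yaml::write_yaml(list(components = design$components, mixtures = cols), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$components) || is.null(cfg$mixtures))
    stop("design file must contain `components` and `mixtures`", call. = FALSE)
  phi <- do.call(cbind, lapply(cfg$mixtures, as.numeric))
  colnames(phi) <- names(cfg$mixtures)
  mix_design(cfg$components, phi)
}

#' @rdname write_design
#' @export
write_manifest <- function(manifest, path) {
  entries <- purrr::pmap(manifest, function(sample_id, role, replicate, round, ...) {
    list(sample_id = sample_id, role = role,
         replicate = as.integer(replicate), round = round)
  })
  yaml::write_yaml(list(samples = entries), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_manifest <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$samples)) stop("manifest file must contain `samples`", call. = FALSE)
  purrr::map_dfr(cfg$samples, ~ tibble::tibble(
    sample_id = .x$sample_id, role = .x$role,
    replicate = as.integer(.x$replicate), round = .x$round %||% "round1"
  ))
}
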