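#' Real-valued Tanimoto similarity of two masked CBF volumes
#'
#' Quantitative registration QC: both images are clipped at 0, normalized to
#' their `p`-th percentile within the brain mask, and voxels exceeding either
#' image's percentile are jointly excluded; the real-valued Tanimoto
#' coefficient `100 * sum(ab) / (sum(a^2) + sum(b^2) - sum(ab))` is then
#' computed over the included voxels. It ranges from 0% (disjoint support)
#' to 100% (identical images); above 70% is conventionally regarded as
#' excellent agreement between perfusion images.
#'
#' @param a,b [volumetric_image()]s on one geometry.
#' @param mask Brain mask [volumetric_image()] on the same geometry.
#' @param p Normalization percentile (default 97).
#' @return A `similarity_score`: `tc_percent`, `n_voxels_included`,
#'   `percentile_used`, `mask_provenance`.
#' @export
real_valued_tc <- function(a, b, mask, p = 97) {
  stopifnot(inherits(a, "volumetric_image"), inherits(b, "volumetric_image"))
  if (!same_geometry(a$geometry, b$geometry) ||
      !same_geometry(a$geometry, mask$geometry))
    stop("images and mask must share one geometry")
  na <- percentile_normalize(a, mask, p)
  nb <- percentile_normalize(b, mask, p)
  inc <- mask$voxels * na$included$voxels * nb$included$voxels
  idx <- which(inc == 1)
  if (!length(idx)) stop("degenerate input: joint inclusion mask is empty")
  va <- na$normalized$voxels[idx]
  vb <- nb$normalized$voxels[idx]
  saa <- sum(va^2); sbb <- sum(vb^2); sab <- sum(va * vb)
  if (saa + sbb == 0)
    stop("degenerate input: both images are zero over the included mask")
  structure(list(tc_percent = 100 * sab / (saa + sbb - sab),
                 n_voxels_included = length(idx),
                 percentile_used = p,
                 mask_provenance = sprintf(
                   "brain mask (%d voxels), joint exclusion above p%g of either image",
                   sum(mask$voxels == 1), p)),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("<similarity_score> TC %.2f%% over %d voxels (p%g normalization)\n",
              x$tc_percent, x$n_voxels_included, x$percentile_used))
  invisible(x)
}

#' Mean CBF per atlas region
#'
#' Arithmetic mean of CBF over the voxels of each integer atlas label, as
#' consumed by downstream regional statistics (e.g. per-gyrus group models).
#' Requested labels absent from the atlas are reported in the `absent_labels`
#' attribute, never as zero-valued rows.
#'
#' @param cbf_std CBF [volumetric_image()] in template space.
#' @param atlas Integer-valued label [volumetric_image()] on the same grid.
#' @param labels Optional integer subset (default: all nonzero labels).
#' @param label_names Optional named character vector, names = label ids.
#' @return `data.frame` with `label_id`, `label_name`, `mean_cbf`, `n_voxels`;
#'   attribute `absent_labels` lists requested-but-missing labels.
#' @export
region_mean_cbf <- function(cbf_std, atlas, labels = NULL, label_names = NULL) {
  stopifnot(inherits(cbf_std, "volumetric_image"), inherits(atlas, "volumetric_image"))
  if (!same_geometry(cbf_std$geometry, atlas$geometry))
    stop("CBF and atlas must share one geometry")
  av <- atlas$voxels
  if (max(abs(av - round(av))) > 0)
    stop("atlas payload must be integer-valued labels")
  av <- as.integer(round(av))
  present <- sort(unique(av[av != 0]))
  if (is.null(labels)) labels <- present
  labels <- as.integer(labels)
  absent <- setdiff(labels, present)
  use <- intersect(labels, present)
  cv <- as.vector(cbf_std$voxels)
  rows <- lapply(use, function(l) {
    sel <- av == l
    data.frame(label_id = l,
               label_name = if (!is.null(label_names) &&
                                as.character(l) %in% names(label_names))
                 unname(label_names[as.character(l)]) else NA_character_,
               mean_cbf = mean(cv[sel]), n_voxels = sum(sel))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label_id = integer(), label_name = character(),
               mean_cbf = numeric(), n_voxels = integer())
  attr(out, "absent_labels") <- absent
  out
}

#' Tanimoto comparison table across subjects and strategies
#'
#' Computes the masked, percentile-normalized Tanimoto coefficient of every
#' normalized CBF volume against a common standard-space reference, plus a
#' per-strategy quartile summary (the data behind a strategy-comparison
#' boxplot).
#'
#' @param results Nested list: `results[[subject]][[strategy]]` is either a
#'   `normalization_result` or a standard-space CBF [volumetric_image()].
#' @param reference Reference CBF [volumetric_image()] in template space
#'   (e.g. the template pseudo-CBF image).
#' @param mask Brain mask on the reference geometry.
#' @param p Normalization percentile (default 97).
#' @param csv,summary_csv Optional output CSV paths.
#' @return List with `table` (subject, strategy, tc_percent, n_voxels) and
#'   `summary` (strategy, q25, median, q75, n).
#' @export
strategy_comparison <- function(results, reference, mask, p = 97,
                                csv = NULL, summary_csv = NULL) {
  stopifnot(is.list(results), inherits(reference, "volumetric_image"))
  if (is.null(names(results)))
    names(results) <- paste0("subject", seq_along(results))
  rows <- list()
  for (subj in names(results)) {
    per <- results[[subj]]
    for (strat in names(per)) {
      x <- per[[strat]]
      img <- if (inherits(x, "normalization_result")) x$cbf_std else x
      if (!same_geometry(img$geometry, reference$geometry))
        stop("result for ", subj, "/", strat, " is not on the reference geometry")
      sc <- real_valued_tc(img, reference, mask, p)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, strategy = strat, tc_percent = sc$tc_percent,
        n_voxels = sc$n_voxels_included)
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$strategy), function(d)
    data.frame(strategy = d$strategy[1],
               q25 = stats::quantile(d$tc_percent, 0.25, type = 7, names = FALSE),
               median = stats::median(d$tc_percent),
               q75 = stats::quantile(d$tc_percent, 0.75, type = 7, names = FALSE),
               n = nrow(d))))
  rownames(summ) <- NULL
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(summary_csv)) utils::write.csv(summ, summary_csv, row.names = FALSE)
  list(table = tab, summary = summ)
}
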