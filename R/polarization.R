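# Polarization index over attractor activity:
#   pI = A1/T1 - A2/T2
# A_x = summed activity fraction of polarity-x nodes of the chosen
# layer, T_x = number of such nodes. +1 is fully inflammatory
# (M1-like), -1 fully tissue-protective (M2-like).

#' Canonical macrophage output polarity assignments
#'
#' The inflammatory (type-1, M1-like) and tissue-protective (type-2,
#' M2-like) transcriptional outputs of the curated macrophage model,
#' as ASCII-aliased symbols (IFNB for IFN-beta, TNFA for TNF-alpha,
#' TGFB for TGF-beta). Useful for validating the `polarity` column of
#' a loaded node table.
#' @format character vectors of node ids.
#' @export
MACROPHAGE_TYPE1_OUTPUTS <- c("CD64", "CD68", "CIITA", "CXCL10", "IFNB",
                              "IL12A", "IL12B", "IL1B", "IL6", "iNOS",
                              "TNFA")

#' @rdname MACROPHAGE_TYPE1_OUTPUTS
#' @export
MACROPHAGE_TYPE2_OUTPUTS <- c("CCL17", "CCL22", "CCL24", "CD209", "MERTK",
                              "MRC1", "TGFB")

#' Polarization index of an attractor
#'
#' For a limit cycle, each node contributes the fraction of cycle
#' states in which it is active; nodes without a `type1`/`type2`
#' polarity assignment never influence the index. With `layer =
#' "input"` the index is computed over the clamped input pattern
#' (inputs are constant across the attractor), which characterises the
#' environment itself.
#'
#' @param attractor a `bcn_attractor`.
#' @param net the `bcn` the attractor was computed on.
#' @param layer `"output"` (default) or `"input"`.
#' @return list of class `bcn_polarization` with `pI`, `A1`, `A2`,
#'   `T1`, `T2`.
#' @export
polarization_index <- function(attractor, net, layer = c("output", "input")) {
  layer <- match.arg(layer)
  nd <- net$nodes
  sel <- nd$class == layer
  t1_ids <- nd$id[sel & nd$polarity == "type1"]
  t2_ids <- nd$id[sel & nd$polarity == "type2"]
  if (length(t1_ids) == 0L || length(t2_ids) == 0L)
    stop(sprintf(
      "polarization index undefined: layer '%s' has %d type1 and %d type2 nodes",
      layer, length(t1_ids), length(t2_ids)))
  act <- attractor$activity
  A1 <- sum(act[t1_ids])
  A2 <- sum(act[t2_ids])
  structure(list(pI = A1 / length(t1_ids) - A2 / length(t2_ids),
                 A1 = A1, A2 = A2,
                 T1 = length(t1_ids), T2 = length(t2_ids)),
            class = "bcn_polarization")
}

#' @export
print.bcn_polarization <- function(x, ...) {
  cat(sprintf("pI = %+.4f  (A1 = %.3g of T1 = %d; A2 = %.3g of T2 = %d)\n",
              x$pI, x$A1, x$T1, x$A2, x$T2))
  invisible(x)
}

#' Detect a polarization flip
#'
#' A perturbation flips an established polarization when both the
#' baseline and the perturbed attractor are committed (`|pI|` strictly
#' above the threshold) and the two indices have opposite signs. A
#' perturbed pI of exactly 0 is never a flip.
#'
#' @param pI_base,pI_pert baseline and perturbed polarization indices.
#' @param threshold commitment threshold (strict); default 0.2.
#' @return integer bit (1 = flip).
#' @export
detect_flip <- function(pI_base, pI_pert, threshold = 0.2) {
  stopifnot(threshold > 0)
  as.integer(abs(pI_base) > threshold & abs(pI_pert) > threshold &
               sign(pI_base) * sign(pI_pert) < 0)
}

#' Correlation between environment and response polarization
#'
#' Runs every supplied environment unperturbed, computes the
#' polarization index of the input layer (the stimulus) and of the
#' output layer (the transcriptional response), and returns their
#' Pearson product-moment correlation.
#'
#' @param net a `bcn` with polarity assignments on both layers.
#' @param environments list of active-input vectors (>= 3).
#' @return list with `r`, and the paired `pI_in` / `pI_out` vectors.
#' @export
input_output_correlation <- function(net, environments) {
  if (length(environments) < 3L)
    stop("need at least 3 environments")
  atts <- batch_attractors(net, environments)
  pI_in <- vapply(atts, function(a)
    polarization_index(a, net, "input")$pI, numeric(1))
  pI_out <- vapply(atts, function(a)
    polarization_index(a, net, "output")$pI, numeric(1))
  if (stats::sd(pI_in) == 0 || stats::sd(pI_out) == 0)
    stop("zero variance in a polarization series; correlation undefined")
  list(r = stats::cor(pI_in, pI_out), pI_in = pI_in, pI_out = pI_out)
}
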