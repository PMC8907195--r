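#' Weighted, undirected, region-labelled adjacency matrix
#'
#' The unit of analysis: a symmetric, non-negative `n x n` matrix of
#' connection weights (streamline counts) between labelled brain regions.
#' The diagonal holds self-connections and is zeroed as a normalisation
#' step before any metric is computed (see [zero_diagonal()]).
#'
#' @param weights numeric matrix, square, symmetric within `tol`,
#'   all entries >= 0.
#' @param labels character vector of unique region names; defaults to
#'   `rownames(weights)`.
#' @param tol absolute tolerance for the symmetry check.
#' @return an object of class `weighted_adjacency`: the numeric matrix with
#'   `dimnames` set to the labels.
#' @export
weighted_adjacency <- function(weights, labels = rownames(weights), tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop_hc("weights must be a numeric matrix", "hemiconn_not_matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    stop_hc(sprintf("matrix is not square: %d x %d", nrow(weights), ncol(weights)),
            "hemiconn_nonsquare")
  }
  n <- nrow(weights)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    stop_hc("labels must be unique and match the matrix dimension",
            "hemiconn_label_mismatch")
  }
  if (anyNA(weights)) stop_hc("weights contain NA", "hemiconn_na")
  asym <- max(abs(weights - t(weights)))
  if (asym > tol) {
    stop_hc(sprintf("matrix asymmetric beyond tolerance (max |A - t(A)| = %g)", asym),
            "hemiconn_asymmetric")
  }
  if (min(weights) < 0) {
    stop_hc("negative weights are not allowed", "hemiconn_negative")
  }
  w <- (weights + t(weights)) / 2   # remove numerically negligible asymmetry
  dimnames(w) <- list(labels, labels)
  class(w) <- c("weighted_adjacency", "matrix", "array")
  w
}

#' @export
print.weighted_adjacency <- function(x, ...) {
  n <- nrow(x)
  m <- sum(x[upper.tri(x)] > 0)
  cat(sprintf("<weighted_adjacency> %d nodes, %d edges, density %.3f\n",
              n, m, m / choose(n, 2)))
  invisible(x)
}

#' Test for the weighted_adjacency class
#' @param x object.
#' @return logical.
#' @export
is_weighted_adjacency <- function(x) inherits(x, "weighted_adjacency")

#' Node labels of an adjacency matrix
#' @param A a `weighted_adjacency`.
#' @return character vector of region labels.
#' @export
node_labels <- function(A) rownames(A)

# strip the class so plain matrix arithmetic applies
as_weights <- function(A) {
  attr(A, "class") <- NULL
  A
}

stop_hc <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hemiconn_error")))
}

#' Set the matrix diagonal to zero
#'
#' Self-connections carry no information for the metrics used here; the
#' diagonal is zeroed as the first processing step. Idempotent; off-diagonal
#' entries are untouched.
#'
#' @param A a `weighted_adjacency`.
#' @return a `weighted_adjacency` with a zero diagonal.
#' @export
zero_diagonal <- function(A) {
  stopifnot(is_weighted_adjacency(A))
  w <- as_weights(A)
  diag(w) <- 0
  weighted_adjacency(w)
}

#' Region atlas for one hemisphere
#'
#' Holds the full ordered label set for the hemisphere of interest, the
#' named sensorimotor subset (M1, S1, SMA, thalamus, caudate, putamen,
#' pallidum) and the negative-control node (inferior occipital gyrus).
#'
#' @param all_labels character vector of region names for the hemisphere.
#' @param sensorimotor named character vector mapping short sensorimotor
#'   names to atlas labels.
#' @param control single atlas label used as negative control.
#' @return an object of class `node_atlas`.
#' @export
node_atlas <- function(all_labels, sensorimotor, control) {
  all_labels <- as.character(all_labels)
  if (anyDuplicated(all_labels)) stop_hc("duplicate atlas labels", "hemiconn_label_mismatch")
  missing <- setdiff(c(unname(sensorimotor), control), all_labels)
  if (length(missing)) {
    stop_hc(paste("atlas subset labels not in all_labels:",
                  paste(missing, collapse = ", ")), "hemiconn_label_mismatch")
  }
  structure(list(all_labels = all_labels,
                 sensorimotor = sensorimotor,
                 control = control),
            class = "node_atlas")
}

#' Default 47-region single-hemisphere atlas
#'
#' AAL2-style left-hemisphere labels for the 47 cortical and subcortical
#' regions retained after excluding small sub-cerebellar parcels, with the
#' sensorimotor subset and the inferior occipital gyrus control node.
#'
#' @return a `node_atlas` with 47 labels.
#' @export
default_atlas <- function() {
  labels <- c(
    "Precentral_L", "Frontal_Sup_2_L", "Frontal_Mid_2_L", "Frontal_Inf_Oper_L",
    "Frontal_Inf_Tri_L", "Frontal_Inf_Orb_2_L", "Rolandic_Oper_L",
    "Supp_Motor_Area_L", "Olfactory_L", "Frontal_Sup_Medial_L",
    "Frontal_Med_Orb_L", "Rectus_L", "OFCmed_L", "OFCant_L", "OFCpost_L",
    "OFClat_L", "Insula_L", "Cingulate_Ant_L", "Cingulate_Mid_L",
    "Cingulate_Post_L", "Hippocampus_L", "ParaHippocampal_L", "Amygdala_L",
    "Calcarine_L", "Cuneus_L", "Lingual_L", "Occipital_Sup_L",
    "Occipital_Mid_L", "Occipital_Inf_L", "Fusiform_L", "Postcentral_L",
    "Parietal_Sup_L", "Parietal_Inf_L", "SupraMarginal_L", "Angular_L",
    "Precuneus_L", "Paracentral_Lobule_L", "Caudate_L", "Putamen_L",
    "Pallidum_L", "Thalamus_L", "Heschl_L", "Temporal_Sup_L",
    "Temporal_Pole_Sup_L", "Temporal_Mid_L", "Temporal_Pole_Mid_L",
    "Temporal_Inf_L")
  node_atlas(
    all_labels = labels,
    sensorimotor = c(M1 = "Precentral_L", S1 = "Postcentral_L",
                     SMA = "Supp_Motor_Area_L", thalamus = "Thalamus_L",
                     caudate = "Caudate_L", putamen = "Putamen_L",
                     pallidum = "Pallidum_L"),
    control = "Occipital_Inf_L")
}

#' Subset an adjacency matrix to the hemisphere (atlas) of interest
#'
#' Returns the principal submatrix over `atlas$all_labels`, in atlas order.
#' Rows/columns outside the atlas (the lesioned hemisphere, small excluded
#' parcels) are discarded.
#'
#' @param A a `weighted_adjacency` whose labels contain the atlas labels.
#' @param atlas a `node_atlas`.
#' @return a `weighted_adjacency` over the atlas labels.
#' @export
subset_hemisphere <- function(A, atlas) {
  stopifnot(is_weighted_adjacency(A), inherits(atlas, "node_atlas"))
  missing <- setdiff(atlas$all_labels, node_labels(A))
  if (length(missing)) {
    stop_hc(paste("matrix lacks atlas labels:", paste(missing, collapse = ", ")),
            "hemiconn_label_mismatch")
  }
  w <- as_weights(A)[atlas$all_labels, atlas$all_labels, drop = FALSE]
  weighted_adjacency(w)
}

#' Density-based edge thresholding
#'
#' Removes the weakest `remove_fraction` of the *non-zero* edges (zeros are
#' absent edges, not weak ones) of each subject matrix, pruning spuriously
#' reconstructed fibres. With `m` non-zero upper-triangle edges, exactly
#' `floor(remove_fraction * m)` edges are zeroed. Ties at the cut weight are
#' broken deterministically by ascending (weight, row index, column index)
#' over the upper triangle. Surviving weights are unchanged.
#'
#' @param A a `weighted_adjacency`.
#' @param remove_fraction fraction of non-zero edges to remove, in `[0, 1)`;
#'   default 0.25.
#' @return a `weighted_adjacency` with the weakest edges zeroed.
#' @export
density_threshold <- function(A, remove_fraction = 0.25) {
  stopifnot(is_weighted_adjacency(A))
  if (!is.numeric(remove_fraction) || length(remove_fraction) != 1 ||
      is.na(remove_fraction) || remove_fraction < 0 || remove_fraction >= 1) {
    stop_hc("remove_fraction must be a single number in [0, 1)",
            "hemiconn_bad_fraction")
  }
  w <- as_weights(A)
  ut <- which(upper.tri(w) & w > 0)
  m <- length(ut)
  k <- floor(remove_fraction * m)
  if (k > 0) {
    rc <- arrayInd(ut, dim(w))
    ord <- order(w[ut], rc[, 1], rc[, 2])
    kill <- rc[ord[seq_len(k)], , drop = FALSE]
    w[kill] <- 0
    w[kill[, c(2, 1), drop = FALSE]] <- 0
  }
  weighted_adjacency(w)
}

#' Binarize an adjacency matrix
#'
#' Maps every non-zero weight to 1, leaving zeros in place. Used before
#' degree-based metrics (hierarchical and neighbourhood complexity).
#'
#' @param A a `weighted_adjacency`.
#' @return a binary `weighted_adjacency`.
#' @export
binarize <- function(A) {
  stopifnot(is_weighted_adjacency(A))
  w <- as_weights(A)
  weighted_adjacency((w > 0) * 1)
}

#' Read a labelled adjacency matrix from CSV
#'
#' File dialect: first header cell empty, then the `n` region labels; each
#' subsequent row is a label followed by `n` numeric cells. Validation
#' failures (non-square, asymmetry beyond tolerance, negative entries, label
#' mismatch) raise distinct condition classes.
#'
#' @param path CSV file path.
#' @param expected_labels optional character vector; if supplied the file's
#'   labels must match exactly (same order).
#' @param tol symmetry tolerance passed to [weighted_adjacency()].
#' @return a `weighted_adjacency`.
#' @export
read_adjacency <- function(path, expected_labels = NULL, tol = 1e-9) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  w <- as.matrix(df[, -1, drop = FALSE])
  mode(w) <- "numeric"
  if (nrow(w) != ncol(w)) {
    stop_hc(sprintf("file %s is not a square matrix: %d x %d",
                    path, nrow(w), ncol(w)), "hemiconn_nonsquare")
  }
  header <- colnames(df)[-1]
  if (!identical(header, labels)) {
    stop_hc("row labels do not match column labels", "hemiconn_label_mismatch")
  }
  if (!is.null(expected_labels) && !identical(labels, as.character(expected_labels))) {
    stop_hc("file labels do not match expected_labels", "hemiconn_label_mismatch")
  }
  rownames(w) <- labels
  weighted_adjacency(w, labels = labels, tol = tol)
}

#' Write a labelled adjacency matrix to CSV
#'
#' Inverse of [read_adjacency()] on its own output (labels bitwise equal,
#' weights equal to full double precision).
#'
#' @param A a `weighted_adjacency`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(A, path) {
  stopifnot(is_weighted_adjacency(A))
  w <- as_weights(A)
  df <- data.frame(format(w, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(w), stringsAsFactors = FALSE), ""), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest CSV
#'
#' Columns: `id, group, age, sex, lesion_volume, AHA, MA, BBTA, BBTU,
#' matrix_path`; empty cells are missing values. Group codes are restricted
#' to AIS (arterial ischemic stroke), PVI (periventricular venous
#' infarction) and TDC (typically developing controls); scores are checked
#' against their instrument ranges.
#'
#' @param path manifest CSV path.
#' @return a data.frame, one row per subject.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  required <- c("id", "group", "age", "sex", "lesion_volume",
                "AHA", "MA", "BBTA", "BBTU", "matrix_path")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_hc(paste("manifest lacks columns:", paste(missing, collapse = ", ")),
            "hemiconn_manifest")
  }
  if (!all(df$group %in% c("AIS", "PVI", "TDC"))) {
    stop_hc("group must be one of AIS, PVI, TDC", "hemiconn_manifest")
  }
  if (anyDuplicated(df$id)) stop_hc("duplicate subject ids", "hemiconn_manifest")
  for (sc in c("AHA", "MA")) {
    v <- df[[sc]]
    if (any(!is.na(v) & (v < 0 | v > 100))) {
      stop_hc(sprintf("%s scores must lie in [0, 100]", sc), "hemiconn_manifest")
    }
  }
  for (sc in c("BBTA", "BBTU")) {
    v <- df[[sc]]
    if (any(!is.na(v) & v < 0)) {
      stop_hc(sprintf("%s scores must be non-negative", sc), "hemiconn_manifest")
    }
  }
  df
}
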