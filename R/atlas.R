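# Cohort perfusion probability and majority maps over co-registered voxel
# label volumes, plus atlas overlap tables. Volumes are integer 3D arrays in
# a common template grid; the label convention is 0 = none and consecutive
# codes for the major arteries (default MCA = 1, ACA = 2, PCA = 3).
# Registration/normalisation to the template is out of scope: inputs must be
# pre-registered (e.g. NIfTI volumes resampled to the template).

default_artery_labels <- c(MCA = 1L, ACA = 2L, PCA = 3L)

#' Read / write label volumes (NIfTI)
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return integer 3D array with attribute `voxel_mm` (per-axis size).
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.array(img))), dim = dim(img))
  attr(arr, "voxel_mm") <- RNifti::pixdim(img)
  arr
}

#' @rdname read_label_volume
#' @param vol integer 3D array (optionally with a `voxel_mm` attribute).
#' @param voxel_mm voxel size override (length 3).
#' @export
write_label_volume <- function(vol, path, voxel_mm = NULL) {
  vox <- voxel_mm %||% attr(vol, "voxel_mm") %||% c(1, 1, 1)
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)))
  RNifti::pixdim(img) <- vox
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Perfusion probability map over a cohort
#'
#' For every template voxel x and artery i, \eqn{P_i(x) = N_{x,i} /
#' \sum_{j \in S} N_{x,j}}, where \eqn{N_{x,i}} is the number of cohort
#' members in which artery i perfuses x. Voxels supported by fewer than
#' `min_count` members, or outside the mask, are excluded. Cohort members are
#' either exclusive label arrays (codes per `labels`) or — to represent
#' overlap territories where one patient's voxel is perfused by several
#' arteries — named lists of binary masks, one per artery, each contributing
#' one count.
#'
#' @param cohort list of integer 3D arrays, or list of named lists of binary
#'   arrays (names from `names(labels)`).
#' @param min_count minimum supporting members to retain a voxel (default 10,
#'   e.g. 10 of a 40-member cohort).
#' @param mask optional logical/integer array; voxels where `mask == 0` are
#'   excluded.
#' @param labels named integer vector, artery -> label code.
#' @return object of class `probability_map`: list with `P` (named list of
#'   probability arrays), `N` (support count array), `retained` (logical
#'   array), `labels`, `n_cohort`.
#' @export
probability_map <- function(cohort, min_count = 10, mask = NULL,
                            labels = default_artery_labels) {
  if (!length(cohort)) {
    stop_perfterra("empty cohort", class = "perfterra_validation_error")
  }
  dims <- lapply(cohort, function(v) {
    if (is.list(v)) dim(v[[1]]) else dim(v)
  })
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop_perfterra("cohort grid shapes differ",
                   class = "perfterra_validation_error")
  }
  if (min_count > length(cohort)) {
    warning("min_count exceeds cohort size; every voxel will be excluded")
  }
  d <- dims[[1]]
  counts <- lapply(labels, function(code) array(0L, d))
  for (v in cohort) {
    if (is.list(v)) {
      for (a in names(labels)) {
        if (!is.null(v[[a]])) {
          counts[[a]] <- counts[[a]] + (v[[a]] != 0)
        }
      }
    } else {
      for (a in names(labels)) {
        counts[[a]] <- counts[[a]] + (v == labels[[a]])
      }
    }
  }
  N <- Reduce(`+`, counts)
  retained <- N >= min_count
  if (!is.null(mask)) retained <- retained & (mask != 0)
  P <- lapply(counts, function(cnt) {
    p <- array(NA_real_, d)
    p[retained] <- cnt[retained] / N[retained]
    p
  })
  structure(list(P = P, N = N, retained = retained, labels = labels,
                 n_cohort = length(cohort)),
            class = "probability_map")
}

#' Majority perfusion-territory map
#'
#' Assigns each retained voxel to the artery with the highest probability;
#' ties are broken by the fixed artery order of the label table (MCA before
#' ACA before PCA) and flagged. Excluded voxels get code 0.
#'
#' @param pmap a [probability_map()].
#' @return integer array of label codes with attributes `ties` (logical
#'   array) and `labels`.
#' @export
majority_map <- function(pmap) {
  d <- dim(pmap$N)
  k <- length(pmap$labels)
  flat <- vapply(pmap$P, as.vector, numeric(prod(d)))
  out <- integer(prod(d))
  ties <- logical(prod(d))
  ret <- as.vector(pmap$retained)
  if (any(ret)) {
    sub <- flat[ret, , drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    mx <- sub[cbind(seq_len(nrow(sub)), best)]
    ties[ret] <- rowSums(sub == mx) > 1
    out[ret] <- pmap$labels[best]
  }
  res <- array(out, d)
  attr(res, "ties") <- array(ties, d)
  attr(res, "labels") <- pmap$labels
  res
}

#' Territory overlap tables between two label maps
#'
#' Row-normalised percentage confusion matrices in both directions: entry
#' (l, m) of `a_to_b` is the percentage of voxels labeled l in map A that
#' carry label m in map B (rows sum to 100). Voxels where either map is 0
#' (none) are excluded.
#'
#' @param map_a,map_b integer label arrays on the same grid.
#' @param labels named integer vector of codes to compare.
#' @return list with `a_to_b` and `b_to_a` percentage matrices.
#' @export
overlap_table <- function(map_a, map_b, labels = default_artery_labels) {
  stopifnot(identical(dim(map_a), dim(map_b)))
  a <- as.vector(map_a)
  b <- as.vector(map_b)
  keep <- a %in% labels & b %in% labels
  if (!any(keep)) {
    stop_perfterra("no voxels labeled in both maps",
                   class = "perfterra_validation_error")
  }
  a <- a[keep]; b <- b[keep]
  one_way <- function(x, y) {
    tab <- matrix(0, length(labels), length(labels),
                  dimnames = list(names(labels), names(labels)))
    for (i in seq_along(labels)) {
      sel <- x == labels[[i]]
      if (!any(sel)) { tab[i, ] <- NA_real_; next }
      for (j in seq_along(labels)) {
        tab[i, j] <- 100 * sum(y[sel] == labels[[j]]) / sum(sel)
      }
    }
    tab
  }
  list(a_to_b = one_way(a, b), b_to_a = one_way(b, a))
}
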