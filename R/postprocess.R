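# Connected-component labeling. EBImage::bwlabel is 4-connected; for
# 8-connectivity, 4-connected labels touching diagonally are merged with a
# union-find pass over the label adjacency pairs.
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  lab <- as.matrix(EBImage::bwlabel(mask))
  n <- max(lab)
  if (connectivity == 4 || n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs (down-right and down-left offsets)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                        pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- relabel[lab[lab > 0]]
  lab
}

#' Keep the largest connected component
#'
#' Tumors are one contiguous region; stray small detections are removed by
#' keeping only the maximal-area connected component of the binary mask.
#' Equal-area ties are broken deterministically in favor of the component
#' containing the lexicographically smallest `(row, col)` pixel.
#'
#' @param mask binary mask; an empty mask is returned unchanged.
#' @param connectivity 8 (default) or 4.
#' @return binary mask with at most one connected component.
#' @export
largest_component <- function(mask, connectivity = 8) {
  m <- as_mask_matrix(mask)
  if (sum(m) == 0) return(m)
  lab <- label_components(m, connectivity)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    # first tied label encountered in (row, col) scan order
    idx <- which(lab %in% best)
    rc <- cbind(row(lab)[idx], col(lab)[idx])
    ord <- order(rc[, 1], rc[, 2])
    best <- lab[idx[ord[1]]]
  }
  (lab == best) * 1
}

# Binary disk: pixels within Euclidean distance <= radius of the center.
disk_kernel <- function(radius_px) {
  d <- 2 * radius_px + 1
  ctr <- radius_px + 1
  k <- outer(seq_len(d), seq_len(d),
             function(i, j) (i - ctr)^2 + (j - ctr)^2 <= radius_px^2)
  k * 1
}

#' Morphological closing with a disk
#'
#' Dilation followed by erosion with a disk-shaped structuring element
#' (pixels within Euclidean distance `radius_px` of the center), filling
#' holes and gaps narrower than the element. The mask is padded by the
#' radius before the operation so that closing remains extensive at the
#' image border.
#'
#' @param mask binary mask.
#' @param radius_px disk radius in pixels (`>= 1`).
#' @return closed binary mask.
#' @export
close_mask <- function(mask, radius_px = 3) {
  m <- as_mask_matrix(mask)
  if (radius_px < 1) stop("radius_px must be >= 1")
  r <- as.integer(radius_px)
  pad <- matrix(0, nrow(m) + 2 * r, ncol(m) + 2 * r)
  pad[r + seq_len(nrow(m)), r + seq_len(ncol(m))] <- m
  k <- disk_kernel(r)
  closed <- as.matrix(EBImage::erode(EBImage::dilate(pad, k), k))
  out <- closed[r + seq_len(nrow(m)), r + seq_len(ncol(m)), drop = FALSE]
  (out > 0.5) * 1
}

#' Standard prediction cleanup
#'
#' The full post-processing pipeline applied to every binarized prediction:
#' first keep the largest connected component, then morphologically close it.
#'
#' @inheritParams largest_component
#' @inheritParams close_mask
#' @export
postprocess_mask <- function(mask, radius_px = 3, connectivity = 8) {
  close_mask(largest_component(mask, connectivity), radius_px)
}
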