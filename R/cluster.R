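# Neighbor-count conformational clustering (Daura et al. scheme).

#' Pairwise-RMSD neighbor-count clustering of an ensemble
#'
#' Classic trajectory clustering: compute all pairwise minimal RMSDs (after
#' Kabsch superposition on the selected atoms); iteratively take the
#' structure with the most neighbors within `cutoff` as a cluster center,
#' remove it and its neighbors, and repeat until no structures remain. Ties
#' are broken by the lowest frame index. The central structure of the largest
#' cluster is the representative conformation.
#'
#' @param ensemble a `dna_ensemble` (or list of N x 3 coordinate matrices).
#' @param cutoff RMSD cutoff in nm (default 0.5).
#' @param selection atom selection: `"backbone"` (default; backbone heavy
#'   atoms), `"all"`, or an integer vector of atom indices.
#' @return object of class `cluster_result`: `clusters` (list of frame-index
#'   vectors, largest first), `centers` (frame index per cluster), `cutoff`,
#'   `largest_fraction`, and `representative` (center of the largest
#'   cluster).
#' @export
daura_cluster <- function(ensemble, cutoff = 0.5, selection = "backbone") {
  if (inherits(ensemble, "dna_ensemble")) {
    nf <- n_frames(ensemble)
    sel <- if (identical(selection, "backbone")) {
      which(backbone_selection(ensemble$atoms))
    } else if (identical(selection, "all")) {
      seq_len(nrow(ensemble$atoms))
    } else as.integer(selection)
    frames <- lapply(seq_len(nf), function(f)
      structure_frame_xyz(ensemble, f)[sel, , drop = FALSE])
  } else if (is.list(ensemble)) {
    frames <- lapply(ensemble, as.matrix)
    nf <- length(frames)
  } else stop("ensemble must be a dna_ensemble or a list of coordinate matrices")
  if (nf < 1) stop("empty ensemble")
  cut_A <- cutoff * 10

  # pairwise RMSD (upper triangle)
  within <- matrix(FALSE, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq(i + 1, nf)) {
      within[i, j] <- within[j, i] <-
        kabsch_rmsd(frames[[i]], frames[[j]]) <= cut_A
    }
  }
  diag(within) <- TRUE

  remaining <- seq_len(nf)
  clusters <- list()
  centers <- integer(0)
  while (length(remaining)) {
    counts <- colSums(within[remaining, remaining, drop = FALSE])
    center <- remaining[which.max(counts)]   # which.max: lowest index on ties
    members <- remaining[within[center, remaining]]
    clusters[[length(clusters) + 1L]] <- members
    centers <- c(centers, center)
    remaining <- setdiff(remaining, members)
  }
  ord <- order(vapply(clusters, length, integer(1)), decreasing = TRUE)
  clusters <- clusters[ord]
  centers <- centers[ord]
  structure(list(clusters = clusters, centers = centers, cutoff = cutoff,
                 largest_fraction = length(clusters[[1]]) / nf,
                 representative = centers[1], n_frames = nf),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters over %d frames (cutoff %.2f nm); largest %.1f%% (center frame %d)\n",
              length(x$clusters), x$n_frames, x$cutoff,
              100 * x$largest_fraction, x$representative))
  invisible(x)
}
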