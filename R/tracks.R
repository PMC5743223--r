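#' Build lineage-track backbones
#'
#' The backbone of a lineage is the set of clones whose commitment degree
#' to that lineage is at least `threshold` (default 0.70, boundary
#' inclusive). A threshold above 0.5 guarantees each clone belongs to at
#' most one backbone; unipotent clones (commitment 1) participate.
#'
#' @param commitments N x 6 matrix of commitment degrees (rows sum to 1).
#' @param coords N x 2 embedding coordinates aligned with `commitments`.
#' @param threshold in (0.5, 1].
#' @return List of class `track_backbones`: `members` (named list of row
#'   indices per lineage), `coords`, `threshold`, `empty` (lineages with
#'   no backbone clones).
#' @export
build_backbones <- function(commitments, coords, threshold = 0.7) {
  commitments <- as.matrix(commitments)
  coords <- as.matrix(coords)
  if (threshold <= 0.5 || threshold > 1) {
    abort("`threshold` must lie in (0.5, 1] so backbones cannot overlap.")
  }
  stopifnot(ncol(commitments) == 6, ncol(coords) == 2,
            nrow(commitments) == nrow(coords))
  rs <- rowSums(commitments)
  if (any(abs(rs - 1) > 1e-6)) abort("Commitment rows must sum to 1.")
  lin <- colnames(commitments) %||% lineage_names()
  members <- lapply(seq_len(6), function(k) which(commitments[, k] >= threshold))
  names(members) <- lin
  empty <- lin[lengths(members) == 0]
  if (length(empty) > 0) {
    inform(paste0("Empty backbone(s): ", paste(empty, collapse = ", ")))
  }
  structure(list(members = members, coords = coords, threshold = threshold,
                 empty = empty),
            class = "track_backbones")
}

#' Distance of every clone to every lineage track
#'
#' The distance of a clone to a track is the Euclidean distance to the
#' nearest clone on that track's backbone, measured in the embedding.
#' Empty backbones yield `Inf`.
#'
#' @param coords N x 2 coordinates.
#' @param backbones a `track_backbones` object (>= 1 non-empty backbone).
#' @return N x 6 matrix of distances.
#' @export
distance_to_tracks <- function(coords, backbones) {
  stopifnot(inherits(backbones, "track_backbones"))
  coords <- as.matrix(coords)
  if (all(lengths(backbones$members) == 0)) {
    abort("All backbones are empty.")
  }
  bc <- backbones$coords
  out <- matrix(Inf, nrow(coords), length(backbones$members),
                dimnames = list(rownames(coords), names(backbones$members)))
  for (k in seq_along(backbones$members)) {
    idx <- backbones$members[[k]]
    if (length(idx) == 0) next
    # subtract-then-square, exactly as a naive double loop would
    d2 <- 0
    for (j in seq_len(ncol(coords))) {
      d2 <- d2 + outer(coords[, j], bc[idx, j], "-")^2
    }
    out[, k] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Assign each clone to its nearest lineage track
#'
#' @param distances N x 6 matrix from [distance_to_tracks()]; each row
#'   needs at least one finite entry.
#' @return Tibble of class `track_assignment`: `track` (label of the
#'   minimizing lineage, ties broken by canonical order), `distance`, the
#'   six per-track distances `d_G ... d_pDC`, and `tie`.
#' @export
assign_tracks <- function(distances) {
  distances <- as.matrix(distances)
  lin <- colnames(distances) %||% lineage_names()
  bad <- which(!apply(distances, 1, function(r) any(is.finite(r))))
  if (length(bad) > 0) {
    abort(paste0("Clone row(s) with no finite track distance: ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  widx <- apply(distances, 1, which.min)  # first minimum = canonical order
  tie <- apply(distances, 1, function(r) sum(r == min(r)) > 1)
  if (any(tie)) {
    inform(paste0(sum(tie), " clone(s) equidistant to several tracks; ",
                  "assigned by canonical lineage order."))
  }
  dd <- as_tibble(distances, .name_repair = ~paste0("d_", lin))
  out <- dplyr::bind_cols(
    tibble(track = lin[widx],
           distance = distances[cbind(seq_len(nrow(distances)), widx)],
           tie = tie),
    dd)
  class(out) <- unique(c("track_assignment", class(out)))
  out
}

#' Backbone construction, distances and assignment in one call
#'
#' @param profiles output of [bias_profiles()] for the embedded clones.
#' @param embedding a `clone_tsne` object (or an N x 2 matrix) aligned
#'   with `profiles`.
#' @param threshold backbone commitment threshold.
#' @param space `"embedding"` (default) measures track distances in 2-D;
#'   `"yield"` measures them in the 6-D commitment space instead, for
#'   sensitivity analysis.
#' @return `track_assignment` tibble with `clone_id` prepended.
#' @export
assign_clone_tracks <- function(profiles, embedding, threshold = 0.7,
                                space = c("embedding", "yield")) {
  space <- match.arg(space)
  cm <- as.matrix(profiles[, paste0("cd_", lineage_names())])
  colnames(cm) <- lineage_names()
  coords <- if (inherits(embedding, "clone_tsne")) embedding$coords
            else as.matrix(embedding)
  stopifnot(nrow(cm) == nrow(coords))
  pts <- if (space == "embedding") coords else cm
  bb <- build_backbones(cm, pts[, 1:2, drop = FALSE], threshold)
  bb$coords <- pts  # allow 6-D distances when space = "yield"
  D <- distance_to_tracks(pts, bb)
  out <- assign_tracks(D)
  dplyr::bind_cols(tibble(clone_id = profiles$clone_id), out)
}
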