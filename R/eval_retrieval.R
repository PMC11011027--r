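# Query-gallery retrieval evaluation: Euclidean distance ranking with
# self-exclusion, CMC Rank-k and mean average precision.

#' Euclidean distance between two descriptors
#'
#' `sqrt((A - B) . (A - B))`; symmetric, zero exactly when the vectors are
#' equal.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("descriptor lengths differ")
  sqrt(sum((a - b)^2))
}

#' Identity match indicator
#'
#' 1 when the query and gallery labels are equal, else 0.
#'
#' @param l_image,l_gallery Identity labels (any comparable scalars).
#' @return 0 or 1.
#' @export
match_indicator <- function(l_image, l_gallery) {
  as.integer(l_image == l_gallery)
}

#' Build a gallery set
#'
#' @param descriptors `N x D` matrix.
#' @param labels Length-N identity labels.
#' @param image_ids Length-N unique image keys (default sequential).
#' @return List of class `gallery_set`.
#' @export
gallery_set <- function(descriptors, labels, image_ids = NULL) {
  descriptors <- as.matrix(descriptors)
  image_ids <- image_ids %||% seq_len(nrow(descriptors))
  if (anyDuplicated(image_ids)) stop("gallery image_ids must be unique")
  stopifnot(length(labels) == nrow(descriptors),
            length(image_ids) == nrow(descriptors))
  structure(list(descriptors = descriptors, labels = labels,
                 image_ids = image_ids), class = "gallery_set")
}

#' Rank a gallery against one query
#'
#' Excludes the query's own image (matched by `image_id`), computes Euclidean
#' distances to every remaining gallery descriptor, and sorts ascending
#' (i.e. descending similarity). Ties are broken by gallery index, so the
#' ranking is deterministic.
#'
#' @param query Numeric descriptor vector.
#' @param query_id Image id of the query (excluded from the ranking);
#'   use an id absent from the gallery to keep every item admissible.
#' @param gallery A [gallery_set()].
#' @param query_label Optional identity label of the query, carried into the
#'   result for CMC/mAP computation.
#' @return List of class `ranking_result` with `query_id`, `order`
#'   (admissible gallery indices, best first), `distances` (non-decreasing),
#'   `labels` (gallery labels in ranked order) and `query_label`.
#' @export
rank_gallery <- function(query, query_id, gallery, query_label = NULL) {
  stopifnot(inherits(gallery, "gallery_set"))
  if (length(query) != ncol(gallery$descriptors)) {
    stop("query descriptor length does not match the gallery")
  }
  keep <- which(gallery$image_ids != query_id)
  if (length(keep) == 0L) stop("gallery is empty after excluding the query's own image")
  diffs <- sweep(gallery$descriptors[keep, , drop = FALSE], 2, query, "-")
  d <- unname(sqrt(rowSums(diffs^2)))
  o <- order(d, seq_along(d))
  structure(list(query_id = query_id, order = keep[o], distances = d[o],
                 labels = gallery$labels[keep][o], query_label = query_label),
            class = "ranking_result")
}

#' CMC value at rank k
#'
#' Fraction of queries whose top-k ranked gallery items contain at least one
#' item with the query's identity.
#'
#' @param rankings List of [rank_gallery()] results carrying `query_label`.
#' @param k Rank cutoff (>= 1).
#' @return Value in `[0, 1]`.
#' @export
cmc_at_k <- function(rankings, k) {
  stopifnot(k >= 1)
  hits <- vapply(rankings, function(r) {
    kk <- min(k, length(r$labels))
    any(r$labels[seq_len(kk)] == r$query_label)
  }, logical(1))
  mean(hits)
}

#' Mean average precision over a set of rankings
#'
#' Per query, AP is the mean over its relevant gallery items of the
#' precision at the rank of each relevant item (the usual re-identification
#' convention, not 11-point interpolation); mAP is the mean AP over queries.
#' Queries with no same-identity gallery item are excluded with a warning;
#' the excluded count is attached as attribute `"n_excluded"`.
#'
#' @param rankings List of [rank_gallery()] results carrying `query_label`.
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(rankings) {
  aps <- vapply(rankings, function(r) {
    rel <- which(r$labels == r$query_label)
    if (length(rel) == 0L) return(NA_real_)
    mean(seq_along(rel) / rel)
  }, numeric(1))
  n_excluded <- sum(is.na(aps))
  if (n_excluded > 0L) {
    warning(sprintf("%d quer%s with no relevant gallery item excluded from mAP",
                    n_excluded, if (n_excluded == 1L) "y" else "ies"))
  }
  structure(mean(aps, na.rm = TRUE), n_excluded = n_excluded)
}

# Shared evaluation core over a descriptor matrix (query set = gallery set,
# self-exclusion by index).
evaluate_descriptors <- function(descriptors, labels, image_ids = NULL,
                                 max_k = NULL) {
  g <- gallery_set(descriptors, labels, image_ids)
  rankings <- lapply(seq_len(nrow(g$descriptors)), function(i) {
    rank_gallery(g$descriptors[i, ], g$image_ids[i], g,
                 query_label = g$labels[i])
  })
  max_k <- max_k %||% (nrow(g$descriptors) - 1L)
  cmc <- vapply(seq_len(max_k), function(k) cmc_at_k(rankings, k), numeric(1))
  list(cmc = cmc, rankings = rankings)
}

#' Evaluate query-gallery retrieval
#'
#' Extracts descriptors for the query and gallery sets (which may be the
#' same set: each query then ranks the gallery with its own image excluded),
#' ranks by ascending Euclidean distance, and reports mAP and the full CMC
#' curve.
#'
#' @param model A [reid_model()] (or `NULL` when `query`/`gallery` already
#'   carry `descriptors` matrices).
#' @param query,gallery Lists with `images`, `labels` and optionally `ids`
#'   (unique image keys; shared keys between query and gallery mark the same
#'   physical image, which is excluded from that query's ranking). `gallery`
#'   defaults to the query set.
#' @param feature Retrieval feature passed to [extract_descriptors()].
#' @return List of class `eval_report` with `mAP`, `rank1`, `rank5`, `cmc`
#'   (vector over k), `Q` (number of scored queries) and `n_excluded`.
#' @export
evaluate_reid <- function(model, query, gallery = NULL, feature = NULL) {
  gallery <- gallery %||% query
  qd <- query$descriptors %||% extract_descriptors(model, query$images, feature)
  gd <- if (identical(gallery, query)) qd else {
    gallery$descriptors %||% extract_descriptors(model, gallery$images, feature)
  }
  qids <- query$ids %||% paste0("q", seq_len(nrow(qd)))
  gids <- gallery$ids %||% if (identical(gallery, query)) qids else
    paste0("g", seq_len(nrow(gd)))
  g <- gallery_set(gd, gallery$labels, gids)
  rankings <- lapply(seq_len(nrow(qd)), function(i) {
    rank_gallery(qd[i, ], qids[i], g, query_label = query$labels[i])
  })
  map <- suppressWarnings(mean_average_precision(rankings))
  max_k <- max(vapply(rankings, function(r) length(r$labels), integer(1)))
  cmc <- vapply(seq_len(max_k), function(k) cmc_at_k(rankings, k), numeric(1))
  structure(list(mAP = as.numeric(map),
                 rank1 = cmc[1L],
                 rank5 = cmc[min(5L, max_k)],
                 cmc = cmc,
                 Q = length(rankings) - attr(map, "n_excluded"),
                 n_excluded = attr(map, "n_excluded")),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Retrieval evaluation over %d queries\n", x$Q))
  cat(sprintf("  mAP     %.4f\n  Rank-1  %.4f\n  Rank-5  %.4f\n",
              x$mAP, x$rank1, x$rank5))
  if (x$n_excluded > 0) {
    cat(sprintf("  (%d queries had no relevant gallery item)\n", x$n_excluded))
  }
  invisible(x)
}
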