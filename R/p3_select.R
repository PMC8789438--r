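#' Extract a subject's P3 scalp map
#'
#' Averages the subject's valid aligned target trials, locates the P3 peak as
#' the (first) maximum of the CSP projection of that average, and reads the
#' 16-channel topography at the peak sample.
#'
#' @param aligned An `aligned_trial_set` with labeled trials.
#' @param template The `erp_template` whose filter defines the projection.
#' @param valid_only Use only trials flagged valid (default `TRUE`).
#' @return A `p3_map`: `subject_id`, `topography` (named 16-vector,
#'   microvolts), `peak_sample` (1-based), `peak_latency_ms` (relative to the
#'   aligned window start).
#' @export
extract_p3_map <- function(aligned, template, valid_only = TRUE) {
  keep <- aligned$labels == 1
  if (valid_only) keep <- keep & aligned$validity
  if (!any(keep)) stop("no valid target trials to extract a P3 map from")
  avg <- apply(aligned$trials[keep, , , drop = FALSE], c(2, 3), mean)
  p <- drop(crossprod(template$filter$weights, avg))
  peak <- which.max(p)               # first maximum
  topo <- avg[, peak]
  names(topo) <- aligned$channels
  m <- list(subject_id = aligned$subject_id,
            topography = topo,
            peak_sample = peak,
            peak_latency_ms = (peak - 1) * 1000 / aligned$fs)
  class(m) <- "p3_map"
  m
}

#' Cluster P3 maps into strong and weak groups
#'
#' K-means (Euclidean, `k = 2`, seeded, 10 restarts) on the raw 16-channel
#' topography vectors.  The cluster whose centroid has the larger mean
#' amplitude over the parieto-occipital channels is labeled strong.  If the
#' maps are degenerate (fewer than `k` distinct vectors) all subjects are
#' returned as one strong group and the result is flagged.
#'
#' @param maps List of `p3_map`.
#' @param k Number of clusters (2).
#' @param seed Seed for the K-means restarts.
#' @return List with `strong_ids`, `weak_ids`, `assignment` (named integer),
#'   `degenerate` flag.
#' @export
cluster_p3_maps <- function(maps, k = 2, seed = 1L) {
  if (length(maps) < 2) stop("need at least two maps to cluster")
  x <- t(vapply(maps, function(m) m$topography, numeric(16)))
  rownames(x) <- vapply(maps, function(m) m$subject_id, character(1))
  if (nrow(unique(x)) < k) {
    return(list(strong_ids = rownames(x), weak_ids = character(0),
                assignment = stats::setNames(rep(1L, nrow(x)), rownames(x)),
                degenerate = TRUE))
  }
  set.seed(seed)
  km <- kmeans(x, centers = k, nstart = 10)
  post <- intersect(posterior_channels(), colnames(x))
  strength <- rowMeans(km$centers[, post, drop = FALSE])
  strong_cl <- which.max(strength)
  list(strong_ids = rownames(x)[km$cluster == strong_cl],
       weak_ids = rownames(x)[km$cluster != strong_cl],
       assignment = stats::setNames(km$cluster, rownames(x)),
       degenerate = FALSE)
}

#' Scalar P3 strength of a map
#'
#' Mean topography amplitude over the parietal/parieto-occipital/occipital
#' channels; used to order subjects by P3 strength (descending, ties broken
#' by subject id) when picking the first-m strongest subjects for
#' source-domain size sweeps.
#'
#' @param map A `p3_map`.
#' @return Numeric scalar (microvolts).
#' @export
p3_strength <- function(map) {
  post <- intersect(posterior_channels(), names(map$topography))
  mean(map$topography[post])
}

#' Order subject ids by descending P3 strength
#'
#' @param maps List of `p3_map`.
#' @return Character vector of subject ids, strongest first; ties broken by
#'   subject id.
#' @export
order_by_p3_strength <- function(maps) {
  ids <- vapply(maps, function(m) m$subject_id, character(1))
  s <- vapply(maps, p3_strength, numeric(1))
  ids[order(-s, ids)]
}

#' Pool selected subjects' trials into a labeled source domain
#'
#' Concatenates the valid labeled aligned trials of the selected subjects,
#' ordered by (subject, trial index).
#'
#' @param pool List of `aligned_trial_set`, one per subject.
#' @param ids Subject ids to include (nonempty).
#' @param template The shared `erp_template` (stored with the domain).
#' @return A `source_domain`: `trials` (n x 16 x 100), `labels`,
#'   `subject` (per trial), `member_ids`, `template`.
#' @export
build_source_domain <- function(pool, ids, template = NULL) {
  if (length(ids) == 0) stop("source-domain selection is empty")
  pool_ids <- vapply(pool, function(a) a$subject_id, character(1))
  missing <- setdiff(ids, pool_ids)
  if (length(missing) > 0)
    stop("subjects not in pool: ", paste(missing, collapse = ", "))
  parts <- list(); labs <- list(); subj <- list()
  for (id in ids) {
    a <- pool[[match(id, pool_ids)]]
    keep <- which(a$validity)
    keep <- keep[order(a$trial_index[keep])]
    parts[[id]] <- a$trials[keep, , , drop = FALSE]
    labs[[id]] <- a$labels[keep]
    subj[[id]] <- rep(id, length(keep))
  }
  n <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  d <- dim(parts[[1]])
  trials <- array(NA_real_, c(n, d[2], d[3]))
  at <- 0L
  for (id in ids) {
    k <- dim(parts[[id]])[1]
    if (k > 0) trials[(at + 1):(at + k), , ] <- parts[[id]]
    at <- at + k
  }
  sd <- list(trials = trials,
             labels = unlist(labs, use.names = FALSE),
             subject = unlist(subj, use.names = FALSE),
             member_ids = ids,
             template = template)
  class(sd) <- "source_domain"
  sd
}
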