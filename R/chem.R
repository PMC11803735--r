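#' Molecular fingerprints
#'
#' A fingerprint is a fixed-length binary bit vector with its generation
#' parameters attached. [make_fingerprint()] computes a hashed topological
#' linear-path fingerprint (OpenBabel FP2, paths up to 7 bonds hashed into
#' 1024 bits) from a SMILES string; it is invariant to SMILES
#' canonicalization. Synthetic bit vectors from [gen_fingerprints()] carry
#' the same class.
#'
#' @param bits logical (or 0/1) vector
#' @param params list of generation parameters (at least `n_bits`, `type`)
#' @return A `fingerprint` (logical vector with attributes).
#' @export
fingerprint <- function(bits, params = list(n_bits = length(bits), type = "raw")) {
  structure(as.logical(bits), params = params, class = "fingerprint")
}

#' @rdname fingerprint
#' @param smiles a SMILES string
#' @param id compound id, used in error messages
#' @export
make_fingerprint <- function(smiles, id = smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("unparseable SMILES for compound '", id, "': ",
                             smiles, call. = FALSE)
  )
  # single-atom molecules have no bond paths: FP2 is empty by definition,
  # and the SDF->OBMol conversion cannot represent them
  if (nrow(ChemmineR::atomblock(sdf[[1]])) < 2L) {
    return(fingerprint(rep(FALSE, 1024L),
                       params = list(n_bits = 1024L, type = "FP2",
                                     max_path_bonds = 7L)))
  }
  fps <- suppressWarnings(ChemmineR::fingerprintOB(sdf, "FP2"))
  bits <- fps[[1]]@fp
  fingerprint(bits != 0,
              params = list(n_bits = length(bits), type = "FP2",
                            max_path_bonds = 7L))
}

#' Tanimoto similarity between two fingerprints
#'
#' `|a AND b| / |a OR b|`; defined as 1 when both vectors are empty (two
#' featureless molecules are identical for triage purposes).
#'
#' @param a,b fingerprints (or logical vectors) of equal length
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' All-pairs Tanimoto similarity matrix
#' @param fps named list of fingerprints (equal lengths)
#' @return symmetric similarity matrix
#' @export
tanimoto_matrix <- function(fps) {
  m <- do.call(rbind, lapply(fps, as.numeric))
  inter <- tcrossprod(m)
  pop <- rowSums(m)
  uni <- outer(pop, pop, "+") - inter
  s <- ifelse(uni == 0, 1, inter / uni)
  rownames(s) <- colnames(s) <- names(fps) %||% as.character(seq_along(fps))
  s
}

#' Threshold clustering of compounds by Tanimoto similarity
#'
#' Average-linkage hierarchical clustering on distance `1 - Tanimoto`, with
#' the tree cut at distance `1 - threshold`: compounds sharing a cluster are
#' those merged at similarity >= threshold (default 0.45). Cluster labels
#' are canonicalized by each cluster's lexicographically smallest member id,
#' so the assignment is invariant to input order.
#'
#' @param fps named list of fingerprints
#' @param threshold similarity threshold defining clusters (default 0.45)
#' @param linkage hclust method: "average" (default), "single" or "complete"
#' @return list: `cluster` (named integer vector, labels 1..k in order of
#'   smallest member id), `k`, `tree` (hclust, NULL for a single compound),
#'   `threshold`, `similarity` (matrix).
#' @export
cluster_compounds <- function(fps, threshold = 0.45,
                              linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (length(fps) == 0L) stop("need at least one fingerprint")
  s <- tanimoto_matrix(fps)
  ids <- rownames(s)
  if (length(fps) == 1L) {
    cl <- stats::setNames(1L, ids)
    return(list(cluster = cl, k = 1L, tree = NULL,
                threshold = threshold, similarity = s))
  }
  tree <- stats::hclust(stats::as.dist(1 - s), method = linkage)
  raw <- stats::cutree(tree, h = 1 - threshold)
  # canonicalize labels by smallest member id
  firsts <- vapply(split(ids, raw), min, character(1))
  ord <- order(firsts)
  relabel <- integer(length(firsts))
  relabel[ord] <- seq_along(ord)
  cl <- stats::setNames(relabel[raw], ids)
  list(cluster = cl, k = max(cl), tree = tree,
       threshold = threshold, similarity = s)
}

#' Pick one representative compound per cluster
#'
#' The representative is the cluster medoid: the member with maximal mean
#' intra-cluster Tanimoto similarity, ties broken by lexicographic compound
#' id. Singleton clusters return their sole member.
#'
#' @param assignment result of [cluster_compounds()]
#' @param fps the fingerprints that were clustered (used if the assignment
#'   lacks a similarity matrix)
#' @return data.frame: `cluster`, `compound_id`, `n_members`,
#'   `mean_similarity`.
#' @export
pick_representatives <- function(assignment, fps = NULL) {
  s <- assignment$similarity
  if (is.null(s)) s <- tanimoto_matrix(fps)
  cl <- assignment$cluster
  rows <- lapply(sort(unique(cl)), function(k) {
    members <- sort(names(cl)[cl == k])
    if (length(members) == 1L) {
      return(data.frame(cluster = k, compound_id = members, n_members = 1L,
                        mean_similarity = 1, stringsAsFactors = FALSE))
    }
    sub <- s[members, members, drop = FALSE]
    mean_sim <- (rowSums(sub) - 1) / (length(members) - 1L)
    best <- members[which.max(mean_sim)]  # which.max takes first => lexicographic tie-break
    data.frame(cluster = k, compound_id = best, n_members = length(members),
               mean_similarity = unname(mean_sim[best]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
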