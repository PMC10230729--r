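# Bacteriocin grouping: all-versus-all normalized bit-score similarity and
# single-linkage clustering at a 0.95 threshold.

#' Normalized bit-score similarity of two proteins
#'
#' Computed as `2 * S(A,B) / (S(A,A) + S(B,B))` where `S` are local-alignment
#' bit scores; identical sequences give exactly 1.0. `S(A,B)` is symmetrized
#' as the maximum of the two alignment orderings (identical for symmetric
#' substitution matrices).
#'
#' @param a,b Non-empty protein sequences.
#' @param params A [scoring_params()] object.
#' @return List: `s_ab`, `s_aa`, `s_bb` (bit scores) and `similarity`.
#' @export
pairwise_similarity <- function(a, b, params = scoring_params()) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  s_aa <- bit_score(align_protein(a, a, params)$score, params)
  s_bb <- bit_score(align_protein(b, b, params)$score, params)
  if (s_aa + s_bb <= 0)
    stop("degenerate sequences with non-positive self-alignment bit scores")
  s_ab <- bit_score(max(align_protein(a, b, params)$score,
                        align_protein(b, a, params)$score), params)
  list(s_ab = s_ab, s_aa = s_aa, s_bb = s_bb,
       similarity = 2 * s_ab / (s_aa + s_bb))
}

#' All-versus-all similarity table for a protein set
#'
#' @param proteins Named character vector of proteins (names are ids; only the
#'   first whitespace-delimited token is kept).
#' @param params A [scoring_params()] object.
#' @return Data frame: id_a, id_b, s_ab, s_aa, s_bb, similarity for all
#'   unordered pairs (a < b in input order).
#' @export
similarity_table <- function(proteins, params = scoring_params()) {
  ids <- sub("\\s.*$", "", names(proteins))
  n <- length(proteins)
  self_bits <- vapply(proteins, function(p)
    bit_score(align_protein(p, p, params)$score, params), 0)
  rows <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    s_ab <- bit_score(max(align_protein(proteins[[i]], proteins[[j]], params)$score,
                          align_protein(proteins[[j]], proteins[[i]], params)$score),
                      params)
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = ids[i], id_b = ids[j], s_ab = s_ab,
      s_aa = self_bits[i], s_bb = self_bits[j],
      similarity = 2 * s_ab / (self_bits[i] + self_bits[j]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(id_a = character(), id_b = character(), s_ab = numeric(),
                      s_aa = numeric(), s_bb = numeric(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Cluster bacteriocins by similarity threshold
#'
#' Single-linkage clustering: clusters are the connected components of the
#' graph whose edges are pairs with similarity at or above the threshold.
#' Pairs missing from the table are treated as below threshold. Cluster ids
#' are deterministic (the smallest member id); the representative is the
#' member with the smallest enrichment q-value when `q_values` is supplied,
#' otherwise the smallest id.
#'
#' @param similarities Data frame from [similarity_table()] (columns id_a,
#'   id_b, similarity).
#' @param ids All protein ids to assign (singletons included even without
#'   pairs); defaults to the ids present in `similarities`.
#' @param threshold Similarity threshold (default 0.95).
#' @param q_values Optional named vector of enrichment q-values used to pick
#'   cluster representatives.
#' @return Data frame: id, cluster, representative.
#' @export
cluster_bacteriocins <- function(similarities, ids = NULL, threshold = 0.95,
                                 q_values = NULL) {
  if (is.null(ids)) ids <- sort(unique(c(similarities$id_a, similarities$id_b)))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  keep <- similarities$similarity >= threshold
  if (any(keep)) {
    edges <- rbind(similarities$id_a[keep], similarities$id_b[keep])
    g <- igraph::add_edges(g, as.vector(edges))
  }
  comp <- igraph::components(g)$membership
  cluster_of <- vapply(split(ids, comp), function(members) min(members), "")
  cluster <- cluster_of[as.character(comp)]
  rep_of <- vapply(split(ids, comp), function(members) {
    if (!is.null(q_values) && any(members %in% names(q_values))) {
      qv <- q_values[members]
      qv[is.na(qv)] <- Inf
      members[order(qv, members)][1L]
    } else min(members)
  }, "")
  data.frame(id = ids, cluster = unname(cluster),
             representative = unname(rep_of[as.character(comp)]),
             stringsAsFactors = FALSE)
}
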