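# Screening a genome collection for clustered bacteriocins and per-taxon
# genome-fraction profiles.

#' Screen a genome collection for clustered bacteriocins
#'
#' A cluster is present in a genome if any of its member proteins hits the
#' genome with an E-value below the threshold (via [search_sequences()]);
#' presence is boolean, so multiple member hits are not double-counted.
#'
#' @param genomes Named character vector of genome sequences.
#' @param clusters Cluster assignment from [cluster_bacteriocins()] (columns
#'   id, cluster).
#' @param db Named character vector of bacteriocin proteins whose ids match
#'   `clusters$id`.
#' @param taxonomy Data frame with a `genome_id` column covering the genomes;
#'   genomes without a taxonomy entry are excluded with a warning.
#' @param params A [scoring_params()] object.
#' @return Logical genome x cluster presence matrix.
#' @export
screen_collection <- function(genomes, clusters, db, taxonomy,
                              params = scoring_params()) {
  ids <- db_ids(db)
  keep <- names(genomes) %in% taxonomy$genome_id
  if (!all(keep)) {
    warning("excluding genomes without taxonomy: ",
            paste(names(genomes)[!keep], collapse = ", "))
    genomes <- genomes[keep]
  }
  cluster_ids <- sort(unique(clusters$cluster))
  pres <- matrix(FALSE, nrow = length(genomes), ncol = length(cluster_ids),
                 dimnames = list(names(genomes), cluster_ids))
  if (length(cluster_ids) == 0L || length(genomes) == 0L) return(pres)
  member_db <- db[ids %in% clusters$id]
  if (length(member_db) > 0L) {
    hits <- search_sequences(genomes, member_db, params)
    if (nrow(hits) > 0L) {
      hit_cluster <- clusters$cluster[match(hits$subject_id, clusters$id)]
      for (r in seq_len(nrow(hits)))
        pres[hits$query_id[r], hit_cluster[r]] <- TRUE
    }
  }
  pres
}

#' Per-taxon genome-fraction profile for each bacteriocin cluster
#'
#' For a given cluster and taxon, the profile value is the fraction of that
#' taxon's genomes having at least one hit against the cluster. The rendered
#' profile drops taxa whose fraction is at or below `report_min`; the full
#' table is always returned.
#'
#' @param presence Genome x cluster logical matrix from [screen_collection()].
#' @param taxonomy Taxonomy table (genome_id, species, genus, family, class).
#' @param rank `"species"` or `"genus"`.
#' @param report_min Display cutoff for the rendered profile (default 0.01).
#' @return List with `full` (data frame: cluster, taxon, n_genomes,
#'   n_hit, fraction) and `rendered` (rows with fraction > report_min, taxa
#'   ordered by taxonomic class then name).
#' @export
taxon_profile <- function(presence, taxonomy, rank = c("species", "genus"),
                          report_min = 0.01) {
  rank <- match.arg(rank)
  taxon <- taxonomy[[rank]][match(rownames(presence), taxonomy$genome_id)]
  cls <- taxonomy$class[match(rownames(presence), taxonomy$genome_id)]
  taxon_class <- vapply(split(cls, taxon), function(x) x[1L], "")
  rows <- list()
  for (cl in colnames(presence)) {
    hit <- tapply(presence[, cl], taxon, sum)
    tot <- tapply(rep(1L, nrow(presence)), taxon, sum)
    rows[[cl]] <- data.frame(
      cluster = cl, taxon = names(hit), n_genomes = as.integer(tot),
      n_hit = as.integer(hit), fraction = as.numeric(hit / tot),
      stringsAsFactors = FALSE)
  }
  full <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(), taxon = character(), n_genomes = integer(),
               n_hit = integer(), fraction = numeric(), stringsAsFactors = FALSE)
  rownames(full) <- NULL
  rendered <- full[full$fraction > report_min, , drop = FALSE]
  rendered <- rendered[order(taxon_class[rendered$taxon], rendered$taxon), ,
                       drop = FALSE]
  rownames(rendered) <- NULL
  list(full = full, rendered = rendered, rank = rank)
}

#' Rank species by bacteriocin prevalence and pick the associated species
#'
#' Species are sorted by their genome-fraction for the cluster (descending),
#' ties broken by genome count (descending) then name. The top species is the
#' cluster's associated species for the strain-diversity analysis.
#'
#' @param profile Output of [taxon_profile()] at species rank.
#' @param cluster_id Cluster to rank.
#' @return Data frame of species with fraction > 0, sorted; zero rows when the
#'   profile is all zero. The first row is the associated species.
#' @export
associated_species <- function(profile, cluster_id) {
  stopifnot(identical(profile$rank, "species"))
  tab <- profile$full[profile$full$cluster == cluster_id & profile$full$fraction > 0, ,
                      drop = FALSE]
  tab <- tab[order(-tab$fraction, -tab$n_genomes, tab$taxon), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
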