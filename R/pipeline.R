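# Pipeline orchestration: run every stage under one configuration with
# structured logging, a run manifest with file digests, and a report document.

#' Pipeline run configuration
#'
#' Bundles either a [synthetic_config()] (the simulate stage then generates
#' all inputs) or paths to existing inputs, together with the analysis
#' thresholds: E-value cutoff 1e-5, enrichment q cutoff 0.01, minimum infant
#' prevalence 0.10, clustering similarity 0.95, rarefaction depth (for
#' synthetic runs the sample read count; 1e6 otherwise), profile display
#' cutoff 0.01, and operon window flank 10,000 bp.
#'
#' @param outdir Output directory for all stage files.
#' @param synthetic A [synthetic_config()], or `NULL` when `inputs` is given.
#' @param inputs Named list of paths (reads_dir, metadata, db, genomes_dir or
#'   genomes, taxonomy, optionally contigs and reference_proteins); validated
#'   at run time.
#' @param params A [scoring_params()] object (E-value threshold lives here).
#' @param q_threshold,min_prevalence Enrichment thresholds.
#' @param similarity_threshold Clustering threshold.
#' @param rarefaction_depth Reads per sample after rarefaction; `NULL` picks
#'   the synthetic sample depth (or 1e6 for file inputs).
#' @param report_min Taxon-profile display cutoff.
#' @param flank Operon window flank (bp).
#' @param k K-mer size for the classifier index.
#' @param seed Integer seed for all stochastic stages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(outdir, synthetic = synthetic_config(), inputs = NULL,
                       params = scoring_params(), q_threshold = 0.01,
                       min_prevalence = 0.10, similarity_threshold = 0.95,
                       rarefaction_depth = NULL, report_min = 0.01,
                       flank = 10000L, k = 31L, seed = NULL) {
  stopifnot(xor(is.null(synthetic), is.null(inputs)))
  if (!is.null(inputs)) {
    missing <- !vapply(inputs, file.exists, TRUE)
    if (any(missing))
      stop("input paths do not exist: ",
           paste(unlist(inputs[missing]), collapse = ", "))
  }
  if (is.null(rarefaction_depth))
    rarefaction_depth <- if (!is.null(synthetic)) synthetic$reads_per_sample else 1000000L
  if (is.null(seed)) seed <- if (!is.null(synthetic)) synthetic$seed else 1L
  thresholds <- c(evalue = params$evalue_threshold, q = q_threshold,
                  min_prevalence = min_prevalence,
                  similarity = similarity_threshold,
                  depth = rarefaction_depth, report_min = report_min,
                  flank = flank)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  structure(list(outdir = outdir, synthetic = synthetic, inputs = inputs,
                 params = params, q_threshold = q_threshold,
                 min_prevalence = min_prevalence,
                 similarity_threshold = similarity_threshold,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 report_min = report_min, flank = as.integer(flank),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "run_config")
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config[setdiff(names(config), "outdir")])), tmp)
  unname(tools::md5sum(tmp))
}

#' @noRd
stage_log <- function(stage, ...) {
  message(sprintf("[bacmine] stage=%s %s", stage, paste0(..., collapse = " ")))
}

#' @noRd
digest_files <- function(paths, outdir) {
  d <- tools::md5sum(paths)
  rel <- sub(paste0("^", normalizePath(outdir, mustWork = FALSE), "/?"), "",
             normalizePath(paths, mustWork = FALSE))
  stats::setNames(unname(d), rel)
}

#' Run the full bacteriocin mining pipeline
#'
#' Executes the stages simulate (or ingest), search, enrich, cluster, screen,
#' profile, diversity and operon in dependency order, writing each stage's
#' tables under `config$outdir` and recording file digests in a manifest.
#' Re-running a completed run directory with an unchanged configuration
#' performs no recomputation unless `force = TRUE`. The returned report
#' carries the abundance-by-age-group summary, the enrichment table, the
#' cluster map, taxon profiles, the per-cluster diversity fits, and the
#' operon table.
#'
#' @param config A [run_config()].
#' @param force Recompute even when a manifest with the same configuration
#'   hash exists.
#' @return List (class `bacmine_run`) with `manifest` and `report`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_path <- file.path(outdir, "manifest.json")
  report_path <- file.path(outdir, "report.rds.txt")
  if (!force && file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    files <- unlist(unname(lapply(old$stages, function(s) s$digests)))
    paths <- file.path(outdir, names(files))
    if (identical(old$config_hash, unname(hash)) && all(file.exists(paths)) &&
        identical(unname(tools::md5sum(paths)), unname(files))) {
      stage_log("manifest", "unchanged config; reusing completed run")
      report <- if (file.exists(file.path(outdir, "report.md")))
        readLines(file.path(outdir, "report.md")) else NULL
      return(invisible(structure(list(manifest = old, report = report),
                                 class = "bacmine_run")))
    }
  }
  stages <- list()
  add_stage <- function(name, files) {
    stages[[name]] <<- list(name = name,
                            digests = as.list(digest_files(files, outdir)),
                            time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    stage_log(name, "done:", length(files), "output file(s)")
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  params <- config$params

  # --- stage 1: simulate or ingest ------------------------------------------
  syn <- config$synthetic
  if (!is.null(syn)) {
    run_stage("simulate", {
      db <- make_bacteriocin_db(syn)
      collection <- make_genome_collection(syn, db)
      sim <- simulate_metagenomes(syn, collection, outdir = file.path(outdir, "reads"))
      write_fasta(db$proteins, file.path(outdir, "bacteriocins.faa"))
      write_fasta(collection$genomes, file.path(outdir, "genomes.fasta"))
      write_tsv(collection$taxonomy, file.path(outdir, "taxonomy.tsv"))
      write_tsv(collection$truth$carriage, file.path(outdir, "truth_carriage.tsv"))
      metadata <- sim$metadata
      samples <- sim$samples
      # synthetic contigs: neighborhoods cut from up to 3 carrier genomes,
      # standing in for metagenome assemblies of high-abundance samples
      carr <- collection$truth$carriage
      contigs <- character(0)
      if (nrow(carr) > 0L) {
        pick <- carr[!duplicated(carr$genome_id), , drop = FALSE]
        pick <- pick[seq_len(min(3L, nrow(pick))), , drop = FALSE]
        for (i in seq_len(nrow(pick))) {
          g <- collection$genomes[[pick$genome_id[i]]]
          ws <- max(0L, pick$start[i] - 2000L)
          we <- min(nchar(g), pick$end[i] + 2000L)
          contigs[sprintf("contig%02d src=%s", i, pick$genome_id[i])] <-
            substr(g, ws + 1L, we)
        }
        write_fasta(contigs, file.path(outdir, "contigs.fasta"))
      }
      # reference set for the operon scan: cluster base proteins as the
      # bacteriocin category plus decoy immunity/secretion references
      ref <- withr::with_seed(config$seed + 505L, {
        decoys <- vapply(c(80L, 110L), function(len)
          paste0(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = ""), "")
        c(db$proteins[grepl("_v1 ", names(db$proteins))],
          stats::setNames(decoys, c("ref_imm category=immunity",
                                    "ref_sec category=secretion")))
      })
      names(ref) <- sub("class=", "category=bacteriocin class=", names(ref))
      write_fasta(ref, file.path(outdir, "reference_proteins.faa"))
      db_seqs <- db$proteins
      genomes <- collection$genomes
      taxonomy <- collection$taxonomy
      add_stage("simulate", c(file.path(outdir, "bacteriocins.faa"),
                              file.path(outdir, "genomes.fasta"),
                              file.path(outdir, "taxonomy.tsv"),
                              file.path(outdir, "reads", "metadata.tsv")))
    })
  } else {
    run_stage("simulate", {
      inp <- config$inputs
      db_seqs <- read_fasta(inp$db)
      genomes <- if (!is.null(inp$genomes)) read_fasta(inp$genomes) else {
        files <- list.files(inp$genomes_dir, full.names = TRUE)
        do.call(c, lapply(files, read_fasta))
      }
      taxonomy <- read_tsv(inp$taxonomy)
      metadata <- read_tsv(inp$metadata)
      rfiles <- file.path(inp$reads_dir, paste0(metadata$sample_id, ".fastq"))
      samples <- lapply(rfiles, read_reads)
      names(samples) <- metadata$sample_id
      contigs <- if (!is.null(inp$contigs)) read_fasta(inp$contigs) else character(0)
      ref <- if (!is.null(inp$reference_proteins)) read_fasta(inp$reference_proteins)
             else character(0)
      add_stage("simulate", c(inp$db, inp$taxonomy, inp$metadata))
    })
  }

  # --- stage 2: translated search and abundance -----------------------------
  run_stage("search", {
    results <- lapply(samples, search_reads, db = db_seqs, params = params)
    abund <- abundance_matrix(results)
    abund_df <- data.frame(sample_id = rownames(abund$fractions),
                           total_reads = abund$total_reads,
                           unique_reads = abund$unique_reads,
                           abundance = abund$abundance,
                           abund$class_fractions, abund$fractions,
                           check.names = FALSE)
    write_tsv(abund_df, file.path(outdir, "abundance.tsv"))
    add_stage("search", file.path(outdir, "abundance.tsv"))
  })

  # --- stage 3: enrichment ---------------------------------------------------
  run_stage("enrich", {
    enrichment <- enrich_bacteriocins(abund, metadata,
                                      q_threshold = config$q_threshold,
                                      min_prevalence = config$min_prevalence)
    write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))
    ages <- assign_age_groups(metadata)
    grp <- ages$group[match(names(abund$abundance), ages$sample_id)]
    age_summary <- data.frame(
      group = names(AGE_GROUP_RANGES),
      n = as.integer(table(factor(grp, levels = names(AGE_GROUP_RANGES)))),
      median_abundance = vapply(names(AGE_GROUP_RANGES), function(g)
        if (any(grp == g)) stats::median(abund$abundance[grp == g]) else NA_real_, 0),
      p_vs_infant = vapply(names(AGE_GROUP_RANGES), function(g) {
        if (g == "infant" || !any(grp == g) || !any(grp == "infant")) return(NA_real_)
        rank_sum_test(abund$abundance[grp == "infant"], abund$abundance[grp == g])
      }, 0), stringsAsFactors = FALSE)
    write_tsv(age_summary, file.path(outdir, "age_summary.tsv"))
    add_stage("enrich", c(file.path(outdir, "enrichment.tsv"),
                          file.path(outdir, "age_summary.tsv")))
  })

  # --- stage 4: clustering of enriched bacteriocins --------------------------
  run_stage("cluster", {
    enriched_ids <- enrichment$bacteriocin[enrichment$tier != "excluded"]
    ids <- sub("\\s.*$", "", names(db_seqs))
    sel <- db_seqs[ids %in% enriched_ids]
    names(sel) <- sub("\\s.*$", "", names(sel))
    if (length(sel) > 0L) {
      sims <- similarity_table(sel, params)
      qv <- stats::setNames(enrichment$q_value, enrichment$bacteriocin)
      clusters <- cluster_bacteriocins(sims, ids = names(sel),
                                       threshold = config$similarity_threshold,
                                       q_values = qv)
    } else {
      sims <- similarity_table(character(0), params)
      clusters <- data.frame(id = character(), cluster = character(),
                             representative = character(), stringsAsFactors = FALSE)
    }
    write_tsv(sims, file.path(outdir, "similarity_pairs.tsv"))
    write_tsv(clusters, file.path(outdir, "clusters.tsv"))
    add_stage("cluster", c(file.path(outdir, "similarity_pairs.tsv"),
                           file.path(outdir, "clusters.tsv")))
  })

  # --- stage 5: genome screen -------------------------------------------------
  run_stage("screen", {
    presence <- screen_collection(genomes, clusters, db_seqs, taxonomy, params)
    pres_df <- data.frame(genome_id = rownames(presence), presence,
                          check.names = FALSE)
    write_tsv(pres_df, file.path(outdir, "genome_presence.tsv"))
    prof_species <- taxon_profile(presence, taxonomy, "species", config$report_min)
    prof_genus <- taxon_profile(presence, taxonomy, "genus", config$report_min)
    write_tsv(prof_species$full, file.path(outdir, "profile_species.tsv"))
    write_tsv(prof_genus$full, file.path(outdir, "profile_genus.tsv"))
    add_stage("screen", c(file.path(outdir, "genome_presence.tsv"),
                          file.path(outdir, "profile_species.tsv"),
                          file.path(outdir, "profile_genus.tsv")))
  })

  # --- stage 6: k-mer classification and community profile --------------------
  run_stage("profile", {
    index <- build_index(genomes, taxonomy, k = config$k)
    classifications <- lapply(samples, classify_reads, index = index)
    ages <- assign_age_groups(metadata)
    groups <- stats::setNames(ages$group, ages$sample_id)
    profile <- community_profile(classifications, taxonomy, groups = groups)
    shannon_df <- data.frame(sample_id = names(profile$shannon),
                             shannon = profile$shannon,
                             assigned = rowSums(profile$counts))
    write_tsv(shannon_df, file.path(outdir, "shannon.tsv"))
    if (!is.null(profile$pca))
      write_tsv(data.frame(sample_id = rownames(profile$pca), profile$pca),
                file.path(outdir, "pca.tsv"))
    write_tsv(data.frame(sample_id = rownames(profile$counts), profile$counts,
                         check.names = FALSE),
              file.path(outdir, "species_counts.tsv"))
    add_stage("profile", c(file.path(outdir, "shannon.tsv"),
                           file.path(outdir, "species_counts.tsv")))
  })

  # --- stage 7: strain diversity ----------------------------------------------
  run_stage("diversity", {
    ages <- assign_age_groups(metadata)
    infant_ids <- ages$sample_id[ages$superclass == "infant-like"]
    rarefied <- list()
    for (i in seq_along(infant_ids)) {
      sid <- infant_ids[i]
      rarefied[[sid]] <- suppressWarnings(
        rarefy(classifications[[sid]], depth = config$rarefaction_depth,
               seed = config$seed + i))
    }
    fits <- list()
    cluster_ids <- unique(clusters$cluster)
    prof <- taxon_profile(presence, taxonomy, "species", config$report_min)
    for (cl in cluster_ids) {
      members <- clusters$id[clusters$cluster == cl]
      pres_vec <- rowSums(abund$fractions[, members, drop = FALSE]) > 0
      assoc <- associated_species(prof, cl)
      if (nrow(assoc) == 0L) next
      sp <- assoc$taxon[1L]
      rec <- diversity_records(rarefied, sp, taxonomy,
                               stats::setNames(pres_vec, rownames(abund$fractions)))
      fit <- tryCatch(fit_covariance_model(rec), error = function(e) NULL)
      fits[[cl]] <- data.frame(
        cluster = cl, species = sp, n = nrow(rec),
        n_species_genomes = assoc$n_genomes[1L],
        b0 = if (is.null(fit)) NA_real_ else fit$b0,
        a0 = if (is.null(fit)) NA_real_ else fit$a0,
        b1 = if (is.null(fit)) NA_real_ else fit$b1,
        se_a0 = if (is.null(fit)) NA_real_ else fit$se[["a0"]],
        p_a0 = if (is.null(fit)) NA_real_ else fit$p_a0,
        low_resolution = assoc$n_genomes[1L] < 4L,
        stringsAsFactors = FALSE)
    }
    diversity <- if (length(fits)) do.call(rbind, fits) else
      data.frame(cluster = character(), species = character(), n = integer(),
                 n_species_genomes = integer(), b0 = numeric(), a0 = numeric(),
                 b1 = numeric(), se_a0 = numeric(), p_a0 = numeric(),
                 low_resolution = logical(), stringsAsFactors = FALSE)
    rownames(diversity) <- NULL
    write_tsv(diversity, file.path(outdir, "diversity.tsv"))
    add_stage("diversity", file.path(outdir, "diversity.tsv"))
  })

  # --- stage 8: operon scan ----------------------------------------------------
  run_stage("operon", {
    operon <- if (length(contigs) > 0L && length(ref) > 0L && nrow(clusters) > 0L) {
      operon_scan(contigs, clusters, db_seqs, ref, params, flank = config$flank)
    } else {
      data.frame(contig_id = character(), cluster = character(),
                 start = integer(), end = integer(), strand = character(),
                 evalue = numeric(), bacteriocin = character(),
                 immunity = character(), secretion = character(),
                 stringsAsFactors = FALSE)
    }
    write_tsv(operon, file.path(outdir, "operon.tsv"))
    add_stage("operon", file.path(outdir, "operon.tsv"))
  })

  # --- report and manifest -----------------------------------------------------
  report <- c(
    "# bacmine run report",
    sprintf("config hash: %s", hash),
    sprintf("stages completed: %s", paste(names(stages), collapse = ", ")),
    "", "## Bacteriocin gene abundance by age group",
    utils::capture.output(print(age_summary, row.names = FALSE)),
    "", "## Enriched bacteriocins",
    utils::capture.output(print(
      enrichment[enrichment$tier != "excluded", , drop = FALSE], row.names = FALSE)),
    "", sprintf("## Clusters (%d)", length(unique(clusters$cluster))),
    utils::capture.output(print(clusters, row.names = FALSE)),
    "", "## Strain-diversity fits",
    utils::capture.output(print(diversity, row.names = FALSE)),
    "", "## Operon scan",
    utils::capture.output(print(operon, row.names = FALSE)))
  writeLines(report, file.path(outdir, "report.md"))
  manifest <- list(config_hash = unname(hash),
                   package_version = as.character(utils::packageVersion("bacmine")),
                   n_stages = length(stages),
                   stages = stages)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(structure(list(manifest = manifest, report = report,
                           tables = list(abundance = abund_df,
                                         enrichment = enrichment,
                                         age_summary = age_summary,
                                         clusters = clusters,
                                         diversity = diversity,
                                         operon = operon)),
                      class = "bacmine_run"))
}

#' @export
print.bacmine_run <- function(x, ...) {
  cat(sprintf("bacmine run: %d stages completed (config %s)\n",
              x$manifest$n_stages, substr(x$manifest$config_hash, 1, 8)))
  invisible(x)
}
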